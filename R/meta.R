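#' Restricted maximum likelihood estimate of between-study variance
#'
#' Estimates the between-study variance tau^2 of the random/mixed-effects
#' model `y_i = x_i' beta + u_i + e_i`, `u_i ~ N(0, tau^2)`,
#' `e_i ~ N(0, v_i)`, by maximising the restricted log-likelihood
#'
#' `l_R(tau^2) = -1/2 [ sum log(v_i + tau^2) + log |X' W X| + y' P y ]`
#'
#' with `W = diag(1/(v_i + tau^2))` and
#' `P = W - W X (X' W X)^{-1} X' W`, via Fisher scoring
#' (score `= 1/2 (y'PPy - tr(P))`, expected information `= 1/2 tr(P^2)`).
#' Iterates are truncated at zero; convergence when the step falls below
#' `tol` (default 1e-8) within `max_iter` iterations (a warning is issued
#' and the last iterate returned otherwise).
#'
#' @param y effect estimates (length k).
#' @param v sampling variances (> 0).
#' @param X design matrix (default intercept-only); k must exceed its
#'   column count.
#' @param tol,max_iter convergence control.
#' @return tau^2 (scalar, >= 0) with attributes `iterations` and
#'   `converged`.
#' @export
reml_tau2 <- function(y, v, X = NULL, tol = 1e-8, max_iter = 100L) {
  k <- length(y)
  if (is.null(X)) X <- matrix(1, k, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(v) != k) stop("reml_tau2: y and v lengths differ")
  if (any(v <= 0)) stop("reml_tau2: all sampling variances must be > 0")
  if (k <= p) stop("reml_tau2: need more studies (k=", k,
                   ") than design columns (p=", p, ")")
  # method-of-moments style start
  w0 <- 1 / v
  b0 <- solve(crossprod(X, X * w0), crossprod(X, y * w0))
  r0 <- y - X %*% b0
  tau2 <- max(0, sum(w0 * r0^2) / sum(w0) - mean(v))
  conv <- FALSE; it <- 0L
  ll <- restricted_loglik(tau2, y, v, X)
  for (it in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    WX <- X * w
    XtWX_inv <- solve(crossprod(X, WX))
    # P y and diagonal pieces without forming P densely is possible, but
    # k is small (tens of cohorts): form P directly for clarity
    P <- diag(w, k) - WX %*% XtWX_inv %*% t(WX)
    Py <- P %*% y
    score <- 0.5 * (sum(Py^2) - sum(diag(P)))
    info <- 0.5 * sum(P * P)
    if (info <= 0) break
    step <- score / info
    # step-halving keeps the restricted likelihood monotone (guards against
    # Fisher-scoring oscillation near the boundary)
    new <- max(0, tau2 + step)
    ll_new <- restricted_loglik(new, y, v, X)
    h <- 0L
    while (ll_new < ll && h < 20L) {
      step <- step / 2
      new <- max(0, tau2 + step)
      ll_new <- restricted_loglik(new, y, v, X)
      h <- h + 1L
    }
    if (abs(new - tau2) < tol || abs(ll_new - ll) < 1e-10 * (1 + abs(ll))) {
      tau2 <- new; conv <- TRUE; break
    }
    tau2 <- new; ll <- ll_new
  }
  if (!conv && it >= max_iter) {
    # Fisher scoring can cycle on extremely flat likelihoods; fall back to
    # bisection on the (monotone-decreasing) restricted score
    sc <- function(t) {
      w <- 1 / (v + t)
      WX <- X * w
      P <- diag(w, k) - WX %*% solve(crossprod(X, WX)) %*% t(WX)
      0.5 * (sum((P %*% y)^2) - sum(diag(P)))
    }
    if (sc(0) <= 0) {
      tau2 <- 0; conv <- TRUE
    } else {
      hi <- max(tau2, 1)
      tries <- 0L
      while (sc(hi) > 0 && tries < 60L) { hi <- hi * 2; tries <- tries + 1L }
      if (sc(hi) <= 0) {
        lo <- 0
        for (b in 1:200) {
          mid <- (lo + hi) / 2
          if (sc(mid) > 0) lo <- mid else hi <- mid
          if (hi - lo < tol) break
        }
        tau2 <- (lo + hi) / 2; conv <- TRUE
      }
    }
  }
  if (!conv) {
    warning("reml_tau2: not converged after ", max_iter,
            " iterations; returning last iterate")
  }
  structure(tau2, iterations = it, converged = conv)
}

#' Restricted log-likelihood of the random/mixed-effects model
#'
#' `-1/2 [ sum log(v_i + tau^2) + log |X' W X| + y' P y ]` (additive
#' constants dropped); the objective maximised by [reml_tau2()].
#'
#' @inheritParams reml_tau2
#' @param tau2 candidate between-study variance (>= 0).
#' @return scalar log-likelihood value.
#' @export
restricted_loglik <- function(tau2, y, v, X = NULL) {
  k <- length(y)
  if (is.null(X)) X <- matrix(1, k, 1)
  X <- as.matrix(X)
  w <- 1 / (v + tau2)
  WX <- X * w
  XtWX <- crossprod(X, WX)
  b <- solve(XtWX, crossprod(WX, y))
  r <- y - X %*% b
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX)$modulus[1] + sum(w * r^2))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum (1/v_i) (y_i - yhat_i)^2` with fitted values from the
#' inverse-variance-weighted fixed-effect fit of `y` on `X`;
#' `df = k - p`; p-value from the upper chi-square tail.
#'
#' @inheritParams reml_tau2
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(y, v, X = NULL) {
  k <- length(y)
  if (is.null(X)) X <- matrix(1, k, 1)
  X <- as.matrix(X)
  if (any(v <= 0)) stop("cochran_q: all sampling variances must be > 0")
  if (k <= ncol(X)) stop("cochran_q: k must exceed design columns")
  w <- 1 / v
  b <- solve(crossprod(X, X * w), crossprod(X, y * w))
  resid <- y - X %*% b
  Q <- sum(w * resid^2)
  df <- k - ncol(X)
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared heterogeneity percentage
#'
#' The tau^2-based definition `I^2 = 100 tau^2 / (tau^2 + s^2)` with
#' Higgins' typical within-study sampling variance
#' `s^2 = (k-1) sum(1/v) / ((sum 1/v)^2 - sum(1/v^2))`.
#'
#' @param tau2 between-study variance.
#' @param v sampling variances.
#' @return percentage in [0, 100].
#' @export
i_squared <- function(tau2, v) {
  if (length(v) < 2L) stop("i_squared: need k >= 2")
  if (any(v <= 0)) stop("i_squared: all sampling variances must be > 0")
  w <- 1 / v
  denom <- sum(w)^2 - sum(w^2)
  if (denom <= 0) stop("i_squared: degenerate typical sampling variance")
  s2 <- (length(v) - 1) * sum(w) / denom
  100 * tau2 / (tau2 + s2)
}

#' Random-effects meta-analysis (REML, inverse-variance weighting)
#'
#' Pools per-cohort effects with weights `w_i = 1/(v_i + tau^2)` where
#' tau^2 is the REML estimate: `b = sum(w y)/sum(w)`,
#' `se = (sum w)^{-1/2}`, Wald z test and Normal 95% CI. Heterogeneity is
#' summarised by Cochran's Q (computed at fixed-effect weights) and the
#' tau^2-based I^2.
#'
#' @param y per-cohort effects (years, d, ...).
#' @param v per-cohort sampling variances (> 0).
#' @param labels optional cohort labels.
#' @return object of class `meta_result`: `k`, `b`, `se`, `ci_low`,
#'   `ci_high`, `z`, `p`, `tau2`, `Q`, `df_Q`, `p_Q`, `i2`, `method`,
#'   plus the inputs.
#' @export
fit_random_effects <- function(y, v, labels = NULL) {
  k <- length(y)
  if (k < 2L) stop("fit_random_effects: need at least 2 cohorts")
  if (length(v) != k) stop("fit_random_effects: y and v lengths differ")
  if (any(v <= 0)) stop("fit_random_effects: all sampling variances must be > 0")
  tau2 <- as.numeric(reml_tau2(y, v))
  w <- 1 / (v + tau2)
  b <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- b / se
  q <- cochran_q(y, v)
  res <- list(k = k, b = b, se = se,
              ci_low = b - stats::qnorm(0.975) * se,
              ci_high = b + stats::qnorm(0.975) * se,
              z = z, p = 2 * stats::pnorm(-abs(z)),
              tau2 = tau2, Q = q$Q, df_Q = q$df, p_Q = q$p,
              i2 = i_squared(tau2, v),
              method = "REML", y = y, v = v,
              labels = if (is.null(labels)) sprintf("study_%02d", seq_len(k))
                       else as.character(labels))
  class(res) <- "meta_result"
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("random-effects meta-analysis (%s), k = %d\n", x$method, x$k))
  cat(sprintf("  b = %.4f (se %.4f), 95%% CI [%.4f, %.4f], z = %.3f, p = %.4g\n",
              x$b, x$se, x$ci_low, x$ci_high, x$z, x$p))
  cat(sprintf("  tau2 = %.4f, Q(%d) = %.3f (p = %.4g), I2 = %.2f%%\n",
              x$tau2, x$df_Q, x$Q, x$p_Q, x$i2))
  invisible(x)
}

#' Mixed-effects meta-regression with a single moderator
#'
#' Fits `y_i = b0 + b1 m_i + u_i + e_i` with REML tau^2 under the
#' moderator design, generalized-least-squares coefficients, and the Wald
#' chi-square omnibus moderator test `QM = (b1/se1)^2` on 1 df. The
#' heterogeneity accounted for is `R^2 = 100 max(0, (tau2_null -
#' tau2_mod)/tau2_null)` against the moderator-free model, and the residual
#' I^2 uses the moderator-model tau^2. The residual Q (QE) is computed from
#' the moderator-adjusted fixed-effect fit.
#'
#' @param y,v as in [fit_random_effects()].
#' @param moderator numeric (or two-level) moderator vector; binary factors
#'   are coded 0/1.
#' @param labels optional cohort labels.
#' @return object of class `meta_reg_result` with coefficient table
#'   (`coefs`), `QM`, `df_M`, `p_M`, `tau2`, `tau2_null`, `r2`, `i2`
#'   (residual), `QE`, `df_QE`, `p_QE`.
#' @export
fit_meta_regression <- function(y, v, moderator, labels = NULL) {
  k <- length(y)
  if (k <= 2L) stop("fit_meta_regression: need k > 2")
  if (any(v <= 0)) stop("fit_meta_regression: all sampling variances must be > 0")
  if (is.factor(moderator) || is.character(moderator)) {
    lev <- sort(unique(as.character(moderator)))
    if (length(lev) != 2L) {
      stop("fit_meta_regression: categorical moderators must have 2 levels")
    }
    moderator <- as.integer(as.character(moderator) == lev[2])
    mod_label <- paste0(lev[2], "_vs_", lev[1])
  } else {
    moderator <- as.numeric(moderator)
    mod_label <- "moderator"
  }
  if (stats::sd(moderator) == 0) {
    stop("fit_meta_regression: moderator is constant")
  }
  X <- cbind(intercept = 1, moderator = moderator)
  tau2_null <- as.numeric(reml_tau2(y, v))
  tau2 <- as.numeric(reml_tau2(y, v, X))
  w <- 1 / (v + tau2)
  XtWX_inv <- solve(crossprod(X, X * w))
  beta <- unname(drop(XtWX_inv %*% crossprod(X, y * w)))
  se <- unname(sqrt(diag(XtWX_inv)))
  z <- beta / se
  coefs <- data.frame(term = c("intercept", mod_label), beta = beta, se = se,
                      z = z, p = 2 * stats::pnorm(-abs(z)),
                      ci_low = beta - stats::qnorm(0.975) * se,
                      ci_high = beta + stats::qnorm(0.975) * se,
                      row.names = NULL, stringsAsFactors = FALSE)
  qm <- z[2]^2
  qe <- cochran_q(y, v, X)
  r2 <- if (tau2_null > 0) 100 * max(0, (tau2_null - tau2) / tau2_null) else 0
  res <- list(k = k, coefs = coefs, QM = qm, df_M = 1L,
              p_M = stats::pchisq(qm, 1, lower.tail = FALSE),
              tau2 = tau2, tau2_null = tau2_null, r2 = r2,
              i2 = i_squared(tau2, v),
              QE = qe$Q, df_QE = qe$df, p_QE = qe$p,
              method = "REML", y = y, v = v, moderator = moderator,
              labels = labels)
  class(res) <- "meta_reg_result"
  res
}

#' @export
print.meta_reg_result <- function(x, ...) {
  cat(sprintf("mixed-effects meta-regression (%s), k = %d\n", x$method, x$k))
  print(x$coefs, digits = 4)
  cat(sprintf("  QM(%d) = %.3f, p = %.4g; tau2 = %.4f (null %.4f), R2 = %.2f%%, residual I2 = %.2f%%\n",
              x$df_M, x$QM, x$p_M, x$tau2, x$tau2_null, x$r2, x$i2))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: for order statistics `p_(1) <= ... <= p_(n)`,
#' `p_adj(i) = min_{j >= i} ( n p_(j) / j )`, capped at 1, returned in the
#' input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("bh_fdr: p-values must be in [0, 1] and non-missing")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Forest-plot table
#'
#' One row per cohort (effect, CI, relative random-effects weight in %)
#' plus a pooled row; weights are proportional to `1/(v_i + tau^2)` and sum
#' to 100.
#'
#' @param meta a `meta_result` from [fit_random_effects()].
#' @return data.frame with columns `label`, `b`, `ci_low`, `ci_high`,
#'   `weight_pct`, `pooled`.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  w <- 1 / (meta$v + meta$tau2)
  wpct <- 100 * w / sum(w)
  zc <- stats::qnorm(0.975)
  rows <- data.frame(
    label = meta$labels,
    b = meta$y,
    ci_low = meta$y - zc * sqrt(meta$v),
    ci_high = meta$y + zc * sqrt(meta$v),
    weight_pct = wpct,
    pooled = FALSE,
    stringsAsFactors = FALSE)
  pooled <- data.frame(label = "pooled", b = meta$b, ci_low = meta$ci_low,
                       ci_high = meta$ci_high, weight_pct = NA_real_,
                       pooled = TRUE, stringsAsFactors = FALSE)
  out <- rbind(rows, pooled)
  rownames(out) <- NULL
  out
}
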