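#' Sex-stratified ridge brain-age model
#'
#' Fits chronological age on the 77 standardized features by ridge
#' regression, separately per sex, on healthy subjects only. Features are
#' standardized by training means/SDs; the penalty strength is selected by
#' internal k-fold cross-validation over `alpha_grid` (minimum mean squared
#' error; ties go to the smaller alpha). The ridge solution is computed in
#' closed form from the SVD of the standardized design, minimising
#' `||y - Xb||^2 + alpha ||b||^2`.
#'
#' @param table feature table (raw tables are hemisphere-averaged first).
#' @param sex `"male"` or `"female"`; only healthy (`dx == "HC"`) rows of
#'   this sex are used.
#' @param alpha_grid candidate penalty strengths (default `10^-3 ... 10^5`,
#'   log-spaced).
#' @param folds internal CV folds for alpha selection (default 10).
#' @param seed seed for the CV fold assignment.
#' @return object of class `brain_age_model`: standardization means/SDs,
#'   coefficients, intercept, chosen alpha, CV table, training n and age
#'   range.
#' @export
train_brain_age <- function(table, sex = c("male", "female"),
                            alpha_grid = 10^seq(-3, 5, length.out = 9),
                            folds = 10, seed = 1) {
  sex <- match.arg(sex)
  stopifnot(all(alpha_grid >= 0), folds >= 2)
  table <- average_hemispheres(table)
  keep <- table$dx == "HC" & table$sex == sex
  tab <- table[keep, , drop = FALSE]
  n <- nrow(tab)
  if (n < 10L) stop("train_brain_age: fewer than 10 ", sex,
                    " healthy training rows (", n, ")")
  x <- feature_matrix(tab, "averaged")
  if (n <= ncol(x)) {
    warning("train_brain_age: n (", n, ") <= number of features (",
            ncol(x), "); fit is heavily regularized")
  }
  y <- tab$age
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  if (any(sigma == 0)) {
    stop("train_brain_age: constant feature(s): ",
         paste(colnames(x)[sigma == 0], collapse = ", "))
  }
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sigma, "/")

  cv <- NULL
  alpha <- alpha_grid[1]
  if (length(alpha_grid) > 1L) {
    set.seed(as.integer(seed))
    fold <- sample(rep(seq_len(folds), length.out = n))
    sse <- matrix(0, folds, length(alpha_grid))
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- ridge_path(xs[tr, , drop = FALSE], y[tr], alpha_grid)
      pred <- xs[!tr, , drop = FALSE] %*% fit$coef + fit$intercept
      sse[f, ] <- colSums((pred - y[!tr])^2)
    }
    mse <- colSums(sse) / n
    cv <- data.frame(alpha = alpha_grid, cv_mse = mse)
    alpha <- alpha_grid[which.min(mse)]
  }
  fit <- ridge_path(xs, y, alpha)
  model <- list(sex = sex, feature_names = colnames(x), mu = mu,
                sigma = sigma, coef = drop(fit$coef),
                intercept = fit$intercept, alpha = alpha, cv = cv,
                n = n, age_range = range(y))
  class(model) <- "brain_age_model"
  model
}

# closed-form ridge for several alphas at once via SVD of the centred design
ridge_path <- function(xs, y, alphas) {
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(xs)
  uty <- crossprod(sv$u, yc)
  coef <- vapply(alphas, function(a) {
    drop(sv$v %*% (uty * sv$d / (sv$d^2 + a)))
  }, numeric(ncol(xs)))
  coef <- matrix(coef, ncol = length(alphas),
                 dimnames = list(colnames(xs), NULL))
  list(coef = coef, intercept = ybar)
}

#' @export
print.brain_age_model <- function(x, ...) {
  cat("brain_age_model (", x$sex, "): n =", x$n,
      ", alpha =", format(x$alpha),
      ", ages", sprintf("%.1f-%.1f", x$age_range[1], x$age_range[2]), "\n")
  invisible(x)
}

#' Predict brain age
#'
#' @param object a `brain_age_model`.
#' @param table feature table; all rows must match the model's sex.
#' @param ... unused.
#' @return numeric vector of predicted ages (years), named by subject id.
#' @export
predict.brain_age_model <- function(object, table, ...) {
  table <- average_hemispheres(table)
  if (!all(table$sex == object$sex)) {
    stop("predict: table contains ", sum(table$sex != object$sex),
         " row(s) whose sex does not match the '", object$sex, "' model")
  }
  x <- feature_matrix(table, "averaged")
  x <- x[, object$feature_names, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$mu, "-"), 2, object$sigma, "/")
  pred <- drop(xs %*% object$coef) + object$intercept
  names(pred) <- rownames(x)
  if (any(!is.finite(pred))) stop("predict: non-finite prediction")
  pred
}

#' Cross-validated training performance
#'
#' Out-of-fold predictions for every training subject of the given sex,
#' summarised as MAE, Pearson r and R^2.
#'
#' @inheritParams train_brain_age
#' @return list with `metrics` (from [evaluate_predictions()]), the
#'   out-of-fold `predicted` vector and `age`.
#' @export
cross_validate_brain_age <- function(table, sex = c("male", "female"),
                                     alpha_grid = 10^seq(-3, 5, length.out = 9),
                                     folds = 10, seed = 1) {
  sex <- match.arg(sex)
  if (folds < 2) stop("cross_validate_brain_age: folds must be >= 2")
  table <- average_hemispheres(table)
  keep <- table$dx == "HC" & table$sex == sex
  tab <- table[keep, , drop = FALSE]
  n <- nrow(tab)
  if (folds > n) stop("cross_validate_brain_age: folds (", folds,
                      ") exceed n (", n, ")")
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    m <- train_brain_age(tab[fold != f, , drop = FALSE], sex,
                         alpha_grid = alpha_grid,
                         folds = min(10, max(2, sum(fold != f) %/% 10)),
                         seed = seed + f)
    pred[fold == f] <- predict(m, tab[fold == f, , drop = FALSE])
  }
  list(metrics = evaluate_predictions(pred, tab$age),
       predicted = stats::setNames(pred, tab$subject_id), age = tab$age)
}

#' Brain-predicted age difference
#'
#' brain-PAD = predicted age minus chronological age (years); positive
#' values mean an older-looking brain.
#'
#' @param predicted,chronological aligned numeric vectors (years).
#' @return numeric vector of brain-PAD values.
#' @export
compute_brainpad <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("compute_brainpad: length mismatch (", length(predicted), " vs ",
         length(chronological), ")")
  }
  predicted - chronological
}

#' Prediction performance metrics
#'
#' MAE (years), Pearson r between predicted and chronological age, and
#' R^2 defined as r^2 (the proportion of chronological-age variance
#' explained; this definition cannot go negative out of sample).
#'
#' @param predicted,chronological aligned numeric vectors.
#' @return list with `n`, `mae`, `r`, `r_squared`.
#' @export
evaluate_predictions <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("evaluate_predictions: length mismatch")
  }
  n <- length(predicted)
  if (n < 2L) stop("evaluate_predictions: need n >= 2")
  mae <- mean(abs(predicted - chronological))
  if (stats::sd(chronological) == 0) {
    stop("evaluate_predictions: chronological age has zero variance; ",
         "r is undefined (MAE = ", format(mae), ")")
  }
  if (stats::sd(predicted) == 0) {
    warning("evaluate_predictions: constant predictions; r undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(predicted, chronological)
  }
  list(n = n, mae = mae, r = r, r_squared = r^2)
}

#' Sample-size-weighted aggregate of per-cohort performance
#'
#' Weighted mean of a per-cohort metric with weights equal to cohort n, and
#' its standard error taken as the weighted (population) SD of the cohort
#' values divided by sqrt(k).
#'
#' @param values per-cohort metric values (e.g. MAE).
#' @param n per-cohort sample sizes (weights).
#' @return list with `k`, `weighted_mean`, `se` (`NA` when k = 1).
#' @export
aggregate_performance <- function(values, n) {
  ok <- is.finite(values) & is.finite(n) & n > 0
  values <- values[ok]; n <- n[ok]
  k <- length(values)
  if (k == 0L) stop("aggregate_performance: no usable cohorts")
  w <- n / sum(n)
  wm <- sum(w * values)
  se <- if (k >= 2L) sqrt(sum(w * (values - wm)^2)) / sqrt(k) else NA_real_
  list(k = k, weighted_mean = wm, se = se)
}

#' Serialize / restore a brain-age model
#'
#' Plain-text JSON with full double precision, so save -> load -> predict is
#' bit-stable.
#'
#' @param model a `brain_age_model`.
#' @param path file path.
#' @return `save_brain_age_model`: the path, invisibly;
#'   `load_brain_age_model`: the restored model.
#' @export
save_brain_age_model <- function(model, path) {
  stopifnot(inherits(model, "brain_age_model"))
  num <- function(x) formatC(unname(x), digits = 17, format = "g")
  obj <- list(sex = model$sex, feature_names = model$feature_names,
              mu = num(model$mu), sigma = num(model$sigma),
              coef = num(model$coef), intercept = num(model$intercept),
              alpha = num(model$alpha),
              cv = if (!is.null(model$cv)) {
                list(alpha = num(model$cv$alpha),
                     cv_mse = num(model$cv$cv_mse))
              },
              n = model$n, age_range = num(model$age_range))
  # doubles travel as 17-significant-digit strings: exact IEEE round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname save_brain_age_model
#' @export
load_brain_age_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(sex = obj$sex, feature_names = obj$feature_names,
                mu = stats::setNames(as.numeric(obj$mu), obj$feature_names),
                sigma = stats::setNames(as.numeric(obj$sigma), obj$feature_names),
                coef = stats::setNames(as.numeric(obj$coef), obj$feature_names),
                intercept = as.numeric(obj$intercept),
                alpha = as.numeric(obj$alpha),
                cv = if (!is.null(obj$cv)) {
                  data.frame(alpha = as.numeric(obj$cv$alpha),
                             cv_mse = as.numeric(obj$cv$cv_mse))
                } else NULL,
                n = as.integer(obj$n), age_range = as.numeric(obj$age_range))
  class(model) <- "brain_age_model"
  model
}
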