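#' Convert a covariate-adjusted t statistic to Cohen's d
#'
#' Standard consortium practice for covariate-adjusted group contrasts:
#' `d = t (n1 + n2) / (sqrt(n1 n2) sqrt(df))`, with sampling variance
#' `var_d = (n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))`.
#'
#' @param t t statistic of the group term.
#' @param n1,n2 group sizes (each >= 2).
#' @param df residual degrees of freedom (> 0).
#' @return list with `d` and `var_d`.
#' @export
cohens_d_from_t <- function(t, n1, n2, df) {
  if (df <= 0) stop("cohens_d_from_t: df must be > 0")
  if (n1 < 2 || n2 < 2) stop("cohens_d_from_t: group sizes must be >= 2")
  d <- t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
  var_d <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  list(d = d, var_d = var_d)
}

# shared: run lm on a constructed design, return tidy per-term rows
fit_ols_terms <- function(d, formula, cohort_id, term_map) {
  mm <- stats::model.matrix(formula, d)
  qrX <- qr(mm)
  if (qrX$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrX$pivot[(qrX$rank + 1):ncol(mm)]]
    stop("rank-deficient design in cohort '", cohort_id,
         "': collinear column(s) ", paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(formula, data = d)
  s <- summary(fit)$coefficients
  df <- fit$df.residual
  tcrit <- stats::qt(0.975, df)
  out <- data.frame(
    cohort_id = cohort_id,
    term = rownames(s),
    beta = s[, 1], se = s[, 2],
    ci_low = s[, 1] - tcrit * s[, 2],
    ci_high = s[, 1] + tcrit * s[, 2],
    t = s[, 3], p = s[, 4], df = df,
    stringsAsFactors = FALSE)
  if (!is.null(term_map)) {
    m <- match(out$term, names(term_map))
    out$term[!is.na(m)] <- term_map[m[!is.na(m)]]
  }
  rownames(out) <- NULL
  out
}

#' Per-cohort diagnosis model for brain-PAD
#'
#' Ordinary least squares of brain-PAD on a diagnosis indicator (healthy
#' controls as reference) with sex, age, age-squared and, for multi-site
#' cohorts, (n_sites - 1) site dummy covariates. Age and quadratic age
#' absorb the systematic age bias of brain-age prediction
#' (regression-to-the-mean makes raw brain-PAD negatively age-dependent);
#' age is centred within cohort before squaring to limit collinearity,
#' which leaves the diagnosis coefficient unchanged. Cohen's d for the
#' diagnosis term is derived from its t statistic via [cohens_d_from_t()].
#'
#' @param data data.frame with columns `brainpad`, `dx` (`SZ`/`HC`), `sex`,
#'   `age`, `site`, optionally `handedness`.
#' @param cohort_id label carried into the output.
#' @param use_handedness add handedness dummy covariates (reference `right`).
#' @return data.frame of per-term effects (class `cohort_effects`): columns
#'   `cohort_id`, `term`, `beta`, `se`, `ci_low`, `ci_high`, `t`, `p`, `df`,
#'   `n_case`, `n_control`, `d`, `var_d` (d only on the `dx` row).
#' @export
fit_dx_model <- function(data, cohort_id = data$cohort[1],
                         use_handedness = FALSE) {
  need <- c("brainpad", "dx", "sex", "age", "site")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) stop("fit_dx_model: missing column(s): ",
                              paste(miss, collapse = ", "))
  n_case <- sum(data$dx == "SZ"); n_ctrl <- sum(data$dx == "HC")
  if (n_case < 2L || n_ctrl < 2L) {
    stop("fit_dx_model: need >= 2 subjects per diagnosis group (",
         n_case, " SZ, ", n_ctrl, " HC)")
  }
  d <- data.frame(
    brainpad = data$brainpad,
    dx = factor(data$dx, levels = c("HC", "SZ")),
    sex = factor(data$sex, levels = c("female", "male")),
    agec = data$age - mean(data$age),
    site = factor(data$site),
    stringsAsFactors = FALSE)
  rhs <- "dx"
  if (nlevels(droplevels(d$sex)) > 1L) {
    rhs <- c(rhs, "sex")
  } else {
    message("fit_dx_model [", cohort_id, "]: single-sex cohort; sex term dropped")
    d$sex <- NULL
  }
  rhs <- c(rhs, "agec", "I(agec^2)")
  if (nlevels(droplevels(d$site)) > 1L) {
    d$site <- droplevels(d$site)
    rhs <- c(rhs, "site")
  } else d$site <- NULL
  if (use_handedness) {
    h <- factor(data$handedness, levels = c("right", "left", "ambidextrous"))
    if (nlevels(droplevels(h)) > 1L) {
      d$handedness <- droplevels(h)
      rhs <- c(rhs, "handedness")
    }
  }
  fml <- stats::as.formula(paste("brainpad ~", paste(rhs, collapse = " + ")))
  out <- fit_ols_terms(d, fml, cohort_id,
                       term_map = c("dxSZ" = "dx", "sexmale" = "sex",
                                    "agec" = "age", "I(agec^2)" = "age2"))
  out$n_case <- n_case
  out$n_control <- n_ctrl
  out$d <- NA_real_; out$var_d <- NA_real_
  i <- which(out$term == "dx")
  dd <- cohens_d_from_t(out$t[i], n_case, n_ctrl, out$df[i])
  out$d[i] <- dd$d; out$var_d[i] <- dd$var_d
  class(out) <- c("cohort_effects", "data.frame")
  out
}

#' Per-cohort clinical-characteristic model within patients
#'
#' Within SZ patients only: OLS of brain-PAD on one clinical characteristic
#' plus age and age-squared (complete cases on the characteristic).
#' Continuous characteristics (`onset`, `duration`, `panss_total`,
#' `sans_global`, `saps_global`, `cpz`) enter as a slope; antipsychotic
#' class (`ap_class`) is analysed as pairwise contrasts against the
#' unmedicated group via [fit_ap_contrasts()]. Site dummies are added for
#' multi-site cohorts when `use_site` is TRUE.
#'
#' @param data patient rows with `brainpad`, `age`, the clinical columns and
#'   `site`.
#' @param cc clinical characteristic column name.
#' @param cohort_id label carried into the output.
#' @param use_site include site dummies for multi-site cohorts.
#' @param use_handedness add handedness dummies.
#' @param min_n minimum complete cases required.
#' @return `cohort_effects` data.frame (the `cc` row carries the slope), or
#'   rows per contrast for `ap_class`.
#' @export
fit_clinical_model <- function(data, cc, cohort_id = data$cohort[1],
                               use_site = TRUE, use_handedness = FALSE,
                               min_n = 10) {
  if (!all(data$dx == "SZ")) stop("fit_clinical_model: patients only")
  if (cc == "ap_class") {
    return(fit_ap_contrasts(data, cohort_id = cohort_id, use_site = use_site,
                            use_handedness = use_handedness))
  }
  if (!cc %in% names(data)) stop("fit_clinical_model: no column '", cc, "'")
  keep <- !is.na(data[[cc]]) & !is.na(data$brainpad)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < min_n) {
    stop("fit_clinical_model [", cohort_id, "]: fewer than ", min_n,
         " complete cases for '", cc, "'")
  }
  if (stats::sd(data[[cc]]) == 0) {
    stop("fit_clinical_model [", cohort_id, "]: '", cc, "' is constant")
  }
  d <- data.frame(brainpad = data$brainpad,
                  cc = data[[cc]],
                  agec = data$age - mean(data$age),
                  site = factor(data$site))
  rhs <- c("cc", "agec", "I(agec^2)")
  if (use_site && nlevels(droplevels(d$site)) > 1L) {
    d$site <- droplevels(d$site)
    rhs <- c(rhs, "site")
  } else d$site <- NULL
  if (use_handedness) {
    h <- factor(data$handedness, levels = c("right", "left", "ambidextrous"))
    if (nlevels(droplevels(h)) > 1L) {
      d$handedness <- droplevels(h); rhs <- c(rhs, "handedness")
    }
  }
  fml <- stats::as.formula(paste("brainpad ~", paste(rhs, collapse = " + ")))
  out <- fit_ols_terms(d, fml, cohort_id,
                       term_map = c("cc" = cc, "agec" = "age",
                                    "I(agec^2)" = "age2"))
  out$n_case <- nrow(d); out$n_control <- NA_integer_
  out$d <- NA_real_; out$var_d <- NA_real_
  class(out) <- c("cohort_effects", "data.frame")
  out
}

#' Antipsychotic-class contrasts against the unmedicated group
#'
#' One model per contrast (`atypical`, `typical`, `both`, each vs `none`),
#' fitted on the subset of patients in the two classes involved, with age
#' and age-squared covariates. A contrast is skipped (dropped from the
#' output, with attribute `skipped` recording why) when either subgroup has
#' fewer than `min_subgroup` members.
#'
#' @param data patient rows with `ap_class`.
#' @param cohort_id label.
#' @param min_subgroup minimum members per class (default 5).
#' @inheritParams fit_clinical_model
#' @return `cohort_effects` rows with terms `ap_atypical_vs_unmed`,
#'   `ap_typical_vs_unmed`, `ap_both_vs_unmed` (subset to feasible
#'   contrasts); `n_case` = treated-group size, `n_control` = unmedicated
#'   size.
#' @export
fit_ap_contrasts <- function(data, cohort_id = data$cohort[1],
                             min_subgroup = 5, use_site = TRUE,
                             use_handedness = FALSE) {
  if (!all(data$dx == "SZ")) stop("fit_ap_contrasts: patients only")
  data <- data[!is.na(data$ap_class) & !is.na(data$brainpad), , drop = FALSE]
  rows <- list(); skipped <- character(0)
  for (lev in c("atypical", "typical", "both")) {
    sub <- data[data$ap_class %in% c(lev, "none"), , drop = FALSE]
    n1 <- sum(sub$ap_class == lev); n0 <- sum(sub$ap_class == "none")
    term <- paste0("ap_", lev, "_vs_unmed")
    if (n1 < min_subgroup || n0 < min_subgroup) {
      skipped <- c(skipped, sprintf("%s (n_%s=%d, n_unmed=%d)", term, lev,
                                    n1, n0))
      next
    }
    d <- data.frame(brainpad = sub$brainpad,
                    cc = as.integer(sub$ap_class == lev),
                    agec = sub$age - mean(sub$age),
                    site = factor(sub$site))
    rhs <- c("cc", "agec", "I(agec^2)")
    if (use_site && nlevels(droplevels(d$site)) > 1L) {
      d$site <- droplevels(d$site); rhs <- c(rhs, "site")
    } else d$site <- NULL
    if (use_handedness) {
      h <- factor(sub$handedness, levels = c("right", "left", "ambidextrous"))
      if (nlevels(droplevels(h)) > 1L) {
        d$handedness <- droplevels(h); rhs <- c(rhs, "handedness")
      }
    }
    fml <- stats::as.formula(paste("brainpad ~", paste(rhs, collapse = " + ")))
    eff <- fit_ols_terms(d, fml, cohort_id,
                         term_map = c("cc" = term, "agec" = "age",
                                      "I(agec^2)" = "age2"))
    eff <- eff[eff$term == term, , drop = FALSE]
    eff$n_case <- n1; eff$n_control <- n0
    eff$d <- NA_real_; eff$var_d <- NA_real_
    rows[[term]] <- eff
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cohort_id = character(0), term = character(0),
               beta = numeric(0), se = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), t = numeric(0), p = numeric(0),
               df = numeric(0), n_case = integer(0), n_control = integer(0),
               d = numeric(0), var_d = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("cohort_effects", "data.frame")
  out
}

#' Eligibility rule for per-cohort analyses
#'
#' @param min_controls minimum healthy controls for the case-control
#'   analysis (default 10).
#' @param min_subgroup minimum members of any non-empty predictor or
#'   covariate subgroup (default 5); empty subgroups drop the term instead.
#' @param max_control_mae,min_control_r2 sensitivity-mode thresholds on the
#'   model's generalization in healthy controls.
#' @return object of class `eligibility_rule`.
#' @export
eligibility_rule <- function(min_controls = 10, min_subgroup = 5,
                             max_control_mae = 10.0, min_control_r2 = 0.1) {
  stopifnot(min_controls > 0, min_subgroup > 0, max_control_mae > 0,
            min_control_r2 > 0)
  structure(list(min_controls = min_controls, min_subgroup = min_subgroup,
                 max_control_mae = max_control_mae,
                 min_control_r2 = min_control_r2),
            class = "eligibility_rule")
}

#' Decide whether a cohort enters an analysis
#'
#' Primary-mode rules: the case-control analysis requires at least
#' `min_controls` healthy controls; any non-empty predictor or covariate
#' subgroup (diagnosis group, sex within the model, or a categorical
#' clinical class involved in a contrast) with fewer than `min_subgroup`
#' members excludes the cohort from that analysis (an empty subgroup simply
#' drops the term). Sensitivity mode additionally excludes cohorts in which
#' the brain-age model generalised poorly in controls (MAE above
#' `max_control_mae` or R^2 below `min_control_r2`).
#'
#' @param data the cohort's subject rows (needs `dx`, `sex`; clinical
#'   columns as required by `context`).
#' @param rule an [eligibility_rule()].
#' @param context `"dx"` for the case-control analysis, or a clinical
#'   characteristic name for the within-patient models.
#' @param sensitivity apply the generalization thresholds.
#' @param control_mae,control_r2 the cohort's control-group MAE and R^2
#'   (required when `sensitivity = TRUE`).
#' @return list with `include` (logical) and `reasons` (character; empty
#'   when included).
#' @export
check_eligibility <- function(data, rule = eligibility_rule(),
                              context = "dx", sensitivity = FALSE,
                              control_mae = NULL, control_r2 = NULL) {
  reasons <- character(0)
  n_ctrl <- sum(data$dx == "HC")
  n_case <- sum(data$dx == "SZ")
  sub_ok <- function(n, what) {
    if (n > 0 && n < rule$min_subgroup) {
      reasons <<- c(reasons, sprintf("min_subgroup: %s (n=%d)", what, n))
    }
  }
  if (context == "dx") {
    if (n_ctrl < rule$min_controls) {
      reasons <- c(reasons, sprintf("min_controls (n=%d)", n_ctrl))
    }
    sub_ok(n_case, "cases")
    for (s in c("male", "female")) sub_ok(sum(data$sex == s), s)
  } else if (context == "ap_class") {
    # contrast-level feasibility is decided in fit_ap_contrasts; here only
    # require enough patients overall
    sub_ok(sum(!is.na(data$ap_class[data$dx == "SZ"])), "ap_class recorded")
  } else {
    n_cc <- sum(data$dx == "SZ" & !is.na(data[[context]]))
    if (n_cc < max(rule$min_subgroup, 10)) {
      reasons <- c(reasons, sprintf("min_complete_cases: %s (n=%d)",
                                    context, n_cc))
    }
  }
  if (sensitivity) {
    if (is.null(control_mae) || is.null(control_r2)) {
      stop("check_eligibility: sensitivity mode needs control_mae and control_r2")
    }
    if (is.finite(control_mae) && control_mae > rule$max_control_mae) {
      reasons <- c(reasons, sprintf("control_mae > %.2f (%.2f)",
                                    rule$max_control_mae, control_mae))
    }
    if (is.finite(control_r2) && control_r2 < rule$min_control_r2) {
      reasons <- c(reasons, sprintf("control_r2 < %.2f (%.3f)",
                                    rule$min_control_r2, control_r2))
    }
  }
  list(include = length(reasons) == 0L, reasons = reasons)
}
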