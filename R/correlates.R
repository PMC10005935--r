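#' Per-cohort structure coefficients
#'
#' Pearson correlations between predicted brain age and each of the 77
#' features within one cohort (optionally within one diagnosis group).
#' Structure coefficients indicate each feature's contribution to the
#' prediction without being distorted by collinearity among predictors.
#'
#' @param table averaged feature table for one cohort (or subgroup).
#' @param predicted_age predicted ages aligned with the table rows.
#' @param group label stored alongside (e.g. `"HC"`, `"SZ"`, `"all"`).
#' @return data.frame with columns `feature`, `class`, `group`, `r`, `n`;
#'   features with zero variance get `r = NA` with a warning.
#' @export
cohort_feature_correlations <- function(table, predicted_age, group = "all") {
  table <- average_hemispheres(table)
  m <- feature_matrix(table, "averaged")
  if (nrow(m) != length(predicted_age)) {
    stop("cohort_feature_correlations: prediction length mismatch")
  }
  if (nrow(m) < 3L) stop("cohort_feature_correlations: need n >= 3")
  if (stats::sd(predicted_age) == 0) {
    stop("cohort_feature_correlations: predicted age has zero variance")
  }
  sds <- apply(m, 2, stats::sd)
  r <- rep(NA_real_, ncol(m))
  ok <- sds > 0
  if (any(!ok)) {
    warning("cohort_feature_correlations: zero-variance feature(s): ",
            paste(colnames(m)[!ok], collapse = ", "))
  }
  r[ok] <- drop(stats::cor(m[, ok, drop = FALSE], predicted_age))
  cls <- feature_schema()$classes
  data.frame(feature = colnames(m),
             class = cls$class[match(colnames(m), cls$feature)],
             group = group, r = r, n = nrow(m),
             stringsAsFactors = FALSE)
}

#' Consortium-level weighted structure-coefficient summary
#'
#' Sample-size-weighted mean of the per-cohort correlation coefficients for
#' each feature (plain averaging of coefficients by default; Fisher-z
#' averaging available for comparison), and class-level summaries (mean and
#' SD of the weighted feature means across the features of each class) for
#' thickness, surface area and subcortical volumes; the lateral ventricle
#' and ICV are reported individually.
#'
#' @param correlations row-bound output of [cohort_feature_correlations()]
#'   across cohorts (columns `feature`, `class`, `group`, `r`, `n`).
#' @param fisher_z average on the Fisher-z scale and back-transform.
#' @param by_group summarise within each `group` label separately (default
#'   pools all rows).
#' @return object of class `structure_coefficients`: list with
#'   `feature_means` (feature, class, group, weighted r, total n) and
#'   `class_summary` (class, group, mean_r, sd_r, n_features).
#' @export
weighted_feature_summary <- function(correlations, fisher_z = FALSE,
                                     by_group = FALSE) {
  stopifnot(all(c("feature", "class", "r", "n") %in% names(correlations)))
  if (nrow(correlations) == 0L) stop("weighted_feature_summary: empty input")
  cor <- correlations[!is.na(correlations$r), , drop = FALSE]
  cor$grp <- if (by_group) cor$group else "all"
  agg <- function(sub) {
    val <- if (fisher_z) atanh(pmin(pmax(sub$r, -1 + 1e-12), 1 - 1e-12)) else sub$r
    wm <- sum(val * sub$n) / sum(sub$n)
    if (fisher_z) wm <- tanh(wm)
    data.frame(feature = sub$feature[1], class = sub$class[1],
               group = sub$grp[1], r = wm, n = sum(sub$n),
               stringsAsFactors = FALSE)
  }
  parts <- split(cor, interaction(cor$feature, cor$grp, drop = TRUE))
  fm <- do.call(rbind, lapply(parts, agg))
  rownames(fm) <- NULL
  fm <- fm[order(fm$group, match(fm$feature, feature_schema()$averaged)), ]
  cs <- do.call(rbind, lapply(split(fm, interaction(fm$class, fm$group,
                                                    drop = TRUE)),
    function(sub) data.frame(
      class = sub$class[1], group = sub$group[1],
      mean_r = mean(sub$r),
      sd_r = if (nrow(sub) > 1) stats::sd(sub$r) else NA_real_,
      n_features = nrow(sub), stringsAsFactors = FALSE)))
  rownames(cs) <- NULL
  out <- list(feature_means = fm, class_summary = cs,
              fisher_z = fisher_z)
  class(out) <- "structure_coefficients"
  out
}

#' @export
print.structure_coefficients <- function(x, ...) {
  cat("structure coefficients (", nrow(x$feature_means), "feature rows )\n")
  print(x$class_summary, digits = 3)
  invisible(x)
}
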