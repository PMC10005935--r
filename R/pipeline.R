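#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: the data source (a synthetic
#' [generator_config()] or paths to cohort files on disk — exactly one of
#' the two), model settings, the eligibility rule, the analysis list and
#' the seed.
#'
#' @param generator a [generator_config()], or NULL when reading files.
#' @param input_files NULL, or `list(training = <path>, cohorts =
#'   <character vector of paths>)` of delimited feature tables.
#' @param alpha_grid ridge penalty grid.
#' @param cv_folds internal CV folds for alpha selection.
#' @param rule an [eligibility_rule()].
#' @param clinical clinical characteristics to analyse within patients;
#'   `ap_class` expands to the three medicated-vs-unmedicated contrasts, so
#'   the default list yields nine FDR-corrected tests.
#' @param moderators meta-regression moderators (subset of `multi_site`,
#'   `field_strength`, `mean_age`, `pct_female`).
#' @param use_site_in_clinical include site dummies in the within-patient
#'   models of multi-site cohorts.
#' @param seed integer master seed (overrides the generator's own seed so
#'   one number reproduces the whole run).
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       input_files = NULL,
                       alpha_grid = 10^seq(-3, 5, length.out = 9),
                       cv_folds = 10,
                       rule = eligibility_rule(),
                       clinical = c("onset", "duration", "panss_total",
                                    "sans_global", "saps_global",
                                    "ap_class", "cpz"),
                       moderators = c("multi_site", "field_strength",
                                      "mean_age", "pct_female"),
                       use_site_in_clinical = TRUE,
                       seed = 1L) {
  if (is.null(generator) == is.null(input_files)) {
    stop("run_config: supply exactly one of 'generator' or 'input_files'")
  }
  vocab <- c("onset", "duration", "panss_total", "sans_global",
             "saps_global", "ap_class", "cpz")
  bad <- setdiff(clinical, vocab)
  if (length(bad) > 0L) {
    stop("run_config: unknown clinical characteristic(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(moderators, c("multi_site", "field_strength", "mean_age",
                               "pct_female"))
  if (length(bad) > 0L) {
    stop("run_config: unknown moderator(s): ", paste(bad, collapse = ", "))
  }
  structure(list(generator = generator, input_files = input_files,
                 alpha_grid = alpha_grid, cv_folds = cv_folds, rule = rule,
                 clinical = clinical, moderators = moderators,
                 use_site_in_clinical = use_site_in_clinical,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

predict_pooled <- function(models, table) {
  pred <- rep(NA_real_, nrow(table))
  for (sex in names(models)) {
    idx <- which(table$sex == sex)
    if (length(idx) > 0L) {
      pred[idx] <- predict(models[[sex]], table[idx, , drop = FALSE])
    }
  }
  pred
}

safe_eval <- function(pred, age) {
  if (length(pred) < 3L || stats::sd(age) == 0) {
    return(list(n = length(pred), mae = if (length(pred)) mean(abs(pred - age)) else NA_real_,
                r = NA_real_, r_squared = NA_real_))
  }
  tryCatch(evaluate_predictions(pred, age),
           warning = function(w) list(n = length(pred),
                                      mae = mean(abs(pred - age)),
                                      r = NA_real_, r_squared = NA_real_))
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the consortium and training sample, trains the
#' sex-stratified brain-age models, predicts brain age and brain-PAD in
#' every cohort, applies eligibility rules, fits the per-cohort diagnosis
#' and clinical models, pools them with the random-effects meta-engine
#' (years and Cohen's d in parallel), runs the moderator meta-regressions,
#' FDR-corrects the nine clinical tests, and computes the
#' structure-coefficient tables.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: the report tables are written there
#'   via [write_report()]; on a stage failure a `FAILED` marker file naming
#'   the stage is flushed instead.
#' @return object of class `run_report` (a list of result tables; see
#'   [write_report()] for the file layout).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  res <- tryCatch(
    run_pipeline_impl(config),
    error = function(e) e)
  if (inherits(res, "error")) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(c("FAILED", conditionMessage(res)),
                 file.path(out_dir, "FAILED"))
    }
    stop(res)
  }
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

run_pipeline_impl <- function(config) {
  seed <- config$seed
  exclusions <- list()
  note_exclusion <- function(cohort, analysis, reason) {
    exclusions[[length(exclusions) + 1L]] <<- data.frame(
      cohort_id = cohort, analysis = analysis, reason = reason,
      stringsAsFactors = FALSE)
  }

  ## --- data -----------------------------------------------------------
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- seed
    training <- stage_run("generate_training", generate_training_sample(gen))
    cohorts <- stage_run("generate_consortium", generate_consortium(gen))
    specs <- attr(cohorts, "cohort_specs")
  } else {
    training <- stage_run("read_training",
                          read_feature_table(config$input_files$training))
    cohorts <- stage_run("read_cohorts",
                         lapply(config$input_files$cohorts, read_feature_table))
    names(cohorts) <- vapply(cohorts, function(x) x$cohort[1], character(1))
    specs <- NULL
  }
  training <- stage_run("average_training", average_hemispheres(training))
  cohorts <- stage_run("average_cohorts", lapply(cohorts, average_hemispheres))

  ## --- brain-age models ----------------------------------------------
  models <- list(
    male = stage_run("train_male",
                     train_brain_age(training, "male", config$alpha_grid,
                                     folds = config$cv_folds, seed = seed + 11L)),
    female = stage_run("train_female",
                       train_brain_age(training, "female", config$alpha_grid,
                                       folds = config$cv_folds, seed = seed + 12L)))
  # calibration gain: slope of predicted-on-true age in held-in training HC
  pred_train <- predict_pooled(models, training)
  gain <- unname(stats::coef(stats::lm(pred_train ~ training$age))[2])

  ## --- prediction, brain-PAD, performance ----------------------------
  perf <- list(); frames <- list(); ctrl_gen <- list()
  for (cid in names(cohorts)) {
    tab <- cohorts[[cid]]
    pred <- stage_run(paste0("predict:", cid), predict_pooled(models, tab))
    bpad <- compute_brainpad(pred, tab$age)
    frames[[cid]] <- data.frame(
      subject_id = tab$subject_id, cohort = cid, site = tab$site,
      age = tab$age, sex = tab$sex, dx = tab$dx,
      handedness = tab$handedness, onset = tab$onset,
      duration = tab$duration, panss_total = tab$panss_total,
      sans_global = tab$sans_global, saps_global = tab$saps_global,
      ap_class = tab$ap_class, cpz = tab$cpz,
      predicted_age = pred, brainpad = bpad, stringsAsFactors = FALSE)
    for (grp in c("HC", "SZ")) {
      for (sx in c("male", "female")) {
        idx <- tab$dx == grp & tab$sex == sx
        if (sum(idx) == 0L) next
        ev <- safe_eval(pred[idx], tab$age[idx])
        perf[[length(perf) + 1L]] <- data.frame(
          cohort_id = cid, group = grp, sex = sx, n = ev$n, mae = ev$mae,
          r = ev$r, r_squared = ev$r_squared, stringsAsFactors = FALSE)
      }
    }
    idx <- tab$dx == "HC"
    ev <- if (sum(idx) > 0L) safe_eval(pred[idx], tab$age[idx]) else
      list(n = 0L, mae = NA_real_, r = NA_real_, r_squared = NA_real_)
    ctrl_gen[[cid]] <- data.frame(cohort_id = cid, n_control = ev$n,
                                  control_mae = ev$mae,
                                  control_r2 = ev$r_squared,
                                  stringsAsFactors = FALSE)
  }
  performance <- do.call(rbind, perf); rownames(performance) <- NULL
  control_generalization <- do.call(rbind, ctrl_gen)
  rownames(control_generalization) <- NULL

  perf_weighted <- do.call(rbind, lapply(
    split(performance, interaction(performance$group, performance$sex)),
    function(sub) {
      ag_m <- aggregate_performance(sub$mae, sub$n)
      ok <- is.finite(sub$r)
      ag_r <- if (any(ok)) aggregate_performance(sub$r[ok], sub$n[ok]) else
        list(weighted_mean = NA_real_, se = NA_real_)
      data.frame(group = sub$group[1], sex = sub$sex[1], k = ag_m$k,
                 n = sum(sub$n), weighted_mae = ag_m$weighted_mean,
                 mae_se = ag_m$se, weighted_r = ag_r$weighted_mean,
                 r_se = ag_r$se, stringsAsFactors = FALSE)
    }))
  rownames(perf_weighted) <- NULL

  bpad_groups <- do.call(rbind, lapply(c("HC", "SZ"), function(grp) {
    per <- do.call(rbind, lapply(frames, function(f) {
      sub <- f[f$dx == grp, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      data.frame(mean_bpad = mean(sub$brainpad), n = nrow(sub))
    }))
    ag <- aggregate_performance(per$mean_bpad, per$n)
    data.frame(group = grp, k = ag$k, n = sum(per$n),
               weighted_mean_brainpad = ag$weighted_mean, se = ag$se,
               stringsAsFactors = FALSE)
  }))

  ## --- per-cohort diagnosis models -----------------------------------
  dx_rows <- list(); dx_full <- list()
  for (cid in names(frames)) {
    f <- frames[[cid]]
    el <- check_eligibility(f, config$rule, context = "dx")
    if (!el$include) {
      for (rs in el$reasons) note_exclusion(cid, "dx", rs)
      next
    }
    eff <- stage_run(paste0("fit_dx:", cid),
                     suppressMessages(fit_dx_model(f, cohort_id = cid)))
    dx_full[[cid]] <- eff
    dx_rows[[cid]] <- eff[eff$term == "dx", , drop = FALSE]
  }
  dx_effects <- do.call(rbind, dx_rows); rownames(dx_effects) <- NULL
  if (is.null(dx_effects) || nrow(dx_effects) < 2L) {
    stop("pipeline stage 'dx_meta' failed: fewer than 2 eligible cohorts")
  }

  ## --- meta-analysis (years and d) -----------------------------------
  meta_years <- stage_run("dx_meta_years",
                          fit_random_effects(dx_effects$beta, dx_effects$se^2,
                                             labels = dx_effects$cohort_id))
  meta_d <- stage_run("dx_meta_d",
                      fit_random_effects(dx_effects$d, dx_effects$var_d,
                                         labels = dx_effects$cohort_id))

  ## --- moderators -----------------------------------------------------
  mod_values <- data.frame(
    cohort_id = names(frames),
    multi_site = vapply(frames, function(f) length(unique(f$site)) > 1L,
                        logical(1)),
    field_strength = if (!is.null(specs)) {
      specs$field_strength[match(names(frames), specs$cohort_id)]
    } else NA_character_,
    mean_age = vapply(frames, function(f) mean(f$age), numeric(1)),
    pct_female = vapply(frames, function(f) 100 * mean(f$sex == "female"),
                        numeric(1)),
    stringsAsFactors = FALSE)
  moderator_rows <- list(); moderator_fits <- list()
  mv <- mod_values[match(dx_effects$cohort_id, mod_values$cohort_id), ]
  for (mod in config$moderators) {
    x <- mv[[mod]]
    if (mod == "multi_site") x <- as.integer(x)
    if (mod == "field_strength") {
      if (anyNA(x)) { note_exclusion("-", paste0("moderator:", mod),
                                     "field strength unknown"); next }
      x <- as.integer(x == "3T")
    }
    if (length(unique(x)) < 2L) {
      note_exclusion("-", paste0("moderator:", mod), "constant moderator")
      next
    }
    if (nrow(dx_effects) <= 2L) {
      note_exclusion("-", paste0("moderator:", mod),
                     "fewer than 3 eligible cohorts")
      next
    }
    fit <- stage_run(paste0("meta_regression:", mod),
                     fit_meta_regression(dx_effects$beta, dx_effects$se^2, x,
                                         labels = dx_effects$cohort_id))
    moderator_fits[[mod]] <- fit
    moderator_rows[[mod]] <- data.frame(
      moderator = mod, k = fit$k, b = fit$coefs$beta[2],
      se = fit$coefs$se[2], QM = fit$QM, df_M = fit$df_M, p = fit$p_M,
      r2_pct = fit$r2, residual_i2 = fit$i2, stringsAsFactors = FALSE)
  }
  moderators <- do.call(rbind, moderator_rows)
  if (!is.null(moderators)) rownames(moderators) <- NULL

  ## --- clinical characteristics --------------------------------------
  clin_terms <- unlist(lapply(config$clinical, function(cc) {
    if (cc == "ap_class") c("ap_atypical_vs_unmed", "ap_typical_vs_unmed",
                            "ap_both_vs_unmed") else cc
  }))
  clin_rows <- list()
  for (cid in names(frames)) {
    f <- frames[[cid]]
    pats <- f[f$dx == "SZ", , drop = FALSE]
    if (nrow(pats) == 0L) next
    for (cc in config$clinical) {
      el <- check_eligibility(f, config$rule, context = cc)
      if (!el$include) {
        for (rs in el$reasons) note_exclusion(cid, cc, rs)
        next
      }
      eff <- tryCatch({
        if (cc == "ap_class") {
          out <- fit_ap_contrasts(pats, cohort_id = cid,
                                  min_subgroup = config$rule$min_subgroup,
                                  use_site = config$use_site_in_clinical)
          for (sk in attr(out, "skipped")) {
            note_exclusion(cid, "ap_class", paste0("min_subgroup: ", sk))
          }
          out
        } else {
          out <- fit_clinical_model(pats, cc, cohort_id = cid,
                                    use_site = config$use_site_in_clinical)
          out[out$term == cc, , drop = FALSE]
        }
      }, error = function(e) {
        note_exclusion(cid, cc, conditionMessage(e))
        NULL
      })
      if (!is.null(eff) && nrow(eff) > 0L) {
        clin_rows[[length(clin_rows) + 1L]] <- eff
      }
    }
  }
  clinical_effects <- if (length(clin_rows) > 0L) {
    out <- do.call(rbind, clin_rows); rownames(out) <- NULL; out
  } else NULL

  clinical_meta <- do.call(rbind, lapply(clin_terms, function(term) {
    sub <- if (is.null(clinical_effects)) NULL else
      clinical_effects[clinical_effects$term == term, , drop = FALSE]
    if (is.null(sub) || nrow(sub) < 2L) {
      return(data.frame(term = term, k = if (is.null(sub)) 0L else nrow(sub),
                        b = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, z = NA_real_, p = NA_real_,
                        tau2 = NA_real_, i2 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    m <- fit_random_effects(sub$beta, sub$se^2, labels = sub$cohort_id)
    data.frame(term = term, k = m$k, b = m$b, se = m$se, ci_low = m$ci_low,
               ci_high = m$ci_high, z = m$z, p = m$p, tau2 = m$tau2,
               i2 = m$i2, stringsAsFactors = FALSE)
  }))
  ok_p <- !is.na(clinical_meta$p)
  clinical_meta$p_fdr <- NA_real_
  clinical_meta$p_fdr[ok_p] <- bh_fdr(clinical_meta$p[ok_p])

  ## --- structure coefficients ----------------------------------------
  sc_rows <- list()
  for (cid in names(cohorts)) {
    tab <- cohorts[[cid]]
    pred <- frames[[cid]]$predicted_age
    for (grp in c("HC", "SZ")) {
      idx <- tab$dx == grp
      if (sum(idx) < 3L) next
      r <- suppressWarnings(
        cohort_feature_correlations(tab[idx, , drop = FALSE], pred[idx],
                                    group = grp))
      r$cohort_id <- cid
      sc_rows[[length(sc_rows) + 1L]] <- r
    }
  }
  sc_all <- do.call(rbind, sc_rows)
  structure_pooled <- weighted_feature_summary(sc_all, by_group = FALSE)
  structure_by_group <- weighted_feature_summary(sc_all, by_group = TRUE)

  exclusion_log <- if (length(exclusions) > 0L) {
    out <- do.call(rbind, exclusions); rownames(out) <- NULL; out
  } else data.frame(cohort_id = character(0), analysis = character(0),
                    reason = character(0), stringsAsFactors = FALSE)

  report <- list(
    seed = seed,
    config_hash = config_hash(config),
    calibration_gain = gain,
    models = models,
    performance = performance,
    performance_weighted = perf_weighted,
    control_generalization = control_generalization,
    brainpad_groups = bpad_groups,
    dx_effects = dx_effects,
    dx_terms = dx_full,
    dx_meta_years = meta_years,
    dx_meta_d = meta_d,
    forest_years = forest_table(meta_years),
    forest_d = forest_table(meta_d),
    moderator_values = mod_values,
    moderators = moderators,
    moderator_fits = moderator_fits,
    clinical_effects = clinical_effects,
    clinical_meta = clinical_meta,
    structure_pooled = structure_pooled,
    structure_by_group = structure_by_group,
    exclusions = exclusion_log,
    cohort_frames = frames,
    rule = config$rule)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("brainpad run report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  calibration gain g = %.3f\n", x$calibration_gain))
  cat(sprintf("  diagnosis effect: %+.2f years [%.2f, %.2f], d = %.2f, I2 = %.1f%% (k = %d)\n",
              x$dx_meta_years$b, x$dx_meta_years$ci_low,
              x$dx_meta_years$ci_high, x$dx_meta_d$b, x$dx_meta_years$i2,
              x$dx_meta_years$k))
  cat("  clinical tests FDR-significant:",
      sum(x$clinical_meta$p_fdr < 0.05, na.rm = TRUE), "of",
      nrow(x$clinical_meta), "\n")
  invisible(x)
}

#' Sensitivity re-analysis excluding poorly generalising cohorts
#'
#' Re-runs the diagnosis meta-analysis (years and d) on the subset of
#' cohorts whose control-group MAE and R^2 pass the sensitivity thresholds
#' of the eligibility rule, and reports both estimates side by side.
#'
#' @param report a completed [run_pipeline()] report.
#' @param rule eligibility rule carrying the thresholds (defaults to the
#'   rule of the primary run).
#' @return list of class `sensitivity_report`: `primary`, `sensitivity`
#'   (both `meta_result`s on the year scale), `sensitivity_d`, `excluded`
#'   (data.frame naming each dropped cohort and why), `k_primary`,
#'   `k_sensitivity`.
#' @export
run_sensitivity <- function(report, rule = report$rule) {
  stopifnot(inherits(report, "run_report"))
  cg <- report$control_generalization
  eff <- report$dx_effects
  keep <- logical(nrow(eff)); reasons <- character(nrow(eff))
  for (i in seq_len(nrow(eff))) {
    cid <- eff$cohort_id[i]
    row <- cg[cg$cohort_id == cid, ]
    el <- check_eligibility(report$cohort_frames[[cid]], rule,
                            context = "dx", sensitivity = TRUE,
                            control_mae = row$control_mae,
                            control_r2 = row$control_r2)
    keep[i] <- el$include
    reasons[i] <- paste(el$reasons, collapse = "; ")
  }
  if (!any(keep)) stop("run_sensitivity: all cohorts excluded")
  if (sum(keep) < 2L) stop("run_sensitivity: fewer than 2 cohorts remain")
  sub <- eff[keep, , drop = FALSE]
  out <- list(
    primary = report$dx_meta_years,
    sensitivity = fit_random_effects(sub$beta, sub$se^2,
                                     labels = sub$cohort_id),
    sensitivity_d = fit_random_effects(sub$d, sub$var_d,
                                       labels = sub$cohort_id),
    excluded = data.frame(cohort_id = eff$cohort_id[!keep],
                          reason = reasons[!keep], stringsAsFactors = FALSE),
    k_primary = nrow(eff), k_sensitivity = sum(keep))
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("primary     (k=%d): %+.2f years [%.2f, %.2f]\n", x$k_primary,
              x$primary$b, x$primary$ci_low, x$primary$ci_high))
  cat(sprintf("sensitivity (k=%d): %+.2f years [%.2f, %.2f]\n",
              x$k_sensitivity, x$sensitivity$b, x$sensitivity$ci_low,
              x$sensitivity$ci_high))
  if (nrow(x$excluded)) {
    cat("excluded:", paste(x$excluded$cohort_id, collapse = ", "), "\n")
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- formatC(out[[col]], digits = 17, format = "g")
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a run report to disk
#'
#' Flushes every report table as TSV plus a JSON run summary
#' (`summary.json`) with seed, configuration hash and the headline pooled
#' estimates. Identical runs produce byte-identical files.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    performance = report$performance,
    performance_weighted = report$performance_weighted,
    control_generalization = report$control_generalization,
    brainpad_groups = report$brainpad_groups,
    dx_effects = report$dx_effects,
    forest_years = report$forest_years,
    forest_d = report$forest_d,
    moderators = report$moderators,
    clinical_effects = report$clinical_effects,
    clinical_meta = report$clinical_meta,
    structure_features = report$structure_pooled$feature_means,
    structure_classes = report$structure_pooled$class_summary,
    structure_features_by_group = report$structure_by_group$feature_means,
    structure_classes_by_group = report$structure_by_group$class_summary,
    exclusions = report$exclusions,
    moderator_values = report$moderator_values)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]])) {
      write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  summary <- list(
    seed = report$seed,
    config_hash = report$config_hash,
    package_version = as.character(utils::packageVersion("brainpad")),
    calibration_gain = report$calibration_gain,
    dx_effect_years = report$dx_meta_years$b,
    dx_ci = c(report$dx_meta_years$ci_low, report$dx_meta_years$ci_high),
    dx_effect_d = report$dx_meta_d$b,
    tau2 = report$dx_meta_years$tau2,
    Q = report$dx_meta_years$Q,
    df_Q = report$dx_meta_years$df_Q,
    i2 = report$dx_meta_years$i2,
    k = report$dx_meta_years$k,
    clinical_fdr_significant = sum(report$clinical_meta$p_fdr < 0.05,
                                   na.rm = TRUE))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
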