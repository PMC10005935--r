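#' Feature generative model specification
#'
#' Class-level parameters of the generative model for the 77 averaged
#' features. Each feature class has a baseline level (native units), a linear
#' ageing slope per year, an optional quadratic age coefficient, a male sex
#' offset, a between-site SD, a residual SD, and a hemispheric-asymmetry SD.
#' Within a class, individual features get fixed baseline and slope
#' multipliers (spread around 1) so the 34 thickness features, say, are not
#' exchangeable copies. Cortical thickness, surface area and subcortical
#' volumes thin/shrink with age; lateral ventricles expand (with a mild
#' quadratic acceleration); ICV is age-invariant and carries only a sex
#' offset, mimicking head size.
#'
#' Defaults are calibrated so that the standardized age signal
#' (|slope| x SD(age) relative to total SD) is ordered
#' thickness > subcortical > area, the class ordering structural brain-age
#' models typically exhibit.
#'
#' @param thickness,area,subcortical,ventricle,icv named lists with elements
#'   `baseline`, `slope`, `quad`, `sex_offset`, `site_sd`, `resid_sd`,
#'   `hemi_sd`.
#' @return object of class `feature_model_spec`.
#' @export
feature_model_spec <- function(
    thickness   = list(baseline = 2.5,    slope = -0.005, quad = 0,
                       sex_offset = 0.03,  site_sd = 0.04,  resid_sd = 0.12,
                       hemi_sd = 0.04),
    area        = list(baseline = 2500,   slope = -2.5,   quad = 0,
                       sex_offset = 220,   site_sd = 50,    resid_sd = 145,
                       hemi_sd = 45),
    subcortical = list(baseline = 3800,   slope = -8,     quad = 0,
                       sex_offset = 280,   site_sd = 90,    resid_sd = 300,
                       hemi_sd = 90),
    ventricle   = list(baseline = 7000,   slope = 60,     quad = 0.8,
                       sex_offset = 800,   site_sd = 500,   resid_sd = 2500,
                       hemi_sd = 700),
    icv         = list(baseline = 1.45e6, slope = 0,      quad = 0,
                       sex_offset = 1.45e5, site_sd = 2e4, resid_sd = 1.2e5,
                       hemi_sd = 0)) {
  spec <- list(thickness = thickness, area = area, subcortical = subcortical,
               ventricle = ventricle, icv = icv)
  need <- c("baseline", "slope", "quad", "sex_offset", "site_sd", "resid_sd",
            "hemi_sd")
  for (cl in names(spec)) {
    miss <- setdiff(need, names(spec[[cl]]))
    if (length(miss) > 0L) {
      stop("feature_model_spec: class '", cl, "' missing: ",
           paste(miss, collapse = ", "))
    }
    if (spec[[cl]]$resid_sd < 0 || spec[[cl]]$site_sd < 0) {
      stop("feature_model_spec: negative SD in class '", cl, "'")
    }
  }
  if (thickness$slope >= 0)   stop("feature_model_spec: thickness slope must be < 0")
  if (area$slope >= 0)        stop("feature_model_spec: area slope must be < 0")
  if (subcortical$slope >= 0) stop("feature_model_spec: subcortical slope must be < 0")
  if (ventricle$slope <= 0)   stop("feature_model_spec: ventricle slope must be > 0")
  if (icv$slope != 0)         stop("feature_model_spec: icv slope must be 0")
  # standardized age signal ordering (age SD of uniform ages over ~55 years)
  sig <- vapply(spec[c("thickness", "subcortical", "area")], function(p) {
    s <- abs(p$slope) * 15.9
    s / sqrt(s^2 + p$resid_sd^2 + p$site_sd^2)
  }, numeric(1))
  noise_free <- all(vapply(spec[c("thickness", "subcortical", "area")],
                           function(p) p$resid_sd == 0 && p$site_sd == 0,
                           logical(1)))
  if (!noise_free &&
      !(sig["thickness"] > sig["subcortical"] &&
        sig["subcortical"] > sig["area"])) {
    stop("feature_model_spec: standardized age signal must be ordered ",
         "thickness > subcortical > area (got ",
         paste(sprintf("%s=%.3f", names(sig), sig), collapse = ", "), ")")
  }
  class(spec) <- "feature_model_spec"
  spec
}

# fixed per-feature baseline/slope multipliers (part of the model, not random)
feature_multipliers <- function() {
  sch <- feature_schema()
  cls <- sch$classes$class
  bmult <- numeric(length(cls))
  smult <- numeric(length(cls))
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    m <- length(idx)
    if (m == 1L) {
      bmult[idx] <- 1; smult[idx] <- 1
    } else {
      bmult[idx] <- seq(0.85, 1.15, length.out = m)
      # interleave slope multipliers so they are not collinear with baselines
      smult[idx] <- seq(0.70, 1.30, length.out = m)[order(order(seq_len(m) %% 7))]
    }
  }
  data.frame(feature = sch$classes$feature, class = cls,
             bmult = bmult, smult = smult, stringsAsFactors = FALSE)
}

#' Synthetic consortium configuration
#'
#' Full parameterization of the synthetic multi-cohort case-control
#' consortium: number of cohorts, per-cohort group-size and age ranges,
#' sex composition, multi-site structure, scanner field strength mix, the
#' true case-control ageing offset and its between-cohort heterogeneity,
#' clinical-variable distributions, and the seed.
#'
#' The diagnosis effect is injected along the ageing gradient: cohort `c`
#' draws an offset `Delta_c ~ N(delta_years, tau_years^2)` and each case's
#' features are generated at an effective "brain age" of
#' `age + Delta_c` (plus per-subject Gaussian jitter, SD
#' `subject_jitter_sd`, in both groups), i.e. case brains are shifted
#' `Delta_c` years along every feature's age trajectory.
#'
#' @param n_cohorts number of test cohorts (default 26).
#' @param n_case_range,n_control_range integer ranges for per-cohort group
#'   sizes.
#' @param age_range_test,age_range_train admissible age ranges (years).
#' @param pct_male_range_case,pct_male_range_control per-cohort ranges of the
#'   male fraction.
#' @param n_multisite how many cohorts are multi-site; `site_count_range`
#'   sites each (single-site otherwise).
#' @param site_count_range range of site counts for multi-site cohorts.
#' @param pct_3t fraction of cohorts scanned at 3T (rest 1.5T).
#' @param delta_years true mean case-control ageing offset in years.
#' @param tau_years between-cohort SD of the cohort-level offset (years).
#' @param sex_moderation attenuation of the cohort offset per percentage
#'   point of females: cohort mean offset =
#'   `delta_years + sex_moderation * (pct_female - 50)`.
#' @param subject_jitter_sd SD (years) of the per-subject "biological brain
#'   age" jitter around chronological age (default 8). This shared variation
#'   along the ageing gradient is what keeps multivariable brain-age
#'   prediction imperfect (independent feature noise averages away over 77
#'   features), so it calibrates the realistic control-group MAE/r regime
#'   and the within-group brain-PAD spread.
#' @param clinical_params list of clinical distribution parameters (see
#'   defaults).
#' @param clinical_effect optional `list(var = <clinical column>, slope =
#'   <years per unit>)`: adds `slope * (CC - mean CC)` to patients' ageing
#'   offsets, creating a true clinical association (default none: clinical
#'   variables are independent of the brain, a faithful null).
#' @param train_n_male,train_n_female training-sample sizes (healthy only).
#' @param patients_only_cohort if TRUE (default) the last cohort contributes
#'   patients only (no controls).
#' @param male_only_cohort if TRUE (default) the first cohort is 100% male.
#' @param feature_spec a [feature_model_spec()].
#' @param emit `"raw"` (153 columns, default) or `"averaged"` (77).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_cohorts = 26,
                             n_case_range = c(20L, 250L),
                             n_control_range = c(10L, 250L),
                             age_range_test = c(18, 73),
                             age_range_train = c(18, 75),
                             pct_male_range_case = c(0.44, 0.85),
                             pct_male_range_control = c(0.38, 0.72),
                             n_multisite = 6,
                             site_count_range = c(2L, 4L),
                             pct_3t = 0.6,
                             delta_years = 3.55,
                             tau_years = 1.5,
                             sex_moderation = 0,
                             subject_jitter_sd = 8,
                             clinical_params = NULL,
                             clinical_effect = NULL,
                             train_n_male = 952L,
                             train_n_female = 1236L,
                             patients_only_cohort = TRUE,
                             male_only_cohort = TRUE,
                             feature_spec = feature_model_spec(),
                             emit = c("raw", "averaged"),
                             seed = 1L) {
  emit <- match.arg(emit)
  default_clin <- list(
    onset_mean = 24.75, onset_sd = 5.5, onset_min = 16,
    panss_mean = 62.41, panss_sd = 15, panss_min = 30,
    sans_mean = 7.94, sans_sd = 4,
    saps_mean = 6.72, saps_sd = 4,
    cpz_meanlog = log(414.3) - 0.18, cpz_sdlog = 0.6,
    ap_probs = c(atypical = 0.6765, typical = 0.1005,
                 both = 0.1473, none = 0.0757),
    hand_probs = c(right = 0.9115, left = 0.06, ambidextrous = 0.0285))
  if (!is.null(clinical_params)) {
    default_clin[names(clinical_params)] <- clinical_params
  }
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_case_range = as.integer(n_case_range),
              n_control_range = as.integer(n_control_range),
              age_range_test = as.numeric(age_range_test),
              age_range_train = as.numeric(age_range_train),
              pct_male_range_case = pct_male_range_case,
              pct_male_range_control = pct_male_range_control,
              n_multisite = as.integer(n_multisite),
              site_count_range = as.integer(site_count_range),
              pct_3t = pct_3t,
              delta_years = delta_years,
              tau_years = tau_years,
              sex_moderation = sex_moderation,
              subject_jitter_sd = subject_jitter_sd,
              clinical_params = default_clin,
              clinical_effect = clinical_effect,
              train_n_male = as.integer(train_n_male),
              train_n_female = as.integer(train_n_female),
              patients_only_cohort = isTRUE(patients_only_cohort),
              male_only_cohort = isTRUE(male_only_cohort),
              feature_spec = feature_spec,
              emit = emit,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  chk_range <- function(r, name, lo = -Inf, hi = Inf, strict = TRUE) {
    if (length(r) != 2L || anyNA(r) || (strict && r[1] > r[2])) {
      stop("generator_config: invalid range for '", name, "'")
    }
    if (r[1] < lo || r[2] > hi) {
      stop("generator_config: '", name, "' outside admissible bounds [",
           lo, ", ", hi, "]")
    }
  }
  if (is.na(cfg$n_cohorts) || cfg$n_cohorts < 1L) {
    stop("generator_config: 'n_cohorts' must be a positive integer")
  }
  chk_range(cfg$n_case_range, "n_case_range", 1)
  chk_range(cfg$n_control_range, "n_control_range", 0)
  chk_range(cfg$age_range_test, "age_range_test", 18, 75)
  chk_range(cfg$age_range_train, "age_range_train", 18, 75)
  chk_range(cfg$pct_male_range_case, "pct_male_range_case", 0, 1)
  chk_range(cfg$pct_male_range_control, "pct_male_range_control", 0, 1)
  if (cfg$tau_years < 0) stop("generator_config: 'tau_years' must be >= 0")
  if (cfg$subject_jitter_sd < 0) {
    stop("generator_config: 'subject_jitter_sd' must be >= 0")
  }
  if (cfg$n_multisite < 0 || cfg$n_multisite > cfg$n_cohorts) {
    stop("generator_config: 'n_multisite' must be in [0, n_cohorts]")
  }
  chk_range(cfg$site_count_range, "site_count_range", 1)
  if (cfg$pct_3t < 0 || cfg$pct_3t > 1) {
    stop("generator_config: 'pct_3t' must be in [0, 1]")
  }
  if (!is.null(cfg$clinical_effect)) {
    if (!is.list(cfg$clinical_effect) ||
        !all(c("var", "slope") %in% names(cfg$clinical_effect))) {
      stop("generator_config: 'clinical_effect' must be list(var=, slope=)")
    }
  }
  ap <- cfg$clinical_params$ap_probs
  if (abs(sum(ap) - 1) > 0.01 || any(ap < 0)) {
    stop("generator_config: 'clinical_params$ap_probs' must be a probability vector")
  }
  invisible(cfg)
}

# draw features (averaged layout) for subjects with an effective brain age
draw_features <- function(brain_age, male, site_idx, site_effects, spec) {
  mult <- feature_multipliers()
  n <- length(brain_age)
  m <- matrix(0, n, nrow(mult), dimnames = list(NULL, mult$feature))
  a <- brain_age - 45
  for (j in seq_len(nrow(mult))) {
    p <- spec[[mult$class[j]]]
    mu <- p$baseline * mult$bmult[j] + p$slope * mult$smult[j] * a +
      p$quad * a^2 + p$sex_offset * male + site_effects[site_idx, j]
    v <- mu + stats::rnorm(n, 0, p$resid_sd)
    m[, j] <- pmax(v, 0.02 * p$baseline * mult$bmult[j])
  }
  m
}

split_hemispheres <- function(avg, spec) {
  sch <- feature_schema()
  mult <- feature_multipliers()
  n <- nrow(avg)
  out <- matrix(0, n, length(sch$raw), dimnames = list(NULL, sch$raw))
  for (i in seq_len(nrow(sch$pairs))) {
    p <- sch$pairs[i, ]
    cl <- mult$class[mult$feature == p$avg]
    d <- stats::rnorm(n, 0, spec[[cl]]$hemi_sd)
    out[, p$left]  <- avg[, p$avg] + d
    out[, p$right] <- avg[, p$avg] - d
  }
  out[, "icv"] <- avg[, "icv"]
  out
}

assemble_table <- function(meta, avg, spec, emit) {
  feats <- if (emit == "raw") split_hemispheres(avg, spec) else avg
  out <- cbind(meta, as.data.frame(feats))
  rownames(out) <- NULL
  attr(out, "feature_kind") <- emit
  out
}

empty_clinical <- function(n) {
  data.frame(handedness = rep(NA_character_, n),
             onset = NA_real_, duration = NA_real_, panss_total = NA_real_,
             sans_global = NA_real_, saps_global = NA_real_,
             ap_class = NA_character_, cpz = NA_real_,
             stringsAsFactors = FALSE)
}

draw_clinical <- function(age, cp) {
  n <- length(age)
  onset <- stats::rnorm(n, cp$onset_mean, cp$onset_sd)
  onset <- pmin(pmax(onset, cp$onset_min), age - 0.1)
  ap <- sample(names(cp$ap_probs), n, replace = TRUE, prob = cp$ap_probs)
  cpz <- exp(stats::rnorm(n, cp$cpz_meanlog, cp$cpz_sdlog))
  cpz[ap == "none"] <- NA_real_
  data.frame(
    handedness = sample(names(cp$hand_probs), n, replace = TRUE,
                        prob = cp$hand_probs),
    onset = onset,
    duration = age - onset,
    panss_total = pmax(cp$panss_min, stats::rnorm(n, cp$panss_mean, cp$panss_sd)),
    sans_global = pmax(0, stats::rnorm(n, cp$sans_mean, cp$sans_sd)),
    saps_global = pmax(0, stats::rnorm(n, cp$saps_mean, cp$saps_sd)),
    ap_class = ap,
    cpz = cpz,
    stringsAsFactors = FALSE)
}

#' Generate the healthy training sample
#'
#' Healthy adults only (no diagnosis offset), by default 952 males and 1236
#' females with ages uniform on the training age range, scanned at a single
#' notional site without site effects. Used to train the sex-stratified
#' brain-age models.
#'
#' @param config a [generator_config()].
#' @return feature table (raw or averaged layout per `config$emit`).
#' @export
generate_training_sample <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$train_n_male + config$train_n_female
  male <- rep(c(1L, 0L), c(config$train_n_male, config$train_n_female))
  age <- stats::runif(n, config$age_range_train[1], config$age_range_train[2])
  brain_age <- age + stats::rnorm(n, 0, config$subject_jitter_sd)
  site_effects <- matrix(0, 1, 77)
  avg <- draw_features(brain_age, male, rep(1L, n), site_effects,
                       config$feature_spec)
  meta <- cbind(
    data.frame(subject_id = sprintf("TRAIN_%05d", seq_len(n)),
               cohort = "TRAIN", site = "TRAIN_s1", age = age,
               sex = ifelse(male == 1L, "male", "female"), dx = "HC",
               stringsAsFactors = FALSE),
    empty_clinical(n)[, c("handedness", "onset", "duration", "panss_total",
                          "sans_global", "saps_global", "ap_class", "cpz")])
  hand <- config$clinical_params$hand_probs
  meta$handedness <- sample(names(hand), n, replace = TRUE, prob = hand)
  assemble_table(meta, avg, config$feature_spec, config$emit)
}

#' Draw the per-cohort design of a consortium
#'
#' Internal randomisation of cohort-level settings (sizes, age window, sex
#' mix, site structure, field strength) from the configured ranges.
#' @keywords internal
draw_cohort_specs <- function(config) {
  k <- config$n_cohorts
  rint <- function(r, n) {
    if (r[1] == r[2]) rep(r[1], n) else sample(seq(r[1], r[2]), n, replace = TRUE)
  }
  mid <- stats::runif(k, 27, 41)               # cohort mean-age targets
  halfw <- stats::runif(k, 6, 14)
  lo <- pmax(config$age_range_test[1], mid - halfw)
  hi <- pmin(config$age_range_test[2], mid + halfw)
  specs <- data.frame(
    cohort_id = sprintf("C%02d", seq_len(k)),
    n_case = rint(config$n_case_range, k),
    n_control = rint(config$n_control_range, k),
    age_lo = lo, age_hi = hi,
    pct_male_case = stats::runif(k, config$pct_male_range_case[1],
                                 config$pct_male_range_case[2]),
    pct_male_control = stats::runif(k, config$pct_male_range_control[1],
                                    config$pct_male_range_control[2]),
    n_sites = 1L,
    field_strength = ifelse(stats::runif(k) < config$pct_3t, "3T", "1.5T"),
    patients_only = FALSE,
    stringsAsFactors = FALSE)
  if (config$n_multisite > 0L) {
    # spread multi-site status deterministically over the roster
    ms <- unique(round(seq(2, max(2, k - 1),
                           length.out = min(config$n_multisite, k))))
    specs$n_sites[ms] <- rint(config$site_count_range, length(ms))
  }
  if (config$patients_only_cohort) {
    specs$patients_only[k] <- TRUE
    specs$n_control[k] <- 0L
  }
  if (config$male_only_cohort) {
    specs$pct_male_case[1] <- 1
    specs$pct_male_control[1] <- 1
  }
  specs
}

#' Generate one synthetic cohort
#'
#' Cases are shifted `Delta_c` years along every feature's ageing trajectory,
#' with `Delta_c ~ N(delta_years, tau_years^2)` drawn once per cohort
#' (optionally attenuated by the cohort's percent female); every subject
#' additionally carries Gaussian "biological age" jitter. Site effects are
#' drawn once per site and added to all its subjects; clinical variables are
#' drawn for cases from the configured distributions (independent of the
#' brain unless `clinical_effect` is set).
#'
#' @param spec one row of [draw_cohort_specs()] (or a list with the same
#'   fields: `cohort_id`, `n_case`, `n_control`, `age_lo`, `age_hi`,
#'   `pct_male_case`, `pct_male_control`, `n_sites`, `field_strength`,
#'   `patients_only`).
#' @param config a [generator_config()].
#' @param seed integer seed for this cohort.
#' @return feature table with metadata (class attribute `cohort_info` holds
#'   `delta_c` and the field strength).
#' @export
generate_cohort <- function(spec, config, seed) {
  stopifnot(inherits(config, "generator_config"))
  spec <- as.list(spec)
  if (spec$n_case < 1L) stop("generate_cohort: n_case must be >= 1")
  set.seed(as.integer(seed))
  n_case <- as.integer(spec$n_case)
  n_ctrl <- as.integer(spec$n_control)
  n <- n_case + n_ctrl
  dx <- rep(c("SZ", "HC"), c(n_case, n_ctrl))
  n_male_case <- round(n_case * spec$pct_male_case)
  n_male_ctrl <- if (n_ctrl > 0L) round(n_ctrl * spec$pct_male_control) else 0L
  male <- c(rep(c(1L, 0L), c(n_male_case, n_case - n_male_case)),
            rep(c(1L, 0L), c(n_male_ctrl, n_ctrl - n_male_ctrl)))
  age <- stats::runif(n, spec$age_lo, spec$age_hi)

  pct_female <- 100 * (1 - sum(male) / n)
  delta_mean <- config$delta_years +
    config$sex_moderation * (pct_female - 50)
  delta_c <- stats::rnorm(1, delta_mean, config$tau_years)

  clin <- empty_clinical(n)
  is_case <- dx == "SZ"
  clin[is_case, ] <- draw_clinical(age[is_case], config$clinical_params)
  hand <- config$clinical_params$hand_probs
  if (any(!is_case)) {
    clin$handedness[!is_case] <- sample(names(hand), sum(!is_case),
                                        replace = TRUE, prob = hand)
  }

  offset <- stats::rnorm(n, 0, config$subject_jitter_sd)
  offset[is_case] <- offset[is_case] + delta_c
  ce <- config$clinical_effect
  if (!is.null(ce) && !is.null(ce$slope) && ce$slope != 0) {
    cc <- clin[[ce$var]][is_case]
    offset[is_case] <- offset[is_case] + ce$slope * (cc - mean(cc, na.rm = TRUE))
  }
  brain_age <- age + offset

  site_ids <- sprintf("%s_s%d", spec$cohort_id, seq_len(spec$n_sites))
  site_idx <- sample(rep(seq_len(spec$n_sites), length.out = n))
  sp <- config$feature_spec
  mult <- feature_multipliers()
  site_effects <- matrix(0, spec$n_sites, 77)
  if (spec$n_sites > 1L) {
    for (j in seq_len(77)) {
      site_effects[, j] <- stats::rnorm(spec$n_sites, 0,
                                        sp[[mult$class[j]]]$site_sd)
    }
  }
  avg <- draw_features(brain_age, male, site_idx, site_effects, sp)
  meta <- cbind(
    data.frame(subject_id = sprintf("%s_%04d", spec$cohort_id, seq_len(n)),
               cohort = spec$cohort_id, site = site_ids[site_idx],
               age = age, sex = ifelse(male == 1L, "male", "female"),
               dx = dx, stringsAsFactors = FALSE),
    clin)
  tab <- assemble_table(meta, avg, sp, config$emit)
  attr(tab, "cohort_info") <- list(cohort_id = spec$cohort_id,
                                   delta_c = delta_c,
                                   field_strength = spec$field_strength,
                                   n_sites = spec$n_sites)
  tab
}

#' Generate a full synthetic consortium
#'
#' Draws the cohort roster ([draw_cohort_specs()]) and generates each cohort
#' with a seed derived from the configuration seed, so the whole consortium
#' is reproduced byte-identically from `(config, seed)`.
#'
#' @param config a [generator_config()].
#' @return named list of cohort feature tables (one per cohort), with the
#'   roster in attribute `cohort_specs`.
#' @export
generate_consortium <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  specs <- draw_cohort_specs(config)
  cohorts <- vector("list", nrow(specs))
  names(cohorts) <- specs$cohort_id
  for (i in seq_len(nrow(specs))) {
    cohorts[[i]] <- generate_cohort(specs[i, ], config,
                                    seed = config$seed + 1000L * i)
  }
  attr(cohorts, "cohort_specs") <- specs
  cohorts
}

weighted_stat <- function(means, weights) {
  ok <- is.finite(means) & is.finite(weights) & weights > 0
  if (!any(ok)) return(c(mean = NA_real_, min = NA_real_, max = NA_real_, k = 0))
  c(mean = sum(means[ok] * weights[ok]) / sum(weights[ok]),
    min = min(means[ok]), max = max(means[ok]), k = sum(ok))
}

#' Weighted demographic and clinical summary of a consortium
#'
#' Per-characteristic weighted mean and min-max range of the per-cohort
#' means, weights equal to the per-cohort group size (for antipsychotic-class
#' percentages: the number of cases with a recorded class). This is the
#' machine-readable analogue of a consortium demographics table.
#'
#' @param cohorts list of cohort feature tables (e.g. from
#'   [generate_consortium()]).
#' @return data.frame with columns `characteristic`, `group`,
#'   `weighted_mean`, `min`, `max`, `k`.
#' @export
describe_consortium <- function(cohorts) {
  if (length(cohorts) < 1L) stop("describe_consortium: no cohorts supplied")
  per <- lapply(cohorts, function(tab) {
    sz <- tab[tab$dx == "SZ", , drop = FALSE]
    hc <- tab[tab$dx == "HC", , drop = FALSE]
    ap_n <- sum(!is.na(sz$ap_class))
    list(
      n_sz = nrow(sz), n_hc = nrow(hc), ap_n = ap_n,
      cpz_n = sum(!is.na(sz$cpz)),
      sz = c(pct_male = 100 * mean(sz$sex == "male"),
             mean_age = mean(sz$age),
             onset = mean(sz$onset, na.rm = TRUE),
             duration = mean(sz$duration, na.rm = TRUE),
             panss_total = mean(sz$panss_total, na.rm = TRUE),
             sans_global = mean(sz$sans_global, na.rm = TRUE),
             saps_global = mean(sz$saps_global, na.rm = TRUE),
             cpz = mean(sz$cpz, na.rm = TRUE)),
      hc = c(pct_male = if (nrow(hc) > 0) 100 * mean(hc$sex == "male") else NA_real_,
             mean_age = if (nrow(hc) > 0) mean(hc$age) else NA_real_),
      ap = if (ap_n > 0) {
        100 * vapply(c("atypical", "typical", "both", "none"), function(l) {
          mean(sz$ap_class == l, na.rm = TRUE)
        }, numeric(1))
      } else rep(NA_real_, 4))
  })
  g <- function(f) vapply(per, f, numeric(1))
  rows <- list()
  add <- function(characteristic, group, means, weights) {
    s <- weighted_stat(means, weights)
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = characteristic, group = group,
      weighted_mean = s["mean"], min = s["min"], max = s["max"], k = s["k"],
      stringsAsFactors = FALSE)
  }
  n_sz <- g(function(p) p$n_sz); n_hc <- g(function(p) p$n_hc)
  for (ch in c("pct_male", "mean_age", "onset", "duration", "panss_total",
               "sans_global", "saps_global")) {
    add(ch, "SZ", g(function(p) p$sz[[ch]]), n_sz)
  }
  add("cpz", "SZ", g(function(p) p$sz[["cpz"]]), g(function(p) p$cpz_n))
  for (ch in c("pct_male", "mean_age")) {
    add(ch, "HC", g(function(p) p$hc[[ch]]), n_hc)
  }
  ap_w <- g(function(p) p$ap_n)
  labs <- c("pct_ap_atypical", "pct_ap_typical", "pct_ap_both", "pct_ap_none")
  for (i in 1:4) {
    add(labs[i], "SZ", g(function(p) p$ap[i]), ap_w)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
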