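test_that("training sample has the configured composition and seeding contract", {
  cfg <- generator_config(seed = 1, emit = "averaged")
  tab <- generate_training_sample(cfg)
  expect_identical(nrow(tab), 2188L)
  expect_identical(sum(tab$sex == "male"), 952L)
  expect_identical(sum(tab$sex == "female"), 1236L)
  expect_true(all(tab$dx == "HC"))
  expect_true(all(tab$age >= 18 & tab$age <= 75))
  expect_true(all(is.na(tab$onset)))

  # same seed -> identical; different seed -> different
  cfg_small <- tiny_config(seed = 1)
  t1 <- generate_training_sample(cfg_small)
  t2 <- generate_training_sample(cfg_small)
  expect_identical(t1, t2)
  t3 <- generate_training_sample(tiny_config(seed = 2))
  expect_false(isTRUE(all.equal(t1$icv, t3$icv)))
})

test_that("noise-free generator is an exact deterministic function of age and sex", {
  nf <- function(p) { p$resid_sd <- 0; p$site_sd <- 0; p$hemi_sd <- 0; p }
  spec <- do.call(feature_model_spec,
                  lapply(feature_model_spec(), nf))
  cfg <- tiny_config(seed = 5, feature_spec = spec, subject_jitter_sd = 0)
  tab <- generate_training_sample(cfg)
  mult <- brainpad:::feature_multipliers()
  j <- which(mult$feature == "fusiform_thick")
  p <- spec$thickness
  expected <- p$baseline * mult$bmult[j] +
    p$slope * mult$smult[j] * (tab$age - 45) +
    p$sex_offset * (tab$sex == "male")
  expect_equal(tab$fusiform_thick, expected, tolerance = 1e-12)
  # ICV is age-flat: only sex moves it
  expect_true(all(tapply(tab$icv, tab$sex, var) < 1e-12))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(generator_config(n_cohorts = 0), "n_cohorts")
  expect_error(generator_config(tau_years = -1), "tau_years")
  expect_error(generator_config(age_range_test = c(10, 73)), "age_range_test")
  expect_error(generator_config(pct_male_range_case = c(0.9, 0.5)),
               "pct_male_range_case")
  expect_error(generator_config(site_count_range = c(0L, 2L)),
               "site_count_range")
})

test_that("cohort generation honours the null model, site structure and clinical margins", {
  cfg <- tiny_config(seed = 2, delta_years = 0, tau_years = 0)
  spec <- list(cohort_id = "C01", n_case = 4000, n_control = 4000,
               age_lo = 20, age_hi = 60, pct_male_case = 0.5,
               pct_male_control = 0.5, n_sites = 3, field_strength = "3T",
               patients_only = FALSE)
  tab <- generate_cohort(spec, cfg, seed = 10)
  expect_identical(length(unique(tab$site)), 3L)
  # delta = 0, tau = 0: case and control feature means agree in law
  for (f in c("fusiform_thick", "hippocampus_vol", "latvent_vol")) {
    cases <- tab[[f]][tab$dx == "SZ"]; ctrls <- tab[[f]][tab$dx == "HC"]
    expect_lt(abs(mean(cases) - mean(ctrls)),
              4 * sd(tab[[f]]) * sqrt(2 / 4000))
  }
  # antipsychotic class margins within sampling error of the configured mix
  ap <- table(tab$ap_class[tab$dx == "SZ"]) / 4000
  probs <- cfg$clinical_params$ap_probs
  for (l in names(probs)) {
    expect_lt(abs(ap[[l]] - probs[[l]]),
              4 * sqrt(probs[[l]] * (1 - probs[[l]]) / 4000))
  }
  # duration identity and clinical domains
  sz <- tab[tab$dx == "SZ", ]
  expect_equal(sz$duration, sz$age - sz$onset, tolerance = 1e-12)
  expect_true(all(sz$duration >= 0))
  expect_true(all(sz$panss_total >= 30) && all(sz$sans_global >= 0))
  expect_true(all(is.na(sz$cpz[sz$ap_class == "none"])))
  expect_true(all(!is.na(sz$cpz[sz$ap_class != "none"])))
  expect_true(all(is.na(tab$onset[tab$dx == "HC"])))
})

test_that("injected diagnosis effect shifts each feature by Delta x its age slope", {
  cfg <- tiny_config(seed = 4, delta_years = 5, tau_years = 0)
  spec <- list(cohort_id = "C01", n_case = 10000, n_control = 10000,
               age_lo = 20, age_hi = 60, pct_male_case = 0.5,
               pct_male_control = 0.5, n_sites = 1, field_strength = "3T",
               patients_only = FALSE)
  tab <- generate_cohort(spec, cfg, seed = 20)
  mult <- brainpad:::feature_multipliers()
  fsp <- cfg$feature_spec
  ratios <- vapply(which(mult$class %in% c("thickness", "subcortical", "area")),
                   function(j) {
    f <- mult$feature[j]
    diff <- mean(tab[[f]][tab$dx == "SZ"]) - mean(tab[[f]][tab$dx == "HC"])
    slope <- fsp[[mult$class[j]]]$slope * mult$smult[j]
    diff / slope
  }, numeric(1))
  # each feature's implied Delta is near 5 on average over features
  expect_lt(abs(mean(ratios) - 5), 0.5)
  expect_gt(min(ratios), 0)
})

test_that("large-sample feature-age correlations are ordered thickness > subcortical > area with positive ventricle", {
  cfg <- tiny_config(seed = 6)
  spec <- list(cohort_id = "C01", n_case = 1, n_control = 12000,
               age_lo = 18, age_hi = 73, pct_male_case = 1,
               pct_male_control = 0.5, n_sites = 1, field_strength = "3T",
               patients_only = FALSE)
  tab <- generate_cohort(spec, cfg, seed = 30)
  hc <- tab[tab$dx == "HC", ]
  m <- feature_matrix(hc)
  r <- drop(cor(m, hc$age))
  cls <- feature_schema()$classes$class
  mean_abs <- tapply(abs(r), cls, mean)
  expect_gt(mean_abs[["thickness"]], mean_abs[["subcortical"]])
  expect_gt(mean_abs[["subcortical"]], mean_abs[["area"]])
  expect_gt(r[cls == "ventricle"], 0)
  expect_true(all(r[cls %in% c("thickness", "subcortical", "area")] < 0))
})

test_that("consortium roster matches the configured design", {
  cfg <- generator_config(seed = 8, emit = "averaged")
  cons <- generate_consortium(cfg)
  expect_length(cons, 26)
  specs <- attr(cons, "cohort_specs")
  expect_identical(sum(specs$patients_only), 1L)
  expect_identical(specs$n_control[specs$patients_only], 0L)
  expect_identical(specs$pct_male_case[1], 1)
  expect_identical(sum(specs$n_sites > 1), 6L)
  # small consortium
  cons3 <- generate_consortium(tiny_config(seed = 9, n_cohorts = 3,
                                           n_multisite = 1,
                                           patients_only_cohort = FALSE))
  expect_length(cons3, 3)
})

test_that("weighted consortium description reproduces closed-form weighted means", {
  a <- make_avg_table(1, seed = 1, age = 10, dx = "SZ", cohort = "A")
  b <- make_avg_table(3, seed = 2, age = rep(20, 3), dx = rep("SZ", 3),
                      cohort = "B")
  b$subject_id <- paste0("B", b$subject_id)
  d <- describe_consortium(list(A = a, B = b))
  row <- d[d$characteristic == "mean_age" & d$group == "SZ", ]
  expect_equal(row$weighted_mean, 17.5)
  expect_equal(c(row$min, row$max), c(10, 20))
  # single cohort: mean equals the cohort mean, range collapses
  d1 <- describe_consortium(list(A = b))
  r1 <- d1[d1$characteristic == "mean_age" & d1$group == "SZ", ]
  expect_equal(r1$weighted_mean, 20)
  expect_equal(r1$min, r1$max)
  expect_error(describe_consortium(list()), "no cohorts")
})

test_that("default consortium demographics land inside the intended published-style ranges", {
  cfg <- generator_config(seed = 11, emit = "averaged")
  cons <- generate_consortium(cfg)
  d <- describe_consortium(cons)
  g <- function(ch, grp) d$weighted_mean[d$characteristic == ch & d$group == grp]
  expect_gt(g("mean_age", "SZ"), 18.36); expect_lt(g("mean_age", "SZ"), 43.66)
  expect_gt(g("mean_age", "HC"), 22.58); expect_lt(g("mean_age", "HC"), 41.41)
  expect_lt(abs(g("onset", "SZ") - 24.75), 2.5)
  expect_lt(abs(g("duration", "SZ") - 10.83), 3.5)
  expect_lt(abs(g("panss_total", "SZ") - 62.41), 3)
  expect_lt(abs(g("pct_ap_atypical", "SZ") - 67.65), 5)
})
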