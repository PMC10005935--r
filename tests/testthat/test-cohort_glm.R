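test_that("noise-free constructed coefficients are recovered to machine precision", {
  d <- make_glm_cohort(n = 200, seed = 1, n_sites = 3)
  eff <- suppressWarnings(fit_dx_model(d))  # noise-free: perfect-fit warning
  expect_equal(eff$beta[eff$term == "dx"], 3, tolerance = 1e-10)
  expect_equal(eff$beta[eff$term == "sex"], 1.5, tolerance = 1e-10)
  expect_equal(eff$beta[eff$term == "age"], -0.2, tolerance = 1e-10)
  expect_equal(eff$beta[eff$term == "age2"], 0.01, tolerance = 1e-10)
  # three sites -> exactly two site dummy rows
  expect_identical(sum(grepl("^site", eff$term)), 2L)
  # CI identity and d/t sign coherence
  i <- which(eff$term == "dx")
  expect_equal(eff$ci_low[i], eff$beta[i] - qt(0.975, eff$df[i]) * eff$se[i])
  expect_equal(eff$ci_high[i], eff$beta[i] + qt(0.975, eff$df[i]) * eff$se[i])
  expect_equal(sign(eff$d[i]), sign(eff$t[i]))
})

test_that("degrees of freedom equal n minus fitted parameters", {
  d <- make_glm_cohort(n = 150, seed = 2, n_sites = 2, noise_sd = 1)
  eff <- fit_dx_model(d)
  # intercept + dx + sex + age + age2 + 1 site dummy = 6
  expect_equal(unique(eff$df), 150 - 6)
})

test_that("single-sex cohorts drop the sex term; collinear designs error", {
  d <- make_glm_cohort(n = 80, seed = 3)
  d$sex <- "male"
  d$brainpad <- 1 + 3 * (d$dx == "SZ") - 0.2 * (d$age - mean(d$age))
  suppressWarnings(expect_message(eff <- fit_dx_model(d), "sex term dropped"))
  expect_false("sex" %in% eff$term)
  expect_equal(eff$beta[eff$term == "dx"], 3, tolerance = 1e-10)

  # site perfectly confounded with diagnosis
  d2 <- make_glm_cohort(n = 60, seed = 4, noise_sd = 1)
  d2$site <- ifelse(d2$dx == "SZ", "s1", "s2")
  expect_error(fit_dx_model(d2), "collinear")
})

test_that("site adjustment leaves the diagnosis estimate unchanged in balanced designs", {
  # balanced: every site has the same dx composition; site effects cancel
  n <- 160
  d <- data.frame(
    cohort = "B01",
    dx = rep(c("SZ", "HC"), each = n / 2),
    sex = rep(c("male", "female"), n / 2),
    age = rep(runif(n / 2, 20, 60), 2),
    site = rep(rep(c("s1", "s2"), each = n / 4), 2),
    stringsAsFactors = FALSE)
  set.seed(5)
  agec <- d$age - mean(d$age)
  noise <- rnorm(n / 2)
  d$brainpad <- 2 * (d$dx == "SZ") + 4 * (d$site == "s2") - 0.1 * agec +
    rep(noise, 2)
  eff_site <- fit_dx_model(d)
  d_nosite <- d; d_nosite$site <- "s1"
  eff_flat <- fit_dx_model(d_nosite)
  expect_equal(eff_site$beta[eff_site$term == "dx"],
               eff_flat$beta[eff_flat$term == "dx"], tolerance = 1e-8)
})

test_that("Cohen's d conversion matches its formula and the two-sample oracle", {
  r <- cohens_d_from_t(0, 40, 60, 96)
  expect_equal(r$d, 0)
  expect_equal(r$var_d, 100 / 2400)
  r2 <- cohens_d_from_t(2, 50, 50, 96)
  expect_equal(r2$d, 2 * 100 / (50 * sqrt(96)))
  expect_equal(r2$var_d, 100 / 2500 + r2$d^2 / 200)
  expect_error(cohens_d_from_t(1, 50, 50, 0), "df")

  # covariate-free two-group design: d equals the standardized mean
  # difference with pooled SD
  set.seed(6)
  g1 <- rnorm(40, 1, 2); g2 <- rnorm(60, 0, 2)
  tt <- t.test(g1, g2, var.equal = TRUE)
  n1 <- 40; n2 <- 60; df <- n1 + n2 - 2
  d_conv <- cohens_d_from_t(unname(tt$statistic), n1, n2, df)$d
  # the t-to-d conversion is exactly the mean difference over the pooled SD
  # with total-n denominator (sqrt(SS_pooled / (n1 + n2)))
  sp <- sqrt(((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2))
  d_direct <- (mean(g1) - mean(g2)) / sp
  expect_lt(abs(d_conv - d_direct), 1e-6)
})

test_that("clinical models recover injected slopes and honour contrast labelling", {
  set.seed(7)
  n <- 150
  pats <- data.frame(
    cohort = "P01", dx = "SZ", sex = "male",
    age = runif(n, 20, 60), site = "P01_s1",
    sans_global = pmax(0, rnorm(n, 8, 4)),
    ap_class = sample(c("atypical", "typical", "both", "none"), n,
                      replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15)),
    handedness = "right",
    stringsAsFactors = FALSE)
  pats$brainpad <- 0.2 * pats$sans_global + rnorm(n, 0, 2)
  eff <- fit_clinical_model(pats, "sans_global")
  i <- which(eff$term == "sans_global")
  expect_lt(abs(eff$beta[i] - 0.2), 4 * eff$se[i])

  ap <- fit_ap_contrasts(pats)
  expect_setequal(ap$term, c("ap_atypical_vs_unmed", "ap_typical_vs_unmed",
                             "ap_both_vs_unmed"))
  # a small subgroup drops only its contrast
  pats2 <- pats[!(pats$ap_class == "typical" &
                    duplicated(pats$ap_class == "typical") == FALSE), ]
  pats2 <- pats
  idx <- which(pats2$ap_class == "typical")
  pats2$ap_class[idx[-(1:4)]] <- "atypical"   # leave 4 typical users
  ap2 <- fit_ap_contrasts(pats2)
  expect_false("ap_typical_vs_unmed" %in% ap2$term)
  expect_true("ap_atypical_vs_unmed" %in% ap2$term)
  expect_match(attr(ap2, "skipped"), "ap_typical_vs_unmed", all = FALSE)

  expect_error(fit_clinical_model(pats, "panss_total"), "panss_total")
  pats$panss_total <- 50
  expect_error(fit_clinical_model(pats, "panss_total"), "constant")
})

test_that("clinical slope CIs cover an injected effect in most replicates", {
  covered <- 0
  for (i in 1:100) {
    set.seed(100 + i)
    n <- 80
    pats <- data.frame(cohort = "P01", dx = "SZ", sex = "female",
                       age = runif(n, 20, 60), site = "s1",
                       sans_global = pmax(0, rnorm(n, 8, 4)),
                       stringsAsFactors = FALSE)
    pats$brainpad <- 0.2 * pats$sans_global + rnorm(n, 0, 2)
    eff <- fit_clinical_model(pats, "sans_global")
    j <- which(eff$term == "sans_global")
    covered <- covered + (eff$ci_low[j] <= 0.2 && 0.2 <= eff$ci_high[j])
  }
  expect_gte(covered, 90)
})

test_that("eligibility decisions follow the control, subgroup and sensitivity rules", {
  rule <- eligibility_rule()
  d <- data.frame(dx = rep(c("SZ", "HC"), c(40, 9)),
                  sex = sample(rep(c("male", "female"), length.out = 49)),
                  stringsAsFactors = FALSE)
  dec <- check_eligibility(d, rule, context = "dx")
  expect_false(dec$include)
  expect_match(dec$reasons, "min_controls", all = FALSE)

  d2 <- data.frame(dx = rep(c("SZ", "HC"), c(40, 30)),
                   sex = rep(c("male", "female"), c(67, 3)),
                   stringsAsFactors = FALSE)
  dec2 <- check_eligibility(d2, rule, context = "dx")
  expect_false(dec2$include)
  expect_match(dec2$reasons, "female", all = FALSE)

  # all-male cohort: the sex subgroup is empty, the term is dropped instead
  d3 <- data.frame(dx = rep(c("SZ", "HC"), c(40, 30)), sex = "male",
                   stringsAsFactors = FALSE)
  expect_true(check_eligibility(d3, rule, context = "dx")$include)

  # sensitivity thresholds
  dec4 <- check_eligibility(d3, rule, context = "dx", sensitivity = TRUE,
                            control_mae = 10.5, control_r2 = 0.4)
  expect_false(dec4$include)
  expect_match(dec4$reasons, "control_mae", all = FALSE)
  expect_true(check_eligibility(d3, rule, context = "dx", sensitivity = TRUE,
                                control_mae = 9.5, control_r2 = 0.4)$include)
  expect_false(check_eligibility(d3, rule, context = "dx", sensitivity = TRUE,
                                 control_mae = 9.5, control_r2 = 0.05)$include)
  expect_error(check_eligibility(d3, rule, context = "dx", sensitivity = TRUE),
               "control_mae")
})

test_that("diagnosis test keeps its nominal size under the null with age-age2 adjustment", {
  # raw brain-PAD is age-dependent (regression to the mean); the covariates
  # must leave the null dx test at its nominal level
  reps <- 400; alpha <- 0.05
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    set.seed(2000 + i)
    n <- 80
    d <- data.frame(cohort = "N01",
                    dx = rep(c("SZ", "HC"), each = n / 2),
                    sex = sample(c("male", "female"), n, replace = TRUE),
                    age = runif(n, 20, 65), site = "s1",
                    stringsAsFactors = FALSE)
    # age-bias: brain-PAD shrinks with age, plus curvature
    d$brainpad <- 10 - 0.25 * d$age + 0.002 * d$age^2 + rnorm(n, 0, 3)
    eff <- suppressMessages(fit_dx_model(d))
    rej[i] <- eff$p[eff$term == "dx"] < alpha
  }
  expect_lt(abs(mean(rej) - alpha), 0.03)
})
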