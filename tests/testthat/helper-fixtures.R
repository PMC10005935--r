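# Shared fixtures and independent oracles for the test suite.

# small consortium configuration for fast end-to-end tests
tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_cohorts = 4,
    n_case_range = c(40L, 60L),
    n_control_range = c(30L, 50L),
    n_multisite = 1,
    train_n_male = 250L,
    train_n_female = 300L,
    emit = "averaged",
    seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# a minimal averaged feature table built from scratch: constant-plus-noise
# positive features with full metadata
make_avg_table <- function(n, seed = 1, age = NULL, sex = NULL, dx = NULL,
                           cohort = "T01", site = "T01_s1") {
  set.seed(seed)
  sch <- feature_schema()
  if (is.null(age)) age <- runif(n, 20, 70)
  if (is.null(sex)) sex <- sample(c("male", "female"), n, replace = TRUE)
  if (is.null(dx)) dx <- sample(c("SZ", "HC"), n, replace = TRUE)
  tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    cohort = cohort, site = site, age = age, sex = sex,
                    dx = dx, handedness = "right", onset = NA_real_,
                    duration = NA_real_, panss_total = NA_real_,
                    sans_global = NA_real_, saps_global = NA_real_,
                    ap_class = NA_character_, cpz = NA_real_,
                    stringsAsFactors = FALSE)
  for (f in sch$averaged) tab[[f]] <- abs(rnorm(n, 100, 10)) + 1
  tab
}

# constructed cohort with exactly known linear-model coefficients
make_glm_cohort <- function(n = 120, seed = 1, n_sites = 1,
                            beta_dx = 3, beta_sex = 1.5, beta_age = -0.2,
                            beta_age2 = 0.01, site_effects = NULL,
                            noise_sd = 0) {
  set.seed(seed)
  d <- data.frame(
    cohort = "X01",
    dx = sample(c("SZ", "HC"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 20, 65),
    site = sample(sprintf("X01_s%d", seq_len(n_sites)), n, replace = TRUE),
    handedness = sample(c("right", "left"), n, replace = TRUE,
                        prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
  agec <- d$age - mean(d$age)
  if (is.null(site_effects)) site_effects <- seq(0, by = 0.5,
                                                 length.out = n_sites)
  names(site_effects) <- sort(unique(d$site))
  d$brainpad <- 1 + beta_dx * (d$dx == "SZ") + beta_sex * (d$sex == "male") +
    beta_age * agec + beta_age2 * agec^2 + site_effects[d$site] +
    rnorm(n, 0, noise_sd)
  d
}

# independent brute-force maximiser of the restricted log-likelihood:
# coarse grid then golden-section refinement
grid_reml_tau2 <- function(y, v, X = NULL, upper = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  f <- function(t) restricted_loglik(t, y, v, X)
  if (is.null(upper)) upper <- max(1e-3, 20 * (var(y) + max(v)))
  grid <- seq(0, upper, length.out = 4001)
  ll <- vapply(grid, f, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (f(0) >= opt$objective) 0 else opt$maximum
}

# brute-force Benjamini-Hochberg: p_adj(j) = min_{i >= j} n p_(i) / i in the
# sorted order, mapped back
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (j in seq_len(n)) {
    adj[j] <- min(1, min(n * ps[j:n] / (j:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}
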