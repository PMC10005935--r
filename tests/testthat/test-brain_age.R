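test_that("infinite regularization shrinks predictions to the training mean age", {
  tab <- make_avg_table(120, seed = 1, dx = rep("HC", 120))
  m <- suppressWarnings(train_brain_age(tab, "male", alpha_grid = 1e12,
                                        seed = 1))
  males <- tab[tab$sex == "male", ]
  pred <- predict(m, males)
  expect_lt(max(abs(pred - m$intercept)), 0.05)
  expect_equal(m$intercept, mean(tab$age[tab$sex == "male"]))
})

test_that("noise-free linear features are recovered exactly out of sample", {
  n <- 300
  set.seed(2)
  age <- runif(n, 20, 70)
  tab <- make_avg_table(n, seed = 2, age = age, sex = rep("male", n),
                        dx = rep("HC", n))
  sch <- feature_schema()
  # age = 2 x the informative feature; others carry faint deterministic
  # age signal so nothing is constant
  tab[[sch$averaged[1]]] <- age / 2
  for (f in sch$averaged[-1]) tab[[f]] <- 100 + 0.001 * age * runif(1)
  train <- tab[1:250, ]; test <- tab[251:n, ]
  m <- train_brain_age(train, "male", alpha_grid = 1e-8, seed = 3)
  expect_lt(max(abs(predict(m, test) - test$age)), 0.01)
})

test_that("training guards: too few rows, constant features, sex filtering", {
  tab <- make_avg_table(30, seed = 3, dx = rep("HC", 30),
                        sex = rep(c("male", "female"), 15))
  expect_error(train_brain_age(tab[1:12, ], "male", alpha_grid = 1),
               "fewer than 10")
  tab2 <- make_avg_table(60, seed = 4, dx = rep("HC", 60))
  tab2$icv <- 1400
  expect_error(suppressWarnings(train_brain_age(tab2, "male", alpha_grid = 1)),
               "icv")
  m <- suppressWarnings(train_brain_age(tab, "female", alpha_grid = 1))
  expect_identical(m$n, 15L)
  expect_error(predict(m, tab), "sex")
})

test_that("ridge predictions are invariant to affine feature rescaling", {
  cfg <- tiny_config(seed = 5)
  tab <- generate_training_sample(cfg)
  m1 <- train_brain_age(tab, "male", alpha_grid = c(1, 10), seed = 7)
  tab2 <- tab
  tab2$insula_thick <- 100 * tab2$insula_thick + 12  # same information
  m2 <- train_brain_age(tab2, "male", alpha_grid = c(1, 10), seed = 7)
  males <- tab$sex == "male"
  expect_equal(predict(m1, tab[males, ]), predict(m2, tab2[males, ]),
               tolerance = 1e-8)
})

test_that("training residual norm is nondecreasing in alpha", {
  cfg <- tiny_config(seed = 6)
  tab <- generate_training_sample(cfg)
  males <- tab[tab$sex == "male" & tab$dx == "HC", ]
  x <- feature_matrix(males)
  xs <- scale(x)
  alphas <- 10^seq(-2, 6, length.out = 9)
  fit <- brainpad:::ridge_path(xs, males$age, alphas)
  rss <- vapply(seq_along(alphas), function(i) {
    sum((males$age - (xs %*% fit$coef[, i] + fit$intercept))^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-8))
})

test_that("cross-validation honours its contracts and detects the permutation null", {
  cfg <- tiny_config(seed = 7)
  tab <- generate_training_sample(cfg)
  expect_error(cross_validate_brain_age(tab, "male", folds = 1), "folds")
  expect_error(cross_validate_brain_age(tab[1:40, ], "male", folds = 500),
               "exceed")
  cv <- cross_validate_brain_age(tab, "male", alpha_grid = c(1, 100),
                                 folds = 5, seed = 1)
  expect_gt(cv$metrics$r, 0.3)
  # permuted ages: no signal left
  tab_perm <- tab
  set.seed(8)
  idx <- tab_perm$sex == "male"
  tab_perm$age[idx] <- sample(tab_perm$age[idx])
  cvp <- cross_validate_brain_age(tab_perm, "male", alpha_grid = c(1, 100),
                                  folds = 5, seed = 1)
  expect_lt(abs(cvp$metrics$r), 0.15)
  mad_age <- mean(abs(tab_perm$age[idx] - mean(tab_perm$age[idx])))
  expect_lt(abs(cvp$metrics$mae - mad_age) / mad_age, 0.25)
})

test_that("brain-PAD is predicted minus chronological age", {
  expect_equal(compute_brainpad(30, 25), 5)
  expect_equal(compute_brainpad(c(40, 50), c(40, 50)), c(0, 0))
  set.seed(9)
  pred <- rnorm(20, 50, 5); age <- rnorm(20, 50, 5)
  expect_equal(compute_brainpad(pred, age) + age, pred)
  expect_error(compute_brainpad(1:3, 1:2), "length")
})

test_that("performance metrics match closed forms and flag degenerate inputs", {
  ev <- evaluate_predictions(c(22, 28, 25), c(20, 30, 25))
  expect_equal(ev$mae, mean(c(2, 2, 0)))
  ev2 <- evaluate_predictions(c(22, 28), c(20, 30))
  expect_error(ev2, NA)
  expect_equal(ev2$mae, 2); expect_equal(ev2$r, 1); expect_equal(ev2$r_squared, 1)
  perfect <- evaluate_predictions(c(20, 30, 40), c(20, 30, 40))
  expect_equal(perfect$mae, 0); expect_equal(perfect$r, 1)
  expect_error(evaluate_predictions(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_warning(ev3 <- evaluate_predictions(c(5, 5, 5), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(ev3$r))
})

test_that("evaluate rejects a single observation", {
  expect_error(evaluate_predictions(1, 1), "n >= 2")
})

test_that("weighted MAE aggregation matches hand-computed values", {
  ag <- aggregate_performance(c(5, 10), c(10, 30))
  expect_equal(ag$weighted_mean, 8.75)
  ag2 <- aggregate_performance(c(5, 10), c(20, 20))
  expect_equal(ag2$weighted_mean, 7.5)
  expect_equal(ag2$se, 2.5 / sqrt(2))
  ag1 <- aggregate_performance(7, 100)
  expect_true(is.na(ag1$se))
  expect_equal(ag1$weighted_mean, 7)
})

test_that("model serialization round trip is bit-stable under prediction", {
  cfg <- tiny_config(seed = 10)
  tab <- generate_training_sample(cfg)
  m <- train_brain_age(tab, "female", alpha_grid = c(0.1, 10, 1000), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_brain_age_model(m, path)
  m2 <- load_brain_age_model(path)
  females <- tab[tab$sex == "female", ][1:50, ]
  expect_identical(predict(m, females), predict(m2, females))
  expect_identical(m2$alpha, m$alpha)
  expect_identical(m2$coef, m$coef)
})

test_that("ridge solution agrees with an independent ridge implementation", {
  skip_if_not_installed("MASS")
  cfg <- tiny_config(seed = 12)
  tab <- generate_training_sample(cfg)
  males <- tab[tab$sex == "male" & tab$dx == "HC", ]
  x <- feature_matrix(males)
  # population-SD standardization to match lm.ridge's internal scaling
  n <- nrow(x)
  mu <- colMeans(x)
  sdp <- apply(x, 2, function(c) sqrt(sum((c - mean(c))^2) / n))
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdp, "/")
  alpha <- 25
  ours <- brainpad:::ridge_path(xs, males$age, alpha)
  theirs <- MASS::lm.ridge(age ~ ., data = data.frame(age = males$age, xs),
                           lambda = alpha)
  expect_equal(drop(ours$coef), drop(theirs$coef), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("shifting features along the ageing gradient shifts predictions by about Delta x gain", {
  cfg <- tiny_config(seed = 13)
  tab <- generate_training_sample(cfg)
  m_m <- train_brain_age(tab, "male", alpha_grid = 10^seq(-1, 3), seed = 3)
  males <- tab[tab$sex == "male", ]
  pred0 <- predict(m_m, males)
  gain <- unname(coef(lm(pred0 ~ males$age))[2])
  delta <- 6
  mult <- brainpad:::feature_multipliers()
  shifted <- males
  for (j in seq_len(nrow(mult))) {
    f <- mult$feature[j]
    slope <- cfg$feature_spec[[mult$class[j]]]$slope * mult$smult[j]
    shifted[[f]] <- shifted[[f]] + delta * slope
  }
  pred1 <- predict(m_m, shifted)
  shift <- mean(pred1 - pred0)
  expect_lt(abs(shift - delta * gain) / (delta * gain), 0.15)
})
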