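test_that("feature expansion produces the classical classes", {
  df <- data.frame(catchment_id = 1:20, a = seq(0, 10, length.out = 20),
                   b = stats::rnorm(20), tid = rep(c(0, 1), 10))
  # single covariate, linear only: one feature equal to rescaled x
  fs <- expand_features(df, 1:20, classes = "linear", vars = "a")
  X <- feature_matrix(fs, df)
  expect_equal(ncol(X), 1L)
  expect_equal(unname(X[, 1]), seq(0, 1, length.out = 20))
  # two continuous covariates, {linear, quadratic, product}: 2+2+1 features
  fs2 <- expand_features(df, 1:20, classes = c("linear", "quadratic",
                                               "product"),
                         vars = c("a", "b"))
  expect_equal(length(fs2$features), 5L)
  # binary covariate: categorical indicators only
  fs3 <- expand_features(df, 1:20, vars = "tid")
  expect_true(all(vapply(fs3$features, `[[`, "", "kind") == "categorical"))
  # knots strictly inside the rescaled range
  fs4 <- expand_features(df, 1:20, classes = "hinge", n_knots = 10L,
                         vars = "a")
  ks <- vapply(fs4$features, `[[`, 0, "knot")
  expect_true(all(ks > 0 & ks < 1))
  # constant-over-background covariate contributes no features
  df$cst <- c(rep(1, 10), stats::rnorm(10))
  fs5 <- expand_features(df, 1:10, vars = c("a", "cst"))
  expect_equal(fs5$dropped, "cst")
  # clamping at prediction time
  fs6 <- expand_features(df, 5:15, classes = "linear", vars = "a")
  Xc <- feature_matrix(fs6, df)
  expect_true(all(Xc >= 0 & Xc <= 1))
})

test_that("two-atom binary feature fit recovers the closed form", {
  bg <- matrix(rep(c(0, 1), each = 10), ncol = 1)
  pr <- matrix(c(1, 1, 1, 0), ncol = 1)   # presence mean 0.75
  m <- fit_maxent(pr, bg, beta_multiplier = 0)
  expect_equal(unname(m$lambda), log(3), tolerance = 1e-6)
})

test_that("empty and degenerate models behave as the transform dictates", {
  # all features identically zero: uniform raw distribution, logistic 0.5
  m0 <- fit_maxent(matrix(0, 3, 2), matrix(0, 8, 2), 1)
  expect_equal(unname(predict_maxent(m0, matrix(0, 1, 2), "raw")), 1 / 8)
  expect_equal(unname(predict_maxent(m0, matrix(0, 1, 2), "logistic")), 0.5)
  expect_equal(m0$entropy_H, log(8))
  expect_error(fit_maxent(matrix(0, 0, 1), matrix(0, 5, 1), 1), "presence")
  expect_error(fit_maxent(matrix(NaN, 1, 1), matrix(0, 5, 1), 1),
               "non-finite")
})

test_that("fits satisfy normalization, KKT and the regularization path", {
  withr::with_seed(31L, {
    for (r in 1:5) {
      nb <- 60L
      p <- 5L
      bgX <- matrix(stats::runif(nb * p), nb, p)
      prX <- bgX[sample(nb, 15L, replace = TRUE), ] +
        matrix(stats::rnorm(15L * p, sd = 0.05), 15L, p)
      m1 <- fit_maxent(prX, bgX, 1)
      # raw background distribution sums to one
      expect_equal(sum(predict_maxent(m1, bgX, "raw")), 1, tolerance = 1e-10)
      # KKT certificate
      expect_lte(m1$kkt, 1e-4)
      # shrinkage along the path
      m15 <- fit_maxent(prX, bgX, 15)
      expect_lte(sum(abs(m15$lambda)), sum(abs(m1$lambda)) + 1e-12)
      # penalized training gain non-increasing in beta: the minimized
      # objective is non-decreasing
      expect_gte(m15$objective, m1$objective - 1e-10)
    }
  })
})

test_that("fitted objective matches the dense-optimizer oracle", {
  withr::with_seed(42L, {
    worst <- 0
    for (r in 1:10) {
      nb <- sample(8:20, 1)
      p <- sample(1:4, 1)
      np <- sample(2:10, 1)
      bgX <- matrix(stats::runif(nb * p), nb, p)
      # presence rows drawn from the background keep the presence feature
      # means inside the background hull; at beta = 0 a finite optimum
      # additionally needs the mean strictly inside, guaranteed by at
      # least p + 1 affinely independent distinct rows
      bm <- sample(c(0, 1, 5), 1)
      if (bm == 0) np <- max(np, p + 2L)
      prX <- bgX[sample(nb, np, replace = bm > 0), , drop = FALSE]
      m <- fit_maxent(prX, bgX, bm)
      worst <- max(worst, abs(m$objective -
                                maxent_oracle_objective(prX, bgX, bm)))
    }
    expect_lt(worst, 1e-5)
  })
})

test_that("prediction transforms are monotone in the raw value", {
  withr::with_seed(8L, {
    bgX <- matrix(stats::runif(80), 40, 2)
    prX <- bgX[sample(40, 10), ]
    m <- fit_maxent(prX, bgX, 1)
    new <- matrix(stats::runif(60), 30, 2)
    r <- predict_maxent(m, new, "raw")
    lg <- predict_maxent(m, new, "logistic")
    cc <- predict_maxent(m, new, "cloglog")
    expect_identical(order(r), order(lg))
    expect_identical(order(r), order(cc))
    expect_true(all(lg > 0 & lg < 1))
    expect_true(all(cc > 0 & cc < 1))
  })
})

test_that("beta tuning picks the highest-AUC multiplier, smallest on ties", {
  withr::with_seed(12L, {
    # separable data: the least-regularized fit wins
    bgX <- matrix(stats::runif(200), 100, 2)
    prX <- matrix(stats::runif(60, 0.7, 1), 30, 2)
    tn <- tune_beta(prX, bgX, grid = c(1, 5, 15))
    expect_equal(tn$chosen_beta, 1)
    expect_true(all(tn$auc_per_beta >= 0 & tn$auc_per_beta <= 1,
                    na.rm = TRUE))
    # one-value grid trivially chosen
    expect_equal(tune_beta(prX, bgX, grid = 7)$chosen_beta, 7)
    # exact tie resolves to the smaller value: duplicate grid entries
    tn2 <- tune_beta(prX, bgX, grid = c(3, 3))
    expect_equal(tn2$chosen_beta, 3)
  })
})

test_that("k-fold SD maps quantify presence-sample sensitivity", {
  withr::with_seed(19L, {
    bgX <- matrix(stats::runif(100), 50, 2)
    prX <- bgX[sample(50, 8), ]
    # a single presence row duplicated: every fold has the same feature
    # means, so the refits coincide and the SD is exactly zero
    dup <- prX[rep(1, 8), ]
    sd0 <- kfold_sd(dup, bgX, bgX, k = 4L, seed = 1L)
    expect_equal(max(sd0), 0)
    # k = 2 on a hand-built instance matches direct two-model computation
    folds <- withr::with_seed(7L, sample(rep(1:2, length.out = 8)))
    m1 <- fit_maxent(prX[folds != 1, ], bgX, 1)
    m2 <- fit_maxent(prX[folds != 2, ], bgX, 1)
    direct <- apply(cbind(predict_maxent(m1, bgX, "logistic"),
                          predict_maxent(m2, bgX, "logistic")), 1, stats::sd)
    expect_equal(kfold_sd(prX, bgX, bgX, k = 2L, seed = 7L), direct,
                 tolerance = 1e-8)
    expect_true(all(sd0 >= 0))
    expect_error(kfold_sd(prX, bgX, bgX, k = 10L, seed = 1L), "smaller k")
  })
})

test_that("the species-level wrapper predicts from covariate tables", {
  land <- tiny_landscape()
  pres <- consolidate_presences(land$occurrences, land$catchments)
  sp <- names(which.max(vapply(pres, length, 0L)))
  frame <- tally_surveys(land$catchments, land$surveys)
  bg <- sample_background(eligible_background(frame, pres[[sp]]),
                          selection_weights(eligible_background(frame,
                                                                pres[[sp]]),
                                            frame),
                          200L, seed = 2L)
  m <- fit_species_sdm(land$covariates, pres[[sp]], bg)
  pred <- predict(m, land$covariates)
  expect_length(pred, nrow(land$catchments))
  expect_true(all(pred > 0 & pred < 1))
  # background raw values renormalize to one through the wrapper too
  expect_equal(sum(predict(m, land$covariates, bg, transform = "raw")), 1,
               tolerance = 1e-10)
})
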