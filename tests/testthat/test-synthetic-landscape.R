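test_that("hierarchy generation respects counts, nesting and determinism", {
  cfg <- landscape_config(2L, 2L, 2L, 5L, seed = 11L)
  fr <- generate_hierarchy(cfg)
  expect_equal(nrow(fr), 40L)
  expect_equal(length(unique(fr$huc12)), 8L)
  expect_silent(validate_catchment_frame(fr))

  # degenerate single-catchment landscape still nests consistently
  fr1 <- generate_hierarchy(landscape_config(1L, 1L, 1L, 1L, seed = 1L))
  expect_equal(nrow(fr1), 1L)
  expect_silent(validate_catchment_frame(fr1))

  # bit-reproducible under a fixed seed
  expect_identical(fr, generate_hierarchy(cfg))

  expect_error(landscape_config(0L), "positive integer")
  expect_error(landscape_config(autocorrelation_range = -1), "nonnegative")
})

test_that("catchments within the same HUC are spatially contiguous", {
  fr <- generate_hierarchy(landscape_config(4L, 2L, 2L, 10L, seed = 2L))
  # within-HUC8 centroid spread is much smaller than the landscape spread
  within <- tapply(fr$centroid_x, fr$huc8, function(x) diff(range(x)))
  expect_true(max(within) < diff(range(fr$centroid_x)))
})

test_that("covariate fields honour the autocorrelation range", {
  # range 0: neighbouring catchments are uncorrelated
  cfg0 <- landscape_config(1L, 1L, 1L, 500L, n_covariates = 1L,
                           autocorrelation_range = 0, seed = 9L)
  fr0 <- generate_hierarchy(cfg0)
  cv0 <- generate_covariates(fr0, cfg0)
  ord <- order(fr0$centroid_x)
  x <- cv0$cov_01[ord]
  expect_lt(abs(stats::cor(x[-1], x[-length(x)])), 0.2)

  # range far beyond the extent: the field is near-constant in space
  withr::with_seed(4L, {
    coords <- cbind(stats::runif(300), stats::runif(300))
    noise <- matrix(stats::rnorm(300), 300, 1)
    f <- smooth_gaussian_field(coords, noise, range = 100)
    expect_lt(stats::var(drop(f)), 0.01)   # spatial variance << marginal (1)
  })

  # determinism and the guaranteed binary covariate
  expect_identical(cv0, generate_covariates(fr0, cfg0))
  expect_true(all(cv0$tidal %in% c(0, 1)))
  expect_setequal(covariate_names(cv0, "binary"), "tidal")
})

test_that("true suitability calibrates the intercept to the prevalence target", {
  land <- tiny_landscape()
  covs <- land$covariates

  # flat response: zero coefficient gives constant suitability = target
  sp0 <- true_species("flat", c(cov_01 = 0), 0.3)
  s0 <- true_suitability(covs, sp0)
  expect_equal(unname(s0), rep(0.3, nrow(covs)), tolerance = 1e-9)

  # calibration: mean suitability hits the target within 1e-6
  sp1 <- true_species("a", c(cov_01 = 1), 0.3)
  expect_lt(abs(mean(true_suitability(covs, sp1)) - 0.3), 1e-6)

  # near-infinite coefficient: suitability approaches an indicator whose
  # mean still matches the prevalence target
  sp2 <- true_species("b", c(cov_01 = 1e3), 0.25)
  s2 <- true_suitability(covs, sp2)
  expect_lt(mean(s2 > 0.01 & s2 < 0.99), 0.05)
  cut <- stats::quantile(covs$cov_01, 0.75)
  expect_gt(stats::cor(as.numeric(covs$cov_01 > cut), s2), 0.95)

  expect_error(true_suitability(covs, true_species("c", c(nope = 1), 0.5)),
               "unknown covariate")
  expect_error(true_species("d", c(cov_01 = 1), 1.0), "inside")
})

test_that("survey simulation allocates effort as configured", {
  fr <- generate_hierarchy(landscape_config(2L, 4L, 2L, 10L, seed = 3L))
  n10 <- length(unique(fr$huc10))

  # near-uniform regime: chi-square GOF across HUC10s not significant
  sm <- survey_model(effort_concentration = 1e6, n_surveys = 10L * n10,
                     seed = 21L)
  sv <- simulate_surveys(fr, sm)
  counts <- table(factor(fr$huc10[match(sv$catchment_id, fr$catchment_id)],
                         levels = unique(fr$huc10)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # concentrated regime leaves some HUC10s unsurveyed
  sv2 <- simulate_surveys(fr, survey_model(effort_concentration = 0.1,
                                           n_surveys = 50L, seed = 8L))
  surveyed <- unique(fr$huc10[match(sv2$catchment_id, fr$catchment_id)])
  expect_lt(length(surveyed), n10)

  # single survey lands in exactly one catchment
  sv3 <- simulate_surveys(fr, survey_model(n_surveys = 1L, seed = 2L))
  tal <- tally_surveys(fr, sv3)
  expect_equal(sum(tal$survey_count), 1L)
  expect_equal(sum(tal$survey_count > 0), 1L)

  # determinism
  expect_identical(sv, simulate_surveys(fr, sm))
  expect_error(survey_model(detection_prob = 0), "detection_prob")
})

test_that("occurrence sampling is presence-only and detection-limited", {
  fr <- toy_frame()
  surveys <- data.frame(catchment_id = paste0("c", 1:6), year = 2000L)

  # suitability 1 + detection 1: occurrences = surveyed set
  truth1 <- stats::setNames(rep(1 - 1e-12, 6), fr$catchment_id)
  occ1 <- sample_occurrences(truth1, surveys, 1, seed = 1L)
  expect_setequal(occ1$catchment_id, fr$catchment_id)

  # suitability 0: no records at all
  truth0 <- stats::setNames(rep(0, 6), fr$catchment_id)
  expect_equal(nrow(sample_occurrences(truth0, surveys, 1, seed = 1L)), 0L)

  # binomial bounds at suitability 0.5, 1000 surveyed, detection 1
  ids <- sprintf("k%04d", 1:1000)
  occ <- sample_occurrences(stats::setNames(rep(0.5, 1000), ids),
                            data.frame(catchment_id = ids, year = 2000L),
                            1, seed = 42L)
  expect_lt(abs(nrow(occ) - 500), 3 * sqrt(250))

  # occurrences only ever reference surveyed catchments
  some <- surveys[1:3, , drop = FALSE]
  occ3 <- sample_occurrences(truth1, some, 0.7, seed = 5L)
  expect_true(all(occ3$catchment_id %in% some$catchment_id))

  expect_error(sample_occurrences(truth1, surveys, 0, seed = 1L),
               "detection_prob")
})

test_that("synthetic landscape writes interchangeable CSV schemas", {
  dir <- withr::local_tempdir()
  land <- tiny_landscape()
  cfg <- landscape_config(2L, 3L, 2L, 25L, n_covariates = 3L, seed = 3L)
  synthetic_landscape(cfg, survey = survey_model(n_surveys = 800L,
                                                 effort_concentration = 1,
                                                 seed = 3L), dir = dir)
  back <- read_landscape_csv(dir)
  expect_identical(back$catchments$catchment_id, land$catchments$catchment_id)
  expect_equal(back$covariates$cov_01, land$covariates$cov_01)
  expect_equal(nrow(back$occurrences), nrow(land$occurrences))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  # prevalence calibration invariant on the truth table
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  prevs <- vapply(land$species, `[[`, 0, "prevalence_target")
  expect_equal(unname(colMeans(truth[, -1])), unname(prevs), tolerance = 1e-6)
})
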