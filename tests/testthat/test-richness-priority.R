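test_that("binary maps and richness stacking conserve counts", {
  pred <- stats::setNames(c(0.1, 0.5, 0.9), c("a", "b", "c"))
  expect_equal(unname(binary_map(pred, 0.5)), c(0L, 1L, 1L))
  expect_equal(sum(binary_map(pred, 1.1)), 0L)
  expect_equal(sum(binary_map(pred, 0.1)), 3L)

  maps <- list(
    s1 = stats::setNames(c(1L, 0L, 1L), c("a", "b", "c")),
    s2 = stats::setNames(c(1L, 0L, 0L), c("a", "b", "c")),
    s3 = stats::setNames(c(1L, 1L, 0L), c("a", "b", "c"))
  )
  ranks <- c(s1 = "very_high", s2 = "not_listed", s3 = "not_listed")
  rm <- stack_richness(maps, ranks)
  expect_equal(rm$overall_richness, c(3L, 1L, 1L))
  expect_equal(rm$rsgcn_richness, c(1L, 0L, 1L))
  expect_true(all(rm$rsgcn_richness <= rm$overall_richness))
  # misaligned catchment sets are an error
  maps$s3 <- stats::setNames(maps$s3, c("a", "b", "d"))
  expect_error(stack_richness(maps, ranks), "aligned")
})

test_that("min-max scaling follows the documented conventions", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_scale(rep(3, 4)), rep(0, 4))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_scale(x), x)
  expect_equal(minmax_scale(c(1, NA, 3)), c(0, NA, 1))
  expect_error(minmax_scale(numeric(0)), "empty")
})

test_that("survey priority rewards rich, unsurveyed catchments", {
  rm <- stack_richness(list(
    s1 = stats::setNames(c(1L, 1L, 0L, 0L), letters[1:4]),
    s2 = stats::setNames(c(1L, 0L, 0L, 0L), letters[1:4])
  ), c(s1 = "not_listed", s2 = "not_listed"))
  sp <- survey_priority(rm, surveyed_ids = c("b", "d"))
  # unsurveyed catchment at max richness scores 1
  expect_equal(sp$score[sp$catchment_id == "a"], 1)
  # surveyed catchment at min richness scores 0
  expect_equal(sp$score[sp$catchment_id == "d"], 0)
  # degenerate: everyone surveyed at equal richness collapses to zero
  rm2 <- rm
  rm2$overall_richness <- rep(2L, 4)
  sp2 <- survey_priority(rm2, surveyed_ids = letters[1:4])
  expect_equal(sp2$score, rep(0, 4))
})

test_that("restoration priority masks catchments outside the recorded range", {
  fr <- toy_hierarchy()   # 2 HUC8s x 4 catchments each
  h8 <- unique(fr$huc8)
  pres <- list(spA = fr$catchment_id[fr$huc8 == h8[1]][1],
               spB = fr$catchment_id[2])
  ranks <- c(spA = "very_high", spB = "moderate", spC = "high")
  n <- nrow(fr)
  withr::with_seed(3L, {
    prot <- stats::runif(n, 0, 100)
    forest <- stats::runif(n, 0, 100)
    change <- stats::runif(n, 0, 30)
  })
  rp <- restoration_priority(fr, prot, forest, change, pres, ranks)
  # only high / very-high species get surfaces
  expect_setequal(names(rp), c("spA", "spC"))
  # eligibility is exactly the HUC8-record rule
  expect_equal(rp$spA$eligible, fr$huc8 == h8[1])
  expect_true(all(is.na(rp$spA$score[!rp$spA$eligible])))
  expect_true(all(!is.na(rp$spA$score[rp$spA$eligible])))
  # a species with no records anywhere is ineligible everywhere
  expect_true(all(!rp$spC$eligible))
  # the underlying surface is shared: where both are eligible scores match
  both <- rp$spA$eligible & fr$huc8 == h8[1]
  expect_equal(rp$spA$score[both],
               minmax_scale(minmax_scale(prot) + minmax_scale(forest) -
                              minmax_scale(change))[both])
})

test_that("protection priority composes its four scaled criteria", {
  rm <- stack_richness(list(
    s1 = stats::setNames(c(1L, 0L, 1L, 0L), letters[1:4])
  ), c(s1 = "not_listed"))
  # hand-built 4-catchment table, spreadsheet-style recomputation
  forest <- c(80, 20, 60, 40)
  wet <- c(10, 0, 5, 2.5)
  res <- c(0.9, 0.1, 0.5, 0.3)
  pp <- protection_priority(rm, forest, wet, res)
  manual <- minmax_scale(minmax_scale(c(1, 0, 1, 0)) + minmax_scale(forest) +
                           minmax_scale(wet) + minmax_scale(res))
  expect_equal(pp$score, manual)
  # extremes attained: the best catchment scores 1, the worst 0
  expect_equal(pp$score[1], 1)
  expect_equal(pp$score[2], 0)
})

test_that("priority surfaces are monotone in richness", {
  base <- stats::setNames(c(2L, 1L, 3L, 0L), letters[1:4])
  mk <- function(r) {
    rm <- data.frame(catchment_id = names(r), overall_richness = unname(r),
                     rsgcn_richness = 0L)
    class(rm) <- c("richness_map", "data.frame")
    rm
  }
  s1 <- survey_priority(mk(base), "b")
  bumped <- base
  bumped["b"] <- bumped["b"] + 1L
  s2 <- survey_priority(mk(bumped), "b")
  expect_gte(s2$score[2], s1$score[2])
  p1 <- protection_priority(mk(base), 1:4, 1:4, 1:4)
  p2 <- protection_priority(mk(bumped), 1:4, 1:4, 1:4)
  expect_gte(p2$score[2], p1$score[2])
})

test_that("priority ranking is invariant to affine transforms of an input", {
  withr::with_seed(10L, {
    rm <- stack_richness(list(
      s1 = stats::setNames(sample(0:1, 50, TRUE), sprintf("c%02d", 1:50))
    ), c(s1 = "not_listed"))
    forest <- stats::runif(50, 0, 100)
    wet <- stats::runif(50, 0, 40)
    resil <- stats::runif(50)
    p1 <- protection_priority(rm, forest, wet, resil)
    p2 <- protection_priority(rm, 3 * forest + 7, wet, resil)
    expect_equal(p1$score, p2$score, tolerance = 1e-12)
  })
})

test_that("interspecies and protection correlations use Spearman ranks", {
  ids <- sprintf("c%02d", 1:20)
  withr::with_seed(2L, {
    a <- stats::setNames(stats::runif(20), ids)
  })
  surfs <- list(s1 = a, s2 = a, s3 = stats::setNames(1 - unname(a), ids))
  m <- interspecies_correlation(surfs)
  expect_equal(m["s1", "s2"], 1)
  expect_equal(m["s1", "s3"], -1)
  expect_equal(m, t(m))
  # agreement with the explicit rank-formula oracle
  withr::with_seed(6L, {
    b <- stats::setNames(stats::runif(20), ids)
  })
  m2 <- interspecies_correlation(list(x = a, y = b))
  ra <- rank(a)
  rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(m2["x", "y"], oracle, tolerance = 1e-12)

  # protection-vs-protected: identical ranks give 1, independence near 0
  surf <- priority_surface("protection", ids, minmax_scale(unname(a)))
  expect_equal(protection_vs_protected_correlation(surf, unname(a))$region, 1)
  withr::with_seed(33L, {
    big <- priority_surface("protection", sprintf("c%04d", 1:1000),
                            stats::runif(1000))
    indep <- stats::runif(1000)
  })
  expect_lt(abs(protection_vs_protected_correlation(big, indep)$region), 0.1)
})

test_that("state summaries aggregate surveys, richness and priorities", {
  fr <- toy_frame()
  rm <- stack_richness(list(
    s1 = stats::setNames(rep(1L, 6), fr$catchment_id),
    s2 = stats::setNames(rep(1L, 6), fr$catchment_id)
  ), c(s1 = "not_listed", s2 = "not_listed"))
  surveys <- data.frame(catchment_id = c("c1", "c1", "c4"), year = 2000L)
  surf <- list(
    survey = priority_surface("survey", fr$catchment_id,
                              c(0.2, 0.4, 0.6, 0.8, 1, 0)),
    restoration_spA = priority_surface("restoration", fr$catchment_id,
                                       c(0.5, 0.5, 0.5, NA, NA, NA),
                                       species_id = "spA")
  )
  ss <- state_summaries(fr, rm, surf, surveys)
  expect_equal(ss$n_surveys, c(2L, 1L))
  expect_equal(ss$mean_richness, c(2, 2))   # uniform richness, SE 0
  expect_equal(ss$mean_survey, c(mean(c(0.2, 0.4, 0.6)), mean(c(0.8, 1, 0))))
  # statewide-ineligible species reports the N/A marker
  expect_equal(ss$mean_restoration_spA, c(0.5, NA))
  expect_equal(ss$se_mean_richness, NULL)   # no such column
})
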