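# Small fixtures built in code; no files on disk.

# Hand-built frame: 6 catchments in 2 HUC10s of one HUC8.
# HUC10 A (c1..c3) is surveyed, HUC10 B (c4..c6) is not.
toy_frame <- function(surveys_a = c(2L, 1L, 0L)) {
  data.frame(
    catchment_id = paste0("c", 1:6),
    huc12 = rep(c("h12a", "h12b"), each = 3),
    huc10 = rep(c("A", "B"), each = 3),
    huc8 = "H8",
    state = rep(c("S1", "S2"), each = 3),
    centroid_x = seq(0, 1, length.out = 6),
    centroid_y = 0,
    survey_count = c(surveys_a, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# A nested toy hierarchy: 2 HUC8 x 2 HUC10 x 1 HUC12 x 2 catchments.
toy_hierarchy <- function() {
  generate_hierarchy(landscape_config(2L, 2L, 1L, 2L, seed = 5L))
}

# Small synthetic landscape for fast end-to-end tests.
tiny_landscape <- function(seed = 3L, n_surveys = 800L, species = NULL) {
  cfg <- landscape_config(n_huc8 = 2L, n_huc10_per_huc8 = 3L,
                          n_huc12_per_huc10 = 2L,
                          n_catchments_per_huc12 = 25L,
                          n_covariates = 3L, seed = seed)
  synthetic_landscape(cfg,
                      species = species,
                      survey = survey_model(n_surveys = n_surveys,
                                            effort_concentration = 1,
                                            seed = seed))
}

# Independent dense-optimizer oracle for the penalized maxent objective:
# split lambda = a - b with a, b >= 0 turns the L1 problem into a smooth
# box-constrained one, solved by L-BFGS-B.  Deliberately shares no code
# with fit_maxent().
maxent_oracle_objective <- function(presence_X, background_X, beta_multiplier) {
  Ep <- colMeans(presence_X)
  s <- apply(background_X, 2, stats::sd)
  beta <- beta_multiplier * s / sqrt(nrow(presence_X))
  p <- ncol(background_X)
  fn <- function(ab) {
    lam <- ab[1:p] - ab[(p + 1):(2 * p)]
    eta <- drop(background_X %*% lam)
    m <- max(eta)
    m + log(sum(exp(eta - m))) - sum(Ep * lam) +
      sum(beta * (ab[1:p] + ab[(p + 1):(2 * p)]))
  }
  gr <- function(ab) {
    lam <- ab[1:p] - ab[(p + 1):(2 * p)]
    eta <- drop(background_X %*% lam)
    w <- exp(eta - max(eta))
    q <- w / sum(w)
    g <- drop(crossprod(background_X, q)) - Ep
    c(g + beta, -g + beta)
  }
  stats::optim(rep(0, 2 * p), fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 5000, factr = 1))$value
}

# Brute-force AUC by explicit pair counting.
auc_bruteforce <- function(pres, bg) {
  s <- 0
  for (p in pres) s <- s + sum(p > bg) + 0.5 * sum(p == bg)
  s / (length(pres) * length(bg))
}

# Dense-grid threshold oracle.  The grid argmax is snapped up to the next
# pooled score: every t in the open interval between adjacent data values
# induces the same classification as the upper value, so the canonical
# representative of the maximizing flat stretch is a data value.
threshold_bruteforce <- function(pres, bg, n_grid = 1e4) {
  pool <- sort(unique(c(pres, bg)))
  grid <- sort(unique(c(pool, seq(min(pool), max(pool),
                                  length.out = n_grid))))
  tot <- vapply(grid, function(t) mean(pres >= t) + mean(bg < t), 0)
  t_star <- grid[which(tot >= max(tot) - 1e-12)[1]]
  min(pool[pool >= t_star])
}
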