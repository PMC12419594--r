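#' Configuration for a synthetic catchment landscape
#'
#' Describes a nested hydrologic-unit hierarchy (HUC8 > HUC10 > HUC12 >
#' catchment) laid out on an abstract planar grid, plus the covariate field
#' settings.  The generator exists so that the whole modelling and
#' prioritization pipeline can be exercised against a landscape with known
#' truth; it emulates the structure of regional hydrography data, not its
#' geometry.
#'
#' @param n_huc8 number of HUC8 units.
#' @param n_huc10_per_huc8 number of HUC10 units nested in each HUC8.
#' @param n_huc12_per_huc10 number of HUC12 units nested in each HUC10.
#' @param n_catchments_per_huc12 number of catchments in each HUC12.
#' @param n_covariates number of continuous environmental covariates; one
#'   binary covariate (a tidal-influence analogue) is always added.
#' @param autocorrelation_range spatial range (abstract coordinate units) of
#'   the Gaussian smoothing kernel that induces autocorrelation in the
#'   covariate fields; `0` gives independent noise per catchment.
#' @param n_states number of state labels cycled over HUC8 units.
#' @param seed integer seed; all generation is reproducible given the config.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_huc8 = 6L, n_huc10_per_huc8 = 4L,
                             n_huc12_per_huc10 = 5L,
                             n_catchments_per_huc12 = 42L,
                             n_covariates = 5L,
                             autocorrelation_range = 0.25,
                             n_states = 6L,
                             seed = 1L) {
  stopifnot_positive_int(n_huc8, "n_huc8")
  stopifnot_positive_int(n_huc10_per_huc8, "n_huc10_per_huc8")
  stopifnot_positive_int(n_huc12_per_huc10, "n_huc12_per_huc10")
  stopifnot_positive_int(n_catchments_per_huc12, "n_catchments_per_huc12")
  stopifnot_positive_int(n_covariates, "n_covariates")
  stopifnot_positive_int(n_states, "n_states")
  if (!is.finite(autocorrelation_range) || autocorrelation_range < 0) {
    stop("invalid config: autocorrelation_range must be a nonnegative real")
  }
  structure(list(
    n_huc8 = as.integer(n_huc8),
    n_huc10_per_huc8 = as.integer(n_huc10_per_huc8),
    n_huc12_per_huc10 = as.integer(n_huc12_per_huc10),
    n_catchments_per_huc12 = as.integer(n_catchments_per_huc12),
    n_covariates = as.integer(n_covariates),
    autocorrelation_range = autocorrelation_range,
    n_states = as.integer(n_states),
    seed = as.integer(seed)
  ), class = "landscape_config")
}

#' Generate the nested catchment hierarchy
#'
#' Lays HUC8 units on a coarse grid, subdivides each into HUC10 and HUC12
#' cells, and scatters catchment centroids inside their HUC12 cell, so that
#' catchments sharing a hydrologic unit are spatially contiguous.  Each HUC8
#' is assigned a state label.
#'
#' @param config a [landscape_config()].
#' @return a catchment frame: `data.frame` with columns `catchment_id`,
#'   `huc12`, `huc10`, `huc8`, `state`, `centroid_x`, `centroid_y`,
#'   `survey_count` (initialized to 0).
#' @export
generate_hierarchy <- function(config) {
  if (!inherits(config, "landscape_config")) config <- do.call(landscape_config, config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    g8 <- ceiling(sqrt(config$n_huc8))
    g10 <- ceiling(sqrt(config$n_huc10_per_huc8))
    g12 <- ceiling(sqrt(config$n_huc12_per_huc10))
    rows <- list()
    idx <- 0L
    for (i8 in seq_len(config$n_huc8)) {
      huc8 <- sprintf("H8_%02d", i8)
      st <- sprintf("S%d", ((i8 - 1L) %% config$n_states) + 1L)
      ox8 <- ((i8 - 1L) %% g8)
      oy8 <- ((i8 - 1L) %/% g8)
      for (i10 in seq_len(config$n_huc10_per_huc8)) {
        huc10 <- sprintf("%s_%02d", huc8, i10)
        ox10 <- ox8 + ((i10 - 1L) %% g10) / g10
        oy10 <- oy8 + ((i10 - 1L) %/% g10) / g10
        for (i12 in seq_len(config$n_huc12_per_huc10)) {
          huc12 <- sprintf("%s_%02d", huc10, i12)
          ox12 <- ox10 + ((i12 - 1L) %% g12) / (g10 * g12)
          oy12 <- oy10 + ((i12 - 1L) %/% g12) / (g10 * g12)
          n <- config$n_catchments_per_huc12
          cx <- ox12 + stats::runif(n) / (g10 * g12)
          cy <- oy12 + stats::runif(n) / (g10 * g12)
          idx <- idx + 1L
          rows[[idx]] <- data.frame(
            catchment_id = sprintf("%s_C%03d", huc12, seq_len(n)),
            huc12 = huc12, huc10 = huc10, huc8 = huc8, state = st,
            centroid_x = cx, centroid_y = cy,
            survey_count = 0L,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    frame <- do.call(rbind, rows)
    rownames(frame) <- NULL
    validate_catchment_frame(frame)
    frame
  })
}

#' Gaussian-kernel smoothing of per-catchment white noise
#'
#' The spatial-autocorrelation primitive behind the synthetic covariates: a
#' value at catchment i is the kernel-weighted sum of independent noise at
#' all catchments, normalized so each output has unit marginal variance.
#' `range = 0` returns the noise unchanged (independent values); a range far
#' exceeding the landscape extent yields a field that is nearly constant in
#' space (though its level still varies across realizations).
#'
#' @param coords two-column matrix of centroid coordinates.
#' @param noise matrix of iid standard-normal draws, `nrow(coords)` rows.
#' @param range kernel scale (same units as coords).
#' @return matrix of smoothed fields, same shape as `noise`.
#' @export
smooth_gaussian_field <- function(coords, noise, range) {
  noise <- as.matrix(noise)
  if (range <= 0) return(noise)
  n <- nrow(coords)
  out <- matrix(0, n, ncol(noise))
  block <- 512L
  inv2r2 <- 1 / (2 * range^2)
  for (start in seq(1L, n, by = block)) {
    ix <- start:min(start + block - 1L, n)
    d2 <- outer(coords[ix, 1L], coords[, 1L], "-")^2 +
      outer(coords[ix, 2L], coords[, 2L], "-")^2
    w <- exp(-d2 * inv2r2)
    out[ix, ] <- (w %*% noise) / sqrt(rowSums(w^2))
  }
  out
}

#' Generate spatially autocorrelated environmental covariates
#'
#' Draws `n_covariates` continuous fields plus one binary field (a
#' tidal-influence analogue obtained by thresholding a smoothed field at its
#' 80th percentile, so tidal catchments form spatial clusters).
#'
#' @param frame catchment frame from [generate_hierarchy()].
#' @param config the [landscape_config()] used to build `frame`.
#' @return a [covariate_table()] with columns `cov_01..cov_k` (continuous,
#'   catchment scale) and `tidal` (binary).
#' @export
generate_covariates <- function(frame, config) {
  if (nrow(frame) == 0L) stop("generate_covariates: empty frame")
  withr::with_seed(derive_seed(config$seed, 2L), {
    n <- nrow(frame)
    k <- config$n_covariates
    coords <- cbind(frame$centroid_x, frame$centroid_y)
    noise <- matrix(stats::rnorm(n * (k + 1L)), n, k + 1L)
    fields <- smooth_gaussian_field(coords, noise, config$autocorrelation_range)
    tidal <- as.integer(fields[, k + 1L] >
                          stats::quantile(fields[, k + 1L], 0.8, names = FALSE))
    df <- data.frame(catchment_id = frame$catchment_id, stringsAsFactors = FALSE)
    for (j in seq_len(k)) df[[sprintf("cov_%02d", j)]] <- fields[, j]
    df$tidal <- tidal
    covariate_table(df,
                    types = c(rep("continuous", k), "binary"),
                    scales = rep("catchment", k + 1L))
  })
}

#' Auxiliary prioritization covariates for the synthetic landscape
#'
#' Percent protected land, percent forest, percent wetland, projected
#' land-use change and a climate-resilience score, generated as smoothed
#' fields pushed through a logistic so the percentage columns live in
#' plausible ranges.  These stand in for the external GIS layers consumed by
#' the prioritization stage.
#'
#' @param frame catchment frame.
#' @param config the matching [landscape_config()].
#' @return data.frame with `catchment_id`, `protected_pct`, `forest_pct`,
#'   `wetland_pct`, `landuse_change_pct`, `resilience`.
#' @export
generate_aux_covariates <- function(frame, config) {
  withr::with_seed(derive_seed(config$seed, 3L), {
    n <- nrow(frame)
    coords <- cbind(frame$centroid_x, frame$centroid_y)
    noise <- matrix(stats::rnorm(n * 5L), n, 5L)
    f <- smooth_gaussian_field(coords, noise, config$autocorrelation_range)
    data.frame(
      catchment_id = frame$catchment_id,
      protected_pct = 100 * stats::plogis(1.2 * f[, 1L] - 1.5),
      forest_pct = 100 * stats::plogis(f[, 2L] + 0.5),
      wetland_pct = 100 * stats::plogis(f[, 3L] - 1.5),
      landuse_change_pct = 100 * stats::plogis(f[, 4L] - 2),
      resilience = stats::plogis(f[, 5L]),
      stringsAsFactors = FALSE
    )
  })
}

#' Define a species with known response to the environment
#'
#' The data-generating truth for one synthetic species: a sparse coefficient
#' vector over covariates, a target regional prevalence, and an RSGCN
#' (Regional Species of Greatest Conservation Need) rank used by the
#' prioritization stage.
#'
#' @param species_id identifier.
#' @param coefficients named numeric vector; names must match covariate
#'   columns.
#' @param prevalence_target mean occupancy probability, strictly in (0, 1).
#' @param rsgcn_rank one of `"very_high"`, `"high"`, `"moderate"`,
#'   `"not_listed"`.
#' @return a `true_species` list.
#' @export
true_species <- function(species_id, coefficients, prevalence_target,
                         rsgcn_rank = "not_listed") {
  if (!is.numeric(coefficients) || is.null(names(coefficients))) {
    stop("coefficients must be a named numeric vector")
  }
  if (!is.finite(prevalence_target) || prevalence_target <= 0 ||
      prevalence_target >= 1) {
    stop("prevalence_target must lie strictly inside (0, 1)")
  }
  rsgcn_rank <- match.arg(rsgcn_rank,
                          c("very_high", "high", "moderate", "not_listed"))
  structure(list(species_id = species_id, coefficients = coefficients,
                 intercept = NA_real_, prevalence_target = prevalence_target,
                 rsgcn_rank = rsgcn_rank),
            class = "true_species")
}

#' Default pool of twelve synthetic species
#'
#' Mirrors the modelled community: twelve species with regional prevalences
#' spread between 5% and 35% and an RSGCN composition of two very-high,
#' three high, two moderate and five unlisted species (seven RSGCN species
#' in total).  Each species responds to three or four covariates with
#' effect sizes between 2 and 3.5 on the logit scale, so the latent truth
#' discriminates occupied from unoccupied catchments about as strongly as
#' the real survey data do (the published regional mussel models reach AUCs
#' of 0.94-0.99; these draws give truth-model AUC ceilings in the same
#' range).  Weaker effects would leave even a truth-knowing oracle below
#' the recoverability the generator is meant to provide.
#'
#' @param covariate_names covariate columns the species may respond to.
#' @param n_species number of species (default 12).
#' @param seed integer seed.
#' @return list of [true_species()] objects.
#' @export
default_species_pool <- function(covariate_names, n_species = 12L, seed = 1L) {
  ranks <- rep(c("very_high", "high", "moderate", "not_listed"),
               times = pmax(round(n_species * c(2, 3, 2, 5) / 12), 1))[seq_len(n_species)]
  prev <- seq(0.05, 0.35, length.out = n_species)
  withr::with_seed(derive_seed(seed, 4L), {
    prev <- sample(prev)
    lapply(seq_len(n_species), function(i) {
      k <- sample(3:min(4L, length(covariate_names)), 1L)
      nm <- sample(covariate_names, k)
      cf <- stats::runif(k, 2, 3.5) * sample(c(-1, 1), k, replace = TRUE)
      names(cf) <- nm
      true_species(sprintf("sp%02d", i), cf, prev[i], ranks[i])
    })
  })
}

#' True occupancy probability per catchment
#'
#' Inverse-logit of the species' linear predictor, with the intercept
#' calibrated by a 1-D root find so the landscape-mean suitability equals
#' the species' prevalence target (to within 1e-6).
#'
#' @param covariates a [covariate_table()].
#' @param species a [true_species()].
#' @return named numeric vector of suitabilities in (0, 1), one per
#'   catchment.
#' @export
true_suitability <- function(covariates, species) {
  missing_cov <- setdiff(names(species$coefficients), names(covariates))
  if (length(missing_cov) > 0L) {
    stop("unknown covariate(s) in species coefficients: ",
         paste(missing_cov, collapse = ", "))
  }
  X <- as.matrix(covariates[names(species$coefficients)])
  eta <- drop(X %*% species$coefficients)
  target <- species$prevalence_target
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  b0 <- stats::uniroot(f, c(-5, 5), extendInt = "upX", tol = 1e-12)$root
  suit <- stats::plogis(b0 + eta)
  names(suit) <- covariates$catchment_id
  suit
}

#' Survey-effort model
#'
#' Governs how unevenly survey events spread over HUC10 units: HUC10 weights
#' are drawn from a symmetric Dirichlet with the given concentration (small
#' values concentrate effort and leave some HUC10s unsurveyed; large values
#' approach uniform effort), and the catchment within a HUC10 is chosen
#' uniformly.
#'
#' @param effort_concentration nonnegative Dirichlet concentration.
#' @param n_surveys number of survey events.
#' @param detection_prob per-survey detection probability in (0, 1].
#' @param year_range inclusive integer range survey years are drawn from.
#' @param seed integer seed.
#' @return a `survey_model` list.
#' @export
survey_model <- function(effort_concentration = 0.5, n_surveys = 4000L,
                         detection_prob = 0.8, year_range = c(1948L, 2022L),
                         seed = 1L) {
  stopifnot_positive_int(n_surveys, "n_surveys")
  if (!is.finite(effort_concentration) || effort_concentration < 0) {
    stop("invalid config: effort_concentration must be nonnegative")
  }
  if (!is.finite(detection_prob) || detection_prob <= 0 || detection_prob > 1) {
    stop("invalid config: detection_prob must lie in (0, 1]")
  }
  structure(list(effort_concentration = effort_concentration,
                 n_surveys = as.integer(n_surveys),
                 detection_prob = detection_prob,
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "survey_model")
}

#' Simulate spatially uneven survey effort
#'
#' Two-stage allocation: a random simplex of HUC10 weights (symmetric
#' Dirichlet via normalized gamma draws), then a uniform catchment within
#' the chosen HUC10.  With a small concentration some HUC10s receive no
#' surveys at all, reproducing the unsurveyed-watershed regime that the
#' background sampler must handle.
#'
#' @param frame catchment frame.
#' @param model a [survey_model()].
#' @return data.frame of survey events with columns `catchment_id`, `year`.
#' @export
simulate_surveys <- function(frame, model) {
  withr::with_seed(derive_seed(model$seed, 5L), {
    hucs <- unique(frame$huc10)
    a <- model$effort_concentration
    g <- if (a == 0) {
      w <- numeric(length(hucs))
      w[sample.int(length(hucs), 1L)] <- 1
      w
    } else {
      stats::rgamma(length(hucs), shape = a)
    }
    if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
    w <- g / sum(g)
    huc_draw <- sample(hucs, model$n_surveys, replace = TRUE, prob = w)
    by_huc <- split(frame$catchment_id, frame$huc10)
    catch <- vapply(huc_draw, function(h) {
      ids <- by_huc[[h]]
      ids[sample.int(length(ids), 1L)]
    }, character(1), USE.NAMES = FALSE)
    years <- sample(seq(model$year_range[1L], model$year_range[2L]),
                    model$n_surveys, replace = TRUE)
    data.frame(catchment_id = catch, year = years, stringsAsFactors = FALSE)
  })
}

#' Record per-catchment survey counts on the frame
#'
#' @param frame catchment frame.
#' @param surveys survey-event records.
#' @return the frame with its `survey_count` column replaced by the tally.
#' @export
tally_surveys <- function(frame, surveys) {
  tab <- table(surveys$catchment_id)
  frame$survey_count <- as.integer(tab[frame$catchment_id])
  frame$survey_count[is.na(frame$survey_count)] <- 0L
  frame
}

#' Detection-limited presence-only occurrence records
#'
#' Each catchment's latent occupancy is a Bernoulli draw from its true
#' suitability; every survey event at an occupied catchment yields an
#' occurrence record with probability `detection_prob`.  Output is
#' presence-only: unoccupied or undetected catchments leave no trace, and
#' records can only reference surveyed catchments.
#'
#' @param truth named suitability vector from [true_suitability()].
#' @param surveys survey-event records.
#' @param detection_prob per-event detection probability in (0, 1].
#' @param seed integer seed.
#' @param species_id identifier stamped on the records.
#' @return data.frame with `species_id`, `catchment_id`, `year`, `habitat`.
#' @export
sample_occurrences <- function(truth, surveys, detection_prob, seed,
                               species_id = "sp") {
  if (!is.finite(detection_prob) || detection_prob <= 0 || detection_prob > 1) {
    stop("invalid config: detection_prob must lie in (0, 1]")
  }
  bad <- setdiff(unique(surveys$catchment_id), names(truth))
  if (length(bad) > 0L) stop("surveys reference catchments missing from truth")
  withr::with_seed(seed, {
    occupied <- names(truth)[stats::runif(length(truth)) < truth]
    at_occ <- surveys[surveys$catchment_id %in% occupied, , drop = FALSE]
    detected <- stats::runif(nrow(at_occ)) < detection_prob
    hits <- at_occ[detected, , drop = FALSE]
    data.frame(
      species_id = rep(species_id, nrow(hits)),
      catchment_id = hits$catchment_id,
      year = hits$year,
      habitat = if (nrow(hits) > 0L) {
        sample(c("lotic", "lentic"), nrow(hits), replace = TRUE,
               prob = c(0.8085, 0.1915))
      } else character(0),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic landscape with known truth
#'
#' One call that produces every table the pipeline consumes: catchments,
#' covariates, auxiliary prioritization covariates, survey events,
#' presence-only occurrence records, the species definitions, and the true
#' suitability surfaces.  Written as CSVs when `dir` is given, using the
#' same schemas the pipeline reads, so synthetic and real data are
#' interchangeable.
#'
#' @param config a [landscape_config()].
#' @param species list of [true_species()]; default [default_species_pool()].
#' @param survey a [survey_model()]; defaults to 4,000 events at
#'   concentration 0.5 and detection 0.8.
#' @param dir optional output directory for the CSV set.
#' @return list with `catchments`, `covariates`, `aux`, `surveys`,
#'   `occurrences`, `species`, `truth` (catchment x species matrix of
#'   suitabilities).
#' @export
synthetic_landscape <- function(config = landscape_config(),
                                species = NULL, survey = NULL, dir = NULL) {
  frame <- generate_hierarchy(config)
  covs <- generate_covariates(frame, config)
  aux <- generate_aux_covariates(frame, config)
  cov_names <- setdiff(names(covs), "catchment_id")
  if (is.null(species)) species <- default_species_pool(cov_names, seed = config$seed)
  if (is.null(survey)) survey <- survey_model(seed = config$seed)
  surveys <- simulate_surveys(frame, survey)
  frame <- tally_surveys(frame, surveys)
  truth <- sapply(species, function(sp) true_suitability(covs, sp))
  colnames(truth) <- vapply(species, `[[`, "", "species_id")
  occ <- do.call(rbind, lapply(seq_along(species), function(i) {
    sample_occurrences(truth[, i], surveys, survey$detection_prob,
                       seed = derive_seed(config$seed, 100L + i),
                       species_id = species[[i]]$species_id)
  }))
  rownames(occ) <- NULL
  out <- list(catchments = frame, covariates = covs, aux = aux,
              surveys = surveys, occurrences = occ, species = species,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(frame, file.path(dir, "catchments.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(covs), file.path(dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(aux, file.path(dir, "aux_covariates.csv"), row.names = FALSE)
    utils::write.csv(surveys, file.path(dir, "surveys.csv"), row.names = FALSE)
    utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
    sp_tab <- data.frame(
      species_id = vapply(species, `[[`, "", "species_id"),
      rsgcn_rank = vapply(species, `[[`, "", "rsgcn_rank"),
      prevalence_target = vapply(species, `[[`, 0, "prevalence_target"),
      stringsAsFactors = FALSE
    )
    utils::write.csv(sp_tab, file.path(dir, "species.csv"), row.names = FALSE)
    utils::write.csv(cbind(data.frame(catchment_id = frame$catchment_id),
                           as.data.frame(truth)),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  }
  out
}
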