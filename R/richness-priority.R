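#' Binarize predictions at a threshold
#'
#' @param predictions named numeric vector of predictions.
#' @param threshold decision threshold (typically from
#'   [max_sens_spec_threshold()]); predictions `>= threshold` become 1.
#' @return named integer 0/1 vector.
#' @export
binary_map <- function(predictions, threshold) {
  stats::setNames(as.integer(predictions >= threshold), names(predictions))
}

#' Stack binary species maps into richness surfaces
#'
#' Overall richness is the per-catchment count of species predicted
#' present; RSGCN richness counts only species ranked very high, high or
#' moderate conservation need.
#'
#' @param binary_maps named list of 0/1 vectors, one per species, all over
#'   the identical catchment set.
#' @param rsgcn_ranks named character vector of ranks per species
#'   (`very_high`, `high`, `moderate`, `not_listed`).
#' @return a `richness_map`: data.frame with `catchment_id`,
#'   `overall_richness`, `rsgcn_richness`.
#' @export
stack_richness <- function(binary_maps, rsgcn_ranks) {
  ids <- names(binary_maps[[1L]])
  for (m in binary_maps) {
    if (!identical(names(m), ids)) {
      stop("binary maps are not aligned on the same catchment set")
    }
  }
  M <- do.call(cbind, binary_maps)
  rsgcn <- names(binary_maps)[rsgcn_ranks[names(binary_maps)] %in%
                                c("very_high", "high", "moderate")]
  out <- data.frame(
    catchment_id = ids,
    overall_richness = as.integer(rowSums(M)),
    rsgcn_richness = as.integer(rowSums(M[, rsgcn, drop = FALSE])),
    stringsAsFactors = FALSE
  )
  class(out) <- c("richness_map", "data.frame")
  out
}

#' Survey priority surface
#'
#' Catchments with high predicted richness and no recent survey rank
#' highest: `minmax_scale(minmax_scale(overall_richness) - surveyed)`,
#' where `surveyed` is the binary indicator of a survey after the cutoff
#' year (1992 in the reference configuration: only the last thirty years of
#' effort count).
#'
#' @param richness a `richness_map`.
#' @param surveyed_ids catchments surveyed after the cutoff year.
#' @return a `priority_surface` (action `"survey"`), defined everywhere.
#' @export
survey_priority <- function(richness, surveyed_ids) {
  surveyed <- as.numeric(richness$catchment_id %in% surveyed_ids)
  score <- minmax_scale(minmax_scale(richness$overall_richness) - surveyed)
  priority_surface("survey", richness$catchment_id, score)
}

#' Restoration priority surface(s)
#'
#' One shared habitat-quality surface for the whole region —
#' `minmax_scale(scale(protected) + scale(forest) - scale(landuse_change))`
#' — with species-specific eligibility: population restoration happens
#' within the species' recorded range, so catchments whose HUC8 contains no
#' record of the focal species are ineligible and receive no score (`NA`,
#' not 0).  Restricted to species of high or very high conservation
#' concern.
#'
#' @param frame catchment frame.
#' @param protected_pct,forest_pct,landuse_change_pct per-catchment
#'   columns aligned with `frame`.
#' @param presences per-species presence list from
#'   [consolidate_presences()].
#' @param rsgcn_ranks named ranks per species.
#' @return named list of `priority_surface` objects (action
#'   `"restoration"`), one per eligible-rank species.
#' @export
restoration_priority <- function(frame, protected_pct, forest_pct,
                                 landuse_change_pct, presences, rsgcn_ranks) {
  base <- minmax_scale(minmax_scale(protected_pct) + minmax_scale(forest_pct) -
                         minmax_scale(landuse_change_pct))
  species <- names(rsgcn_ranks)[rsgcn_ranks %in% c("very_high", "high")]
  out <- lapply(species, function(sp) {
    eligible <- huc8_occurrence_layer(presences[[sp]] %||% character(0),
                                      frame) == 1L
    score <- ifelse(eligible, base, NA_real_)
    priority_surface("restoration", frame$catchment_id, score,
                     species_id = sp, eligible = eligible)
  })
  stats::setNames(out, species)
}

#' Land-protection priority surface
#'
#' `minmax_scale(scale(richness) + scale(forest) + scale(wetland) +
#' scale(resilience))`: catchments with more predicted species, more forest
#' and wetland cover, and higher climate resilience rank higher.
#'
#' @param richness a `richness_map`.
#' @param forest_pct,wetland_pct,resilience per-catchment columns aligned
#'   with the richness map.
#' @return a `priority_surface` (action `"protection"`), defined
#'   everywhere.
#' @export
protection_priority <- function(richness, forest_pct, wetland_pct,
                                resilience) {
  score <- minmax_scale(minmax_scale(richness$overall_richness) +
                          minmax_scale(forest_pct) +
                          minmax_scale(wetland_pct) +
                          minmax_scale(resilience))
  priority_surface("protection", richness$catchment_id, score)
}

#' Construct a priority surface
#'
#' @param action `"survey"`, `"restoration"` or `"protection"`.
#' @param catchment_id catchment ids.
#' @param score scores in `[0, 1]`; `NA` marks ineligible catchments.
#' @param species_id focal species (restoration only).
#' @param eligible logical eligibility mask (defaults to `!is.na(score)`).
#' @return a `priority_surface` data.frame.
#' @export
priority_surface <- function(action = c("survey", "restoration", "protection"),
                             catchment_id, score, species_id = NULL,
                             eligible = NULL) {
  action <- match.arg(action)
  if (is.null(eligible)) eligible <- !is.na(score)
  defined <- score[!is.na(score)]
  if (length(defined) > 0L && (min(defined) < -1e-9 || max(defined) > 1 + 1e-9)) {
    stop("priority scores must lie in [0, 1]")
  }
  out <- data.frame(catchment_id = catchment_id, score = score,
                    eligible = eligible, stringsAsFactors = FALSE)
  attr(out, "action") <- action
  attr(out, "species_id") <- species_id
  class(out) <- c("priority_surface", "data.frame")
  out
}

#' Interspecies correlation of predicted surfaces
#'
#' Spearman rho between each species pair's predicted probability of
#' occurrence across catchments.  Constant surfaces yield `NA` entries.
#'
#' @param surfaces named list of aligned prediction vectors (>= 2 species).
#' @return symmetric matrix of rho with unit diagonal.
#' @export
interspecies_correlation <- function(surfaces) {
  if (length(surfaces) < 2L) stop("need at least two species surfaces")
  ids <- names(surfaces[[1L]])
  for (s in surfaces) {
    if (!identical(names(s), ids)) stop("surfaces are not aligned")
  }
  M <- do.call(cbind, surfaces)
  n_sp <- ncol(M)
  out <- matrix(NA_real_, n_sp, n_sp,
                dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(n_sp)) {
    for (j in seq_len(n_sp)) {
      out[i, j] <- if (i == j) 1 else spearman_rho(M[, i], M[, j])
    }
  }
  out
}

#' Correlation between protection priority and current protection
#'
#' Quantifies whether already-protected catchments are the ones the
#' analysis prioritizes: Spearman rho between the protection priority score
#' and current percent protected land, region-wide and (when states are
#' given) per state.  Low values mean high-priority catchments are largely
#' unprotected today.
#'
#' @param protection a protection `priority_surface`.
#' @param protected_pct per-catchment percent protected, aligned.
#' @param states optional per-catchment state labels.
#' @return list with `region` (scalar rho) and `by_state` (named vector,
#'   when states are given).
#' @export
protection_vs_protected_correlation <- function(protection, protected_pct,
                                                states = NULL) {
  region <- spearman_rho(protection$score, protected_pct)
  out <- list(region = region)
  if (!is.null(states)) {
    out$by_state <- vapply(split(seq_along(states), states), function(ix) {
      spearman_rho(protection$score[ix], protected_pct[ix])
    }, 0)
  }
  out
}

#' Per-state summary of surveys, richness and priorities
#'
#' One row per state: total survey events, mean predicted richness per
#' catchment, and mean (with standard error) priority score per surface.
#' Restoration surfaces with no eligible catchment in a state report `NA`
#' (the not-applicable marker).
#'
#' @param frame catchment frame with `state`.
#' @param richness a `richness_map` aligned with the frame.
#' @param surfaces named list of `priority_surface` objects.
#' @param surveys survey-event records (for the per-state survey counts).
#' @return data.frame, one row per state.
#' @export
state_summaries <- function(frame, richness, surfaces, surveys) {
  if (!"state" %in% names(frame)) stop("frame has no state labels")
  states <- sort(unique(frame$state))
  surv_state <- frame$state[match(surveys$catchment_id, frame$catchment_id)]
  rich <- richness$overall_richness[match(frame$catchment_id,
                                          richness$catchment_id)]
  out <- data.frame(
    state = states,
    n_surveys = as.integer(vapply(states, function(s) sum(surv_state == s,
                                                          na.rm = TRUE), 0L)),
    mean_richness = vapply(states, function(s) mean(rich[frame$state == s]), 0),
    stringsAsFactors = FALSE
  )
  for (nm in names(surfaces)) {
    sc <- surfaces[[nm]]$score[match(frame$catchment_id,
                                     surfaces[[nm]]$catchment_id)]
    mval <- vapply(states, function(s) {
      x <- sc[frame$state == s]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0)
    sval <- vapply(states, function(s) se_mean(sc[frame$state == s]), 0)
    out[[paste0("mean_", nm)]] <- mval
    out[[paste0("se_", nm)]] <- sval
  }
  rownames(out) <- NULL
  out
}
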