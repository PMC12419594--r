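#' Candidate catchments for background selection
#'
#' Background points characterize the surveyed environment, so the candidate
#' pool excludes (1) every catchment lying in a HUC10 with no survey records
#' for any species — a bias correction: MaxEnt assumes equal sampling
#' probability across the region, which uneven survey effort violates — and
#' (2) every catchment with a known occurrence of the focal species.  Each
#' surviving catchment is represented once, by its centroid.
#'
#' @param frame catchment frame with populated `survey_count`.
#' @param presences character vector of focal-species presence catchment
#'   ids.
#' @return character vector of candidate catchment ids.
#' @export
eligible_background <- function(frame, presences = character(0)) {
  surveyed_huc10 <- unique(frame$huc10[frame$survey_count > 0])
  cand <- frame$catchment_id[frame$huc10 %in% surveyed_huc10 &
                               !(frame$catchment_id %in% presences)]
  if (length(cand) == 0L) {
    stop("no eligible background catchments remain after excluding ",
         "unsurveyed HUC10s and focal-species presence catchments")
  }
  cand
}

#' Survey-probability weights for background candidates
#'
#' Weights reflect each candidate's probability of having been surveyed.
#' Two published readings of the rule are supported:
#' `catchment_share` (default) makes the weight proportional to the share of
#' all survey events that occurred in the catchment; `huc10_share` divides
#' the encompassing HUC10's share of survey events evenly among its
#' candidate catchments.  Under `catchment_share`, never-surveyed (but
#' eligible) catchments would get exactly zero weight, so a small floor
#' `eps` (default `0.1 / n_candidates`) keeps them selectable; weights are
#' renormalized to sum to one.
#'
#' @param candidates candidate catchment ids from [eligible_background()].
#' @param frame catchment frame with `survey_count`.
#' @param mode `"catchment_share"` or `"huc10_share"`.
#' @param eps weight floor applied to zero-weight candidates under
#'   `catchment_share`; `0` disables the floor.
#' @return named numeric vector of weights over candidates, summing to 1.
#' @export
selection_weights <- function(candidates, frame,
                              mode = c("catchment_share", "huc10_share"),
                              eps = NULL) {
  mode <- match.arg(mode)
  if (length(candidates) == 0L) stop("no candidates")
  idx <- match(candidates, frame$catchment_id)
  if (anyNA(idx)) stop("candidates missing from frame")
  total <- sum(frame$survey_count)
  if (total == 0) stop("selection_weights: frame has no surveys")
  if (mode == "catchment_share") {
    w <- frame$survey_count[idx] / total
    if (is.null(eps)) eps <- 0.1 / length(candidates)
    if (eps > 0) w[w == 0] <- eps
  } else {
    huc_surv <- tapply(frame$survey_count, frame$huc10, sum)
    n_cand_huc <- table(frame$huc10[idx])
    h <- frame$huc10[idx]
    w <- (huc_surv[h] / total) / as.numeric(n_cand_huc[h])
  }
  w <- as.numeric(w)
  if (sum(w) == 0) stop("all candidate weights are zero")
  stats::setNames(w / sum(w), candidates)
}

#' Draw a background point set
#'
#' If no more candidates exist than the requested number, all candidates are
#' used (the wide-ranging-species rule: when exclusions leave fewer than the
#' cap, every available centroid becomes background).  Otherwise, draws
#' `n_background` distinct catchments by weighted sampling without
#' replacement (iterative draw-and-remove with renormalization, as
#' implemented by [sample()]).
#'
#' @param candidates candidate catchment ids.
#' @param weights weights from [selection_weights()] (aligned or named).
#' @param n_background cap on the number of background points (default
#'   10,000).
#' @param seed integer seed for reproducibility.
#' @return character vector of selected catchment ids (unsorted draw order
#'   for audit; duplicate-free).
#' @export
sample_background <- function(candidates, weights, n_background = 10000L,
                              seed = 1L) {
  stopifnot_positive_int(n_background, "n_background")
  if (length(weights) != length(candidates)) {
    weights <- weights[candidates]
  }
  if (any(!is.finite(weights)) || any(weights < 0)) stop("invalid weights")
  if (length(candidates) <= n_background) return(candidates)
  withr::with_seed(seed, {
    sample(candidates, n_background, replace = FALSE, prob = weights)
  })
}

#' Write the per-species background audit file
#'
#' @param candidates candidate ids.
#' @param weights candidate weights.
#' @param selected ids drawn as background.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_background_audit <- function(candidates, weights, selected, path) {
  utils::write.csv(data.frame(
    catchment_id = candidates,
    weight = as.numeric(weights),
    selected = as.integer(candidates %in% selected),
    stringsAsFactors = FALSE
  ), path, row.names = FALSE)
  invisible(path)
}
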