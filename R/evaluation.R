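#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random presence outscores a random background
#' point, with ties counting one half: the mean over all presence x
#' background pairs of `1[p > b] + 0.5 * 1[p == b]`.  Computed via ranks
#' (identical to brute-force pair counting, which the tests verify), so it
#' is invariant under strictly monotone transforms of the scores.  Models
#' with AUC above 0.7 are conventionally deemed acceptable.
#'
#' @param presence_scores,background_scores nonempty numeric vectors.
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores)
  nb <- length(background_scores)
  if (np == 0L || nb == 0L) stop("auc: empty score vector")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Continuous Boyce Index
#'
#' Slides overlapping windows across the range of the evaluation scores; in
#' each window computes the predicted-to-expected ratio `F = P / E`, where
#' `P` is the fraction of presence scores and `E` the fraction of
#' evaluation scores falling inside (windows with `E = 0` are skipped), and
#' returns the Spearman correlation between `F` and the window midpoint.  A
#' calibrated model concentrates presences at high scores, giving an index
#' near 1; a chance model gives about 0; an inverted model, near -1.
#'
#' @param presence_scores scores at presence catchments.
#' @param evaluation_scores scores characterizing availability (background
#'   or all catchments).
#' @param n_windows number of window midpoints (default 101).
#' @param window_width window width as a fraction of the score range
#'   (default 0.1).
#' @return scalar in `[-1, 1]`.
#' @export
boyce_index <- function(presence_scores, evaluation_scores,
                        n_windows = 101L, window_width = 0.1) {
  if (length(evaluation_scores) == 0L || length(presence_scores) == 0L) {
    stop("boyce_index: empty scores")
  }
  lo <- min(evaluation_scores)
  hi <- max(evaluation_scores)
  if (hi <= lo) {
    stop("boyce_index undefined: evaluation scores are constant")
  }
  w <- window_width * (hi - lo)
  mids <- seq(lo + w / 2, hi - w / 2, length.out = n_windows)
  P <- vapply(mids, function(m) {
    mean(presence_scores >= m - w / 2 & presence_scores <= m + w / 2)
  }, 0)
  E <- vapply(mids, function(m) {
    mean(evaluation_scores >= m - w / 2 & evaluation_scores <= m + w / 2)
  }, 0)
  keep <- E > 0
  if (sum(keep) < 3L) stop("boyce_index undefined: too few populated windows")
  f_ratio <- P[keep] / E[keep]
  if (length(unique(f_ratio)) < 2L) return(0)
  stats::cor(f_ratio, mids[keep], method = "spearman")
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Scans the sorted unique pooled scores; at a candidate `t`, sensitivity is
#' the fraction of presences with score `>= t` (a presence exactly at the
#' threshold counts as predicted present — the inclusive convention) and
#' specificity the fraction of background with score `< t`.  Returns the
#' maximizing threshold, taking the smallest on ties (greater inclusion
#' than exclusion).
#'
#' @param presence_scores,background_scores nonempty numeric vectors
#'   (background points act as pseudoabsences).
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
max_sens_spec_threshold <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0L || length(background_scores) == 0L) {
    stop("max_sens_spec_threshold: empty score vector")
  }
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(cand, function(t) mean(background_scores < t), 0)
  total <- sens + spec
  best <- which(total >= max(total) - 1e-12)[1L]   # smallest t on ties
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' False-negative and possible-new-catchment bookkeeping
#'
#' Given a binary predicted-occurrence map over the full landscape and the
#' set of catchments with records, counts `n_false_negative` (catchments
#' with records that the model predicts absent) and `n_possible_new`
#' (catchments predicted present that have no records).
#'
#' @param binary_map named 0/1 vector over all catchments.
#' @param presence_ids catchment ids with records of the focal species.
#' @return list with `n_false_negative`, `n_possible_new`.
#' @export
classification_bookkeeping <- function(binary_map, presence_ids) {
  predicted_present <- names(binary_map)[binary_map == 1]
  list(
    n_false_negative = length(setdiff(presence_ids, predicted_present)),
    n_possible_new = length(setdiff(predicted_present, presence_ids))
  )
}

#' Full evaluation report for one species model
#'
#' Bundles AUC, the Continuous Boyce Index over all-catchment predictions,
#' the max-sensitivity-plus-specificity threshold with its sensitivity and
#' specificity, the percent of catchments predicted occupied, and the
#' false-negative / possible-new-catchment counts.
#'
#' @param predictions named prediction vector over all catchments.
#' @param presence_ids presence catchment ids.
#' @param background_ids background catchment ids.
#' @param n_windows,window_width Boyce-index window settings.
#' @return an `evaluation_report` list.
#' @export
evaluate_model <- function(predictions, presence_ids, background_ids,
                           n_windows = 101L, window_width = 0.1) {
  pres <- predictions[presence_ids]
  bg <- predictions[background_ids]
  a <- auc(pres, bg)
  cbi <- tryCatch(boyce_index(pres, predictions, n_windows, window_width),
                  error = function(e) NA_real_)
  th <- max_sens_spec_threshold(pres, bg)
  bmap <- binary_map(predictions, th$threshold)
  book <- classification_bookkeeping(bmap, presence_ids)
  structure(list(
    auc = a, auc_acceptable = a > 0.7, cbi = cbi,
    threshold = th$threshold, sensitivity = th$sensitivity,
    specificity = th$specificity,
    pct_predicted_present = 100 * mean(bmap),
    n_false_negative = book$n_false_negative,
    n_possible_new = book$n_possible_new,
    n_presence = length(presence_ids), n_background = length(background_ids)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("Model evaluation: AUC = %.3f%s, CBI = %s\n",
                     "  threshold = %.4f (sens %.3f, spec %.3f)\n",
                     "  %.2f%% of catchments predicted present; ",
                     "%d false negatives, %d possible new catchments\n"),
              x$auc, if (x$auc_acceptable) " (acceptable)" else "",
              if (is.na(x$cbi)) "NA" else sprintf("%.3f", x$cbi),
              x$threshold, x$sensitivity, x$specificity,
              x$pct_predicted_present, x$n_false_negative, x$n_possible_new))
  invisible(x)
}
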