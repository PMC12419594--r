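#' Spearman rank-correlation matrix over covariates
#'
#' Pairwise Spearman rho (average ranks for ties) over the covariate columns
#' of a table.  Pairs involving a constant column are undefined and reported
#' as `NA`; the screening report flags them.
#'
#' @param covariates a [covariate_table()] or data.frame with
#'   `catchment_id` plus numeric columns.
#' @param vars optional subset of covariate names.
#' @return symmetric matrix of rho with unit diagonal.
#' @export
spearman_matrix <- function(covariates, vars = NULL) {
  if (is.null(vars)) vars <- setdiff(names(covariates), "catchment_id")
  X <- as.matrix(covariates[vars])
  if (nrow(X) < 3L) stop("spearman_matrix: need at least 3 rows")
  suppressWarnings(m <- stats::cor(X, method = "spearman"))
  const <- apply(X, 2L, function(x) length(unique(x)) < 2L)
  m[const, ] <- NA_real_
  m[, const] <- NA_real_
  diag(m) <- 1
  m
}

#' Drop collinear covariates by rank correlation
#'
#' Implements the screening rule: any covariate pair with `|rho|` strictly
#' exceeding the threshold loses its lower-priority member.  The field's
#' usual resolution (ask experts which variable is more ecologically
#' relevant) is replaced by an explicit, reproducible `keep_priority`
#' ordering.  The procedure is equivalent to a greedy pass in priority
#' order: keep a covariate iff it is not over-correlated with any
#' already-kept covariate; it terminates with no retained pair above the
#' threshold and is invariant to input row order.
#'
#' @param rho symmetric correlation matrix from [spearman_matrix()].
#' @param threshold flag pairs with `|rho| > threshold` (strict; default
#'   0.70).
#' @param keep_priority covariate names in decreasing priority; must cover
#'   every covariate involved in a flagged pair.  Defaults to the matrix
#'   column order.
#' @return a `screening_report` list: `spearman_matrix`, `flagged_pairs`
#'   (data.frame a, b, rho), `dropped`, `retained`, `vif` (empty until
#'   [compute_vif()] fills it).
#' @export
screen_collinear <- function(rho, threshold = 0.70, keep_priority = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  vars <- colnames(rho)
  flag_idx <- which(abs(rho) > threshold & upper.tri(rho), arr.ind = TRUE)
  flagged <- data.frame(a = vars[flag_idx[, 1L]], b = vars[flag_idx[, 2L]],
                        rho = rho[flag_idx], stringsAsFactors = FALSE)
  if (is.null(keep_priority)) keep_priority <- vars
  involved <- unique(c(flagged$a, flagged$b))
  uncovered <- setdiff(involved, keep_priority)
  if (length(uncovered) > 0L) {
    stop("keep_priority does not cover flagged covariate(s): ",
         paste(uncovered, collapse = ", "))
  }
  ordered <- c(intersect(keep_priority, vars), setdiff(vars, keep_priority))
  kept <- character(0)
  for (v in ordered) {
    over <- kept[!is.na(rho[v, kept]) & abs(rho[v, kept]) > threshold]
    if (length(over) == 0L) kept <- c(kept, v)
  }
  dropped <- setdiff(vars, kept)
  structure(list(spearman_matrix = rho, flagged_pairs = flagged,
                 dropped = dropped, retained = vars[vars %in% kept],
                 threshold = threshold, vif = numeric(0)),
            class = "screening_report")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of covariate j on all other covariates (with intercept).
#' Exact collinearity is reported as an `Inf` sentinel rather than an
#' exception.  The screening convention keeps all covariates with VIF below
#' 5.
#'
#' @param covariates a [covariate_table()] or data.frame.
#' @param vars covariate names to assess (default: all continuous columns).
#' @return named numeric vector of VIFs (all `>= 1`, possibly `Inf`).
#' @export
compute_vif <- function(covariates, vars = NULL) {
  if (is.null(vars)) {
    vars <- if (!is.null(attr(covariates, "cov_type"))) {
      covariate_names(covariates, "continuous")
    } else setdiff(names(covariates), "catchment_id")
  }
  X <- as.matrix(covariates[vars])
  if (length(vars) < 2L) return(stats::setNames(rep(1, length(vars)), vars))
  if (nrow(X) < length(vars) + 1L) stop("compute_vif: need at least p+1 rows")
  if (any(apply(X, 2L, stats::sd) == 0)) stop("compute_vif: constant column")
  vif <- vapply(seq_along(vars), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(pmax(vif, 1), vars)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Covariate screening report\n")
  cat(sprintf("  %d covariates, threshold |rho| > %.2f\n",
              ncol(x$spearman_matrix), x$threshold))
  cat(sprintf("  flagged pairs: %d; dropped: %s\n", nrow(x$flagged_pairs),
              if (length(x$dropped) == 0L) "none" else
                paste(x$dropped, collapse = ", ")))
  if (length(x$vif) > 0L) {
    cat("  VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a screening report
#'
#' Writes the correlation matrix as CSV plus a plain-text log of flags and
#' drops.
#'
#' @param report a `screening_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_screening_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(dir, "spearman_matrix.csv")
  utils::write.csv(report$spearman_matrix, mpath)
  lpath <- file.path(dir, "screening_log.txt")
  lines <- c(
    sprintf("collinearity threshold: |rho| > %.2f (strict)", report$threshold),
    sprintf("flagged pairs: %d", nrow(report$flagged_pairs)),
    if (nrow(report$flagged_pairs) > 0L) {
      sprintf("  %s ~ %s (rho = %.3f)", report$flagged_pairs$a,
              report$flagged_pairs$b, report$flagged_pairs$rho)
    },
    sprintf("dropped: %s", if (length(report$dropped) == 0L) "none" else
      paste(report$dropped, collapse = ", ")),
    sprintf("retained: %s", paste(report$retained, collapse = ", ")),
    if (length(report$vif) > 0L) {
      sprintf("VIF %s: %.3f", names(report$vif), report$vif)
    }
  )
  writeLines(lines, lpath)
  invisible(c(mpath, lpath))
}
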