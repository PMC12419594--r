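#' Expand covariates into MaxEnt feature classes
#'
#' Builds the model basis from the classical feature classes.  Continuous
#' covariates are first rescaled to `[0, 1]` using their minimum and maximum
#' over the background; the classes are then: `linear` (z), `quadratic`
#' (z^2), `product` (z_a * z_b over all continuous pairs), `hinge` (forward
#' `max(0, (z - k) / (1 - k))` and reverse `max(0, (k - z) / k)` at each
#' knot) and `threshold` (`1[z > k]`), with knots at `n_knots` evenly spaced
#' background quantiles strictly inside the range.  Binary covariates
#' receive `categorical` indicators only, one per background level.  A
#' covariate constant over the background contributes no features (it is
#' recorded, not an error).
#'
#' @param covariates a [covariate_table()] (or data.frame with
#'   `catchment_id`).
#' @param background_ids catchment ids defining the background sample.
#' @param classes subset of
#'   `c("linear","quadratic","product","hinge","threshold","categorical")`.
#' @param n_knots number of hinge/threshold knots per covariate.
#' @param vars covariate columns to use (default all).
#' @return a `feature_set`: scaling constants, knot positions, and feature
#'   descriptors; used with [feature_matrix()].
#' @export
expand_features <- function(covariates, background_ids,
                            classes = c("linear", "quadratic", "product",
                                        "hinge", "threshold", "categorical"),
                            n_knots = 10L, vars = NULL) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (is.null(vars)) vars <- setdiff(names(covariates), "catchment_id")
  idx <- match(background_ids, covariates$catchment_id)
  if (anyNA(idx)) stop("background ids missing from covariate table")
  if (length(idx) == 0L) stop("empty background")
  tp <- attr(covariates, "cov_type")
  scaling <- list()
  dropped <- character(0)
  for (v in vars) {
    x <- covariates[[v]][idx]
    is_bin <- if (!is.null(tp) && v %in% names(tp)) tp[[v]] == "binary" else
      all(covariates[[v]] %in% c(0, 1))
    if (length(unique(x)) < 2L) {
      dropped <- c(dropped, v)
      next
    }
    if (is_bin) {
      scaling[[v]] <- list(type = "binary", levels = sort(unique(x)))
    } else {
      lo <- min(x)
      hi <- max(x)
      z <- (x - lo) / (hi - lo)
      probs <- seq_len(n_knots) / (n_knots + 1)
      knots <- unique(stats::quantile(z, probs, names = FALSE, type = 7))
      knots <- knots[knots > 1e-9 & knots < 1 - 1e-9]
      scaling[[v]] <- list(type = "continuous", min = lo, max = hi,
                           knots = knots)
    }
  }
  cont <- names(scaling)[vapply(scaling, function(s) s$type == "continuous",
                                TRUE)]
  bin <- setdiff(names(scaling), cont)
  feats <- list()
  add <- function(kind, v1, v2 = NA_character_, knot = NA_real_,
                  level = NA_real_, name) {
    feats[[length(feats) + 1L]] <<- list(kind = kind, v1 = v1, v2 = v2,
                                         knot = knot, level = level,
                                         name = name)
  }
  for (v in cont) {
    if ("linear" %in% classes) add("linear", v, name = paste0("lin:", v))
    if ("quadratic" %in% classes) add("quadratic", v, name = paste0("quad:", v))
    if ("hinge" %in% classes) {
      for (k in scaling[[v]]$knots) {
        add("hinge_fwd", v, knot = k, name = sprintf("hingef:%s@%.6f", v, k))
        add("hinge_rev", v, knot = k, name = sprintf("hinger:%s@%.6f", v, k))
      }
    }
    if ("threshold" %in% classes) {
      for (k in scaling[[v]]$knots) {
        add("threshold", v, knot = k, name = sprintf("thr:%s@%.6f", v, k))
      }
    }
  }
  if ("product" %in% classes && length(cont) > 1L) {
    for (i in seq_len(length(cont) - 1L)) {
      for (j in seq((i + 1L), length(cont))) {
        add("product", cont[i], cont[j],
            name = paste0("prod:", cont[i], "*", cont[j]))
      }
    }
  }
  if ("categorical" %in% classes) {
    for (v in bin) {
      for (lv in scaling[[v]]$levels) {
        add("categorical", v, level = lv, name = sprintf("cat:%s=%g", v, lv))
      }
    }
  }
  structure(list(vars = names(scaling), scaling = scaling,
                 features = feats, classes = classes, n_knots = n_knots,
                 dropped = dropped),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d features over %d covariates (classes: %s)\n",
              length(x$features), length(x$vars),
              paste(x$classes, collapse = ", ")))
  if (length(x$dropped) > 0L) {
    cat("  constant over background, no features:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a feature set on catchments
#'
#' Builds the numeric design matrix for a set of catchments.  At prediction
#' time continuous covariates are clamped to the background `[0, 1]` range
#' before transformation, avoiding extrapolation artifacts.
#'
#' @param fs a `feature_set` from [expand_features()].
#' @param covariates the covariate table.
#' @param ids catchment ids (default: all rows).
#' @param clamp clamp rescaled values into `[0, 1]` (default `TRUE`).
#' @return numeric matrix, one row per id, one named column per feature.
#' @export
feature_matrix <- function(fs, covariates, ids = NULL, clamp = TRUE) {
  if (is.null(ids)) ids <- covariates$catchment_id
  idx <- match(ids, covariates$catchment_id)
  if (anyNA(idx)) stop("ids missing from covariate table")
  z <- list()
  for (v in fs$vars) {
    s <- fs$scaling[[v]]
    x <- covariates[[v]][idx]
    if (s$type == "continuous") {
      zz <- (x - s$min) / (s$max - s$min)
      if (clamp) zz <- pmin(pmax(zz, 0), 1)
      z[[v]] <- zz
    } else {
      z[[v]] <- x
    }
  }
  p <- length(fs$features)
  M <- matrix(0, length(ids), p)
  nm <- character(p)
  for (j in seq_len(p)) {
    f <- fs$features[[j]]
    nm[j] <- f$name
    M[, j] <- switch(f$kind,
      linear = z[[f$v1]],
      quadratic = z[[f$v1]]^2,
      product = z[[f$v1]] * z[[f$v2]],
      hinge_fwd = pmax(0, (z[[f$v1]] - f$knot) / (1 - f$knot)),
      hinge_rev = pmax(0, (f$knot - z[[f$v1]]) / f$knot),
      threshold = as.numeric(z[[f$v1]] > f$knot),
      categorical = as.numeric(z[[f$v1]] == f$level),
      stop("unknown feature kind: ", f$kind)
    )
  }
  colnames(M) <- nm
  rownames(M) <- ids
  M
}
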