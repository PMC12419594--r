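# Internal: smooth part of the objective and its gradient.
#   f(lambda) = log Z(lambda) - <E_pres f, lambda>,  Z over the background.
# J = f + sum_j beta_j |lambda_j| is the (convex) penalized negative
# presence log-likelihood, up to an additive constant.
maxent_obj_parts <- function(lambda, bgX, Ep) {
  eta <- drop(bgX %*% lambda)
  m <- max(eta)
  w <- exp(eta - m)
  Z <- sum(w)
  q <- w / Z
  logZ <- m + log(Z)
  list(f = logZ - sum(Ep * lambda), q = q, logZ = logZ,
       Eq = drop(crossprod(bgX, q)))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# KKT slack of the L1 problem: for zero coordinates the excess of |grad|
# over beta; for active coordinates the absolute stationarity residual.
kkt_slack <- function(lambda, grad, beta_vec) {
  active <- lambda != 0
  v <- abs(grad) - beta_vec
  v[active] <- abs(grad[active] + sign(lambda[active]) * beta_vec[active])
  v[!active] <- pmax(v[!active], 0)
  v
}

#' Fit a regularized maximum-entropy presence/background model
#'
#' Maximizes the penalized presence log-likelihood of the Gibbs distribution
#' `q(i) = exp(lambda . f_i) / Z` over the background, minus the L1 penalty
#' `sum_j beta_j |lambda_j|` with `beta_j = beta_multiplier * s_j /
#' sqrt(n_presence)` (`s_j` the feature's background standard deviation).
#' The optimizer is accelerated proximal gradient (FISTA with backtracking
#' and restart) followed by an active-set Newton polish, so the
#' Karush-Kuhn-Tucker condition `|E_pres f_j - E_q f_j| <= beta_j`
#' holds to tight tolerance at the solution.  Features with zero background
#' variance are excluded from fitting (their coefficient is fixed at zero).
#'
#' @param presence_X feature matrix of presence catchments (rows).
#' @param background_X feature matrix of background catchments; same
#'   columns.
#' @param beta_multiplier nonnegative regularization multiplier.
#' @param lambda_init optional warm-start coefficient vector.
#' @param kkt_tol target maximum KKT slack (default 1e-6).
#' @param obj_tol relative objective-change tolerance (default 1e-9).
#' @param max_iter FISTA iteration cap.
#' @param lambda_box box bound on every coefficient (default 50, enormous
#'   on the unit feature scale).  On near-separable degenerate instances
#'   the penalized optimum can fail to exist (a separating feature
#'   direction outruns its penalty; packaged implementations dodge the
#'   case by adding presence samples to the background).  The box keeps
#'   the solve finite; a fit that stalls at the bound is returned with
#'   `certified = FALSE` and `at_bound = TRUE` rather than erroring.
#' @param transform default output transform for [predict_maxent()].
#' @return a `maxent_model` with coefficients, `log_normalizer` (log Z over
#'   the fitted background), `entropy_H` (entropy of the raw background
#'   distribution), the per-feature penalties, and convergence diagnostics.
#' @export
fit_maxent <- function(presence_X, background_X, beta_multiplier = 1,
                       lambda_init = NULL, kkt_tol = 1e-6, obj_tol = 1e-9,
                       max_iter = 5000L, lambda_box = 50,
                       transform = "logistic") {
  presence_X <- as.matrix(presence_X)
  background_X <- as.matrix(background_X)
  if (nrow(presence_X) < 1L) stop("maxent fit requires at least one presence")
  if (nrow(background_X) < 2L) stop("maxent fit requires >= 2 background points")
  if (ncol(presence_X) != ncol(background_X)) stop("feature column mismatch")
  if (any(!is.finite(presence_X)) || any(!is.finite(background_X))) {
    stop("non-finite feature values")
  }
  if (beta_multiplier < 0) stop("beta_multiplier must be nonnegative")
  p_all <- ncol(background_X)
  n_pres <- nrow(presence_X)
  s_all <- apply(background_X, 2L, stats::sd)
  # A feature whose presence mean lies outside the closed background range
  # has an infeasible moment constraint over the background support: no
  # finite coefficient vector satisfies stationarity and the objective is
  # unbounded below once the gap exceeds the penalty.  (Packaged MaxEnt
  # implementations avoid the case by adding presence samples to the
  # background; this model keeps the background pure and excludes the
  # feature instead, recording it.)
  Ep_all <- colMeans(presence_X)
  bg_lo <- apply(background_X, 2L, min)
  bg_hi <- apply(background_X, 2L, max)
  feasible <- Ep_all <= bg_hi + 1e-12 & Ep_all >= bg_lo - 1e-12
  use <- s_all > 1e-12 & feasible
  lambda_full <- stats::setNames(rep(0, p_all), colnames(background_X))

  if (any(use)) {
    bgX <- background_X[, use, drop = FALSE]
    Ep <- colMeans(presence_X[, use, drop = FALSE])
    beta_vec <- beta_multiplier * s_all[use] / sqrt(n_pres)
    p <- ncol(bgX)
    lambda <- rep(0, p)
    if (!is.null(lambda_init)) {
      li <- lambda_init
      if (!is.null(names(li)) && !is.null(colnames(background_X))) {
        li <- li[colnames(background_X)]
        li[is.na(li)] <- 0
      }
      lambda <- as.numeric(li[use])
    }

    J_of <- function(lam, f = NULL) {
      if (is.null(f)) f <- maxent_obj_parts(lam, bgX, Ep)$f
      f + sum(beta_vec * abs(lam))
    }

    # --- FISTA with backtracking and function-value restart ---
    L <- 1
    y <- lambda
    t_acc <- 1
    parts <- maxent_obj_parts(lambda, bgX, Ep)
    J_prev <- parts$f + sum(beta_vec * abs(lambda))
    iters <- 0L
    kkt <- Inf
    stalled <- 0L
    for (it in seq_len(max_iter)) {
      iters <- it
      py <- maxent_obj_parts(y, bgX, Ep)
      gy <- py$Eq - Ep
      repeat {
        cand <- pmin(pmax(soft_threshold(y - gy / L, beta_vec / L),
                          -lambda_box), lambda_box)
        d <- cand - y
        f_cand <- maxent_obj_parts(cand, bgX, Ep)$f
        if (f_cand <= py$f + sum(gy * d) + (L / 2) * sum(d * d) + 1e-14) break
        L <- L * 2
        if (L > 1e12) break
      }
      t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
      y_new <- cand + ((t_acc - 1) / t_new) * (cand - lambda)
      J_new <- J_of(cand, f_cand)
      if (J_new > J_prev) {        # restart momentum
        y_new <- cand
        t_new <- 1
      }
      moved <- sum(abs(cand - lambda))
      lambda <- cand
      y <- y_new
      t_acc <- t_new
      if (it %% 5L == 0L || moved == 0) {
        pl <- maxent_obj_parts(lambda, bgX, Ep)
        kkt <- max(kkt_slack(lambda, pl$Eq - Ep, beta_vec))
        if (kkt <= kkt_tol) break
        if (abs(J_prev - J_new) <= obj_tol * (1 + abs(J_new))) {
          if (kkt <= 1e-4) break
          # stalled at the box bound: the unconstrained optimum does not
          # exist, so further iteration cannot earn the certificate
          if (any(abs(lambda) >= lambda_box - 1e-6)) {
            stalled <- stalled + 1L
            if (stalled >= 20L) break
          }
        } else stalled <- 0L
      }
      J_prev <- J_new
      L <- max(L / 1.5, 1e-4)
    }

    # --- active-set Newton polish (skipped for box-bounded solutions) ---
    at_bound <- any(abs(lambda) >= lambda_box - 1e-6)
    for (round in if (at_bound) integer(0) else seq_len(40L)) {
      pl <- maxent_obj_parts(lambda, bgX, Ep)
      grad <- pl$Eq - Ep
      slack <- kkt_slack(lambda, grad, beta_vec)
      kkt <- max(slack)
      if (kkt <= 1e-10) break
      A <- which(lambda != 0)
      worst_inactive <- which.max(slack * (lambda == 0))
      if (length(A) == 0L || (lambda[worst_inactive] == 0 &&
                              slack[worst_inactive] > max(slack[A], 0))) {
        # bring the worst violating zero coordinate in via one prox step
        j <- worst_inactive
        if (slack[j] <= kkt_tol) break
        varq <- sum(pl$q * bgX[, j]^2) - pl$Eq[j]^2
        step <- 1 / max(varq, 1e-8)
        lambda[j] <- soft_threshold(-grad[j] * step, beta_vec[j] * step)
        if (lambda[j] == 0) break
        next
      }
      if (length(A) > 400L) break
      sA <- sign(lambda[A])
      gA <- grad[A] + sA * beta_vec[A]
      if (max(abs(gA)) <= 1e-11 && max(slack[-A], 0) <= kkt_tol) break
      XA <- bgX[, A, drop = FALSE]
      qX <- XA * pl$q
      H <- crossprod(XA, qX) - tcrossprod(pl$Eq[A])
      diag(H) <- diag(H) + 1e-11
      delta <- tryCatch(solve(H, -gA), error = function(e) NULL)
      if (is.null(delta)) break
      # truncate at the first sign flip; flipped coordinate leaves the set
      alpha <- 1
      cross <- which(delta != 0 & sA * (lambda[A] + delta) < 0)
      if (length(cross) > 0L) {
        steps <- -lambda[A][cross] / delta[cross]
        alpha <- max(min(steps), 0)
      }
      J_cur <- J_of(lambda, pl$f)
      ok <- FALSE
      for (ls in seq_len(25L)) {
        cand <- lambda
        cand[A] <- lambda[A] + alpha * delta
        cand[A][sA * cand[A] < 0] <- 0
        if (J_of(cand) <= J_cur + 1e-14) {
          lambda <- cand
          ok <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!ok) break
    }
    pl <- maxent_obj_parts(lambda, bgX, Ep)
    kkt <- max(kkt_slack(lambda, pl$Eq - Ep, beta_vec))
    lambda_full[use] <- lambda
    objective <- pl$f + sum(beta_vec * abs(lambda))
    logZ <- pl$logZ
    q <- pl$q
  } else {
    iters <- 0L
    kkt <- 0
    at_bound <- FALSE
    objective <- log(nrow(background_X))
    logZ <- log(nrow(background_X))
    q <- rep(1 / nrow(background_X), nrow(background_X))
    beta_vec <- numeric(0)
  }
  eta_bg <- drop(background_X %*% lambda_full)
  H <- logZ - sum(q * eta_bg)
  beta_full <- stats::setNames(rep(0, p_all), colnames(background_X))
  beta_full[use] <- if (any(use)) beta_multiplier * s_all[use] / sqrt(n_pres) else numeric(0)
  structure(list(
    lambda = lambda_full,
    beta_multiplier = beta_multiplier,
    beta_vec = beta_full,
    feature_sd = s_all,
    excluded_features = colnames(background_X)[!use],
    infeasible_features = colnames(background_X)[s_all > 1e-12 & !feasible],
    log_normalizer = logZ,
    entropy_H = H,
    n_presence = n_pres,
    n_background = nrow(background_X),
    output_transform = transform,
    objective = objective,
    iterations = iters,
    kkt = kkt,
    certified = kkt <= 1e-4,
    at_bound = at_bound,
    feature_set = NULL,
    species_id = NULL
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("MaxEnt model%s: %d features (%d nonzero), beta = %g\n",
                     "  n_presence = %d, n_background = %d\n",
                     "  logZ = %.4f, H = %.4f, KKT slack = %.2e\n"),
              if (is.null(x$species_id)) "" else paste0(" [", x$species_id, "]"),
              length(x$lambda), sum(x$lambda != 0), x$beta_multiplier,
              x$n_presence, x$n_background, x$log_normalizer, x$entropy_H,
              x$kkt))
  invisible(x)
}

#' Predict from a fitted MaxEnt model on a feature matrix
#'
#' `raw` values are the Gibbs density `exp(lambda . f - log Z)` (they sum to
#' one over the fitted background).  The `logistic` transform is
#' `e^H r / (1 + e^H r)` and `cloglog` is `1 - exp(-e^H r)`, with `H` the
#' entropy of the raw background distribution; both are monotone in the raw
#' value and lie in (0, 1).
#'
#' @param model a `maxent_model`.
#' @param X feature matrix with the model's columns.
#' @param transform `"raw"`, `"logistic"` or `"cloglog"` (default: the
#'   model's configured transform).
#' @return numeric vector of predictions.
#' @export
predict_maxent <- function(model, X, transform = NULL) {
  transform <- transform %||% model$output_transform
  lp <- drop(as.matrix(X) %*% model$lambda) - model$log_normalizer
  switch(transform,
    raw = exp(lp),
    logistic = stats::plogis(model$entropy_H + lp),
    cloglog = -expm1(-exp(model$entropy_H + lp)),
    stop("unknown transform: ", transform)
  )
}

#' Fit a species distribution model from a covariate table
#'
#' Convenience wrapper binding feature expansion to the fit: expands
#' features over the background sample, builds the presence and background
#' design matrices, and fits.  The returned model carries its feature set,
#' so [predict()] works directly from a covariate table.
#'
#' @param covariates a [covariate_table()].
#' @param presence_ids presence catchment ids.
#' @param background_ids background catchment ids.
#' @param beta_multiplier regularization multiplier.
#' @param classes feature classes, as in [expand_features()].
#' @param n_knots hinge/threshold knots per covariate.
#' @param vars covariate columns to use.
#' @param transform default output transform.
#' @param ... passed to [fit_maxent()].
#' @return a `maxent_model` with an embedded `feature_set`.
#' @export
fit_species_sdm <- function(covariates, presence_ids, background_ids,
                            beta_multiplier = 1,
                            classes = c("linear", "quadratic", "product",
                                        "hinge", "threshold", "categorical"),
                            n_knots = 10L, vars = NULL,
                            transform = "logistic", ...) {
  fs <- expand_features(covariates, background_ids, classes = classes,
                        n_knots = n_knots, vars = vars)
  bgX <- feature_matrix(fs, covariates, background_ids)
  prX <- feature_matrix(fs, covariates, presence_ids)
  model <- fit_maxent(prX, bgX, beta_multiplier, transform = transform, ...)
  model$feature_set <- fs
  model
}

#' @export
predict.maxent_model <- function(object, covariates, ids = NULL,
                                 transform = NULL, ...) {
  if (is.null(object$feature_set)) {
    stop("model has no feature set; use predict_maxent() on a feature matrix")
  }
  if (is.null(ids)) ids <- covariates$catchment_id
  X <- feature_matrix(object$feature_set, covariates, ids, clamp = TRUE)
  stats::setNames(predict_maxent(object, X, transform), ids)
}

#' Tune the regularization multiplier over a grid
#'
#' Fits the model at every multiplier in the grid (descending, with warm
#' starts along the path) and scores each fit by training AUC of presences
#' against background, mirroring the single-dataset selection procedure.
#' The chosen multiplier attains the maximum AUC, with ties broken toward
#' the smallest value.  A failed fit is recorded and its grid value skipped;
#' if every fit fails, an error is raised.
#'
#' @param presence_X,background_X feature matrices.
#' @param grid multiplier grid (default `1:15`).
#' @param transform transform stored on the refitted chosen model.
#' @param ... passed to [fit_maxent()].
#' @return a `tuning_result`: `grid`, `auc_per_beta`, `chosen_beta`,
#'   `model` (the fit at the chosen multiplier), `failed` (grid values whose
#'   fit failed).
#' @export
tune_beta <- function(presence_X, background_X, grid = 1:15,
                      transform = "logistic", ...) {
  if (length(grid) == 0L) stop("empty grid")
  ord <- order(grid, decreasing = TRUE)
  aucs <- stats::setNames(rep(NA_real_, length(grid)), grid)
  models <- vector("list", length(grid))
  warm <- NULL
  failed <- numeric(0)
  for (i in ord) {
    b <- grid[i]
    m <- tryCatch(
      fit_maxent(presence_X, background_X, b, lambda_init = warm,
                 transform = transform, ...),
      error = function(e) e
    )
    if (inherits(m, "error")) {
      failed <- c(failed, b)
      next
    }
    warm <- m$lambda
    models[[i]] <- m
    aucs[i] <- auc(predict_maxent(m, presence_X, "raw"),
                   predict_maxent(m, background_X, "raw"))
  }
  if (all(is.na(aucs))) stop("all fits failed during beta tuning")
  best <- max(aucs, na.rm = TRUE)
  chosen_i <- which(!is.na(aucs) & aucs >= best - 1e-12)
  chosen_i <- chosen_i[which.min(grid[chosen_i])]
  structure(list(grid = grid, auc_per_beta = aucs,
                 chosen_beta = grid[chosen_i], model = models[[chosen_i]],
                 failed = failed),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Beta tuning over {%s}: chosen %g (AUC = %.4f)\n",
              paste(x$grid, collapse = ","), x$chosen_beta,
              x$auc_per_beta[as.character(x$chosen_beta)]))
  invisible(x)
}

#' Per-catchment k-fold variability of predictions
#'
#' Partitions the presences into k folds, refits on each set of k-1 folds
#' with the background held fixed, and returns the per-catchment standard
#' deviation of the k logistic predictions — a map of model sensitivity to
#' the presence sample.
#'
#' @param presence_X,background_X feature matrices used for fitting.
#' @param target_X feature matrix of the catchments to map.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param beta_multiplier regularization multiplier.
#' @param lambda_init optional warm start (e.g., the full-data fit).
#' @param transform transform whose predictions are summarized.
#' @param ... passed to [fit_maxent()].
#' @return numeric vector: SD over folds for each row of `target_X`.
#' @export
kfold_sd <- function(presence_X, background_X, target_X, k = 10L, seed = 1L,
                     beta_multiplier = 1, lambda_init = NULL,
                     transform = "logistic", ...) {
  n <- nrow(presence_X)
  if (n < k) stop("fewer presences (", n, ") than folds (", k,
                  "); use a smaller k")
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  preds <- matrix(NA_real_, nrow(target_X), k)
  for (fold in seq_len(k)) {
    m <- fit_maxent(presence_X[folds != fold, , drop = FALSE], background_X,
                    beta_multiplier, lambda_init = lambda_init,
                    transform = transform, ...)
    preds[, fold] <- predict_maxent(m, target_X, transform)
  }
  apply(preds, 1L, stats::sd)
}
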