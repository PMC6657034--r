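# Offset-aware high-dimensional selectors: L1-penalised Cox regression
# (coordinate descent, 10-fold CV deviance tuning) and componentwise
# likelihood boosting (25-resample bootstrap stopping). Both treat the
# frozen clinical linear predictor as a fixed offset, so the clinical
# coefficients are never re-estimated.

#' Selector configuration
#'
#' @param method `"lasso"` or `"boosting"`.
#' @param cv_folds Cross-validation folds for the LASSO penalty (default 10).
#' @param n_bootstrap Bootstrap resamples for the boosting stopping
#'   iteration (default 25).
#' @param step_size Boosting learning rate `nu` in `(0, 1]` (default 0.1).
#' @param mstop_max Maximum boosting iterations scanned (default 100).
#' @param lambda_grid_size,lambda_min_ratio Penalty grid: `lambda_max` down
#'   to `lambda_min_ratio * lambda_max`, log-spaced, of this length
#'   (defaults 100 and 0.01).
#' @param standardize Standardize features within the fitting sample
#'   (default `TRUE`; coefficients are always returned on the original
#'   feature scale).
#' @return A `selector_config` list.
#' @export
selector_config <- function(method = c("lasso", "boosting"), cv_folds = 10L,
                            n_bootstrap = 25L, step_size = 0.1,
                            mstop_max = 100L, lambda_grid_size = 100L,
                            lambda_min_ratio = 0.01, standardize = TRUE) {
  method <- match.arg(method)
  stopifnot(cv_folds >= 2L, n_bootstrap >= 1L, step_size > 0, step_size <= 1,
            mstop_max >= 0L, lambda_grid_size >= 1L,
            lambda_min_ratio > 0, lambda_min_ratio <= 1)
  structure(
    list(method = method, cv_folds = as.integer(cv_folds),
         n_bootstrap = as.integer(n_bootstrap), step_size = step_size,
         mstop_max = as.integer(mstop_max),
         lambda_grid_size = as.integer(lambda_grid_size),
         lambda_min_ratio = lambda_min_ratio, standardize = standardize),
    class = "selector_config"
  )
}

# Center/scale columns with the 1/n variance convention; zero-variance
# columns get scale 1 (they can never be selected).
standardize_cols <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(X^2) - ctr^2)
  sc[sc < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, sc, "/")
  list(X = Xs, center = ctr, scale = sc)
}

prep_sorted <- function(time, event) {
  rs <- cox_riskset(time, event)
  list(rs = rs,
       grp0 = as.integer(rs$grp - 1L),
       first0 = as.integer(rs$first - 1L),
       d = as.numeric(rs$d))
}

#' Largest penalty with an all-zero solution
#'
#' `lambda_max` is the maximum absolute per-observation score component of
#' the offset model at `beta = 0` over the standardized features; at or
#' above it the L1 penalty dominates and the combined model collapses to
#' the clinical model.
#'
#' @param X Omics matrix (patients x features).
#' @param time,event Survival outcome.
#' @param offset Fixed clinical linear predictor (default 0).
#' @param standardize Standardize features first (default `TRUE`).
#' @return A single positive number.
#' @export
lasso_lambda_max <- function(X, time, event, offset = 0, standardize = TRUE) {
  n <- nrow(X)
  if (length(offset) == 1L) offset <- rep(offset, n)
  Xs <- if (standardize) standardize_cols(X)$X else X
  rs <- cox_riskset(time, event)
  u <- numeric(n)
  u[rs$ord] <- cox_ll_parts(offset[rs$ord], rs)$u
  # nudged up a hair so the all-zero solution is exact at lambda_max
  max(abs(crossprod(Xs, u))) / n * (1 + 1e-9)
}

lasso_default_grid <- function(lambda_max, config) {
  exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
          length.out = config$lambda_grid_size))
}

#' Offset Cox LASSO coefficient path
#'
#' Maximises `(1/n) pl(offset + X beta) - lambda * sum(|beta_j|)` along a
#' descending penalty grid by cyclic coordinate descent on the iteratively
#' reweighted quadratic approximation, warm-started from the previous
#' grid point. Coefficients are returned on the original feature scale.
#'
#' @inheritParams lasso_lambda_max
#' @param lambdas Descending penalty grid.
#' @param thresh Coordinate-descent convergence threshold.
#' @return A `cox_lasso_path`: list with `lambdas`, `beta` (features x
#'   grid, original scale), `n_selected` per grid point and the attained
#'   partial log-likelihoods.
#' @export
lasso_path_offset <- function(X, time, event, offset = 0, lambdas,
                              standardize = TRUE, thresh = 1e-7) {
  n <- nrow(X)
  if (length(offset) == 1L) offset <- rep(offset, n)
  stopifnot(length(offset) == n)
  if (is.unsorted(rev(lambdas), strictly = FALSE)) {
    stop("penalty grid must be descending", call. = FALSE)
  }
  std <- if (standardize) standardize_cols(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  sp <- prep_sorted(time, event)
  ord <- sp$rs$ord
  res <- cox_lasso_path_cpp(
    std$X[ord, , drop = FALSE], as.integer(event[ord]),
    sp$grp0, sp$first0, sp$d, offset[ord], as.numeric(lambdas),
    thresh = thresh
  )
  if (any(res$flagged)) {
    warning("coefficients hit the monotone-likelihood guard for ",
            sum(res$flagged), " penalty value(s)", call. = FALSE)
  }
  beta <- res$beta / std$scale   # back to original scale
  rownames(beta) <- colnames(X) %||% paste0("g", seq_len(ncol(X)))
  structure(
    list(lambdas = as.numeric(lambdas), beta = beta,
         n_selected = colSums(beta != 0), loglik = as.numeric(res$loglik),
         path_stop = res$path_stop, standardize = standardize),
    class = "cox_lasso_path"
  )
}

# Event-stratified fold assignment; refolds (bounded) if a training
# complement ends up without events.
stratified_folds <- function(event, k, seed) {
  assign_once <- function() {
    fold <- integer(length(event))
    for (s in c(0L, 1L)) {
      ix <- which(event == s)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    fold
  }
  withr::with_seed(seed, {
    for (try in 1:10) {
      fold <- assign_once()
      ok <- vapply(seq_len(k), function(f) sum(event[fold != f]) >= 1, logical(1))
      if (all(ok)) return(fold)
      warning("refolding: a fold's training complement had no events", call. = FALSE)
    }
    stop("could not build cross-validation folds with events in every training part",
         call. = FALSE)
  })
}

#' Choose the LASSO penalty by cross-validated partial-likelihood deviance
#'
#' Folds are event-stratified. For each fold the path is fitted on the
#' complement and the held-out deviance contribution is
#' `-2 * (pl_all(beta) - pl_train(beta))` (the "verum" decomposition),
#' both evaluated with the offset in place. The grid value minimising the
#' mean contribution is returned; ties go to the larger penalty (the
#' sparser model).
#'
#' @inheritParams lasso_path_offset
#' @param config A [selector_config()] (grid size/ratio, folds).
#' @param seed Integer seed for the fold assignment.
#' @return A list: chosen `lambda`, the `grid`, mean deviance `cvm`, and
#'   the full-data `path`.
#' @export
cv_lambda <- function(X, time, event, offset = 0, config = selector_config("lasso"),
                      seed = 1L) {
  n <- nrow(X)
  stopifnot(n >= config$cv_folds)
  if (length(offset) == 1L) offset <- rep(offset, n)
  lmax <- lasso_lambda_max(X, time, event, offset, config$standardize)
  grid <- lasso_default_grid(lmax, config)
  fold <- stratified_folds(event, config$cv_folds, seed)
  dev <- matrix(NA_real_, config$cv_folds, length(grid))
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    path_f <- lasso_path_offset(X[tr, , drop = FALSE], time[tr], event[tr],
                                offset[tr], grid, config$standardize)
    for (l in seq_along(grid)) {
      b <- path_f$beta[, l]
      nz <- which(b != 0)
      eta_all <- offset + if (length(nz)) drop(X[, nz, drop = FALSE] %*% b[nz]) else 0
      ll_all <- cox_partial_loglik(eta_all, time, event)
      ll_tr <- cox_partial_loglik(eta_all[tr], time[tr], event[tr])
      dev[f, l] <- -2 * (ll_all - ll_tr)
      if (l >= path_f$path_stop && l < length(grid)) {
        dev[f, (l + 1):length(grid)] <- dev[f, l]  # early-terminated tail
        break
      }
    }
  }
  cvm <- colMeans(dev)
  path <- lasso_path_offset(X, time, event, offset, grid, config$standardize)
  best <- which.min(cvm[seq_len(path$path_stop)])  # first index = largest lambda on ties
  list(lambda = grid[best], index = best, grid = grid, cvm = cvm, path = path)
}

#' Componentwise likelihood boosting from a clinical offset
#'
#' Gradient boosting on the Breslow partial log-likelihood with
#' single-feature least-squares base-learners: the fit is initialised at
#' the offset, each iteration fits every feature to the negative gradient,
#' updates only the best-fitting one by `nu` times its least-squares
#' slope, and early stopping yields selection and shrinkage. Base-learner
#' ties break to the lowest column index.
#'
#' @inheritParams lasso_path_offset
#' @param config A [selector_config()] (`step_size`, `mstop_max`,
#'   `standardize`).
#' @param mstop Number of iterations; defaults to `config$mstop_max`.
#' @return A `cox_boost_path`: per-iteration selected feature and slope,
#'   the training log-likelihood path, and `beta_at(m)` support via
#'   [boost_coef()].
#' @export
boost_offset <- function(X, time, event, offset = 0,
                         config = selector_config("boosting"),
                         mstop = config$mstop_max) {
  if (mstop < 0) stop("mstop must be non-negative", call. = FALSE)
  n <- nrow(X)
  if (length(offset) == 1L) offset <- rep(offset, n)
  std <- if (config$standardize) standardize_cols(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  sp <- prep_sorted(time, event)
  ord <- sp$rs$ord
  res <- cox_boost_path_cpp(std$X[ord, , drop = FALSE],
                            as.integer(event[ord]), sp$grp0, sp$first0,
                            sp$d, offset[ord], config$step_size,
                            as.integer(mstop))
  structure(
    list(selected = as.integer(res$selected), slope = as.numeric(res$slope),
         loglik = as.numeric(res$loglik), mstop = mstop,
         scale = std$scale, feature_names = colnames(X) %||%
           paste0("g", seq_len(ncol(X))), p = ncol(X)),
    class = "cox_boost_path"
  )
}

#' Coefficients of a boosting path at iteration m
#' @param path A `cox_boost_path`.
#' @param m Iteration in `0..mstop`.
#' @return Named coefficient vector on the original feature scale.
#' @export
boost_coef <- function(path, m = path$mstop) {
  stopifnot(m >= 0, m <= path$mstop)
  beta <- numeric(path$p)
  if (m > 0) {
    for (k in seq_len(m)) beta[path$selected[k]] <- beta[path$selected[k]] + path$slope[k]
  }
  setNames(beta / path$scale, path$feature_names)
}

#' Choose the boosting stopping iteration by bootstrap out-of-bag risk
#'
#' Draws `n_bootstrap` bootstrap resamples of the fitting data, fits the
#' boosting path to each (standardizing within the resample), and
#' evaluates the out-of-bag negative partial log-likelihood at every
#' iteration. Returns the iteration minimising the mean out-of-bag risk
#' (ties to the smaller, sparser, iteration). Resamples whose out-of-bag
#' part has no events are redrawn (bounded retries).
#'
#' @inheritParams boost_offset
#' @param seed Integer seed for the resampling.
#' @return A list: chosen `mstop` and the mean out-of-bag `risk` curve
#'   (index 1 = iteration 0).
#' @export
bootstrap_mstop <- function(X, time, event, offset = 0,
                            config = selector_config("boosting"), seed = 1L) {
  n <- nrow(X)
  if (length(offset) == 1L) offset <- rep(offset, n)
  M <- config$mstop_max
  risks <- matrix(NA_real_, config$n_bootstrap, M + 1L)
  withr::with_seed(seed, {
    for (b in seq_len(config$n_bootstrap)) {
      oob <- integer(0)
      for (try in 1:20) {
        bag <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(bag))
        if (length(oob) >= 2L && sum(event[oob]) >= 1L) break
        oob <- integer(0)
      }
      if (!length(oob)) {
        warning("bootstrap resample without out-of-bag events skipped", call. = FALSE)
        next
      }
      Xb <- X[bag, , drop = FALSE]
      std <- if (config$standardize) standardize_cols(Xb) else
        list(X = Xb, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
      path <- boost_offset(std$X, time[bag], event[bag], offset[bag],
                           config = selector_config(
                             "boosting", step_size = config$step_size,
                             mstop_max = M, standardize = FALSE),
                           mstop = M)
      # follow the out-of-bag linear predictor along the path incrementally
      Xo <- sweep(sweep(X[oob, , drop = FALSE], 2L, std$center), 2L, std$scale, "/")
      f_oob <- offset[oob]
      rs_oob <- cox_riskset(time[oob], event[oob])
      risks[b, 1L] <- -cox_ll_parts(f_oob[rs_oob$ord], rs_oob)$loglik / length(oob)
      for (m in seq_len(M)) {
        f_oob <- f_oob + path$slope[m] * Xo[, path$selected[m]]
        risks[b, m + 1L] <- -cox_ll_parts(f_oob[rs_oob$ord], rs_oob)$loglik / length(oob)
      }
    }
  })
  if (all(is.na(risks))) stop("no usable bootstrap resample", call. = FALSE)
  risk <- colMeans(risks, na.rm = TRUE)
  list(mstop = which.min(risk) - 1L, risk = risk)
}
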