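# Cox partial-likelihood machinery: Breslow-ties log-likelihood, Newton
# fitting with a fixed offset, Breslow baseline hazard, survival prediction,
# and the product-limit (Kaplan-Meier) estimator.

# Risk-set bookkeeping shared by the likelihood, the fitters and the
# selectors. Observations are sorted by follow-up time; tied times form
# groups that share one risk set.
cox_riskset <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("follow-up times must be finite and non-negative", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  ord <- order(time)
  ts <- time[ord]
  ev <- as.integer(event[ord])
  grp <- cumsum(c(TRUE, diff(ts) > 0))      # tie-group id per sorted obs
  first <- which(!duplicated(grp))          # first sorted index of each group
  d <- as.integer(rowsum(ev, grp)[, 1L])    # events per group
  list(
    n = length(ts), ord = ord, time = ts, event = ev,
    grp = grp, first = first, d = d, n_groups = length(first)
  )
}

# Per-observation log-likelihood pieces at a linear predictor eta (already
# in sorted order). Returns loglik, per-obs score u = dl/deta and the
# diagonal Hessian approximation w used by the IRLS-based selectors, plus
# the cumulative baseline hazard at each observation's time.
cox_ll_parts <- function(eta_sorted, rs) {
  eta <- eta_sorted - mean(eta_sorted)      # shift-invariant; guards exp()
  ee <- exp(eta)
  # risk-set sum S0 for each tie group = reverse cumsum taken at group start
  revcs <- rev(cumsum(rev(ee)))
  S0 <- revcs[rs$first]
  h <- rs$d / S0                            # Breslow hazard increments
  h2 <- rs$d / S0^2
  A_grp <- cumsum(h)                        # cumulative hazard up to group g
  B_grp <- cumsum(h2)
  A <- A_grp[rs$grp]                        # per-obs (obs is in risk set of its own time)
  B <- B_grp[rs$grp]
  ll <- sum(eta[rs$event == 1L]) - sum(rs$d[rs$d > 0] * log(S0[rs$d > 0]))
  u <- rs$event - ee * A
  w <- pmax(ee * A - ee^2 * B, 0)
  list(loglik = ll, u = u, w = w, cumhaz = A, ee = ee, S0 = S0)
}

#' Cox partial log-likelihood (Breslow ties)
#'
#' Evaluates the partial log-likelihood of a fixed linear predictor under
#' the Cox model, with tied event times handled by the Breslow
#' approximation: tied events share a single risk-set denominator.
#'
#' @param eta Numeric linear predictor, one value per patient.
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = event).
#' @return A single number, invariant to adding a constant to `eta`.
#' @examples
#' cox_partial_loglik(c(0, 0, 0), time = c(1, 2, 3), event = c(1, 1, 1))
#' @export
cox_partial_loglik <- function(eta, time, event) {
  if (sum(event) == 0) stop("partial likelihood needs at least one event", call. = FALSE)
  if (length(eta) == 1L) eta <- rep(eta, length(time))
  stopifnot(length(eta) == length(time))
  rs <- cox_riskset(time, event)
  cox_ll_parts(eta[rs$ord], rs)$loglik
}

# Full score vector and observed information for design X (sorted order).
cox_score_info <- function(X_sorted, eta_sorted, rs) {
  eta <- eta_sorted - mean(eta_sorted)
  ee <- exp(eta)
  q <- ncol(X_sorted)
  revS0 <- rev(cumsum(rev(ee)))
  S0 <- revS0[rs$first]
  eX <- X_sorted * ee
  S1 <- apply(eX, 2L, function(col) rev(cumsum(rev(col))))[rs$first, , drop = FALSE]
  # S2 over the upper triangle of x x'
  idx <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  S2flat <- vapply(seq_len(nrow(idx)), function(k) {
    col <- X_sorted[, idx[k, 1L]] * X_sorted[, idx[k, 2L]] * ee
    rev(cumsum(rev(col)))[rs$first]
  }, numeric(rs$n_groups))
  if (rs$n_groups == 1L) S2flat <- matrix(S2flat, nrow = 1L)
  ev_grp <- rs$d > 0
  xbar <- S1 / S0
  # score: sum over events of (x_i - xbar(t_i))
  Ux <- colSums(X_sorted[rs$event == 1L, , drop = FALSE])
  U <- Ux - colSums(xbar[ev_grp, , drop = FALSE] * rs$d[ev_grp])
  # information
  info <- matrix(0, q, q)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    val <- sum(rs$d[ev_grp] * (S2flat[ev_grp, k] / S0[ev_grp] -
                                 xbar[ev_grp, i] * xbar[ev_grp, j]))
    info[i, j] <- val; info[j, i] <- val
  }
  list(U = U, info = info, S0 = S0)
}

#' Fit a Cox model by Newton-Raphson with an optional fixed offset
#'
#' Maximises the Breslow partial log-likelihood of
#' `offset + design %*% gamma` over `gamma`, keeping `offset` fixed. The
#' offset is how a frozen clinical linear predictor enters omics selection
#' without its coefficients being re-estimated.
#'
#' @param design Numeric matrix, patients x covariates (no intercept; the
#'   partial likelihood is invariant to one).
#' @param time,event Survival outcome.
#' @param offset Fixed per-patient linear predictor added to the model
#'   (default 0).
#' @param max_iter,tol_score,tol_loglik Newton controls: at most
#'   `max_iter` iterations with up to 20 step-halvings; convergence when
#'   the largest score component falls below `tol_score` or the relative
#'   log-likelihood change below `tol_loglik`.
#' @return A `fitted_cox` object: coefficients, Breslow baseline cumulative
#'   hazard, and fitting metadata. Coefficients whose standardized
#'   magnitude exceeds 50 trigger a monotone-likelihood (separation)
#'   warning.
#' @seealso [breslow_cumhaz()], [predict_survival()], [fit_km_null()]
#' @export
fit_cox <- function(design, time, event, offset = 0,
                    max_iter = 100L, tol_score = 1e-8, tol_loglik = 1e-10) {
  X <- as.matrix(design)
  n <- length(time)
  stopifnot(nrow(X) == n)
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  if (length(offset) == 1L) offset <- rep(offset, n)
  q <- ncol(X)
  if (q == 0L) stop("design has no columns; use fit_km_null() for the null model", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("design contains a constant column (not identifiable in a Cox model): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  Xc <- sweep(X, 2L, colMeans(X))
  if (qr(Xc)$rank < q) stop("design is rank deficient (collinear columns)", call. = FALSE)

  rs <- cox_riskset(time, event)
  Xs <- X[rs$ord, , drop = FALSE]
  os <- offset[rs$ord]
  gamma <- rep(0, q)
  ll <- cox_ll_parts(os, rs)$loglik
  converged <- FALSE
  iter <- 0L
  max_score <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- os + drop(Xs %*% gamma)
    si <- cox_score_info(Xs, eta, rs)
    max_score <- max(abs(si$U))
    if (max_score < tol_score) { converged <- TRUE; break }
    step <- tryCatch(solve(si$info, si$U), error = function(e) {
      solve(si$info + diag(1e-8, q), si$U)
    })
    # step-halving: require the likelihood not to decrease
    ok <- FALSE
    for (h in 0:20) {
      cand <- gamma + step / 2^h
      ll_new <- cox_ll_parts(os + drop(Xs %*% cand), rs)$loglik
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    gamma <- cand
    ll <- ll_new
    if (rel_change < tol_loglik) { converged <- TRUE; break }
  }
  names(gamma) <- colnames(X) %||% paste0("x", seq_len(q))
  gamma_std <- gamma * sds
  separation <- any(abs(gamma_std) > 50)
  if (separation) {
    warning("possible monotone likelihood (separation): |standardized coefficient| > 50",
            call. = FALSE)
  }
  eta_hat <- offset + drop(X %*% gamma)
  bh <- breslow_cumhaz(time, event, eta_hat)
  structure(
    list(
      kind = "cox",
      coefficients = gamma,
      baseline = bh,
      train = list(time = time, event = event, eta = eta_hat, offset = offset),
      meta = list(n = n, n_events = sum(event), loglik = ll, iter = iter,
                  converged = converged, max_score = max_score,
                  separation = separation)
    ),
    class = "fitted_cox"
  )
}

#' Kaplan-Meier null model as a Cox-model stand-in
#'
#' The no-covariate reference model: every patient is assigned the
#' training-data product-limit survival curve and a constant risk score.
#'
#' @inheritParams fit_cox
#' @return A `fitted_cox` object of kind `"kaplan_meier_null"` with an
#'   empty coefficient vector.
#' @export
fit_km_null <- function(time, event) {
  km <- kaplan_meier(time, event)
  structure(
    list(
      kind = "kaplan_meier_null",
      coefficients = setNames(numeric(0), character(0)),
      km = km,
      train = list(time = time, event = event,
                   eta = rep(0, length(time)), offset = rep(0, length(time))),
      meta = list(n = length(time), n_events = sum(event), loglik = NA_real_,
                  iter = 0L, converged = TRUE, separation = FALSE)
    ),
    class = "fitted_cox"
  )
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' \deqn{\hat\Lambda_0(t) = \sum_{t_i \le t} d_i / \sum_{j: t_j \ge t_i} e^{\eta_j}}
#' with \eqn{d_i} the number of tied events at event time \eqn{t_i}.
#'
#' @param time,event Training survival outcome.
#' @param eta Fitted linear predictor on the training patients.
#' @return A `breslow_cumhaz` step function object; evaluate it with
#'   [cumhaz_at()]. Starts at 0 and is nondecreasing.
#' @export
breslow_cumhaz <- function(time, event, eta = 0) {
  if (length(eta) == 1L) eta <- rep(eta, length(time))
  rs <- cox_riskset(time, event)
  parts <- cox_ll_parts(eta[rs$ord], rs)
  # note cox_ll_parts centers eta; undo so hazard is on the eta scale given
  shift <- mean(eta)
  ev_grp <- rs$d > 0
  t_ev <- rs$time[rs$first][ev_grp]
  jumps <- (rs$d[ev_grp] / parts$S0[ev_grp]) * exp(-shift)
  structure(list(time = t_ev, cumhaz = cumsum(jumps)), class = "breslow_cumhaz")
}

#' Evaluate a cumulative-hazard step function
#' @param bh A `breslow_cumhaz` object.
#' @param t Times (non-negative).
#' @return Cumulative hazard at each `t`.
#' @export
cumhaz_at <- function(bh, t) {
  if (any(t < 0)) stop("negative evaluation time", call. = FALSE)
  if (length(bh$time) == 0L) return(rep(0, length(t)))
  idx <- findInterval(t, bh$time)
  c(0, bh$cumhaz)[idx + 1L]
}

#' Product-limit (Kaplan-Meier) survival estimator
#'
#' Also used, on the flipped event indicator, as the censoring-distribution
#' estimate \eqn{\hat G} for the IPCW evaluation measures.
#'
#' @param time,event Survival outcome.
#' @return A `km_curve` object; evaluate with [km_survival()].
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  rs <- cox_riskset(time, event)
  ut <- rs$time[rs$first]
  n_at_risk <- rs$n - rs$first + 1L
  d <- rs$d
  surv <- cumprod(1 - d / n_at_risk)
  structure(list(time = ut, n_risk = n_at_risk, n_event = d, surv = surv),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#' @param km A `km_curve`.
#' @param t Times.
#' @param left If `TRUE`, return the left limit \eqn{S(t-)} (the value just
#'   before `t`), as needed for IPCW weights at event times.
#' @return Survival probabilities.
#' @export
km_survival <- function(km, t, left = FALSE) {
  if (left) {
    idx <- findInterval(t, km$time, left.open = TRUE)
  } else {
    idx <- findInterval(t, km$time)
  }
  c(1, km$surv)[idx + 1L]
}

#' Predicted survival probabilities from a fitted model
#'
#' For a Cox fit, \eqn{S(t \mid x) = \exp(-\hat\Lambda_0(t) e^{\eta(x)})};
#' for the Kaplan-Meier null model every patient receives the training
#' curve. Rows are patients, columns the requested times; each row starts
#' at 1 for `t = 0` and is nonincreasing.
#'
#' @param object A `fitted_cox`.
#' @param X Covariate matrix matching the model's coefficients (ignored for
#'   the null kind; pass `NULL`).
#' @param times Non-negative evaluation times.
#' @param offset Optional fixed offset for the new patients (default 0).
#' @return Matrix of survival probabilities, patients x times.
#' @export
predict_survival <- function(object, X, times, offset = 0) {
  stopifnot(inherits(object, "fitted_cox"))
  if (any(times < 0)) stop("negative evaluation time", call. = FALSE)
  if (object$kind == "kaplan_meier_null") {
    n <- if (is.null(X)) 1L else nrow(X)
    s <- km_survival(object$km, times)
    return(matrix(rep(s, each = n), nrow = n))
  }
  eta <- predict_lp(object, X, offset = offset)
  H <- cumhaz_at(object$baseline, times)
  exp(-outer(exp(eta), H))
}

#' Linear predictor for new patients
#' @param object A `fitted_cox`.
#' @param X Covariate matrix (ignored for the null kind: returns 0s).
#' @param offset Optional fixed offset.
#' @return Numeric vector of linear predictors.
#' @export
predict_lp <- function(object, X, offset = 0) {
  stopifnot(inherits(object, "fitted_cox"))
  if (object$kind == "kaplan_meier_null") {
    n <- if (is.null(X)) 1L else nrow(X)
    return(rep(0, n) + offset)
  }
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(object$coefficients))
  drop(X %*% object$coefficients) + offset
}

#' @export
print.fitted_cox <- function(x, ...) {
  if (x$kind == "kaplan_meier_null") {
    cat("<fitted_cox> Kaplan-Meier null model; n =", x$meta$n,
        "events =", x$meta$n_events, "\n")
  } else {
    cat("<fitted_cox> n =", x$meta$n, "events =", x$meta$n_events,
        "loglik =", format(x$meta$loglik), "\n")
    print(x$coefficients)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
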