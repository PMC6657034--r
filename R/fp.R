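# Degree-2 fractional polynomial (FP2) transformation and selection for
# the continuous age covariate, used at the richest clinical level.

#' The standard fractional-polynomial power set
#' @return `c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)`.
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' All FP2 candidate power pairs
#' @return A two-column matrix of the 36 ordered pairs `p1 <= p2` (8
#'   repeated + 28 distinct) from the standard power set.
#' @export
fp2_candidates <- function() {
  ps <- fp_power_set()
  pairs <- expand.grid(p1 = ps, p2 = ps)
  as.matrix(pairs[pairs$p1 <= pairs$p2, c("p1", "p2")])
}

#' Create an FP2 specification
#' @param powers Length-2 numeric, members of [fp_power_set()], `p1 <= p2`.
#' @param scale Positive pre-scaling applied to `x` before powering, so the
#'   transformed values are O(1).
#' @return An `fp_spec` object.
#' @export
fp_spec <- function(powers, scale = 1) {
  stopifnot(length(powers) == 2L, scale > 0,
            all(powers %in% fp_power_set()), powers[1] <= powers[2])
  structure(list(powers = as.numeric(powers), scale = scale), class = "fp_spec")
}

fp_term <- function(z, p) if (p == 0) log(z) else z^p

#' FP2 transformation of a positive covariate
#'
#' Columns are `(x/scale)^p1` and `(x/scale)^p2`, with the conventions
#' power 0 -> `ln(x/scale)` and a repeated power `p` ->
#' `((x/scale)^p, (x/scale)^p * ln(x/scale))`.
#'
#' @param x Positive numeric vector.
#' @param spec An [fp_spec()].
#' @return A two-column matrix.
#' @examples
#' fp_transform(10, fp_spec(c(-2, -2)))  # (0.01, 0.01 * log(10))
#' @export
fp_transform <- function(x, spec) {
  stopifnot(inherits(spec, "fp_spec"))
  if (any(x <= 0)) stop("fractional polynomials require positive x", call. = FALSE)
  z <- x / spec$scale
  p1 <- spec$powers[1]; p2 <- spec$powers[2]
  t1 <- fp_term(z, p1)
  t2 <- if (p1 == p2) fp_term(z, p2) * log(z) else fp_term(z, p2)
  out <- cbind(t1, t2)
  colnames(out) <- paste0("fp", 1:2)
  out
}

#' Default FP pre-scaling
#' @param x Positive covariate values.
#' @return `10^round(log10(median(x)))`, so transformed values are O(1).
#' @export
fp_default_scale <- function(x) 10^round(log10(stats::median(x)))

#' Select the best-fitting FP2 transformation by partial likelihood
#'
#' Fits, for each of the 36 FP2 candidates, a Cox model containing
#' `other_design` plus the two FP columns, and returns the candidate with
#' the largest partial log-likelihood. The FP2 term is always retained
#' (no significance testing against simpler functions): the covariate is
#' forced into the model and only its functional form is chosen.
#'
#' @param x Positive continuous covariate (e.g. age).
#' @param time,event Survival outcome.
#' @param other_design Optional matrix of covariates fitted alongside.
#' @param scale Pre-scaling; default [fp_default_scale()].
#' @return An `fp_spec` with attributes `loglik` (the winner's) and
#'   `candidates` (a tibble of all candidate fits).
#' @export
select_fp2 <- function(x, time, event, other_design = NULL,
                       scale = fp_default_scale(x)) {
  if (any(x <= 0)) stop("fractional polynomials require positive x", call. = FALSE)
  cands <- fp2_candidates()
  lls <- rep(NA_real_, nrow(cands))
  n_failed <- 0L
  for (k in seq_len(nrow(cands))) {
    sp <- fp_spec(cands[k, ], scale = scale)
    Z <- fp_transform(x, sp)
    design <- if (is.null(other_design)) Z else cbind(other_design, Z)
    fit <- tryCatch(
      suppressWarnings(fit_cox(design, time, event)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$meta$converged) { n_failed <- n_failed + 1L; next }
    lls[k] <- fit$meta$loglik
  }
  if (n_failed > 0L) {
    warning(n_failed, " FP2 candidate fit(s) failed to converge and were skipped",
            call. = FALSE)
  }
  if (all(is.na(lls))) stop("no FP2 candidate could be fitted", call. = FALSE)
  best <- which.max(lls)
  out <- fp_spec(cands[best, ], scale = scale)
  attr(out, "loglik") <- lls[best]
  attr(out, "candidates") <- tibble::tibble(
    p1 = cands[, 1], p2 = cands[, 2], loglik = lls
  )
  out
}

#' @export
print.fp_spec <- function(x, ...) {
  cat("<fp_spec> powers (", x$powers[1], ", ", x$powers[2], "), scale ",
      x$scale, "\n", sep = "")
  invisible(x)
}
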