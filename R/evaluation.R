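# Prediction-performance measures on independent data: the
# censoring-adjusted (IPCW) concordance index, the IPCW Brier score and its
# integrated version, and the added-value differences with the sign
# convention "positive = omics helped".

#' Censoring-adjusted (IPCW) concordance index
#'
#' Inverse-probability-of-censoring weighted concordance over usable pairs:
#' pair (i, j) is usable when `t_i < t_j`, `t_i <= tau` and patient i had
#' the event; it receives weight `1 / G(t_i-)^2` with `G` the
#' Kaplan-Meier estimate of the censoring distribution (flipped event
#' indicator). A pair is concordant when the earlier failure has the
#' higher risk; risk ties count 1/2. Without censoring this reduces to
#' Harrell's C. A constant risk vector (a model that cannot separate
#' patients) returns `constant_risk_value`.
#'
#' @param risk Predicted risk scores (higher = earlier failure expected).
#' @param time,event Validation survival outcome.
#' @param tau Evaluation horizon; default the largest event time.
#' @param censoring Optional `km_curve` of the censoring distribution;
#'   default estimated from `(time, 1 - event)`.
#' @param constant_risk_value Value returned for a constant risk vector
#'   (default 0.5, a random guess).
#' @return Concordance in `[0, 1]`.
#' @export
cindex_ipcw <- function(risk, time, event, tau = NULL, censoring = NULL,
                        constant_risk_value = 0.5) {
  stopifnot(length(risk) == length(time), all(is.finite(risk)))
  if (diff(range(risk)) == 0) return(constant_risk_value)
  if (is.null(censoring)) censoring <- kaplan_meier(time, 1 - event)
  if (is.null(tau)) {
    if (!any(event == 1)) stop("no events: concordance undefined", call. = FALSE)
    tau <- max(time[event == 1])
  }
  num <- 0
  den <- 0
  for (i in which(event == 1 & time <= tau)) {
    comp <- which(time > time[i])
    if (!length(comp)) next
    G <- km_survival(censoring, time[i], left = TRUE)
    wi <- 1 / max(G, 1e-6)^2
    conc <- sum(risk[comp] < risk[i]) + 0.5 * sum(risk[comp] == risk[i])
    num <- num + wi * conc
    den <- den + wi * length(comp)
  }
  if (den == 0) stop("no usable pairs for the concordance index", call. = FALSE)
  num / den
}

#' IPCW Brier score at a single time
#'
#' \deqn{BS(t) = \frac{1}{n}\sum_i
#'   \hat S(t|x_i)^2 \frac{1(t_i \le t, \delta_i = 1)}{\hat G(t_i-)} +
#'   (1 - \hat S(t|x_i))^2 \frac{1(t_i > t)}{\hat G(t)}}
#' Patients censored before `t` contribute 0. Without censoring
#' (`G` identically 1) this is the unweighted Brier score.
#'
#' @param t Evaluation time.
#' @param surv_prob Predicted survival probabilities at `t`, one per
#'   patient, in `[0, 1]`.
#' @param time,event Validation outcome.
#' @param censoring Optional censoring `km_curve` (default estimated from
#'   the validation data).
#' @return The Brier score at `t` (non-negative).
#' @export
brier_score <- function(t, surv_prob, time, event, censoring = NULL) {
  stopifnot(length(surv_prob) == length(time),
            all(surv_prob >= 0), all(surv_prob <= 1))
  if (is.null(censoring)) censoring <- kaplan_meier(time, 1 - event)
  had_event <- time <= t & event == 1
  still_at_risk <- time > t
  Gt <- km_survival(censoring, t)
  if (any(still_at_risk) && Gt < 1e-6) {
    stop("censoring survival ~ 0 at t = ", t, "; choose a smaller horizon",
         call. = FALSE)
  }
  contrib <- numeric(length(time))
  if (any(had_event)) {
    Gi <- km_survival(censoring, time[had_event], left = TRUE)
    contrib[had_event] <- surv_prob[had_event]^2 / pmax(Gi, 1e-6)
  }
  contrib[still_at_risk] <- (1 - surv_prob[still_at_risk])^2 / Gt
  mean(contrib)
}

#' Integrated Brier score
#'
#' Trapezoid integration of the Brier curve over `[0, tau]`, normalised by
#' `tau` so a constant curve integrates to itself.
#'
#' @param surv_matrix Predicted survival probabilities, patients x grid
#'   times (matching `grid`).
#' @param time,event Validation outcome.
#' @param grid Time grid; default 0 plus the unique validation event times
#'   up to `tau`.
#' @param tau Horizon; default the largest validation event time.
#' @param censoring Optional censoring `km_curve`.
#' @return A list: `ibs` and the Brier `curve` tibble.
#' @export
integrated_brier <- function(surv_matrix, time, event, grid = NULL,
                             tau = NULL, censoring = NULL) {
  if (is.null(censoring)) censoring <- kaplan_meier(time, 1 - event)
  if (is.null(tau)) {
    if (!any(event == 1)) stop("no events: horizon undefined", call. = FALSE)
    tau <- max(time[event == 1])
  }
  stopifnot(tau > 0)
  if (is.null(grid)) grid <- c(0, sort(unique(time[event == 1 & time <= tau])))
  if (!length(grid)) stop("empty integration grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing", call. = FALSE)
  surv_matrix <- as.matrix(surv_matrix)
  stopifnot(ncol(surv_matrix) == length(grid))
  bs <- vapply(seq_along(grid), function(k) {
    brier_score(grid[k], surv_matrix[, k], time, event, censoring)
  }, numeric(1))
  # integrate to tau (constant extension past the last grid point)
  gx <- c(grid, tau)
  gy <- c(bs, bs[length(bs)])
  ibs <- sum(diff(gx) * (head(gy, -1) + tail(gy, -1)) / 2) / tau
  list(ibs = ibs, curve = tibble::tibble(time = grid, brier = bs))
}

#' Added predictive value of the omics part
#'
#' Signed so that positive differences always indicate an added predictive
#' value of the omics data: for the C-index, combined minus clinical (a
#' higher C is better); for the IBS, clinical minus combined (a lower IBS
#' is better).
#'
#' @param clinical,combined One-row evaluation tibbles (or lists) with
#'   fields `level`, `cindex`, `ibs` for the purely clinical and the
#'   combined model at the same clinical-information level.
#' @param measure `"cindex"` or `"ibs"`.
#' @return The signed difference.
#' @export
added_value <- function(clinical, combined, measure = c("cindex", "ibs")) {
  measure <- match.arg(measure)
  if (!identical(as.character(clinical$level), as.character(combined$level))) {
    stop("added value compares models at the same clinical level", call. = FALSE)
  }
  if (measure == "cindex") combined$cindex - clinical$cindex
  else clinical$ibs - combined$ibs
}
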