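# The survival_dataset container: per-patient follow-up, a typed clinical
# tibble, and a dense patients x genes expression matrix, all aligned by
# patient id.

#' Construct a survival dataset
#'
#' Bundles follow-up time, event status, a typed clinical covariate table
#' and a patients x features omics matrix, all in the same patient order.
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param time Positive follow-up times (days); zeros are allowed at
#'   construction and handled by [adjust_zero_times()].
#' @param event 0/1 event indicator (1 = event).
#' @param clinical A data frame of clinical covariates (factors carry their
#'   declared level order; first level is the reference).
#' @param omics Numeric matrix, patients x features, with column names.
#' @param feature_roles Optional character vector labelling each omics
#'   column (`"signal"`, `"surrogate"`, `"noise"`); attached by the
#'   synthetic generator.
#' @param true_lp Optional numeric vector: the true linear predictor used
#'   to generate the data (ground truth for oracle tests).
#' @return A `survival_dataset` object.
#' @export
survival_dataset <- function(patient_id, time, event, clinical, omics,
                             feature_roles = NULL, true_lp = NULL) {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicate patient id", call. = FALSE)
  if (length(time) != n || length(event) != n) {
    stop("time/event length must match patient_id", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("negative or non-finite follow-up time", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  clinical <- tibble::as_tibble(clinical)
  if (nrow(clinical) != n) stop("clinical table row count mismatch", call. = FALSE)
  omics <- as.matrix(omics)
  if (nrow(omics) != n) stop("omics matrix row count mismatch", call. = FALSE)
  if (is.null(colnames(omics))) {
    colnames(omics) <- sprintf("g%05d", seq_len(ncol(omics)))
  }
  if (!is.null(feature_roles)) stopifnot(length(feature_roles) == ncol(omics))
  if (!is.null(true_lp)) stopifnot(length(true_lp) == n)
  structure(
    list(patient_id = patient_id, time = as.numeric(time),
         event = as.integer(event), clinical = clinical, omics = omics,
         feature_roles = feature_roles, true_lp = true_lp),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> n =", length(x$patient_id),
      "| events =", sum(x$event),
      "| clinical covariates:", paste(names(x$clinical), collapse = ", "),
      "| omics features:", ncol(x$omics), "\n")
  invisible(x)
}

#' Number of patients / omics features
#' @param data A `survival_dataset`.
#' @return Integer count.
#' @export
n_patients <- function(data) length(data$patient_id)

#' @rdname n_patients
#' @export
n_features <- function(data) ncol(data$omics)

#' Subset a survival dataset by patient position
#' @param data A `survival_dataset`.
#' @param idx Integer or logical index into patients.
#' @return A `survival_dataset` with the selected patients, all fields
#'   subset consistently.
#' @export
subset_patients <- function(data, idx) {
  survival_dataset(
    patient_id = data$patient_id[idx],
    time = data$time[idx],
    event = data$event[idx],
    clinical = data$clinical[idx, , drop = FALSE],
    omics = data$omics[idx, , drop = FALSE],
    feature_roles = data$feature_roles,
    true_lp = if (!is.null(data$true_lp)) data$true_lp[idx]
  )
}

#' Survival outcome as a tibble
#' @param data A `survival_dataset`.
#' @return A tibble with `patient_id`, `time`, `event` and the clinical
#'   covariates.
#' @export
clinical_table <- function(data) {
  dplyr::bind_cols(
    tibble::tibble(patient_id = data$patient_id, time = data$time,
                   event = data$event),
    data$clinical
  )
}
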