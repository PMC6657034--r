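# Reading/writing study data as delimited text and the preprocessing rules:
# zero-time adjustment, low-expression filtering, stratified splitting.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  # base-R parsing: correctly rounded strtod, so doubles round-trip exactly
  tibble::as_tibble(utils::read.delim(path, sep = detect_delim(path),
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

# write a table whose doubles survive a read round-trip bit-for-bit
write_table_precise <- function(df, path, delim = "\t") {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a clinical table and an omics matrix into a survival dataset
#'
#' Both files are delimited text (TSV or CSV, auto-detected from the header
#' line) with a header row. Patients present in only one of the two files
#' are dropped with a warning; rows are aligned by patient id.
#'
#' @param clinical_path Path to the clinical file: one row per patient, with
#'   id, time and event columns named by `schema` plus the clinical
#'   covariates.
#' @param omics_path Path to the expression file. By default patients are
#'   rows (first column the patient id); set `features_in_rows = TRUE` for
#'   the genes-in-rows orientation shipped by the public repositories
#'   (first column the feature name, one column per patient).
#' @param schema A list naming column roles:
#'   `list(id=, time=, event=, categorical = list(name = levels, ...),
#'   continuous = c(names))`. Categorical values outside the declared level
#'   list are an error. Only covariates named in the schema are retained.
#' @param features_in_rows Orientation flag for the omics file.
#' @return A [survival_dataset()].
#' @details Missing clinical values are refused with an error: multiple
#'   imputation is deliberately outside this package's scope and must be
#'   performed upstream (e.g. with chained-equations imputation) before the
#'   files are read.
#' @export
read_survival_dataset <- function(clinical_path, omics_path, schema,
                                  features_in_rows = FALSE) {
  for (role in c("id", "time", "event")) {
    if (is.null(schema[[role]])) {
      stop("schema must name the '", role, "' column", call. = FALSE)
    }
  }
  clin <- read_table_auto(clinical_path)
  need <- c(schema$id, schema$time, schema$event,
            names(schema$categorical), schema$continuous)
  missing_cols <- setdiff(need, names(clin))
  if (length(missing_cols)) {
    stop("clinical file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(clin[[schema$id]])
  if (anyDuplicated(ids)) {
    stop("duplicate patient id in clinical file: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  time <- clin[[schema$time]]
  if (!is.numeric(time)) {
    stop("non-numeric value in time column '", schema$time, "'", call. = FALSE)
  }
  event <- clin[[schema$event]]
  if (!all(event %in% c(0, 1))) {
    stop("event column '", schema$event, "' must be 0/1", call. = FALSE)
  }

  om <- read_table_auto(omics_path)
  non_num <- which(!vapply(om[, -1L], is.numeric, logical(1)))
  if (length(non_num)) {
    stop("non-numeric expression value in omics column '",
         names(om[, -1L])[non_num[1L]], "'", call. = FALSE)
  }
  if (features_in_rows) {
    feat <- as.character(om[[1L]])
    mat <- t(as.matrix(om[, -1L]))
    colnames(mat) <- feat
    om_ids <- rownames(mat)
  } else {
    om_ids <- as.character(om[[1L]])
    mat <- as.matrix(om[, -1L])
    rownames(mat) <- om_ids
  }
  if (anyDuplicated(om_ids)) stop("duplicate patient id in omics file", call. = FALSE)

  common <- intersect(ids, om_ids)
  dropped <- setdiff(union(ids, om_ids), common)
  if (length(dropped)) {
    warning(length(dropped), " patient(s) present in only one file were dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "", call. = FALSE)
  }
  if (!length(common)) stop("no shared patient ids between the two files", call. = FALSE)
  ci <- match(common, ids)

  covars <- clin[ci, setdiff(need, c(schema$id, schema$time, schema$event)),
                 drop = FALSE]
  for (nm in names(schema$categorical)) {
    lev <- schema$categorical[[nm]]
    vals <- as.character(covars[[nm]])
    bad <- setdiff(stats::na.omit(vals), lev)
    if (length(bad)) {
      stop("value '", bad[1L], "' of covariate '", nm,
           "' is not in its declared level list", call. = FALSE)
    }
    covars[[nm]] <- factor(vals, levels = lev)
  }
  for (nm in schema$continuous) {
    if (!is.numeric(covars[[nm]])) {
      stop("non-numeric value in continuous covariate '", nm, "'", call. = FALSE)
    }
  }
  if (anyNA(covars)) {
    stop("missing clinical values detected; impute upstream (e.g. MICE) ",
         "before reading - imputation is out of scope here", call. = FALSE)
  }
  if (any(time[ci] < 0)) stop("negative follow-up time", call. = FALSE)

  survival_dataset(
    patient_id = common, time = time[ci], event = event[ci],
    clinical = covars, omics = mat[match(common, om_ids), , drop = FALSE]
  )
}

#' Write a survival dataset as delimited text
#'
#' Writes `clinical.tsv` (id, time, event + covariates) and `omics.tsv`
#' (id + one column per feature) into `dir`. Numbers round-trip exactly
#' through [read_survival_dataset()].
#'
#' @param data A `survival_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_survival_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin_path <- file.path(dir, "clinical.tsv")
  om_path <- file.path(dir, "omics.tsv")
  write_table_precise(clinical_table(data), clin_path)
  om <- dplyr::bind_cols(tibble::tibble(patient_id = data$patient_id),
                         tibble::as_tibble(data$omics))
  write_table_precise(om, om_path)
  invisible(c(clinical = clin_path, omics = om_path))
}

#' Schema describing the files written by [write_survival_dataset()]
#' @param data The `survival_dataset` that was (or will be) written.
#' @return A schema list suitable for [read_survival_dataset()].
#' @export
dataset_schema <- function(data) {
  is_fac <- vapply(data$clinical, is.factor, logical(1))
  list(
    id = "patient_id", time = "time", event = "event",
    categorical = lapply(data$clinical[is_fac], levels),
    continuous = names(data$clinical)[!is_fac]
  )
}

#' Replace zero survival times by a small constant
#'
#' A patient who experiences the event on day 0 would otherwise drop out of
#' the partial likelihood; a small constant keeps the observation in the
#' modelling process.
#'
#' @param data A `survival_dataset`.
#' @param epsilon Positive replacement value (default `1e-05`).
#' @return The dataset with every zero time replaced by `epsilon`; all
#'   other times untouched.
#' @export
adjust_zero_times <- function(data, epsilon = 1e-05) {
  stopifnot(epsilon > 0)
  if (any(data$time < 0)) stop("negative follow-up time", call. = FALSE)
  data$time[data$time == 0] <- epsilon
  data
}

#' Drop omics features that are mostly zero
#'
#' Keeps exactly those features whose fraction of nonzero expression values
#' is at least `min_nonzero_fraction` (boundary inclusive), preserving
#' column order. Idempotent.
#'
#' @param data A `survival_dataset`.
#' @param min_nonzero_fraction Required fraction of patients with nonzero
#'   expression, in `[0, 1]` (default 0.5).
#' @return The filtered dataset; the kept feature names are in
#'   `attr(, "kept_features")`.
#' @export
filter_low_expression <- function(data, min_nonzero_fraction = 0.5) {
  stopifnot(min_nonzero_fraction >= 0, min_nonzero_fraction <= 1)
  frac <- colMeans(data$omics != 0)
  keep <- frac >= min_nonzero_fraction
  data$omics <- data$omics[, keep, drop = FALSE]
  if (!is.null(data$feature_roles)) data$feature_roles <- data$feature_roles[keep]
  attr(data, "kept_features") <- colnames(data$omics)
  data
}

round_half_up <- function(x) floor(x + 0.5)

#' Event-stratified train/validation split
#'
#' Splits patients so that the censoring proportion is (up to rounding the
#' same) in both parts: within each event stratum,
#' `round(train_fraction * stratum size)` patients (half up) go to the
#' training part and the remainder to validation.
#'
#' @param data A `survival_dataset`.
#' @param train_fraction Fraction of each stratum assigned to training
#'   (default 2/3).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with elements `train` and `validation`, two disjoint
#'   `survival_dataset`s whose union is `data`.
#' @export
stratified_split <- function(data, train_fraction = 2/3, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  strata <- split(seq_along(data$event), data$event)
  if (length(strata) < 2L) stop("both event strata must be non-empty", call. = FALSE)
  if (any(lengths(strata) < 2L)) {
    stop("each event stratum needs at least 2 patients to split", call. = FALSE)
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(strata, function(ix) {
      k <- round_half_up(train_fraction * length(ix))
      sample(ix, size = k)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_along(data$event), train_idx)
  list(train = subset_patients(data, train_idx),
       validation = subset_patients(data, val_idx))
}
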