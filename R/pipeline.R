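# Orchestration: nested clinical-information levels M0-M4, clinical and
# combined (clinical offset + selected omics) model building, validation
# evaluation, and the subsampling stability analysis.

#' Specify one level of clinical information
#'
#' @param level_id Level label (`"M0"`..`"M4"`).
#' @param variables Tibble with columns `name` (clinical covariate) and
#'   `coding` (`"binary"`, `"categorical"` or `"fp2"`). `NULL` for the
#'   empty level.
#' @return A `clinical_level` object.
#' @export
clinical_level_spec <- function(level_id, variables = NULL) {
  if (is.null(variables)) {
    variables <- tibble::tibble(name = character(0), coding = character(0))
  }
  stopifnot(all(c("name", "coding") %in% names(variables)),
            all(variables$coding %in% c("binary", "categorical", "fp2")))
  structure(list(level_id = level_id, variables = tibble::as_tibble(variables)),
            class = "clinical_level")
}

#' The nested clinical-information levels
#'
#' M0: no clinical information (Kaplan-Meier null model). M1: nodal status
#' dichotomised N0 vs N+. M2: nodal status (4 categories), tumor size
#' (4 categories) and, when the dataset records it, tumor grade
#' (3 categories). M3: M2 plus estrogen receptor status. M4: M3 plus age
#' as a selected FP2 transformation.
#'
#' @param has_grade Include tumor grade in M2-M4 (set `FALSE` for cohorts
#'   that do not record it).
#' @param include Which level ids to return.
#' @return A named list of `clinical_level` objects.
#' @export
clinical_levels <- function(has_grade = TRUE,
                            include = c("M0", "M1", "M2", "M3", "M4")) {
  base2 <- tibble::tibble(
    name = c("nodal", "size", if (has_grade) "grade"),
    coding = "categorical"
  )
  specs <- list(
    M0 = clinical_level_spec("M0"),
    M1 = clinical_level_spec("M1", tibble::tibble(name = "nodal", coding = "binary")),
    M2 = clinical_level_spec("M2", base2),
    M3 = clinical_level_spec("M3", dplyr::bind_rows(
      base2, tibble::tibble(name = "er", coding = "binary"))),
    M4 = clinical_level_spec("M4", dplyr::bind_rows(
      base2, tibble::tibble(name = "er", coding = "binary"),
      tibble::tibble(name = "age", coding = "fp2")))
  )
  specs[include]
}

# Encode a dataset's clinical covariates for one level: one-hot with the
# first declared factor level as reference; binary coding contrasts the
# reference level against all others; fp2 uses the supplied fp_spec.
build_level_design <- function(data, level, fp_spec = NULL) {
  stopifnot(inherits(level, "clinical_level"))
  vars <- level$variables
  cols <- list()
  for (k in seq_len(nrow(vars))) {
    nm <- vars$name[k]
    if (!nm %in% names(data$clinical)) {
      stop("clinical covariate '", nm, "' is missing from the dataset", call. = FALSE)
    }
    v <- data$clinical[[nm]]
    code <- vars$coding[k]
    if (code == "binary") {
      if (is.factor(v)) {
        x <- as.numeric(v != levels(v)[1L])
        cols[[paste0(nm, "_", paste(levels(v)[-1L], collapse = ""))]] <- x
      } else {
        cols[[nm]] <- as.numeric(v)
      }
    } else if (code == "categorical") {
      stopifnot(is.factor(v))
      for (lev in levels(v)[-1L]) {
        cols[[paste0(nm, lev)]] <- as.numeric(v == lev)
      }
    } else {  # fp2
      if (is.null(fp_spec)) {
        stop("an fp_spec is required to encode '", nm, "' as FP2", call. = FALSE)
      }
      Z <- fp_transform(v, fp_spec)
      cols[[paste0(nm, "_fp1")]] <- Z[, 1L]
      cols[[paste0(nm, "_fp2")]] <- Z[, 2L]
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = n_patients(data), ncol = 0))
  }
  do.call(cbind, cols)
}

#' Select FP2 powers for a level on the training data
#'
#' Powers are selected once on the full training data (with the level's
#' other clinical covariates alongside) and then held fixed; only
#' coefficients are refit per subsample.
#'
#' @param train Training `survival_dataset`.
#' @param level A `clinical_level` containing an `fp2` variable.
#' @return An `fp_spec`, or `NULL` if the level has no fp2 variable.
#' @export
select_level_fp <- function(train, level) {
  fp_vars <- level$variables$name[level$variables$coding == "fp2"]
  if (!length(fp_vars)) return(NULL)
  reduced <- clinical_level_spec(
    level$level_id, level$variables[level$variables$coding != "fp2", ])
  other <- build_level_design(train, reduced)
  if (ncol(other) == 0L) other <- NULL
  select_fp2(train$clinical[[fp_vars[1L]]], train$time, train$event,
             other_design = other)
}

#' Fit the purely clinical model of a level
#'
#' M0 yields the Kaplan-Meier null model; other levels encode their
#' covariates (reference-first one-hot; FP2 columns for age) and fit a Cox
#' model with no offset. No selection is performed among clinical
#' variables.
#'
#' @param train Training `survival_dataset`.
#' @param level A `clinical_level`.
#' @param fp_spec FP2 powers for the age term, selected on the full
#'   training data via [select_level_fp()] (required when the level
#'   contains an fp2 variable).
#' @return A `clinical_model`: the fitted Cox (or null) model plus the
#'   encoding information needed to score new patients.
#' @export
build_clinical_model <- function(train, level, fp_spec = NULL) {
  design <- build_level_design(train, level, fp_spec)
  fit <- if (ncol(design) == 0L) {
    fit_km_null(train$time, train$event)
  } else {
    fit_cox(design, train$time, train$event)
  }
  structure(list(level = level, fp_spec = fp_spec, fit = fit),
            class = "clinical_model")
}

#' Clinical linear predictor for (new) patients
#' @param model A `clinical_model`.
#' @param data A `survival_dataset`.
#' @return Numeric vector (all zeros for the M0 null model).
#' @export
clinical_lp <- function(model, data) {
  stopifnot(inherits(model, "clinical_model"))
  if (model$fit$kind == "kaplan_meier_null") return(rep(0, n_patients(data)))
  design <- build_level_design(data, model$level, model$fp_spec)
  predict_lp(model$fit, design)
}

#' Build the combined clinical + omics model of a level
#'
#' Computes the frozen clinical offset from the purely clinical model (a
#' zero vector at M0, where selection runs without an offset), runs the
#' chosen selector with its tuning procedure on the omics matrix, and
#' assembles the combined model. The clinical coefficients are exactly
#' those of the clinical-only fit - they are never re-estimated.
#'
#' @param train Training `survival_dataset`.
#' @param level A `clinical_level`.
#' @param selector A [selector_config()].
#' @param seed Integer seed for the tuning resampling.
#' @param fp_spec FP2 powers (see [build_clinical_model()]).
#' @param clinical Optionally a pre-built `clinical_model` to reuse.
#' @return A `combined_model`: clinical model, sparse omics coefficients on
#'   the original feature scale, selection metadata, and its own Breslow
#'   baseline.
#' @export
build_combined_model <- function(train, level, selector, seed = 1L,
                                 fp_spec = NULL, clinical = NULL) {
  stopifnot(inherits(selector, "selector_config"))
  if (is.null(clinical)) clinical <- build_clinical_model(train, level, fp_spec)
  offset <- clinical_lp(clinical, train)
  X <- train$omics
  if (selector$method == "lasso") {
    cv <- cv_lambda(X, train$time, train$event, offset, selector, seed)
    beta <- cv$path$beta[, cv$index]
    tuning <- cv$lambda
  } else {
    bm <- bootstrap_mstop(X, train$time, train$event, offset, selector, seed)
    path <- boost_offset(X, train$time, train$event, offset, selector,
                         mstop = bm$mstop)
    beta <- boost_coef(path, bm$mstop)
    tuning <- bm$mstop
  }
  nz <- beta != 0
  eta_train <- offset + drop(X %*% beta)
  baseline <- breslow_cumhaz(train$time, train$event, eta_train)
  structure(
    list(clinical = clinical, level = level, selector = selector,
         beta = beta[nz], feature_names = names(beta)[nz],
         n_selected = sum(nz), tuning_value = tuning, baseline = baseline),
    class = "combined_model"
  )
}

#' Risk score (linear predictor) of a model on a dataset
#' @param model A `clinical_model` or `combined_model`.
#' @param data A `survival_dataset`.
#' @return Numeric risk vector (constant for the M0 clinical model).
#' @export
predict_risk <- function(model, data) {
  if (inherits(model, "clinical_model")) return(clinical_lp(model, data))
  stopifnot(inherits(model, "combined_model"))
  lp <- clinical_lp(model$clinical, data)
  if (model$n_selected > 0) {
    lp <- lp + drop(data$omics[, model$feature_names, drop = FALSE] %*% model$beta)
  }
  lp
}

#' Predicted survival curves of a model on a dataset
#' @param model A `clinical_model` or `combined_model`.
#' @param data A `survival_dataset`.
#' @param times Evaluation times.
#' @return Matrix of survival probabilities, patients x times. A combined
#'   model that selected no omics feature predicts exactly as its clinical
#'   model (including the Kaplan-Meier curve at M0).
#' @export
predict_model_survival <- function(model, data, times) {
  if (inherits(model, "clinical_model")) {
    if (model$fit$kind == "kaplan_meier_null") {
      return(predict_survival(model$fit, X = data$omics[, 0, drop = FALSE], times))
    }
    design <- build_level_design(data, model$level, model$fp_spec)
    return(predict_survival(model$fit, design, times))
  }
  stopifnot(inherits(model, "combined_model"))
  if (model$n_selected == 0L) {
    return(predict_model_survival(model$clinical, data, times))
  }
  eta <- predict_risk(model, data)
  H <- cumhaz_at(model$baseline, times)
  exp(-outer(exp(eta), H))
}

#' Evaluate a model on validation data
#'
#' Computes the IPCW C-index and the integrated Brier score on a held-out
#' dataset. The censoring distribution is estimated on the validation data
#' (flipped-indicator Kaplan-Meier); the horizon defaults to the largest
#' validation event time.
#'
#' @param model A `clinical_model` or `combined_model`.
#' @param validation A `survival_dataset` disjoint from the training data.
#' @param tau Optional evaluation horizon.
#' @return One-row tibble: `level`, `model_type`, `selector`, `cindex`,
#'   `ibs`, `n_selected`, `tuning_value`.
#' @export
evaluate_model <- function(model, validation, tau = NULL) {
  time <- validation$time
  event <- validation$event
  if (is.null(tau)) tau <- max(time[event == 1])
  censoring <- kaplan_meier(time, 1 - event)
  grid <- c(0, sort(unique(time[event == 1 & time <= tau])))
  risk <- predict_risk(model, validation)
  sm <- predict_model_survival(model, validation, grid)
  ci <- cindex_ipcw(risk, time, event, tau, censoring)
  ib <- integrated_brier(sm, time, event, grid, tau, censoring)$ibs
  is_comb <- inherits(model, "combined_model")
  tibble::tibble(
    level = model$level$level_id,
    model_type = if (is_comb) "combined" else "clinical",
    selector = if (is_comb) model$selector$method else NA_character_,
    cindex = ci, ibs = ib,
    n_selected = if (is_comb) model$n_selected else NA_integer_,
    tuning_value = if (is_comb) as.numeric(model$tuning_value) else NA_real_
  )
}

#' Subsampling stability analysis of the added predictive value
#'
#' For each of `n_repeats` repeats, a fraction of the training patients is
#' drawn without replacement, all clinical and combined models are rebuilt
#' on the subsample (FP2 powers held fixed from the full training data;
#' feature standardization recomputed inside each fitting sample), and
#' every model is evaluated on the full validation set. The models built
#' on the whole training data are reported as `repeat_id = 0`.
#'
#' @param train,validation Disjoint `survival_dataset`s.
#' @param levels List of `clinical_level`s (default [clinical_levels()]).
#' @param selectors List of [selector_config()]s (default LASSO and
#'   boosting).
#' @param n_repeats Number of subsampling repeats (default 100).
#' @param fraction Subsample fraction (default 0.8); each subsample has
#'   `floor(fraction * n)` patients.
#' @param seed Master seed. Per-repeat seeds are drawn from it up front,
#'   so the report is reproducible and each repeat has its own stream.
#' @param include_full Also fit/evaluate on the whole training data
#'   (default `TRUE`).
#' @param evaluate_on_train If `TRUE`, measures are computed on the full
#'   *training* data instead of the validation set (with a warning):
#'   this is the apparent error, optimistic by construction, and is only
#'   useful to diagnose overfitting — never for model comparison.
#' @param out_dir If given, the report CSV and the resolved configuration
#'   (YAML, including the seed) are written there.
#' @return A `subsampling_report` tibble: one row per repeat x level x
#'   model (clinical rows carry `selector = NA`), with columns `cindex`,
#'   `ibs`, `added_cindex`, `added_ibs`, `n_selected`, `tuning_value`.
#' @export
run_subsampling <- function(train, validation,
                            levels = clinical_levels(),
                            selectors = list(selector_config("lasso"),
                                             selector_config("boosting")),
                            n_repeats = 100L, fraction = 0.8, seed = 1L,
                            include_full = TRUE, evaluate_on_train = FALSE,
                            out_dir = NULL) {
  stopifnot(fraction > 0, fraction < 1, n_repeats >= 1L)
  if (evaluate_on_train) {
    warning("evaluating on the training data measures apparent error and ",
            "is optimistic; do not use it for model comparison", call. = FALSE)
    eval_data <- train
  } else {
    stopifnot(!any(train$patient_id %in% validation$patient_id))
    eval_data <- validation
  }
  n <- n_patients(train)
  m <- floor(fraction * n)
  # FP2 powers: selected once per level on the full training data
  fp_specs <- lapply(levels, function(lv) select_level_fp(train, lv))
  tau <- max(eval_data$time[eval_data$event == 1])

  repeat_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_repeats + 1L))

  run_once <- function(fit_data, repeat_id, rseed) {
    rows <- list()
    sel_seeds <- withr::with_seed(rseed, sample.int(2147483646L, length(selectors) * length(levels)))
    k <- 0L
    for (li in seq_along(levels)) {
      lv <- levels[[li]]
      clin <- build_clinical_model(fit_data, lv, fp_specs[[li]])
      ev_clin <- evaluate_model(clin, eval_data, tau)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        ev_clin, repeat_id = repeat_id,
        added_cindex = NA_real_, added_ibs = NA_real_)
      for (sel in selectors) {
        k <- k + 1L
        comb <- build_combined_model(fit_data, lv, sel, seed = sel_seeds[k],
                                     fp_spec = fp_specs[[li]], clinical = clin)
        ev_comb <- evaluate_model(comb, eval_data, tau)
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          ev_comb, repeat_id = repeat_id,
          added_cindex = added_value(ev_clin, ev_comb, "cindex"),
          added_ibs = added_value(ev_clin, ev_comb, "ibs"))
      }
    }
    dplyr::bind_rows(rows)
  }

  out <- list()
  if (include_full) {
    out[[1L]] <- run_once(train, 0L, repeat_seeds[1L])
  }
  for (r in seq_len(n_repeats)) {
    rseed <- repeat_seeds[r + 1L]
    sub_idx <- withr::with_seed(rseed, {
      for (try in 1:20) {
        idx <- sample.int(n, m)
        if (sum(train$event[idx]) >= 2L) break
      }
      if (sum(train$event[idx]) < 2L) {
        stop("could not draw a subsample with at least 2 events", call. = FALSE)
      }
      idx
    })
    out[[length(out) + 1L]] <- run_once(subset_patients(train, sub_idx), r, rseed)
  }
  report <- dplyr::bind_rows(out)
  report <- dplyr::relocate(report, "repeat_id")
  report$seed <- seed
  class(report) <- c("subsampling_report", class(report))
  attr(report, "config") <- list(
    n_repeats = n_repeats, fraction = fraction, seed = seed,
    levels = names(levels) %||% vapply(levels, function(l) l$level_id, character(1)),
    selectors = vapply(selectors, function(s) s$method, character(1)),
    n_train = n, n_validation = n_patients(validation), tau = tau,
    evaluated_on = if (evaluate_on_train) "train" else "validation",
    fp_powers = lapply(fp_specs, function(s) if (is.null(s)) NULL else s$powers)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(tibble::as_tibble(report), file.path(out_dir, "report.csv"),
                     progress = FALSE)
    yaml::write_yaml(attr(report, "config"), file.path(out_dir, "config.yaml"))
  }
  report
}

#' Boxplot-style summary of a subsampling report
#'
#' Medians and quartiles of the measures and added values per level x
#' selector, over the subsampling repeats (the whole-training-data run,
#' `repeat_id = 0`, is excluded).
#'
#' @param report A `subsampling_report`.
#' @return A tidy tibble, one row per level x selector x measure.
#' @export
summarize_subsampling <- function(report) {
  report |>
    dplyr::filter(.data$repeat_id > 0, .data$model_type == "combined") |>
    tidyr::pivot_longer(
      cols = c("cindex", "ibs", "added_cindex", "added_ibs", "n_selected"),
      names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$level, .data$selector, .data$measure) |>
    dplyr::summarise(
      q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE),
      mean = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}
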