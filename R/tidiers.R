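# broom-style tidiers and ggplot2 methods for the fitted objects and the
# subsampling report.

#' @export
tidy.fitted_cox <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.fitted_cox <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$meta$n, n_events = x$meta$n_events,
                 loglik = x$meta$loglik, iter = x$meta$iter,
                 converged = x$meta$converged,
                 separation = x$meta$separation)
}

#' @export
tidy.clinical_model <- function(x, ...) tidy(x$fit)

#' @export
glance.clinical_model <- function(x, ...) {
  dplyr::mutate(glance(x$fit), level = x$level$level_id, .before = 1L)
}

#' @export
tidy.combined_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$clinical$fit), part = "clinical"),
    tibble::tibble(term = x$feature_names, estimate = unname(x$beta),
                   part = "omics")
  )
}

#' @export
glance.combined_model <- function(x, ...) {
  tibble::tibble(level = x$level$level_id, selector = x$selector$method,
                 n_selected = x$n_selected,
                 tuning_value = as.numeric(x$tuning_value))
}

#' Boxplots of the added predictive value per clinical level
#'
#' Mirrors the study's headline display: the subsampling distribution of
#' the added value (combined minus clinical C-index; clinical minus
#' combined IBS) per level, with the whole-training-data model overlaid as
#' a square.
#'
#' @param object A `subsampling_report`.
#' @param measure `"both"`, `"cindex"` or `"ibs"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subsampling_report <- function(object, measure = "both", ...) {
  long <- object |>
    dplyr::filter(.data$model_type == "combined") |>
    tidyr::pivot_longer(c("added_cindex", "added_ibs"),
                        names_to = "measure", values_to = "added") |>
    dplyr::mutate(measure = sub("added_", "", .data$measure))
  if (measure != "both") long <- dplyr::filter(long, .data$measure == !!measure)
  ggplot2::ggplot(dplyr::filter(long, .data$repeat_id > 0),
                  ggplot2::aes(x = .data$level, y = .data$added)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_point(data = dplyr::filter(long, .data$repeat_id == 0),
                        shape = 15, size = 2.5, colour = "grey30") +
    ggplot2::facet_grid(measure ~ selector, scales = "free_y") +
    ggplot2::labs(x = "level of clinical information",
                  y = "added predictive value (positive = omics helped)")
}

#' Boxplots of the number of selected omics variables per level
#' @param report A `subsampling_report`.
#' @return A ggplot object.
#' @export
plot_n_selected <- function(report) {
  comb <- dplyr::filter(report, .data$model_type == "combined")
  ggplot2::ggplot(dplyr::filter(comb, .data$repeat_id > 0),
                  ggplot2::aes(x = .data$level, y = .data$n_selected,
                               fill = .data$selector)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(
      data = dplyr::filter(comb, .data$repeat_id == 0),
      ggplot2::aes(group = .data$selector), shape = 15, size = 2.5,
      position = ggplot2::position_dodge(width = 0.8), colour = "grey30") +
    ggplot2::scale_fill_grey(start = 0.5, end = 0.9) +
    ggplot2::labs(x = "level of clinical information",
                  y = "selected omics variables")
}
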