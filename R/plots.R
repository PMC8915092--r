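#' Plot a heart-rate series
#'
#' Line plot of the series with missing slots marked along the axis, the
#' usual first look at a gappy wrist export.
#'
#' @param series an `hr_series`.
#' @return a ggplot object.
#' @export
plot_hr_series <- function(series) {
  df <- tibble::as_tibble(series)
  gaps <- df[is.na(df$hr_bpm), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$hr_bpm)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "steelblue") +
    ggplot2::geom_rug(data = gaps, sides = "b", colour = "firebrick", na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "heart rate (bpm)",
                  title = sprintf("%s (%s), %d missing slots",
                                  df$subject_id[1], df$device[1], nrow(gaps))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of an imputation benchmark
#'
#' @param object an `imputation_benchmark`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.imputation_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$rmse), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$method, .data$rmse),
                                   y = .data$rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "masked-slot RMSE (bpm)",
                  title = "Imputation methods ranked by RMSE") +
    ggplot2::theme_minimal()
}

#' Bar chart of the model ranking of a mapping report
#'
#' @param object a `mapping_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mapping_report <- function(object, ...) {
  df <- generics::tidy(object)
  df <- df[!is.na(df$test_rmse), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$algorithm, .data$test_rmse),
                                   y = .data$test_rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "test RMSE (bpm)",
                  title = "Correction models ranked by held-out RMSE") +
    ggplot2::theme_minimal()
}

#' Grouped boxplots of a platform comparison
#'
#' Rebuilds the per-metric five-number summaries as side-by-side boxes for
#' the pipeline and reference groups.
#'
#' @param object an `hrv_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hrv_comparison <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    dplyr::bind_rows(
      dplyr::mutate(object$box_pipeline[[i]], group = "pipeline"),
      dplyr::mutate(object$box_reference[[i]], group = "reference")
    ) |>
      dplyr::mutate(metric = object$metric[i])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, fill = .data$group)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$min, lower = .data$q1,
                                       middle = .data$median, upper = .data$q3,
                                       ymax = .data$max),
                          stat = "identity", width = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = "Per-subject HRV indices: pipeline vs reference") +
    ggplot2::theme_minimal()
}
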