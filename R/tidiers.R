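#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mapping report
#'
#' One row per model family with the winning hyperparameters flattened to a
#' label, the CV score (negated MSE) and the held-out test RMSE in bpm.
#'
#' @param x a `mapping_report` from [evaluate_models()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mapping_report <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    hyperparameters = vapply(x$best_params, function(p) {
      if (is.null(p) || length(p) == 0L) ""
      else paste(names(p), unlist(p), sep = "=", collapse = ", ")
    }, character(1)),
    cv_score = x$cv_score,
    test_rmse = x$test_rmse,
    error = x$error
  )
}

#' @rdname tidy.mapping_report
#' @export
glance.mapping_report <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x),
    n_failed = sum(!is.na(x$error)),
    winner = attr(x, "winner"),
    best_test_rmse = min(x$test_rmse, na.rm = TRUE)
  )
}

#' Tidy a platform comparison
#'
#' One row per HRV metric with the paired t statistic, two-tailed p-value,
#' degrees of freedom, critical values and decision.
#'
#' @param x an `hrv_comparison` from [compare_platforms()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.hrv_comparison <- function(x, ...) {
  tibble::as_tibble(x)[, c("metric", "n", "df", "t_value", "p_value",
                           "critical_t_95", "critical_t_99", "decision")]
}

#' @rdname tidy.hrv_comparison
#' @export
glance.hrv_comparison <- function(x, ...) {
  tibble::tibble(
    alpha = attr(x, "alpha"),
    n_metrics = nrow(x),
    n_no_difference = sum(x$decision == "no_difference"),
    all_no_difference = all(x$decision == "no_difference")
  )
}

#' Tidy an imputation benchmark
#'
#' @param x an `imputation_benchmark` from [benchmark_imputation()].
#' @param ... unused.
#' @return a tibble sorted ascending by RMSE.
#' @export
tidy.imputation_benchmark <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.imputation_benchmark
#' @export
glance.imputation_benchmark <- function(x, ...) {
  ok <- !is.na(x$rmse)
  tibble::tibble(
    best_method = x$method[ok][1],
    best_rmse = x$rmse[ok][1],
    n_methods = nrow(x),
    n_failed = sum(!ok),
    missing_fraction = attr(x, "missing_fraction"),
    seed = attr(x, "seed")
  )
}

#' Tidy an HRV summary into long form
#'
#' @param x an `hrv_summary`.
#' @param ... unused.
#' @return a tibble with columns `metric`, `value`.
#' @export
tidy.hrv_summary <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[, hrv_json_fields],
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}
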