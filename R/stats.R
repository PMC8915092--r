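#' Root mean square error
#'
#' `sqrt(mean((predicted - observed)^2))` — the standard deviation of the
#' residuals around zero.
#'
#' @param predicted,observed numeric vectors of equal length >= 1.
#' @return nonnegative scalar.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch", call. = FALSE)
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' R-squared as the squared Pearson correlation
#'
#' Measures agreement strength between two index vectors as the square of
#' the Pearson correlation coefficient (not 1 - SSE/SST), so it lies in
#' \[0, 1\] and ignores affine offsets.
#'
#' @param x,y numeric vectors, length >= 3, each with nonzero variance.
#' @return scalar in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Paired Student's t-test
#'
#' Classic paired t on per-subject differences: `t = mean(d) / (sd(d) /
#' sqrt(n))` with the sample standard deviation, `df = n - 1`, and a
#' two-tailed p-value from the Student t distribution.
#'
#' @param a,b paired numeric vectors (same subjects, same order), n >= 2.
#' @return list with `t`, `p_two_tailed`, `df`, `mean_diff`, `sd_diff`, `n`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero-variance differences: t statistic undefined", call. = FALSE)
  t_val <- mean(d) / (sd_d / sqrt(n))
  list(t = t_val,
       p_two_tailed = 2 * stats::pt(-abs(t_val), df = n - 1),
       df = n - 1L,
       mean_diff = mean(d), sd_diff = sd_d, n = n)
}

#' One-tailed critical value of the Student t distribution
#'
#' The upper-tail quantile as read from a one-tailed t table: with
#' `confidence = 0.95` and `df = 9` this is 1.833, with `confidence = 0.99`
#' it is 2.821.
#'
#' @param confidence confidence level in (0, 1).
#' @param df positive integer degrees of freedom.
#' @return scalar critical value.
#' @export
t_critical <- function(confidence, df) {
  if (any(confidence <= 0 | confidence >= 1)) stop("confidence must be in (0, 1)", call. = FALSE)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stats::qt(confidence, df = df)
}

#' Compare per-subject HRV metrics from two pipelines
#'
#' For each requested metric, pairs the per-subject values from the two
#' summary tables (same subjects, same order) and reports the paired t
#' statistic, two-tailed p-value, degrees of freedom, the one-tailed 95%
#' and 99% critical values, the accept/reject decision at `alpha` (based on
#' the p-value), and five-number boxplot summaries of each group. If the
#' paired differences are all exactly zero (the two pipelines agree
#' bit-for-bit) the t statistic is reported as 0 with p = 1.
#'
#' @param pipeline,reference data frames with one row per subject holding the
#'   metric columns (e.g. stacked [compute_hrv_summary()] rows).
#' @param metrics metric columns to compare.
#' @param alpha significance level for the decision.
#' @return a tibble of class `hrv_comparison`: one row per metric with
#'   columns `metric`, `n`, `df`, `t_value`, `p_value`, `critical_t_95`,
#'   `critical_t_99`, `decision`, and `box_pipeline` / `box_reference`
#'   list-columns of five-number summaries.
#' @export
compare_platforms <- function(pipeline, reference,
                              metrics = c("sdnn", "rmssd", "pnn50"),
                              alpha = 0.05) {
  if (nrow(pipeline) != nrow(reference)) stop("subject mismatch", call. = FALSE)
  if ("subject_id" %in% names(pipeline) && "subject_id" %in% names(reference) &&
      !identical(pipeline$subject_id, reference$subject_id)) {
    stop("subject mismatch: summaries must list the same subjects in the same order",
         call. = FALSE)
  }
  n <- nrow(pipeline)
  out <- purrr::map_dfr(metrics, function(m) {
    a <- pipeline[[m]]
    b <- reference[[m]]
    if (all(a - b == 0)) {
      tt <- list(t = 0, p_two_tailed = 1, df = n - 1L)
    } else {
      tt <- paired_t_test(a, b)
    }
    tibble::tibble(
      metric = m,
      n = n,
      df = tt$df,
      t_value = tt$t,
      p_value = tt$p_two_tailed,
      critical_t_95 = t_critical(0.95, tt$df),
      critical_t_99 = t_critical(0.99, tt$df),
      decision = if (tt$p_two_tailed < alpha) "difference" else "no_difference",
      box_pipeline = list(five_number(a)),
      box_reference = list(five_number(b))
    )
  })
  attr(out, "alpha") <- alpha
  class(out) <- c("hrv_comparison", class(out))
  out
}

five_number <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, na.rm = TRUE)
  tibble::tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
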