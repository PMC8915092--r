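#' Time-domain HRV summary of an IBI series
#'
#' Computes the standard short-term time-domain indices plus the two
#' segmented indices conventionally defined over 5-minute windows:
#'
#' * `sdnn` — sample standard deviation of all intervals (ms);
#' * `rmssd` — root mean square of successive interval differences (ms);
#' * `pnn50` — percentage of successive differences strictly greater than
#'   50 ms (denominator n - 1);
#' * `sdnn_index` — mean of the per-segment sample standard deviations (ms);
#' * `sdann` — sample standard deviation of the per-segment mean intervals
#'   (ms).
#'
#' Segments are non-overlapping windows of `segment_minutes` of cumulative
#' elapsed time (interval start time decides membership); a trailing partial
#' segment is dropped, and with fewer than two complete segments `sdann` and
#' `sdnn_index` are `NA`. Heart-rate statistics come from 60000 / interval.
#'
#' @param ibi an `ibi_series` (typically after [correct_artifacts()]).
#' @param segment_minutes segment length for `sdann` / `sdnn_index`.
#' @return a one-row tibble of class `hrv_summary` with columns `min_hr`,
#'   `max_hr`, `mean_hr`, `sdnn`, `sdnn_index`, `rmssd`, `pnn50`, `sdann`,
#'   `n_intervals`, `n_artifacts_corrected`, `segment_minutes`.
#' @export
compute_hrv_summary <- function(ibi, segment_minutes = 5) {
  x <- if (is.data.frame(ibi)) ibi$interval_ms else as.numeric(ibi)
  n <- length(x)
  if (n < 2L) stop("need at least 2 intervals for an HRV summary", call. = FALSE)
  d <- diff(x)
  hr <- 60000 / x

  elapsed_start_min <- c(0, cumsum(x)[-n]) / 60000
  seg <- floor(elapsed_start_min / segment_minutes)
  total_min <- sum(x) / 60000
  complete <- seg < floor(total_min / segment_minutes)
  seg_stats <- if (any(complete)) {
    split(x[complete], seg[complete])
  } else {
    list()
  }
  if (length(seg_stats) >= 2L) {
    seg_means <- vapply(seg_stats, mean, numeric(1))
    seg_sds <- vapply(seg_stats, stats::sd, numeric(1))
    sdann <- stats::sd(seg_means)
    sdnn_index <- mean(seg_sds)
  } else {
    sdann <- NA_real_
    sdnn_index <- NA_real_
  }

  out <- tibble::tibble(
    min_hr = min(hr),
    max_hr = max(hr),
    mean_hr = mean(hr),
    sdnn = stats::sd(x),
    sdnn_index = sdnn_index,
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 50) / (n - 1),
    sdann = sdann,
    n_intervals = n,
    n_artifacts_corrected = attr(ibi, "n_artifacts_corrected") %||% 0L,
    segment_minutes = segment_minutes
  )
  class(out) <- c("hrv_summary", class(out))
  out
}

hrv_json_fields <- c("min_hr", "max_hr", "mean_hr", "sdnn", "sdnn_index",
                     "rmssd", "pnn50", "sdann")

#' Write an HRV summary to JSON or CSV
#'
#' JSON serialisation is lossless (full double precision, so a read-back
#' reproduces every field bit-exactly); `NA` segmented indices (undefined
#' with fewer than two complete segments) become JSON `null` / an empty CSV
#' cell. CSV output is one header row plus one value row.
#'
#' @param summary an `hrv_summary` (one row).
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_hrv_summary <- function(summary, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(nrow(summary) == 1L)
  fields <- summary[, hrv_json_fields]
  if (format == "json") {
    jsonlite::write_json(as.list(fields), path, auto_unbox = TRUE,
                         digits = I(17), na = "null", always_decimal = TRUE)
  } else {
    readr::write_csv(fields, path, na = "")
  }
  invisible(path)
}

#' Read an HRV summary written by [write_hrv_summary()]
#'
#' @param path file path (format inferred from the extension).
#' @return a one-row `hrv_summary` tibble (identification columns absent).
#' @export
read_hrv_summary <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::read_json(path)
    vals <- lapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
    out <- tibble::as_tibble(vals[hrv_json_fields])
  } else {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    out <- tibble::as_tibble(lapply(out[hrv_json_fields], as.numeric))
  }
  class(out) <- c("hrv_summary", class(out))
  out
}
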