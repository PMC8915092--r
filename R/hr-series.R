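#' Construct a heart-rate series
#'
#' A heart-rate series is a tibble with one row per sample: `subject_id`,
#' `device` (`"wrist"` or `"reference"`), `time_s` (epoch or elapsed seconds,
#' strictly increasing) and `hr_bpm` (instantaneous heart rate; `NA` marks an
#' explicit missing slot). The nominal sampling period is carried as the
#' `nominal_period_s` attribute so downstream imputation can operate on a
#' regular grid.
#'
#' @param time_s numeric vector of strictly increasing timestamps in seconds.
#' @param hr_bpm numeric vector of heart rates in bpm; `NA` for missing slots.
#' @param subject_id subject label (length 1).
#' @param device `"wrist"` or `"reference"`.
#' @param nominal_period_s nominal sampling period in seconds.
#' @param band plausibility band for non-missing values, in bpm.
#' @param on_band_violation `"error"` (default) or `"missing"` — whether an
#'   out-of-band value aborts or is coerced to a missing slot.
#'
#' @return a tibble of class `hr_series`.
#' @export
hr_series <- function(time_s, hr_bpm,
                      subject_id = "S1",
                      device = c("wrist", "reference"),
                      nominal_period_s = NULL,
                      band = c(20, 260),
                      on_band_violation = c("error", "missing")) {
  device <- match.arg(device)
  on_band_violation <- match.arg(on_band_violation)
  time_s <- as.numeric(time_s)
  hr_bpm <- as.numeric(hr_bpm)
  if (length(time_s) < 1L) stop("heart-rate series must have length >= 1", call. = FALSE)
  if (length(time_s) != length(hr_bpm)) stop("time_s and hr_bpm lengths differ", call. = FALSE)
  if (anyNA(time_s)) stop("timestamps must not be missing", call. = FALSE)
  if (any(duplicated(time_s))) {
    stop("duplicate timestamps at t = ",
         paste(utils::head(unique(time_s[duplicated(time_s)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    ord <- order(time_s)
    time_s <- time_s[ord]
    hr_bpm <- hr_bpm[ord]
  }
  bad <- which(!is.na(hr_bpm) & (!is.finite(hr_bpm) | hr_bpm <= band[1] | hr_bpm >= band[2]))
  if (length(bad)) {
    if (on_band_violation == "error") {
      stop("heart-rate values outside plausibility band (", band[1], ", ", band[2],
           ") bpm at rows: ", paste(utils::head(bad, 10L), collapse = ", "),
           call. = FALSE)
    }
    hr_bpm[bad] <- NA_real_
  }
  if (is.null(nominal_period_s)) {
    nominal_period_s <- if (length(time_s) > 1L) stats::median(diff(time_s)) else 1
  }
  stopifnot(nominal_period_s > 0)
  out <- tibble::tibble(
    subject_id = as.character(subject_id),
    device = device,
    time_s = time_s,
    hr_bpm = hr_bpm
  )
  attr(out, "nominal_period_s") <- as.numeric(nominal_period_s)
  attr(out, "band") <- as.numeric(band)
  class(out) <- c("hr_series", class(out))
  out
}

#' Nominal sampling period of a heart-rate series
#' @param series an `hr_series`.
#' @return period in seconds.
#' @export
nominal_period <- function(series) {
  p <- attr(series, "nominal_period_s")
  if (is.null(p)) stats::median(diff(series$time_s)) else p
}

restore_hr_attrs <- function(out, template) {
  attr(out, "nominal_period_s") <- attr(template, "nominal_period_s")
  attr(out, "band") <- attr(template, "band")
  if (!inherits(out, "hr_series")) class(out) <- c("hr_series", class(out))
  out
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> subject %s, device %s, n = %d (%d missing), period %g s\n",
              x$subject_id[1], x$device[1], nrow(x), sum(is.na(x$hr_bpm)),
              nominal_period(x)))
  NextMethod()
}

#' Read a heart-rate CSV export
#'
#' Expects a UTF-8 CSV with a header naming (at least) a subject column, a
#' timestamp column (ISO-8601 or epoch seconds) and a heart-rate column in
#' bpm, mirroring a wrist-device intraday export. Empty or `NA` heart-rate
#' cells become explicit missing slots; duplicate timestamps (per subject) are
#' rejected; out-of-band heart rates raise a validation error unless
#' `on_band_violation = "missing"`.
#'
#' @param path file path.
#' @param schema named list mapping roles to column names, default
#'   `list(subject = "subject_id", timestamp = "timestamp", hr = "hr_bpm")`.
#' @param device device label for the series.
#' @inheritParams hr_series
#' @return an `hr_series` (multiple subjects allowed; split with
#'   [dplyr::group_split()] on `subject_id` if needed).
#' @export
read_hr_csv <- function(path,
                        schema = list(subject = "subject_id", timestamp = "timestamp", hr = "hr_bpm"),
                        device = c("wrist", "reference"),
                        nominal_period_s = NULL,
                        band = c(20, 260),
                        on_band_violation = c("error", "missing")) {
  device <- match.arg(device)
  on_band_violation <- match.arg(on_band_violation)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- unlist(schema[c("subject", "timestamp", "hr")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts_raw <- raw[[schema$timestamp]]
  time_s <- suppressWarnings(as.numeric(ts_raw))
  iso <- is.na(time_s) & !is.na(ts_raw)
  if (any(iso)) {
    parsed <- as.POSIXct(strptime(ts_raw[iso], "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    alt <- is.na(parsed)
    parsed[alt] <- as.POSIXct(strptime(ts_raw[iso][alt], "%Y-%m-%d %H:%M:%OS",
                                       tz = "UTC"))
    time_s[iso] <- as.numeric(parsed)
  }
  if (anyNA(time_s)) {
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(which(is.na(time_s)), 5L), collapse = ", "), call. = FALSE)
  }
  hr <- suppressWarnings(as.numeric(raw[[schema$hr]]))
  hr[!is.na(raw[[schema$hr]]) & raw[[schema$hr]] == ""] <- NA_real_
  subj <- as.character(raw[[schema$subject]])

  pieces <- lapply(split(seq_along(subj), subj), function(idx) {
    hr_series(time_s[idx], hr[idx], subject_id = subj[idx][1], device = device,
              nominal_period_s = nominal_period_s, band = band,
              on_band_violation = on_band_violation)
  })
  out <- dplyr::bind_rows(pieces)
  restore_hr_attrs(out, pieces[[1]])
}

#' Write a heart-rate series to CSV
#'
#' @param series an `hr_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(series, path) {
  readr::write_csv(
    tibble::tibble(subject_id = series$subject_id,
                   timestamp = series$time_s,
                   hr_bpm = series$hr_bpm),
    path, na = "")
  invisible(path)
}

#' Resample a heart-rate series onto a uniform grid
#'
#' Builds a fixed-period grid spanning the observed time range and snaps each
#' observation to its nearest grid slot (ties break to the earlier slot).
#' Grid slots with no observation within half a period become explicit
#' missing slots. When two observations map to the same slot the nearer one
#' (then the earlier) is kept and the number of dropped samples is reported
#' via a message.
#'
#' @param series an `hr_series`.
#' @param period_s grid period in seconds (default: the series' nominal period).
#' @return a uniform `hr_series` with `nominal_period_s = period_s`.
#' @export
resample_uniform <- function(series, period_s = nominal_period(series)) {
  stopifnot(period_s > 0)
  if (nrow(series) == 0L) stop("cannot resample an empty series", call. = FALSE)
  t0 <- series$time_s[1]
  t1 <- series$time_s[nrow(series)]
  grid <- seq(t0, t1, by = period_s)
  if (grid[length(grid)] < t1 - 1e-9) grid <- c(grid, grid[length(grid)] + period_s)

  slot <- round((series$time_s - t0) / period_s) + 1L
  dist <- abs(series$time_s - (t0 + (slot - 1L) * period_s))
  # ties at exactly half a period snap to the earlier slot
  half <- abs(dist - period_s / 2) < 1e-9
  down <- half & (t0 + (slot - 1L) * period_s) > series$time_s
  slot[down] <- slot[down] - 1L
  dist[down] <- abs(series$time_s[down] - (t0 + (slot[down] - 1L) * period_s))

  keep <- dist <= period_s / 2 + 1e-9 & slot >= 1L & slot <= length(grid)
  ord <- order(slot[keep], dist[keep], series$time_s[keep])
  idx <- which(keep)[ord]
  first_per_slot <- idx[!duplicated(slot[idx])]
  dropped <- sum(keep) - length(first_per_slot)
  if (dropped > 0) message(dropped, " sample(s) dropped in resampling (slot collisions)")

  hr <- rep(NA_real_, length(grid))
  hr[slot[first_per_slot]] <- series$hr_bpm[first_per_slot]
  out <- hr_series(grid, hr, subject_id = series$subject_id[1],
                   device = series$device[1], nominal_period_s = period_s,
                   band = attr(series, "band") %||% c(20, 260))
  out
}

#' Time-align a wrist and a reference series into paired samples
#'
#' Both series must belong to the same subject and be resampled to a common
#' period. One `(wrist_hr, reference_hr)` pair is emitted per grid slot where
#' both devices have a non-missing value within `tolerance_s`.
#'
#' @param wrist,reference `hr_series` objects for the same subject.
#' @param tolerance_s maximum timestamp discrepancy for a slot to pair.
#' @return a tibble with columns `subject_id`, `time_s`, `wrist_hr`,
#'   `reference_hr`, carrying the paired fraction (paired slots / wrist slots)
#'   as the `paired_fraction` attribute. Disjoint ranges yield zero rows with
#'   a warning.
#' @export
align_pair <- function(wrist, reference, tolerance_s = nominal_period(wrist) / 2) {
  if (wrist$subject_id[1] != reference$subject_id[1]) {
    stop("align_pair requires series from the same subject", call. = FALSE)
  }
  j <- findInterval(wrist$time_s, reference$time_s + tolerance_s) + 1L
  ok <- j >= 1L & j <= nrow(reference)
  match_ok <- ok
  match_ok[ok] <- abs(reference$time_s[j[ok]] - wrist$time_s[ok]) <= tolerance_s
  rows <- which(match_ok & !is.na(wrist$hr_bpm))
  rows <- rows[!is.na(reference$hr_bpm[j[rows]])]
  out <- tibble::tibble(
    subject_id = wrist$subject_id[1],
    time_s = wrist$time_s[rows],
    wrist_hr = wrist$hr_bpm[rows],
    reference_hr = reference$hr_bpm[j[rows]]
  )
  if (nrow(out) == 0L) warning("no overlapping samples between wrist and reference series")
  attr(out, "paired_fraction") <- nrow(out) / nrow(wrist)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
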