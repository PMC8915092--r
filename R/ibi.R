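#' Construct an inter-beat-interval series
#'
#' The pipeline's IBI is a pseudo interval derived from uniformly sampled
#' instantaneous heart rate (60000 / HR), not from beat detections. Each
#' interval carries a status flag: `normal`, `artifact` (flagged by a
#' correction rule) or `interpolated` (replaced by the cubic spline).
#'
#' @param intervals_ms positive interval durations in milliseconds.
#' @param flags character vector of per-interval flags; default all `normal`.
#' @param origin `"derived_from_hr"` or `"simulated"`.
#' @return a tibble of class `ibi_series` with columns `interval_ms`, `flag`.
#' @export
ibi_series <- function(intervals_ms,
                       flags = rep("normal", length(intervals_ms)),
                       origin = c("derived_from_hr", "simulated")) {
  origin <- match.arg(origin)
  intervals_ms <- as.numeric(intervals_ms)
  if (length(flags) != length(intervals_ms)) stop("flags and intervals lengths differ", call. = FALSE)
  if (any(!is.finite(intervals_ms) | intervals_ms <= 0)) {
    stop("all intervals must be strictly positive and finite", call. = FALSE)
  }
  if (!all(flags %in% c("normal", "artifact", "interpolated"))) {
    stop("flags must be normal/artifact/interpolated", call. = FALSE)
  }
  out <- tibble::tibble(interval_ms = intervals_ms, flag = as.character(flags))
  attr(out, "origin") <- origin
  class(out) <- c("ibi_series", class(out))
  out
}

#' Convert instantaneous heart rate to pseudo inter-beat intervals
#'
#' Uses IBI\[ms\] = 60000 / HR\[bpm\] slot-by-slot (one pseudo-interval per
#' HR sample). The constant is configurable because some sources quote the
#' relation in centiseconds (HR = 6000 / IBI); milliseconds are the unit used
#' throughout this package.
#'
#' @param series a complete (gap-free) `hr_series`.
#' @param constant numerator of the conversion; 60000 for IBI in ms.
#' @return an `ibi_series` of the same length, all flags `normal`.
#' @export
hr_to_ibi <- function(series, constant = 60000) {
  hr <- if (is.data.frame(series)) series$hr_bpm else as.numeric(series)
  if (anyNA(hr)) stop("hr_to_ibi requires a complete series (impute first)", call. = FALSE)
  if (any(hr <= 0)) stop("heart rate must be positive", call. = FALSE)
  ibi_series(constant / hr, origin = "derived_from_hr")
}

#' Convert pseudo inter-beat intervals back to heart rate
#'
#' @param ibi an `ibi_series` or numeric vector of intervals in ms.
#' @param constant see [hr_to_ibi()].
#' @return numeric vector of heart rates in bpm.
#' @export
ibi_to_hr <- function(ibi, constant = 60000) {
  x <- if (is.data.frame(ibi)) ibi$interval_ms else as.numeric(ibi)
  constant / x
}

#' Artifact-rule configuration
#'
#' Thresholds for the four beat-rejection rules, all relative deviations:
#' Malik flags an interval differing by more than 20% from the preceding
#' accepted interval; Karlsson flags an interior interval diverging by more
#' than 20% from the mean of its raw previous and next neighbours; Kamath is
#' asymmetric (increase > 32.5% or decrease > 24.5% versus the preceding
#' accepted interval); Acar compares against the mean of up to the last nine
#' accepted intervals (20%).
#'
#' @param rule one of `"malik"`, `"karlsson"`, `"kamath"`, `"acar"`.
#' @param malik_threshold,karlsson_threshold,acar_threshold relative deviation.
#' @param kamath_increase,kamath_decrease the asymmetric Kamath thresholds.
#' @param acar_window number of trailing accepted intervals Acar averages.
#' @return a list of class `artifact_rule_config`.
#' @export
artifact_rule_config <- function(rule = c("kamath", "malik", "karlsson", "acar"),
                                 malik_threshold = 0.20,
                                 karlsson_threshold = 0.20,
                                 kamath_increase = 0.325,
                                 kamath_decrease = 0.245,
                                 acar_threshold = 0.20,
                                 acar_window = 9L) {
  rule <- match.arg(rule)
  stopifnot(malik_threshold > 0, karlsson_threshold > 0, kamath_increase > 0,
            kamath_decrease > 0, acar_threshold > 0, acar_window >= 1)
  structure(list(rule = rule, malik_threshold = malik_threshold,
                 karlsson_threshold = karlsson_threshold,
                 kamath_increase = kamath_increase, kamath_decrease = kamath_decrease,
                 acar_threshold = acar_threshold, acar_window = as.integer(acar_window)),
            class = "artifact_rule_config")
}

#' Detect artifact intervals with a beat-rejection rule
#'
#' Malik, Kamath and Acar compare each interval against previously *accepted*
#' intervals (so a burst of ectopics is fully flagged rather than re-anchoring
#' on an artifact); Karlsson compares against the raw previous-and-next
#' neighbours and therefore never flags the first or last interval. The first
#' interval is never flagged by any rule.
#'
#' @param ibi an `ibi_series`.
#' @param config an [artifact_rule_config()].
#' @return integer vector of artifact indices (possibly empty).
#' @export
detect_artifacts <- function(ibi, config = artifact_rule_config()) {
  x <- ibi$interval_ms
  n <- length(x)
  min_n <- if (config$rule == "karlsson") 3L else 2L
  if (n < min_n) stop("need at least ", min_n, " intervals for the ", config$rule, " rule",
                      call. = FALSE)
  flagged <- logical(n)
  if (config$rule == "karlsson") {
    for (i in 2:(n - 1)) {
      m <- (x[i - 1] + x[i + 1]) / 2
      flagged[i] <- abs(x[i] - m) > config$karlsson_threshold * m
    }
  } else if (config$rule == "acar") {
    accepted <- x[1]
    for (i in 2:n) {
      m <- mean(utils::tail(accepted, config$acar_window))
      if (abs(x[i] - m) > config$acar_threshold * m) {
        flagged[i] <- TRUE
      } else {
        accepted <- c(accepted, x[i])
      }
    }
  } else {
    last_acc <- x[1]
    for (i in 2:n) {
      bad <- if (config$rule == "malik") {
        abs(x[i] - last_acc) > config$malik_threshold * last_acc
      } else { # kamath
        (x[i] - last_acc) > config$kamath_increase * last_acc ||
          (last_acc - x[i]) > config$kamath_decrease * last_acc
      }
      if (bad) flagged[i] <- TRUE else last_acc <- x[i]
    }
  }
  which(flagged)
}

#' Replace flagged artifacts by cubic-spline interpolation
#'
#' Flags artifacts with [detect_artifacts()] and replaces them with the value
#' of a cubic spline fitted through the accepted intervals (the replacement
#' strategy used by standard HRV preprocessing software). Accepted values are
#' untouched; replaced slots are flagged `interpolated`.
#'
#' @inheritParams detect_artifacts
#' @return the corrected `ibi_series`, carrying the number of replaced
#'   intervals as attribute `n_artifacts_corrected`.
#' @export
correct_artifacts <- function(ibi, config = artifact_rule_config()) {
  bad <- detect_artifacts(ibi, config)
  out <- ibi
  if (length(bad)) {
    good <- setdiff(seq_len(nrow(ibi)), bad)
    if (length(good) < 4L) {
      stop("only ", length(good), " accepted intervals remain; ",
           "cubic-spline replacement needs >= 4 (consider a laxer rule)", call. = FALSE)
    }
    fit <- stats::spline(good, ibi$interval_ms[good], xout = bad, method = "fmm")
    out$interval_ms[bad] <- fit$y
    out$flag[bad] <- "interpolated"
  }
  attr(out, "n_artifacts_corrected") <- length(bad)
  out
}

#' Choose the artifact rule whose corrected HRV best matches a reference
#'
#' Applies each candidate rule to every subject's IBI series, computes the
#' requested HRV indices from the corrected series, and scores each rule by
#' R-squared (squared Pearson correlation) between the per-subject corrected
#' index vector and the reference index vector, averaged over metrics. The
#' rule with the highest mean R-squared wins; ties break in the order malik,
#' karlsson, kamath, acar.
#'
#' @param ibi_list list of `ibi_series`, one per subject.
#' @param reference_hrv data frame with one row per subject holding reference
#'   values of the metrics (columns named as in [compute_hrv_summary()]).
#' @param rules candidate rule names.
#' @param metrics metric columns to compare.
#' @param segment_minutes segment length for the segmented indices.
#' @return list with `best_rule` and `scores`, a tibble of per-rule mean and
#'   per-metric R-squared.
#' @export
select_correction_rule <- function(ibi_list, reference_hrv,
                                   rules = c("malik", "karlsson", "kamath", "acar"),
                                   metrics = c("sdnn", "rmssd", "pnn50"),
                                   segment_minutes = 5) {
  n_subj <- length(ibi_list)
  if (n_subj < 3L) warning("fewer than 3 subjects: R-squared rule ranking is unstable")
  scores <- purrr::map_dfr(rules, function(rule) {
    cfg <- artifact_rule_config(rule)
    corrected <- purrr::map(ibi_list, function(ib) {
      tryCatch(correct_artifacts(ib, cfg), error = function(e) ib)
    })
    summ <- purrr::map_dfr(corrected, compute_hrv_summary, segment_minutes = segment_minutes)
    r2 <- vapply(metrics, function(m) {
      tryCatch(r_squared(summ[[m]], reference_hrv[[m]]), error = function(e) NA_real_)
    }, numeric(1))
    tibble::tibble(rule = rule, mean_r_squared = mean(r2, na.rm = TRUE),
                   !!!stats::setNames(as.list(r2), paste0("r2_", metrics)))
  })
  best <- scores$rule[which.max(scores$mean_r_squared)]
  list(best_rule = best, scores = scores)
}
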