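#' @name imputation
#' @title Gap-filling methods for uniform heart-rate series
#'
#' @description
#' Eleven classical univariate gap-filling methods operate on the regular
#' grid produced by [resample_uniform()]. All methods leave observed values
#' untouched and return a complete series:
#'
#' * `mean` — every gap gets the series mean;
#' * `ffill` / `bfill` — last/next valid observation propagated;
#' * `linear` — straight line between the gap's anchors;
#' * `spline2` — local quadratic through the three nearest anchors;
#' * `spline3` — global cubic interpolating spline;
#' * `pchip` — shape-preserving piecewise cubic Hermite interpolation;
#' * `akima` — Akima's locally determined piecewise cubic;
#' * `ewma` — exponentially weighted mean of prior observations (span
#'   `ewma_span`, forward pass);
#' * `nearest` — value of the closest observed slot (ties to the earlier);
#' * `knn_mean` — mean of the `k` nearest observed slots by time distance.
#'
#' Methods that cannot reach a slot (a leading gap for `ffill`, a trailing
#' one for `bfill`, slots outside the anchor range for the polynomial
#' interpolants) fall back to `nearest` so the output is always complete.
NULL

IMPUTE_METHODS <- c("mean", "ffill", "bfill", "linear", "spline2", "spline3",
                    "pchip", "akima", "ewma", "nearest", "knn_mean")

min_anchors_for <- function(method) {
  switch(method, spline2 = 3L, spline3 = 4L, akima = 5L, pchip = 2L, 2L)
}

impute_values <- function(x, method, k = 5L, ewma_span = 5) {
  n <- length(x)
  obs <- which(!is.na(x))
  gap <- which(is.na(x))
  if (length(gap) == 0L) return(x)
  need <- min_anchors_for(method)
  if (length(obs) < need) {
    stop("method '", method, "' needs at least ", need, " observed values (got ",
         length(obs), ")", call. = FALSE)
  }
  y <- x
  nearest_of <- function(targets) {
    vapply(targets, function(i) {
      d <- abs(obs - i)
      x[obs[order(d, obs)[1]]]
    }, numeric(1))
  }
  fill <- switch(
    method,
    mean = rep(mean(x[obs]), length(gap)),
    ffill = {
      v <- zoo::na.locf(x, na.rm = FALSE)
      v[is.na(v)] <- nearest_of(which(is.na(v)))
      v[gap]
    },
    bfill = {
      v <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
      v[is.na(v)] <- nearest_of(which(is.na(v)))
      v[gap]
    },
    linear = {
      v <- stats::approx(obs, x[obs], xout = gap, rule = 2)$y
      v
    },
    spline2 = vapply(gap, function(i) {
      a <- obs[order(abs(obs - i), obs)][1:3]
      a <- sort(a)
      # Lagrange quadratic through the three nearest anchors
      l <- vapply(1:3, function(j) {
        others <- a[-j]
        prod((i - others) / (a[j] - others))
      }, numeric(1))
      sum(l * x[a])
    }, numeric(1)),
    spline3 = stats::spline(obs, x[obs], xout = gap, method = "fmm")$y,
    pchip = pracma::pchip(obs, x[obs], pmin(pmax(gap, min(obs)), max(obs))),
    akima = pracma::akimaInterp(obs, x[obs], pmin(pmax(gap, min(obs)), max(obs))),
    ewma = {
      alpha <- 2 / (ewma_span + 1)
      num <- 0; den <- 0
      v <- numeric(n)
      has <- FALSE
      out <- x
      for (i in seq_len(n)) {
        if (is.na(out[i])) {
          out[i] <- if (has) num / den else NA_real_
        }
        if (!is.na(x[i])) {
          num <- (1 - alpha) * num + x[i]
          den <- (1 - alpha) * den + 1
          has <- TRUE
        }
      }
      if (anyNA(out)) out[is.na(out)] <- nearest_of(which(is.na(out)))
      out[gap]
    },
    nearest = nearest_of(gap),
    knn_mean = vapply(gap, function(i) {
      a <- obs[order(abs(obs - i), obs)][seq_len(min(k, length(obs)))]
      mean(x[a])
    }, numeric(1)),
    stop("unknown imputation method: ", method, call. = FALSE)
  )
  y[gap] <- fill
  y
}

#' Fill the gaps of a heart-rate series
#'
#' @param series a uniform `hr_series` with `NA` gaps (see
#'   [resample_uniform()]), or a plain numeric vector with `NA`s.
#' @param method one of the eleven methods listed under [imputation].
#' @param k neighbour count for `knn_mean` (see [select_k_for_knn()]).
#' @param ewma_span span (slots) of the exponential weights for `ewma`.
#' @return a complete series of the same type and length; observed values
#'   are returned unchanged by every method.
#' @export
impute <- function(series, method = "pchip", k = 5L, ewma_span = 5) {
  method <- match.arg(method, IMPUTE_METHODS)
  if (is.data.frame(series)) {
    series$hr_bpm <- impute_values(series$hr_bpm, method, k = k, ewma_span = ewma_span)
    series
  } else {
    impute_values(as.numeric(series), method, k = k, ewma_span = ewma_span)
  }
}

#' Randomly remove slots from a complete series
#'
#' Emulates wrist-device dropouts on a complete reference series: exactly
#' `round(fraction * n)` slots are blanked, drawn as runs whose lengths are
#' geometric with the stated mean, so gaps cluster the way real dropouts do.
#' The first and last slots are never removed (every interpolant keeps its
#' anchors). Reproducible under `seed`.
#'
#' @param series a complete uniform `hr_series` or numeric vector.
#' @param fraction fraction of slots to blank, in (0, 1).
#' @param mean_gap_len mean run length in slots.
#' @param seed integer seed.
#' @return list with `series` (gappy copy) and `mask` (sorted missing
#'   indices, with the seed as attribute).
#' @export
inject_missingness <- function(series, fraction, mean_gap_len = 3, seed = 1L) {
  x <- if (is.data.frame(series)) series$hr_bpm else as.numeric(series)
  n <- length(x)
  if (anyNA(x)) stop("inject_missingness requires a complete series", call. = FALSE)
  m <- round(fraction * n)
  if (fraction <= 0 || fraction >= 1 || m < 1 || m > n - 2L) {
    stop("fraction must leave at least the two boundary slots and remove >= 1", call. = FALSE)
  }
  mask <- withr::with_seed(seed, {
    miss <- logical(n)
    guard <- 0L
    # runs are placed with a one-slot buffer so they do not merge and the
    # realised run lengths keep the stated geometric distribution
    while (sum(miss) < m && guard < 100000L) {
      guard <- guard + 1L
      len <- 1L + stats::rgeom(1L, prob = 1 / mean_gap_len)
      len <- min(len, m - sum(miss))
      start <- sample(2:(n - 1L), 1L)
      run <- start:min(start + len - 1L, n - 1L)
      buffer <- max(2L, start - 1L):min(n - 1L, start + len)
      if (!any(miss[buffer])) miss[run] <- TRUE
    }
    if (sum(miss) < m) { # dense masks: fall back to single-slot fills
      free <- setdiff(which(!miss), c(1L, n))
      extra <- sample(free, m - sum(miss))
      miss[extra] <- TRUE
    }
    which(miss)
  })
  attr(mask, "seed") <- seed
  if (is.data.frame(series)) {
    out <- series
    out$hr_bpm[mask] <- NA_real_
  } else {
    out <- x
    out[mask] <- NA_real_
  }
  list(series = out, mask = mask)
}

#' Pick k for the k-nearest-slot mean imputer
#'
#' Runs `knn_mean` for every candidate `k` and returns the one with the
#' smallest RMSE on the masked slots against the held-out true values; ties
#' go to the smallest `k`.
#'
#' @param series gappy series (vector or `hr_series`).
#' @param truth true values at the masked slots.
#' @param mask indices of the masked slots.
#' @param k_grid candidate neighbour counts.
#' @return the winning `k` (integer).
#' @export
select_k_for_knn <- function(series, truth, mask, k_grid = c(1L, 2L, 3L, 5L, 7L, 10L)) {
  if (length(k_grid) == 0L) stop("empty k grid", call. = FALSE)
  x <- if (is.data.frame(series)) series$hr_bpm else as.numeric(series)
  errs <- vapply(k_grid, function(k) {
    filled <- impute_values(x, "knn_mean", k = k)
    rmse(filled[mask], truth)
  }, numeric(1))
  k_grid[order(errs, k_grid)[1]]
}

#' Benchmark imputation methods by masked-slot RMSE
#'
#' Injects gaps into a complete reference series, fills them with each
#' method, and scores each by RMSE over the injected-missing slots only
#' (untouched observations cannot dilute the score). Methods that fail
#' (e.g. too few anchors) are recorded with `NA` RMSE and the error message
#' rather than aborting the run.
#'
#' @param series complete reference `hr_series` or numeric vector.
#' @param methods methods to benchmark (default: all eleven).
#' @param fraction,mean_gap_len,seed passed to [inject_missingness()].
#' @param k,ewma_span method parameters, see [impute()].
#' @return a tibble of class `imputation_benchmark` sorted ascending by RMSE
#'   with columns `method`, `rmse`, `error`; the missing fraction, seed and
#'   mask are attached as attributes.
#' @export
benchmark_imputation <- function(series, methods = IMPUTE_METHODS,
                                 fraction = 0.1, mean_gap_len = 3, seed = 1L,
                                 k = 5L, ewma_span = 5) {
  methods <- match.arg(methods, IMPUTE_METHODS, several.ok = TRUE)
  x <- if (is.data.frame(series)) series$hr_bpm else as.numeric(series)
  inj <- inject_missingness(x, fraction, mean_gap_len = mean_gap_len, seed = seed)
  truth <- x[inj$mask]
  rows <- purrr::map_dfr(methods, function(m) {
    res <- tryCatch(
      tibble::tibble(method = m,
                     rmse = rmse(impute_values(inj$series, m, k = k,
                                               ewma_span = ewma_span)[inj$mask], truth),
                     error = NA_character_),
      error = function(e) tibble::tibble(method = m, rmse = NA_real_,
                                         error = conditionMessage(e)))
    res
  })
  out <- rows[order(is.na(rows$rmse), rows$rmse), ]
  attr(out, "missing_fraction") <- fraction
  attr(out, "seed") <- seed
  attr(out, "mask") <- inj$mask
  class(out) <- c("imputation_benchmark", class(out))
  out
}
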