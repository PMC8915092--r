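#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root test on a complete heart-rate series, in the configuration
#' standard for this diagnostic: the test regression includes a constant
#' (no deterministic trend), the augmentation lag order is selected by AIC
#' over 0..`max_lag` (default the usual 12 * (n/100)^0.25 ceiling), and the
#' p-value is interpolated from the finite-sample distribution of the
#' constant-only Dickey-Fuller t statistic (tau_mu). p-values outside the
#' tabulated range are clipped to 0.01 / 0.99.
#'
#' @param series complete `hr_series` or numeric vector, length >= 20.
#' @param max_lag maximum augmentation lag considered by AIC.
#' @return list with `statistic`, `p_value`, `lag_order` and
#'   `stationary_at_5pct` (`TRUE` when `p_value < 0.05`, i.e. the unit root
#'   is rejected).
#' @export
adf_stationarity <- function(series, max_lag = NULL) {
  y <- if (is.data.frame(series)) series$hr_bpm else as.numeric(series)
  if (anyNA(y)) stop("series has missing values; impute before testing", call. = FALSE)
  n <- length(y)
  if (n < 20L) stop("need at least 20 observations", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant series: stationarity test undefined", call. = FALSE)
  if (is.null(max_lag)) max_lag <- min(floor(12 * (n / 100)^0.25), floor(n / 3) - 2L)
  max_lag <- max(0L, max_lag)

  dy <- diff(y)
  fit_adf <- function(p) {
    # common estimation sample across candidate lags: rows (max_lag+1)..(n-1)
    idx <- (max_lag + 1L):(n - 1L)
    X <- cbind(1, y[idx])
    if (p > 0) {
      lags <- sapply(seq_len(p), function(j) dy[idx - j])
      X <- cbind(X, lags)
    }
    stats::lm.fit(X, dy[idx])
  }
  aic_of <- function(fit) {
    m <- length(fit$residuals)
    rss <- sum(fit$residuals^2)
    m * log(rss / m) + 2 * (length(fit$coefficients))
  }
  aics <- vapply(0:max_lag, function(p) aic_of(fit_adf(p)), numeric(1))
  p_best <- (0:max_lag)[which.min(aics)]

  # refit on the longest sample for the chosen lag
  idx <- (p_best + 1L):(n - 1L)
  X <- cbind(1, y[idx])
  if (p_best > 0) X <- cbind(X, sapply(seq_len(p_best), function(j) dy[idx - j]))
  fit <- stats::lm.fit(X, dy[idx])
  m <- length(fit$residuals)
  s2 <- sum(fit$residuals^2) / (m - ncol(X))
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se_rho <- sqrt(s2 * XtX_inv[2, 2])
  stat <- fit$coefficients[2] / se_rho

  p_value <- df_tau_mu_pvalue(stat, m)
  list(statistic = unname(stat), p_value = p_value, lag_order = p_best,
       stationary_at_5pct = p_value < 0.05)
}

# Finite-sample quantiles of the Dickey-Fuller tau statistic for the
# constant, no-trend regression (Fuller 1976, Table 8.5.2), interpolated in
# sample size and in the statistic.
df_tau_mu_pvalue <- function(stat, n) {
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  ns <- c(25, 50, 100, 250, 500, 1e5)
  tbl <- rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  )
  quants <- vapply(seq_along(probs), function(j) {
    stats::approx(ns, tbl[, j], xout = min(max(n, 25), 1e5), rule = 2)$y
  }, numeric(1))
  min(max(stats::approx(quants, probs, xout = stat, rule = 2)$y, 0.01), 0.99)
}
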