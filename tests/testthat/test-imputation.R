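test_that("each method fills every gap and never touches observed values", {
  withr::with_seed(3, {
    base <- sine_hr(120)
    inj <- inject_missingness(base, 0.15, seed = 21)
    obs <- setdiff(seq_len(120), inj$mask)
    for (m in c("mean", "ffill", "bfill", "linear", "spline2", "spline3",
                "pchip", "akima", "ewma", "nearest", "knn_mean")) {
      filled <- impute(inj$series, m)
      expect_false(anyNA(filled$hr_bpm), info = m)
      expect_identical(filled$hr_bpm[obs], base$hr_bpm[obs], info = m)
      # complete input: identity
      expect_identical(impute(base, m)$hr_bpm, base$hr_bpm, info = m)
    }
  })
})

test_that("method semantics on hand-checkable gaps", {
  expect_equal(impute(c(1, NA, 3), "linear")[2], 2)
  expect_equal(impute(c(1, NA, 3), "nearest")[2], 1) # tie -> earlier neighbour
  expect_equal(impute(c(1, NA, 3), "mean")[2], 2)
  expect_equal(impute(c(1, NA, 3), "ffill")[2], 1)
  expect_equal(impute(c(1, NA, 3), "bfill")[2], 3)
  expect_equal(impute(c(1, NA, 3), "knn_mean", k = 2)[2], 2)
  # leading gap: ffill falls back to nearest; trailing gap: bfill does
  expect_equal(impute(c(NA, 2, 3), "ffill")[1], 2)
  expect_equal(impute(c(1, 2, NA), "bfill")[3], 2)
  # ewma uses only prior observations
  expect_equal(impute(c(5, 5, NA, 9), "ewma")[3], 5)
  # too few anchors for the requested method errors with the minimum
  expect_error(impute(c(1, NA, 3, NA), "akima"), "at least 5")
  expect_error(impute(c(1, NA, NA), "spline2"), "at least 3")
})

test_that("pchip preserves monotonicity where plain cubic splines overshoot", {
  x <- c(10, 10, 10, 10.5, 80, 85, 85, 85)
  xg <- x
  xg[c(4, 5)] <- NA
  filled <- impute(xg, "pchip")
  expect_false(is.unsorted(filled))
})

test_that("interpolating methods reproduce an exactly linear series", {
  x <- seq(10, 50, length.out = 41)
  inj <- inject_missingness(x, 0.2, seed = 5)
  for (m in c("linear", "spline3", "pchip")) {
    expect_equal(impute(inj$series, m)[inj$mask], x[inj$mask],
                 tolerance = 1e-9, info = m)
  }
})

test_that("inject_missingness removes an exact count, reproducibly, keeping anchors", {
  x <- sine_hr(100)
  inj <- inject_missingness(x, 0.1, seed = 9)
  expect_length(inj$mask, 10L)
  expect_false(1 %in% inj$mask)
  expect_false(100 %in% inj$mask)
  inj2 <- inject_missingness(x, 0.1, seed = 9)
  expect_identical(inj$mask, inj2$mask)
  inj3 <- inject_missingness(x, 0.1, seed = 10)
  expect_false(identical(inj$mask, inj3$mask))
  expect_error(inject_missingness(sine_hr(3), 0.99), "fraction")
})

test_that("select_k_for_knn minimises masked-slot RMSE with ties to smallest k", {
  expect_equal(select_k_for_knn(c(1, NA, 3), truth = 2, mask = 2, k_grid = 1L), 1L)
  # constant series: every k is perfect, smallest wins
  x <- rep(5, 20)
  xg <- x
  xg[10] <- NA
  expect_equal(select_k_for_knn(xg, truth = 5, mask = 10, k_grid = c(4L, 2L, 1L)), 1L)
  expect_error(select_k_for_knn(xg, truth = 5, mask = 10, k_grid = integer(0)), "empty")
})

test_that("benchmark ranks interpolants above mean filling on a smooth series", {
  bench <- benchmark_imputation(sine_hr(900), fraction = 0.1, seed = 7)
  expect_s3_class(bench, "imputation_benchmark")
  expect_false(is.unsorted(bench$rmse[!is.na(bench$rmse)]))
  r <- function(m) bench$rmse[bench$method == m]
  for (m in c("linear", "spline3", "pchip", "akima")) {
    expect_lt(r(m), r("mean"), label = m)
  }
  bench2 <- benchmark_imputation(sine_hr(900), fraction = 0.1, seed = 7)
  expect_identical(bench$rmse, bench2$rmse)
  g <- glance(bench)
  expect_equal(g$missing_fraction, 0.1)
  expect_true(g$best_method %in% c("pchip", "akima", "spline3", "spline2", "linear"))
})

test_that("benchmark records per-method failures instead of aborting", {
  x <- c(60, NA, 62, NA, 64) # complete-series injection happens internally
  short <- hr_series(c(0, 1, 2, 3), c(60, 61, 62, 63), nominal_period_s = 1)
  bench <- benchmark_imputation(short, methods = c("akima", "linear"),
                                fraction = 0.25, seed = 2)
  expect_true(is.na(bench$rmse[bench$method == "akima"]))
  expect_match(bench$error[bench$method == "akima"], "at least 5")
  expect_false(is.na(bench$rmse[bench$method == "linear"]))
})

test_that("ADF flags white noise stationary and a random walk not", {
  # expectations frozen from an independent reference ADF implementation
  # (constant-only regression, AIC lag selection) on these exact fixtures
  withr::with_seed(42, {
    wn <- 70 + rnorm(500)
  })
  withr::with_seed(42, {
    rw <- 70 + cumsum(rnorm(500))
  })
  a <- adf_stationarity(wn)
  expect_true(a$stationary_at_5pct)
  expect_equal(a$statistic, -22.7647, tolerance = 1e-4)
  b <- adf_stationarity(rw)
  expect_false(b$stationary_at_5pct)
  expect_equal(b$statistic, -1.7954, tolerance = 1e-3)
  expect_equal(b$p_value, 0.383, tolerance = 0.05)
  expect_identical(a$stationary_at_5pct, a$p_value < 0.05)

  expect_error(adf_stationarity(c(wn[1:30], NA)), "missing")
  expect_error(adf_stationarity(rep(70, 50)), "constant")
})
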