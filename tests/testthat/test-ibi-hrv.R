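test_that("HR <-> IBI conversion is exact and invertible", {
  expect_equal(hr_to_ibi(hr_series(0, 60))$interval_ms, 1000)
  expect_equal(hr_to_ibi(hr_series(0:1, c(120, 100)))$interval_ms, c(500, 600))
  hr <- c(55.3, 71.2, 88.8)
  expect_equal(ibi_to_hr(hr_to_ibi(hr_series(0:2, hr))), hr, tolerance = 1e-12)
  expect_error(hr_to_ibi(hr_series(0:1, c(60, NA))), "complete")
})

test_that("artifact rules match hand-computed percent changes", {
  kamath <- artifact_rule_config("kamath")
  # +37.5% > 32.5%: flagged; the next interval is judged against accepted 800
  expect_equal(detect_artifacts(ibi_series(c(800, 1100, 800)), kamath), 2L)
  # -22.5% < 24.5%: the asymmetric decrease threshold does not fire
  expect_length(detect_artifacts(ibi_series(c(800, 620, 800)), kamath), 0L)
  # +12.5% < 20%: malik does not fire
  expect_length(detect_artifacts(ibi_series(c(800, 900, 800)),
                                 artifact_rule_config("malik")), 0L)
  expect_equal(detect_artifacts(ibi_series(c(800, 1000, 800)),
                                artifact_rule_config("malik")), 2L)
  # constant series: no rule fires
  const <- ibi_series(rep(800, 10))
  for (r in c("malik", "karlsson", "kamath", "acar")) {
    expect_length(detect_artifacts(const, artifact_rule_config(r)), 0L)
  }
  # karlsson: interior interval vs mean of raw neighbours; ends never flagged
  k <- detect_artifacts(ibi_series(c(800, 1000, 800, 800)),
                        artifact_rule_config("karlsson"))
  expect_equal(k, 2L)
  # burst of ectopics: accepted-interval anchoring flags the whole burst
  burst <- ibi_series(c(800, 1100, 1100, 800))
  expect_equal(detect_artifacts(burst, kamath), c(2L, 3L))
  expect_error(detect_artifacts(ibi_series(800), kamath), "at least 2")
})

test_that("acar compares against the mean of up to the last nine accepted", {
  x <- c(rep(800, 9), 1000, rep(800, 3))
  # mean of last 9 accepted = 800; |1000-800| = 200 > 160 -> flagged
  expect_equal(detect_artifacts(ibi_series(x), artifact_rule_config("acar")), 10L)
  # short history: window shrinks to whatever accepted history exists
  expect_equal(detect_artifacts(ibi_series(c(800, 1000, 800)),
                                artifact_rule_config("acar")), 2L)
})

test_that("cubic-spline replacement only touches flagged slots", {
  ib <- ibi_series(c(800, 1100, 800, 800, 800))
  out <- correct_artifacts(ib, artifact_rule_config("kamath"))
  expect_equal(attr(out, "n_artifacts_corrected"), 1L)
  expect_equal(out$flag, c("normal", "interpolated", "normal", "normal", "normal"))
  expect_gt(out$interval_ms[2], 700)
  expect_lt(out$interval_ms[2], 900)
  expect_identical(out$interval_ms[-2], ib$interval_ms[-2])

  clean <- ibi_series(rep(800, 6))
  same <- correct_artifacts(clean, artifact_rule_config("kamath"))
  expect_identical(same$interval_ms, clean$interval_ms)
  expect_equal(attr(same, "n_artifacts_corrected"), 0L)

  expect_error(correct_artifacts(ibi_series(c(800, 1100, 1150, 1100, 1200)),
                                 artifact_rule_config("malik")), ">= 4")
})

test_that("detect -> correct is idempotent for malik and kamath", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      base <- 800 + 30 * sin(seq_len(300) / 10) + rnorm(300, 0, 10)
      hit <- sample(5:295, 6)
      base[hit] <- base[hit] * 0.6
      for (rule in c("malik", "kamath")) {
        cfg <- artifact_rule_config(rule)
        once <- correct_artifacts(ibi_series(base), cfg)
        twice <- correct_artifacts(ibi_series(once$interval_ms), cfg)
        expect_equal(attr(twice, "n_artifacts_corrected"), 0L,
                     info = paste(rule, rep))
      }
    }
  })
})

test_that("HRV summary matches definitional arithmetic", {
  s <- compute_hrv_summary(ibi_series(c(800, 800, 800)))
  expect_equal(s$sdnn, 0)
  expect_equal(s$rmssd, 0)
  expect_equal(s$pnn50, 0)
  expect_equal(compute_hrv_summary(ibi_series(c(800, 850, 800)))$rmssd, 50)
  # strict > 50 ms
  expect_equal(compute_hrv_summary(ibi_series(c(800, 851, 800)))$pnn50, 100)
  expect_equal(compute_hrv_summary(ibi_series(c(800, 850, 800)))$pnn50, 0)
  # 10 minutes at constant HR: two equal segment means
  ten_min <- ibi_series(rep(1000, 600))
  s10 <- compute_hrv_summary(ten_min)
  expect_equal(s10$sdann, 0)
  expect_equal(s10$sdnn_index, 0)
  expect_equal(s10$min_hr, 60)
  expect_equal(s10$max_hr, 60)
  # fewer than two complete segments: undefined
  expect_true(is.na(compute_hrv_summary(ibi_series(rep(1000, 400)))$sdann))
  expect_error(compute_hrv_summary(ibi_series(800)), "at least 2")
})

test_that("HRV metrics agree with the brute-force oracle", {
  withr::with_seed(14, {
    for (rep in 1:25) {
      n <- sample(50:1200, 1)
      x <- runif(n, 500, 1200)
      s <- compute_hrv_summary(ibi_series(x))
      o <- oracle_hrv(x)
      expect_equal(s$sdnn, o$sdnn, tolerance = 1e-9)
      expect_equal(s$rmssd, o$rmssd, tolerance = 1e-9)
      expect_equal(s$pnn50, o$pnn50, tolerance = 1e-9)
      expect_equal(s$sdann, o$sdann, tolerance = 1e-9)
      expect_equal(s$sdnn_index, o$sdnn_index, tolerance = 1e-9)
    }
  })
})

test_that("scale equivariance holds for the ms indices but not pNN50", {
  withr::with_seed(2, {
    x <- runif(1500, 600, 1100)
    s1 <- compute_hrv_summary(ibi_series(x))
    s2 <- compute_hrv_summary(ibi_series(2 * x), segment_minutes = 10)
    expect_equal(s2$sdnn, 2 * s1$sdnn)
    expect_equal(s2$rmssd, 2 * s1$rmssd)
    # segmented indices scale once the segment length scales with the units
    expect_equal(s2$sdann, 2 * s1$sdann)
    expect_equal(s2$sdnn_index, 2 * s1$sdnn_index)
    expect_false(isTRUE(all.equal(s2$pnn50, s1$pnn50)))
    # sdnn permutation-invariant, rmssd order-sensitive
    y <- c(800, 860, 800, 860, 800, 860)
    yperm <- c(800, 800, 800, 860, 860, 860)
    expect_equal(compute_hrv_summary(ibi_series(y))$sdnn,
                 compute_hrv_summary(ibi_series(yperm))$sdnn)
    expect_false(isTRUE(all.equal(compute_hrv_summary(ibi_series(y))$rmssd,
                                  compute_hrv_summary(ibi_series(yperm))$rmssd)))
  })
})

test_that("rule selection prefers a correcting rule on ectopic-laden data", {
  withr::with_seed(31, {
    clean <- list()
    dirty <- list()
    for (j in 1:6) {
      x <- 800 + 40 * sin(seq_len(500) / 15) + rnorm(500, 0, 8) + j * 15
      clean[[j]] <- x
      xe <- x
      hit <- seq(20, 480, by = 60) + j
      xe[hit] <- xe[hit] * 0.55
      xe[hit + 1] <- xe[hit + 1] * 1.45
      dirty[[j]] <- ibi_series(xe)
    }
    ref <- purrr::map_dfr(clean, ~ compute_hrv_summary(ibi_series(.x)))
    sel <- select_correction_rule(dirty, ref)
    expect_true(sel$best_rule %in% c("malik", "karlsson", "kamath", "acar"))
    expect_equal(nrow(sel$scores), 4L)
    # identical indices give R^2 = 1
    perfect <- purrr::map(clean, ~ ibi_series(.x))
    sel2 <- select_correction_rule(perfect, ref)
    expect_equal(sel2$scores$mean_r_squared, rep(1, 4), tolerance = 1e-9)
    expect_equal(sel2$best_rule, "malik") # tie -> declared rule order
    # single rule supplied: returned as-is
    expect_equal(select_correction_rule(dirty, ref, rules = "kamath")$best_rule,
                 "kamath")
  })
  expect_warning(
    select_correction_rule(list(ibi_series(rep(800, 310) + rep(c(0, 30), 155)),
                                ibi_series(rep(820, 310) + rep(c(0, 25), 155))),
                           tibble::tibble(sdnn = c(15, 13), rmssd = c(30, 25),
                                          pnn50 = c(0, 0))),
    "unstable")
})
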