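test_that("rmse matches hand arithmetic and is homogeneous", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  withr::with_seed(1, {
    a <- rnorm(50)
    b <- rnorm(50)
    expect_equal(rmse(b + 2 * (a - b), b), 2 * rmse(a, b))
  })
  expect_error(rmse(1:3, 1:4), "mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("r_squared is the squared Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(x, -x), 1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), stats::cor(c(1, 2, 3), c(1, 2, 4))^2)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.9642857, tolerance = 1e-6)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(r_squared(c(1, 2), c(1, 2)), "at least 3")
})

test_that("paired t matches the closed form and base R", {
  res <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t, 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2L)
  expect_equal(res$p_two_tailed, 0.0741799, tolerance = 1e-6)

  withr::with_seed(5, {
    a <- rnorm(12, 75, 8)
    b <- a + rnorm(12, 1, 2)
    mine <- paired_t_test(a, b)
    base <- stats::t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(base$statistic), tolerance = 1e-12)
    expect_equal(mine$p_two_tailed, base$p.value, tolerance = 1e-12)
    # antisymmetry in t, p unchanged
    rev <- paired_t_test(b, a)
    expect_equal(rev$t, -mine$t)
    expect_equal(rev$p_two_tailed, mine$p_two_tailed)
  })
  # constant positive shift with zero-mean perturbation: t positive
  a <- c(10, 11, 12, 13)
  expect_gt(paired_t_test(a + 2 + c(-0.1, 0.1, -0.1, 0.1), a)$t, 0)
  # antisymmetric differences: t = 0, p = 1
  null <- paired_t_test(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(null$t, 0)
  expect_equal(null$p_two_tailed, 1)
  expect_error(paired_t_test(c(1, 2), c(0, 1)), "zero-variance")
  expect_error(paired_t_test(1, 1), "at least 2")
})

test_that("t critical values reproduce the one-tailed table", {
  expect_equal(t_critical(0.95, 9), 1.833, tolerance = 5e-4)
  expect_equal(t_critical(0.99, 9), 2.821, tolerance = 5e-4)
  expect_equal(t_critical(0.975, 9), 2.262, tolerance = 5e-4)
  # strictly increasing in confidence, strictly decreasing in df
  confs <- c(0.8, 0.9, 0.95, 0.99)
  expect_false(is.unsorted(t_critical(confs, 9), strictly = TRUE))
  dfs <- c(2, 5, 9, 30, 100)
  expect_false(is.unsorted(rev(t_critical(0.95, dfs)), strictly = TRUE))
  expect_error(t_critical(1.2, 9), "confidence")
  expect_error(t_critical(0.95, 0), "df")
})

test_that("two-tailed p at the one-tailed critical value equals 2*alpha", {
  for (alpha in c(0.05, 0.01, 0.025)) {
    for (df in c(5, 9, 20)) {
      tc <- t_critical(1 - alpha, df)
      p <- 2 * stats::pt(-abs(tc), df)
      expect_equal(p, 2 * alpha, tolerance = 1e-6)
    }
  }
})

test_that("compare_platforms builds the per-metric table with df = n - 1", {
  withr::with_seed(77, {
    pipe <- tibble::tibble(subject_id = sprintf("S%02d", 1:10),
                           sdnn = rnorm(10, 45, 8),
                           rmssd = rnorm(10, 30, 6),
                           pnn50 = runif(10, 5, 30))
    ref <- pipe
    ref$sdnn <- ref$sdnn + rnorm(10, 0, 1)
    ref$rmssd <- ref$rmssd + rnorm(10, 0, 1)
    ref$pnn50 <- ref$pnn50 + rnorm(10, 0, 1)
    cmp <- compare_platforms(pipe, ref)
    expect_equal(nrow(cmp), 3L)
    expect_equal(cmp$df, rep(9L, 3))
    expect_equal(cmp$critical_t_95, rep(t_critical(0.95, 9), 3))
    expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
    expect_identical(cmp$decision, ifelse(cmp$p_value < 0.05,
                                          "difference", "no_difference"))
    # a large constant offset (10x the within-subject sd) must be detected
    shifted <- ref
    shifted$sdnn <- shifted$sdnn + 10 * stats::sd(pipe$sdnn - ref$sdnn)
    cmp2 <- compare_platforms(pipe, shifted, metrics = "sdnn")
    expect_identical(cmp2$decision, "difference")
    # bit-identical pipelines: reported as exact agreement
    cmp3 <- compare_platforms(pipe, pipe, metrics = "sdnn")
    expect_equal(cmp3$t_value, 0)
    expect_equal(cmp3$p_value, 1)
    # subject mismatch is an error
    reordered <- ref[c(2, 1, 3:10), ]
    expect_error(compare_platforms(pipe, reordered), "mismatch")
  })
})

test_that("boxplot summaries are five-number summaries of each group", {
  pipe <- tibble::tibble(sdnn = c(10, 20, 30, 40, 50))
  ref <- tibble::tibble(sdnn = c(11, 22, 31, 43, 51))
  cmp <- compare_platforms(pipe, ref, metrics = "sdnn")
  box <- cmp$box_pipeline[[1]]
  expect_equal(box$min, 10)
  expect_equal(box$median, 30)
  expect_equal(box$max, 50)
  expect_equal(cmp$box_reference[[1]]$median, 31)
  expect_equal(cmp$box_reference[[1]]$max, 51)
})
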