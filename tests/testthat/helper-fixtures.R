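# Shared fixtures, built in code at test time.

# Smooth sinusoidal heart-rate series on a 1 s grid (reference-grade:
# complete, slowly varying).
sine_hr <- function(n = 900, baseline = 70, amplitude = 5, period_s = 12) {
  t <- seq_len(n) - 1
  hr_series(t, baseline + amplitude * sin(2 * pi * t / period_s),
            device = "reference", nominal_period_s = 1)
}

# Brute-force loop implementations of the time-domain indices, kept
# deliberately naive and independent of compute_hrv_summary().
oracle_hrv <- function(x, segment_minutes = 5) {
  n <- length(x)
  mu <- sum(x) / n
  sdnn <- sqrt(sum((x - mu)^2) / (n - 1))
  ssd <- 0
  nn50 <- 0
  for (i in 2:n) {
    d <- x[i] - x[i - 1]
    ssd <- ssd + d^2
    if (abs(d) > 50) nn50 <- nn50 + 1
  }
  rmssd <- sqrt(ssd / (n - 1))
  pnn50 <- 100 * nn50 / (n - 1)
  # segment membership by cumulative elapsed time of the interval start
  seg_len_ms <- segment_minutes * 60000
  start <- 0
  seg_id <- integer(n)
  for (i in seq_len(n)) {
    seg_id[i] <- floor(start / seg_len_ms)
    start <- start + x[i]
  }
  n_complete <- floor(sum(x) / seg_len_ms)
  means <- c(); sds <- c()
  for (s in unique(seg_id[seg_id < n_complete])) {
    seg <- x[seg_id == s]
    means <- c(means, mean(seg))
    sds <- c(sds, stats::sd(seg))
  }
  if (length(means) >= 2) {
    sdann <- stats::sd(means)
    sdnni <- mean(sds)
  } else {
    sdann <- NA_real_
    sdnni <- NA_real_
  }
  list(sdnn = sdnn, rmssd = rmssd, pnn50 = pnn50, sdann = sdann, sdnn_index = sdnni)
}

# Tiny two-subject paired dataset with a known linear relationship.
toy_pairs <- function(n_per_subject = 120, noise_sd = 1, intercept = 2, seed = 42) {
  withr::with_seed(seed, {
    purrr::map_dfr(c("A", "B"), function(id) {
      w <- 70 + 5 * sin(2 * pi * seq_len(n_per_subject) / 40) + rnorm(n_per_subject)
      tibble::tibble(subject_id = id, time_s = seq_len(n_per_subject),
                     wrist_hr = w,
                     reference_hr = w + intercept + rnorm(n_per_subject, 0, noise_sd))
    })
  })
}
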