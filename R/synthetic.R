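#' Subject profile for the synthetic generator
#'
#' Parameters of one simulated resting recording. The generated reference
#' heart rate is `baseline + rsa_amplitude * sin(2*pi*t / rsa_period_s) +
#' trend(t) + AR(1) noise`: a respiratory-sinus-arrhythmia-like oscillation
#' on top of an autocorrelated noise process, with a slow linear drift
#' (`trend_bpm` over the whole recording) that reproduces the
#' non-stationarity real resting recordings show under a unit-root test.
#'
#' @param subject_id label.
#' @param baseline_hr resting baseline in bpm.
#' @param rsa_amplitude amplitude of the respiratory oscillation, bpm.
#' @param rsa_period_s period of the oscillation, seconds (~1 breath).
#' @param ar_coefficient AR(1) coefficient in \[0, 1) of the noise process.
#' @param process_noise_sd innovation standard deviation, bpm.
#' @param trend_bpm total linear drift over the recording, bpm.
#' @param duration_s recording length, seconds (default 900 — a ~15-minute
#'   seated rest).
#' @param period_s sampling period, seconds.
#' @param seed integer seed.
#' @return a list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S1", baseline_hr = 70,
                            rsa_amplitude = 4, rsa_period_s = 12,
                            ar_coefficient = 0.8, process_noise_sd = 1,
                            trend_bpm = 2, duration_s = 900, period_s = 1,
                            seed = 1L) {
  stopifnot(baseline_hr > 20, baseline_hr < 260, ar_coefficient >= 0,
            ar_coefficient < 1, duration_s > 0, period_s > 0)
  structure(list(subject_id = subject_id, baseline_hr = baseline_hr,
                 rsa_amplitude = rsa_amplitude, rsa_period_s = rsa_period_s,
                 ar_coefficient = ar_coefficient, process_noise_sd = process_noise_sd,
                 trend_bpm = trend_bpm, duration_s = duration_s,
                 period_s = period_s, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Degradation profile turning a reference series into a wrist-like one
#'
#' Phenomenological model of wrist-PPG error relative to a chest strap:
#' a constant bias, additive Gaussian measurement noise, clustered dropouts
#' (via [inject_missingness()]) and ectopic-beat-like events, each modelled
#' as one shortened pseudo-interval followed by a compensatory lengthened
#' one — the canonical premature-beat signature the artifact rules target.
#'
#' @param additive_bias constant offset, bpm.
#' @param measurement_noise_sd Gaussian noise SD, bpm.
#' @param missing_fraction fraction of slots dropped (0 disables gaps).
#' @param mean_gap_len mean dropout run length, slots.
#' @param ectopic_rate per-interval probability of an ectopic event.
#' @param ectopic_shortening fractional shortening of the ectopic interval
#'   in (0, 1); the next interval is lengthened by the same fraction.
#' @param seed integer seed.
#' @return a list of class `degradation_profile`.
#' @export
degradation_profile <- function(additive_bias = 0, measurement_noise_sd = 0,
                                missing_fraction = 0, mean_gap_len = 3,
                                ectopic_rate = 0, ectopic_shortening = 0.4,
                                seed = 1L) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1,
            ectopic_rate >= 0, ectopic_rate <= 1,
            ectopic_shortening > 0, ectopic_shortening < 1)
  structure(list(additive_bias = additive_bias,
                 measurement_noise_sd = measurement_noise_sd,
                 missing_fraction = missing_fraction, mean_gap_len = mean_gap_len,
                 ectopic_rate = ectopic_rate, ectopic_shortening = ectopic_shortening,
                 seed = as.integer(seed)),
            class = "degradation_profile")
}

#' Named degradation presets
#'
#' `none` is the identity; `mild` adds 1 bpm noise, 10% clustered dropouts
#' and a 2% ectopic rate; `heavy` doubles the noise and dropout burden.
#'
#' @param preset `"none"`, `"mild"` or `"heavy"`.
#' @param seed integer seed.
#' @return a [degradation_profile()].
#' @export
degradation_preset <- function(preset = c("none", "mild", "heavy"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    none = degradation_profile(seed = seed),
    mild = degradation_profile(measurement_noise_sd = 1, missing_fraction = 0.1,
                               ectopic_rate = 0.02, seed = seed),
    heavy = degradation_profile(additive_bias = 2, measurement_noise_sd = 2,
                                missing_fraction = 0.2, mean_gap_len = 5,
                                ectopic_rate = 0.05, seed = seed))
}

#' Simulate a chest-strap-like reference recording
#'
#' Generates the clean reference heart-rate series for one subject along
#' with its ground-truth pseudo-IBI series and ground-truth HRV summary
#' (computed on the clean intervals). Fully reproducible under the
#' profile's seed. If the composed series leaves the plausibility band the
#' noise is redrawn (up to 20 attempts) before erroring.
#'
#' @param profile a [subject_profile()].
#' @param band plausibility band in bpm.
#' @return list with `reference` (`hr_series`), `ground_truth_ibi`
#'   (`ibi_series`) and `ground_truth_hrv` (one-row `hrv_summary`).
#' @export
simulate_reference <- function(profile, band = c(20, 260)) {
  n <- floor(profile$duration_s / profile$period_s)
  t <- seq(0, by = profile$period_s, length.out = n)
  det <- profile$baseline_hr +
    profile$rsa_amplitude * sin(2 * pi * t / profile$rsa_period_s) +
    profile$trend_bpm * t / max(t[n], 1)
  hr <- withr::with_seed(profile$seed, {
    for (attempt in 1:20) {
      noise <- if (profile$process_noise_sd > 0) {
        as.numeric(stats::arima.sim(list(ar = profile$ar_coefficient), n = n,
                                    sd = profile$process_noise_sd))
      } else rep(0, n)
      cand <- det + noise
      if (all(cand > band[1] & cand < band[2])) break
      cand <- NULL
    }
    if (is.null(cand)) stop("could not generate a series inside the plausibility band",
                            call. = FALSE)
    cand
  })
  reference <- hr_series(t, hr, subject_id = profile$subject_id,
                         device = "reference", nominal_period_s = profile$period_s,
                         band = band)
  gt_ibi <- hr_to_ibi(reference)
  list(reference = reference,
       ground_truth_ibi = gt_ibi,
       ground_truth_hrv = compute_hrv_summary(gt_ibi))
}

#' Degrade a reference recording into a wrist-like recording
#'
#' Applies, in order: additive bias, Gaussian measurement noise, ectopic
#' events (a shortened pseudo-interval followed by a compensatory lengthened
#' one, applied in interval space and mapped back to heart rate), then
#' clustered dropouts. With an all-zero profile the wrist series equals the
#' reference bit-for-bit.
#'
#' @param reference an `hr_series` from [simulate_reference()].
#' @param degradation a [degradation_profile()].
#' @return a wrist `hr_series` on the same grid, possibly with `NA` gaps.
#' @export
degrade_to_wrist <- function(reference, degradation = degradation_profile()) {
  hr <- reference$hr_bpm
  n <- length(hr)
  hr <- withr::with_seed(degradation$seed, {
    if (degradation$additive_bias != 0) hr <- hr + degradation$additive_bias
    if (degradation$measurement_noise_sd > 0) {
      hr <- hr + stats::rnorm(n, 0, degradation$measurement_noise_sd)
    }
    if (degradation$ectopic_rate > 0) {
      ibi <- 60000 / hr
      hit <- which(stats::runif(n - 1L) < degradation$ectopic_rate)
      # drop events whose compensatory partner collides with the next event
      hit <- hit[c(TRUE, diff(hit) > 1L)]
      s <- degradation$ectopic_shortening
      ibi[hit] <- ibi[hit] * (1 - s)
      ibi[hit + 1L] <- ibi[hit + 1L] * (1 + s)
      hr <- 60000 / ibi
    }
    hr
  })
  if (degradation$missing_fraction > 0) {
    hr <- inject_missingness(hr, degradation$missing_fraction,
                             mean_gap_len = degradation$mean_gap_len,
                             seed = degradation$seed)$series
  }
  out <- hr_series(reference$time_s, hr, subject_id = reference$subject_id[1],
                   device = "wrist", nominal_period_s = nominal_period(reference),
                   band = attr(reference, "band") %||% c(20, 260),
                   on_band_violation = "missing")
  out
}

#' Simulate a paired-device cohort with known ground truth
#'
#' Draws per-subject profiles uniformly within `profile_ranges` (defaults
#' reflect older adults at seated rest: baseline 60-90 bpm, respiratory
#' oscillation 2-6 bpm with a 8-15 s period), simulates each reference
#' recording and degrades it into the paired wrist recording. All
#' per-subject seeds derive deterministically from `master_seed`.
#'
#' @param n_subjects number of subjects (>= 2), default 10.
#' @param degradation a [degradation_profile()] or preset name.
#' @param profile_ranges named list of `c(lo, hi)` ranges for `baseline_hr`,
#'   `rsa_amplitude`, `rsa_period_s`, `ar_coefficient`, `process_noise_sd`.
#' @param duration_s,period_s recording length and sampling period.
#' @param master_seed integer seed for the whole cohort.
#' @return a list of class `hrv_cohort`: `subjects` (profile tibble),
#'   `reference` / `wrist` (named lists of `hr_series`),
#'   `ground_truth_ibi` (named list) and `ground_truth_hrv` (tibble with
#'   `subject_id`).
#' @export
make_cohort <- function(n_subjects = 10,
                        degradation = degradation_profile(),
                        profile_ranges = list(baseline_hr = c(60, 90),
                                              rsa_amplitude = c(2, 6),
                                              rsa_period_s = c(8, 15),
                                              ar_coefficient = c(0.7, 0.9),
                                              process_noise_sd = c(0.5, 1.5)),
                        duration_s = 900, period_s = 1, master_seed = 1L) {
  if (is.character(degradation)) degradation <- degradation_preset(degradation,
                                                                   seed = master_seed)
  if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  for (r in profile_ranges) if (r[2] < r[1]) stop("invalid profile range", call. = FALSE)
  draws <- withr::with_seed(master_seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, 2L * n_subjects),
         u = matrix(stats::runif(5L * n_subjects), nrow = n_subjects))
  })
  ids <- sprintf("S%02d", seq_len(n_subjects))
  rng <- function(j, range) range[1] + draws$u[j, ] * (range[2] - range[1])
  profiles <- purrr::map(seq_len(n_subjects), function(j) {
    u <- draws$u[j, ]
    subject_profile(
      subject_id = ids[j],
      baseline_hr = profile_ranges$baseline_hr[1] +
        u[1] * diff(profile_ranges$baseline_hr),
      rsa_amplitude = profile_ranges$rsa_amplitude[1] +
        u[2] * diff(profile_ranges$rsa_amplitude),
      rsa_period_s = profile_ranges$rsa_period_s[1] +
        u[3] * diff(profile_ranges$rsa_period_s),
      ar_coefficient = profile_ranges$ar_coefficient[1] +
        u[4] * diff(profile_ranges$ar_coefficient),
      process_noise_sd = profile_ranges$process_noise_sd[1] +
        u[5] * diff(profile_ranges$process_noise_sd),
      duration_s = duration_s, period_s = period_s,
      seed = draws$seeds[j]
    )
  })
  sims <- purrr::map(profiles, simulate_reference)
  wrist <- purrr::map2(sims, seq_len(n_subjects), function(s, j) {
    dg <- degradation
    dg$seed <- draws$seeds[n_subjects + j]
    degrade_to_wrist(s$reference, dg)
  })
  gt_hrv <- purrr::map2_dfr(sims, ids, function(s, id) {
    dplyr::bind_cols(tibble::tibble(subject_id = id), s$ground_truth_hrv)
  })
  structure(list(
    subjects = purrr::map_dfr(profiles, ~ tibble::as_tibble(unclass(.x))),
    reference = stats::setNames(purrr::map(sims, "reference"), ids),
    wrist = stats::setNames(wrist, ids),
    ground_truth_ibi = stats::setNames(purrr::map(sims, "ground_truth_ibi"), ids),
    ground_truth_hrv = gt_hrv,
    degradation = degradation,
    master_seed = master_seed
  ), class = "hrv_cohort")
}

#' Write a cohort as per-subject CSV files plus ground truth JSON
#'
#' @param cohort an `hrv_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$reference)) {
    write_hr_csv(cohort$reference[[id]], file.path(dir, paste0(id, "_reference.csv")))
    write_hr_csv(cohort$wrist[[id]], file.path(dir, paste0(id, "_wrist.csv")))
  }
  jsonlite::write_json(cohort$ground_truth_hrv, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(dir)
}
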