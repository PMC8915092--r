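#' Pipeline configuration
#'
#' One configuration object drives the end-to-end run: simulate (or load) a
#' paired cohort, impute wrist gaps, optionally apply a wrist-to-reference
#' correction model, reconstruct pseudo-IBI, correct artifacts, compute the
#' HRV summaries and validate them against the reference. Round-trips
#' through YAML via [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param input_dir directory of per-subject CSVs (as written by
#'   [write_cohort()]); `NULL` simulates a cohort instead.
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @param n_subjects,duration_s cohort shape when simulating.
#' @param degradation degradation preset name (`"none"`, `"mild"`,
#'   `"heavy"`) or a [degradation_profile()].
#' @param imputation_method gap-filling method (default `"pchip"`, the
#'   benchmark winner on reference-grade series).
#' @param mapping_model correction model family, one of the eight families
#'   or `"none"` to skip the correction stage (default `"lstm"`, the
#'   best-ranked family on paired wrist/chest data).
#' @param artifact_rule beat-rejection rule (default `"kamath"`).
#' @param segment_minutes segment length for SDANN / SDNN index.
#' @param alpha significance level of the paired validation.
#' @param train_fraction per-subject training fraction for the mapping stage.
#' @param seed master seed; all stage seeds derive from it.
#' @param run_imputation_benchmark whether to benchmark all imputation
#'   methods on the first reference series (adds an
#'   `imputation_benchmark` to the results).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL,
                            n_subjects = 10L, duration_s = 900,
                            degradation = "mild",
                            imputation_method = "pchip",
                            mapping_model = "lstm",
                            artifact_rule = "kamath",
                            segment_minutes = 5, alpha = 0.05,
                            train_fraction = 0.75, seed = 1L,
                            run_imputation_benchmark = TRUE) {
  imputation_method <- match.arg(imputation_method, IMPUTE_METHODS)
  mapping_model <- match.arg(mapping_model, c(MAPPING_ALGORITHMS, "none"))
  artifact_rule <- match.arg(artifact_rule, c("kamath", "malik", "karlsson", "acar"))
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 n_subjects = as.integer(n_subjects), duration_s = duration_s,
                 degradation = degradation,
                 imputation_method = imputation_method,
                 mapping_model = mapping_model, artifact_rule = artifact_rule,
                 segment_minutes = segment_minutes, alpha = alpha,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 run_imputation_benchmark = isTRUE(run_imputation_benchmark)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  if (inherits(vals$degradation, "degradation_profile")) {
    vals$degradation <- unclass(vals$degradation)
  }
  yaml::write_yaml(vals, path)
  invisible(path)
}

stage_seed <- function(seed, offset) (as.integer(seed) + offset * 7919L) %% 2147483629L + 1L

#' Run the full HRV validation pipeline
#'
#' Executes the study flow: simulate (or load) the paired cohort, fill wrist
#' gaps, optionally correct the wrist series toward the reference with the
#' configured model family, reconstruct pseudo inter-beat intervals, apply
#' the configured artifact rule with cubic-spline replacement, compute the
#' per-subject time-domain HRV summaries, and compare them against the
#' reference summaries with paired t-tests. HRV is computed over each
#' subject's full recording. Any stage failure aborts with the stage name;
#' results already computed are retained in the error's `partial` field.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_result`: `hrv_summaries` (per-subject
#'   tibble), `reference_summaries`, `comparison` (an `hrv_comparison`),
#'   `mapping_report` (or `NULL` when `mapping_model = "none"`),
#'   `imputation_benchmark` (or `NULL`), `cohort`, `config` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  results <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("pipeline_stage_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = NULL, partial = results)))
    })
  }

  cohort <- stage("input", {
    if (is.null(config$input_dir)) {
      make_cohort(n_subjects = config$n_subjects,
                  degradation = if (is.character(config$degradation))
                    degradation_preset(config$degradation,
                                       seed = stage_seed(config$seed, 1L))
                  else config$degradation,
                  duration_s = config$duration_s,
                  master_seed = stage_seed(config$seed, 2L))
    } else {
      read_cohort(config$input_dir)
    }
  })
  results$cohort <- cohort
  ids <- names(cohort$wrist)

  wrist_complete <- stage("imputation", {
    lapply(cohort$wrist, function(w) {
      if (anyNA(w$hr_bpm)) impute(w, config$imputation_method) else w
    })
  })

  results$imputation_benchmark <- if (config$run_imputation_benchmark) {
    stage("imputation_benchmark",
          benchmark_imputation(cohort$reference[[1]],
                               fraction = 0.1,
                               seed = stage_seed(config$seed, 3L)))
  } else NULL

  pairs <- stage("alignment", {
    purrr::map_dfr(ids, function(id) {
      align_pair(wrist_complete[[id]], cohort$reference[[id]])
    })
  })

  corrected_hr <- wrist_complete
  results$mapping_report <- NULL
  if (config$mapping_model != "none") {
    mp <- stage("mapping", {
      split_pairs <- split_train_test(pairs, train_fraction = config$train_fraction,
                                      seed = stage_seed(config$seed, 4L))
      spec <- model_spec(config$mapping_model)
      report <- evaluate_models(split_pairs, specs = list(spec),
                                seed = stage_seed(config$seed, 5L))
      gs_params <- report$best_params[[which(report$algorithm == config$mapping_model)]]
      train <- split_pairs[split_pairs$split == "train", ]
      corrected <- lapply(ids, function(id) {
        w <- wrist_complete[[id]]
        ev <- tibble::tibble(subject_id = w$subject_id, time_s = w$time_s,
                             wrist_hr = w$hr_bpm)
        pred <- fit_predict(spec, gs_params, train, ev,
                            seed = stage_seed(config$seed, 5L))$predictions
        w$hr_bpm <- pred
        w
      })
      list(report = report, corrected = stats::setNames(corrected, ids))
    })
    results$mapping_report <- mp$report
    corrected_hr <- mp$corrected
  }

  summaries <- stage("hrv", {
    purrr::map_dfr(ids, function(id) {
      ibi <- hr_to_ibi(corrected_hr[[id]])
      ibi <- correct_artifacts(ibi, artifact_rule_config(config$artifact_rule))
      dplyr::bind_cols(tibble::tibble(subject_id = id),
                       compute_hrv_summary(ibi, config$segment_minutes))
    })
  })
  results$hrv_summaries <- summaries

  reference_summaries <- stage("reference_hrv", {
    if (!is.null(cohort$ground_truth_hrv)) cohort$ground_truth_hrv
    else purrr::map_dfr(ids, function(id) {
      dplyr::bind_cols(tibble::tibble(subject_id = id),
                       compute_hrv_summary(hr_to_ibi(cohort$reference[[id]]),
                                           config$segment_minutes))
    })
  })
  results$reference_summaries <- reference_summaries

  results$comparison <- stage("validation", {
    compare_platforms(summaries, reference_summaries, alpha = config$alpha)
  })

  results$manifest <- pipeline_manifest(results)
  if (!is.null(config$out_dir)) write_pipeline_result(results, config$out_dir)
  class(results) <- "pipeline_result"
  results
}

# deterministic checksum of the numeric outputs (polynomial hash of the
# formatted numbers) so reruns can be compared without binary artifacts
hash_numbers <- function(...) {
  vals <- unlist(list(...), use.names = FALSE)
  s <- paste(sprintf("%.12g", as.numeric(vals)), collapse = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  sprintf("%x", as.integer(h))
}

pipeline_manifest <- function(results) {
  list(
    package_version = as.character(utils::packageVersion("wristhrv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = results$config$seed,
    config = unclass(results$config)[setdiff(names(results$config),
                                             c("input_dir", "out_dir"))],
    output_hash = hash_numbers(
      results$hrv_summaries$sdnn, results$hrv_summaries$rmssd,
      results$hrv_summaries$pnn50,
      results$comparison$t_value, results$comparison$p_value,
      if (!is.null(results$mapping_report)) results$mapping_report$test_rmse)
  )
}

write_pipeline_result <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(results$hrv_summaries, file.path(dir, "hrv_summaries.csv"), na = "")
  readr::write_csv(results$reference_summaries,
                   file.path(dir, "reference_summaries.csv"), na = "")
  cmp <- results$comparison
  readr::write_csv(dplyr::select(tibble::as_tibble(cmp), -dplyr::any_of(
    c("box_pipeline", "box_reference"))), file.path(dir, "comparison.csv"), na = "")
  if (!is.null(results$mapping_report)) {
    tidy_map <- generics::tidy(results$mapping_report)
    readr::write_csv(tidy_map, file.path(dir, "mapping_report.csv"), na = "")
  }
  if (!is.null(results$imputation_benchmark)) {
    readr::write_csv(tibble::as_tibble(results$imputation_benchmark),
                     file.path(dir, "imputation_benchmark.csv"), na = "")
  }
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `<id>_reference.csv`, `<id>_wrist.csv`
#'   and optionally `ground_truth.json`.
#' @return an `hrv_cohort` (without per-subject profiles).
#' @export
read_cohort <- function(dir) {
  refs <- sort(list.files(dir, pattern = "_reference\\.csv$", full.names = TRUE))
  if (!length(refs)) stop("no *_reference.csv files in ", dir, call. = FALSE)
  ids <- sub("_reference\\.csv$", "", basename(refs))
  reference <- lapply(seq_along(ids), function(j) {
    read_hr_csv(refs[j], device = "reference")
  })
  wrist <- lapply(ids, function(id) {
    path <- file.path(dir, paste0(id, "_wrist.csv"))
    if (!file.exists(path)) stop("missing wrist file: ", path, call. = FALSE)
    read_hr_csv(path, device = "wrist")
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    tibble::as_tibble(jsonlite::fromJSON(gt_path))
  } else NULL
  structure(list(subjects = NULL,
                 reference = stats::setNames(reference, ids),
                 wrist = stats::setNames(wrist, ids),
                 ground_truth_ibi = NULL, ground_truth_hrv = gt),
            class = "hrv_cohort")
}
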