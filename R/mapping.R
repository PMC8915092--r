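#' @name mapping
#' @title Wrist-to-reference heart-rate correction models
#'
#' @description
#' The correction stage learns the mapping from wrist heart rate to the
#' simultaneous chest-strap reference from paired samples. Eight model
#' families are compared: multinomial logistic regression (integer-rounded
#' bpm values of the target treated as categories), k-nearest-neighbour
#' regression, a decision tree, a random forest, AdaBoost.R2, ordinary
#' linear regression, a single-layer recurrent network and an LSTM (one
#' LSTM layer plus two sigmoid dense layers with dropout 0.2). Models are
#' tuned by exhaustive grid search under 5-fold cross-validation scored by
#' negated mean squared error (larger is better), refitted on the full
#' training split, and ranked by test RMSE in bpm.
NULL

MAPPING_ALGORITHMS <- c("multinomial_logistic", "knn", "decision_tree",
                        "random_forest", "adaboost", "linear_regression",
                        "rnn", "lstm")

default_grid <- function(algorithm) {
  switch(algorithm,
    multinomial_logistic = list(decay = c(0, 0.1)),
    knn = list(k = c(3, 5, 7, 11)),
    decision_tree = list(maxdepth = c(3, 5, 10, 30)), # 30 = rpart's "no limit"
    random_forest = list(ntree = c(50, 100, 200)),
    adaboost = list(n_estimators = c(25, 50, 100)),
    linear_regression = list(),
    rnn = list(hidden = c(4, 8)),
    lstm = list(hidden = c(4, 8)),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' Specify one correction-model family
#'
#' @param algorithm one of `r paste0('"', MAPPING_ALGORITHMS, '"', collapse = ", ")`.
#' @param grid named list of hyperparameter candidate vectors; defaults per
#'   family (empty for `linear_regression`, which has nothing to tune).
#' @param fixed fixed training settings; for the two nets these are the
#'   batch size 64, 15 epochs, Adam with learning rate 0.1 and first-moment
#'   decay 0.5 (the "momentum" reading for Adam), window length 10 and
#'   dropout 0.2.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(algorithm = MAPPING_ALGORITHMS,
                       grid = NULL,
                       fixed = list()) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (length(grid) == 0L && algorithm != "linear_regression") {
    stop("hyperparameter grid must be non-empty for ", algorithm, call. = FALSE)
  }
  defaults <- list(batch_size = 64L, epochs = 15L, lr = 0.1, beta1 = 0.5,
                   window = 10L, dropout = 0.2, dense_units = 8L)
  fixed <- utils::modifyList(defaults, fixed)
  structure(list(algorithm = algorithm, grid = grid, fixed = fixed),
            class = "model_spec")
}

#' Subject-stratified chronological train/test split
#'
#' Within each subject, rows are ordered by time and the leading
#' `train_fraction` become the training split, the trailing remainder the
#' test split. Every subject therefore contributes a contiguous test
#' segment — which is what later per-subject HRV computation needs — and
#' appears in both splits, with the split fraction within one row of the
#' target.
#'
#' @param pairs tibble of paired samples with columns `subject_id`,
#'   `time_s`, `wrist_hr`, `reference_hr` (see [align_pair()]).
#' @param train_fraction fraction of each subject's rows used for training.
#' @param seed kept for interface symmetry; the chronological split is
#'   deterministic.
#' @return `pairs` with a `split` column (`"train"` / `"test"`).
#' @export
split_train_test <- function(pairs, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1) so both splits are non-empty", call. = FALSE)
  }
  counts <- table(pairs$subject_id)
  if (any(counts < 4L)) {
    stop("subject(s) with fewer than 4 rows: ",
         paste(names(counts)[counts < 4L], collapse = ", "), call. = FALSE)
  }
  pairs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::mutate(split = ifelse(
      dplyr::row_number() <= pmin(pmax(round(train_fraction * dplyr::n()), 1L),
                                  dplyr::n() - 1L),
      "train", "test")) |>
    dplyr::ungroup()
}

normalize_params <- function(x) {
  list(lo = min(x), hi = max(x))
}
norm01 <- function(x, p) if (p$hi > p$lo) (x - p$lo) / (p$hi - p$lo) else rep(0.5, length(x))
denorm01 <- function(z, p) p$lo + z * (p$hi - p$lo)

#' Fit one model family and predict reference heart rate
#'
#' Trains the given family with the chosen hyperparameters on the training
#' rows and returns predictions (bpm) for the evaluation rows. The two nets
#' consume sliding windows of the wrist series (length `window`, stride 1,
#' built within each subject) with inputs and targets min-max normalized to
#' \[0, 1\] from the training rows and predictions inverse-mapped to bpm.
#'
#' @param spec a [model_spec()].
#' @param params named list: one value per grid dimension.
#' @param train training rows (`subject_id`, `time_s`, `wrist_hr`,
#'   `reference_hr`).
#' @param eval_inputs rows to predict (`subject_id`, `time_s`, `wrist_hr`).
#' @param seed integer seed for families with internal randomness.
#' @return list with `predictions` (numeric, bpm) and `model` (the fitted
#'   object; nets expose `epoch_loss`).
#' @export
fit_predict <- function(spec, params, train, eval_inputs, seed = 1L) {
  x <- train$wrist_hr
  y <- train$reference_hr
  xe <- eval_inputs$wrist_hr
  alg <- spec$algorithm
  res <- switch(alg,
    linear_regression = {
      fit <- stats::lm(reference_hr ~ wrist_hr, data = train)
      list(predictions = unname(stats::predict(fit, eval_inputs)), model = fit)
    },
    knn = {
      fit <- FNN::knn.reg(train = matrix(x), test = matrix(xe), y = y,
                          k = params$k)
      list(predictions = fit$pred, model = list(k = params$k))
    },
    decision_tree = {
      fit <- rpart::rpart(reference_hr ~ wrist_hr, data = train, method = "anova",
                          control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                         cp = 1e-4, minsplit = 10,
                                                         xval = 0))
      list(predictions = unname(stats::predict(fit, eval_inputs)), model = fit)
    },
    random_forest = {
      fit <- withr::with_seed(seed, randomForest::randomForest(
        x = data.frame(wrist_hr = x), y = y, ntree = params$ntree))
      list(predictions = unname(stats::predict(fit, data.frame(wrist_hr = xe))),
           model = fit)
    },
    adaboost = {
      fit <- adaboost_r2_fit(x, y, n_estimators = params$n_estimators, seed = seed)
      list(predictions = adaboost_r2_predict(fit, xe), model = fit)
    },
    multinomial_logistic = {
      classes <- factor(round(y))
      fit <- withr::with_seed(seed, nnet::multinom(
        classes ~ wrist_hr, data = data.frame(classes = classes, wrist_hr = x),
        decay = params$decay %||% 0, maxit = 200, trace = FALSE, MaxNWts = 100000))
      pred <- stats::predict(fit, data.frame(wrist_hr = xe), type = "class")
      list(predictions = as.numeric(as.character(pred)), model = fit)
    },
    rnn = ,
    lstm = {
      px <- normalize_params(x)
      py <- normalize_params(y)
      Xtr <- build_windows(norm01(x, px), train$subject_id, spec$fixed$window)
      Xev <- build_windows(norm01(xe, px), eval_inputs$subject_id, spec$fixed$window)
      ytr <- norm01(y, py)
      f <- spec$fixed
      model <- if (alg == "rnn") {
        rnn_fit(Xtr, ytr, hidden = params$hidden, epochs = f$epochs,
                batch_size = f$batch_size, lr = f$lr, beta1 = f$beta1, seed = seed)
      } else {
        lstm_fit(Xtr, ytr, hidden = params$hidden, dense_units = f$dense_units,
                 dropout = f$dropout, epochs = f$epochs, batch_size = f$batch_size,
                 lr = f$lr, beta1 = f$beta1, seed = seed)
      }
      pred <- if (alg == "rnn") rnn_predict(model, Xev) else lstm_predict(model, Xev)
      list(predictions = denorm01(pred, py), model = model)
    },
    stop("unknown algorithm: ", alg, call. = FALSE)
  )
  res
}

#' 5-fold cross-validation score of one hyperparameter point
#'
#' Rows are randomly partitioned into `k` folds (every row validates exactly
#' once); the score is the mean over folds of the negated mean squared error,
#' so larger is better.
#'
#' @param spec a [model_spec()].
#' @param params hyperparameter point (named list).
#' @param train training rows.
#' @param k number of folds.
#' @param seed seed controlling the fold assignment (and model randomness).
#' @return scalar mean negated MSE.
#' @export
kfold_cv <- function(spec, params, train, k = 5L, seed = 1L) {
  n <- nrow(train)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of training rows", call. = FALSE)
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  scores <- vapply(seq_len(k), function(f) {
    tr <- train[folds != f, , drop = FALSE]
    va <- train[folds == f, , drop = FALSE]
    pred <- fit_predict(spec, params, tr, va, seed = seed + f)$predictions
    -mean((pred - va$reference_hr)^2)
  }, numeric(1))
  mean(scores)
}

#' Exhaustive grid search under cross-validation
#'
#' Evaluates every point of the Cartesian hyperparameter grid with
#' [kfold_cv()] and returns the argmax of the mean negated MSE; ties break
#' to the first point in declared grid order. `linear_regression` has an
#' empty grid and returns empty hyperparameters with its CV score.
#'
#' @inheritParams kfold_cv
#' @return list with `best_params`, `best_score` and `grid_scores` (a tibble
#'   of all evaluated points).
#' @export
grid_search <- function(spec, train, k = 5L, seed = 1L) {
  if (length(spec$grid) == 0L) {
    score <- kfold_cv(spec, list(), train, k = k, seed = seed)
    return(list(best_params = list(), best_score = score,
                grid_scores = tibble::tibble(cv_score = score)))
  }
  pts <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(pts)), function(i) {
    kfold_cv(spec, as.list(pts[i, , drop = FALSE]), train, k = k, seed = seed)
  }, numeric(1))
  best <- which.max(scores)
  list(best_params = as.list(pts[best, , drop = FALSE]),
       best_score = scores[best],
       grid_scores = dplyr::bind_cols(tibble::as_tibble(pts),
                                      tibble::tibble(cv_score = scores)))
}

#' Tune, fit and rank the correction-model families
#'
#' For each family: grid search on the training rows (5-fold CV, negated
#' MSE), refit on the full training split with the winning hyperparameters,
#' predict the held-out test rows and report the test RMSE in bpm. Model
#' failures are recorded per entry and the run continues.
#'
#' @param pairs paired samples with a `split` column (see
#'   [split_train_test()]).
#' @param specs list of [model_spec()]s, default all eight families.
#' @param k CV folds.
#' @param seed integer seed.
#' @return a tibble of class `mapping_report`, one row per family, sorted
#'   ascending by `test_rmse`, with columns `algorithm`, `best_params`
#'   (list-column), `cv_score`, `test_rmse`, `error`; the winning family is
#'   the `winner` attribute. Fitted nets' per-epoch training loss is kept in
#'   the `epoch_loss` list-column.
#' @export
evaluate_models <- function(pairs,
                            specs = lapply(MAPPING_ALGORITHMS, model_spec),
                            k = 5L, seed = 1L) {
  if (!"split" %in% names(pairs)) stop("pairs must carry a split column", call. = FALSE)
  train <- pairs[pairs$split == "train", , drop = FALSE]
  test <- pairs[pairs$split == "test", , drop = FALSE]
  rows <- purrr::map_dfr(specs, function(spec) {
    tryCatch({
      gs <- grid_search(spec, train, k = k, seed = seed)
      fp <- fit_predict(spec, gs$best_params, train, test, seed = seed)
      tibble::tibble(
        algorithm = spec$algorithm,
        best_params = list(gs$best_params),
        cv_score = gs$best_score,
        test_rmse = rmse(fp$predictions, test$reference_hr),
        epoch_loss = list(fp$model$epoch_loss),
        error = NA_character_)
    }, error = function(e) {
      tibble::tibble(algorithm = spec$algorithm, best_params = list(NULL),
                     cv_score = NA_real_, test_rmse = NA_real_,
                     epoch_loss = list(NULL), error = conditionMessage(e))
    })
  })
  out <- rows[order(is.na(rows$test_rmse), rows$test_rmse), ]
  attr(out, "winner") <- out$algorithm[which.min(out$test_rmse)]
  class(out) <- c("mapping_report", class(out))
  out
}
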