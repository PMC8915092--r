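test_that("split is subject-stratified, chronological, within one row of 75%", {
  pairs <- toy_pairs(n_per_subject = 8)
  sp <- split_train_test(pairs)
  counts <- table(sp$subject_id, sp$split)
  expect_equal(unname(counts[, "train"]), c(6, 6))
  expect_equal(unname(counts[, "test"]), c(2, 2))
  # chronological: every train row precedes every test row within a subject
  for (id in c("A", "B")) {
    s <- sp[sp$subject_id == id, ]
    expect_lt(max(s$time_s[s$split == "train"]), min(s$time_s[s$split == "test"]))
  }
  expect_error(split_train_test(pairs, train_fraction = 1.0), "train_fraction")
  tiny <- tibble::tibble(subject_id = c("A", "A", "A"), time_s = 1:3,
                         wrist_hr = 70, reference_hr = 70)
  expect_error(split_train_test(tiny), "fewer than 4")
})

test_that("cross-validation partitions every row exactly once and is seeded", {
  pairs <- toy_pairs(n_per_subject = 25)
  spec <- model_spec("linear_regression")
  s1 <- kfold_cv(spec, list(), pairs, k = 5, seed = 3)
  s2 <- kfold_cv(spec, list(), pairs, k = 5, seed = 3)
  expect_identical(s1, s2)
  expect_lte(s1, 0) # negated MSE
  # constant-prediction task: zero error -> score 0
  const <- tibble::tibble(subject_id = "A", time_s = 1:10,
                          wrist_hr = rep(c(1, 2), 5), reference_hr = 5)
  expect_equal(kfold_cv(model_spec("decision_tree"), list(maxdepth = 3),
                        const, k = 5, seed = 1), 0)
  expect_error(kfold_cv(spec, list(), const, k = 11, seed = 1), "exceeds")
})

test_that("grid search is exhaustive with ties to the first grid point", {
  pairs <- toy_pairs(n_per_subject = 30)
  spec <- model_spec("knn", grid = list(k = c(3, 5)))
  gs <- grid_search(spec, pairs, seed = 2)
  expect_equal(nrow(gs$grid_scores), 2L)
  expect_equal(gs$best_score, max(gs$grid_scores$cv_score))
  expect_equal(gs$best_params$k,
               gs$grid_scores$k[which.max(gs$grid_scores$cv_score)])
  # linear regression: empty hyperparameters, CV score still reported
  lin <- grid_search(model_spec("linear_regression"), pairs, seed = 2)
  expect_length(lin$best_params, 0L)
  expect_true(is.finite(lin$best_score))
  # a constant-target task makes every k perfect: first grid point wins
  const <- tibble::tibble(subject_id = "A", time_s = 1:40,
                          wrist_hr = rnorm(40), reference_hr = 7)
  tie <- grid_search(model_spec("knn", grid = list(k = c(5, 3))), const, seed = 1)
  expect_equal(tie$best_params$k, 5)
})

test_that("linear regression recovers slope and intercept", {
  pairs <- toy_pairs(noise_sd = 0, intercept = 5)
  sp <- split_train_test(pairs)
  tr <- sp[sp$split == "train", ]
  te <- sp[sp$split == "test", ]
  fp <- fit_predict(model_spec("linear_regression"), list(), tr, te)
  expect_lt(rmse(fp$predictions, te$reference_hr), 1e-6)
  expect_equal(unname(stats::coef(fp$model)), c(5, 1), tolerance = 1e-8)
})

test_that("knn with k = 1 memorises its training inputs", {
  pairs <- toy_pairs(n_per_subject = 20)
  fp <- fit_predict(model_spec("knn"), list(k = 1), pairs, pairs)
  expect_equal(rmse(fp$predictions, pairs$reference_hr), 0, tolerance = 1e-12)
})

test_that("nets train: loss decreases on a learnable task, seeded runs agree", {
  pairs <- toy_pairs(n_per_subject = 150, noise_sd = 0.5)
  sp <- split_train_test(pairs)
  tr <- sp[sp$split == "train", ]
  te <- sp[sp$split == "test", ]
  for (alg in c("rnn", "lstm")) {
    fp <- fit_predict(model_spec(alg), list(hidden = 8), tr, te, seed = 4)
    expect_length(fp$model$epoch_loss, 15L)
    expect_lt(fp$model$epoch_loss[15], fp$model$epoch_loss[1])
    expect_true(all(is.finite(fp$predictions)))
    # predictions inverse-mapped to bpm stay in the training target range
    expect_true(all(fp$predictions >= min(tr$reference_hr) - 1e-9))
    expect_true(all(fp$predictions <= max(tr$reference_hr) + 1e-9))
    fp2 <- fit_predict(model_spec(alg), list(hidden = 8), tr, te, seed = 4)
    expect_identical(fp$predictions, fp2$predictions)
  }
})

test_that("multinomial logistic predicts integer-rounded bpm categories", {
  pairs <- toy_pairs(n_per_subject = 60)
  sp <- split_train_test(pairs)
  tr <- sp[sp$split == "train", ]
  te <- sp[sp$split == "test", ]
  fp <- fit_predict(model_spec("multinomial_logistic"), list(decay = 0), tr, te,
                    seed = 2)
  expect_true(all(fp$predictions %in% round(tr$reference_hr)))
  expect_lt(rmse(fp$predictions, te$reference_hr), 5)
})

test_that("test rows never influence fitting", {
  pairs <- toy_pairs(n_per_subject = 40)
  sp <- split_train_test(pairs)
  tr <- sp[sp$split == "train", ]
  te <- sp[sp$split == "test", ]
  mutated <- te
  mutated$reference_hr <- mutated$reference_hr + 1000
  f1 <- fit_predict(model_spec("linear_regression"), list(), tr, te)
  f2 <- fit_predict(model_spec("linear_regression"), list(), tr, mutated)
  expect_identical(stats::coef(f1$model), stats::coef(f2$model))
  expect_identical(f1$predictions, f2$predictions)
})

test_that("evaluate_models ranks families and records failures per entry", {
  pairs <- toy_pairs(n_per_subject = 60, noise_sd = 0)
  sp <- split_train_test(pairs)
  specs <- list(model_spec("linear_regression"), model_spec("knn", grid = list(k = 3)))
  rep <- evaluate_models(sp, specs = specs, seed = 5)
  expect_s3_class(rep, "mapping_report")
  expect_equal(nrow(rep), 2L)
  expect_false(is.unsorted(rep$test_rmse))
  # exact linear task: linear regression wins with ~0 RMSE
  expect_equal(attr(rep, "winner"), "linear_regression")
  expect_lt(rep$test_rmse[rep$algorithm == "linear_regression"], 1e-6)
  td <- tidy(rep)
  expect_named(td, c("algorithm", "hyperparameters", "cv_score", "test_rmse", "error"))
  expect_equal(glance(rep)$winner, "linear_regression")

  # a failing family is recorded, the run continues
  broken <- model_spec("knn", grid = list(k = 1e6))
  rep2 <- suppressWarnings(
    evaluate_models(sp, specs = list(model_spec("linear_regression"), broken),
                    seed = 5))
  expect_true(any(!is.na(rep2$error)))
  expect_true(any(is.na(rep2$error)))
})

test_that("cv score of the selected point is the grid maximum", {
  pairs <- toy_pairs(n_per_subject = 40)
  sp <- split_train_test(pairs)
  tr <- sp[sp$split == "train", ]
  gs <- grid_search(model_spec("decision_tree"), tr, seed = 9)
  expect_true(all(gs$best_score >= gs$grid_scores$cv_score))
})
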