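# AdaBoost.R2 (Drucker 1997) for regression over shallow rpart trees:
# boosting with the linear loss, weighted-median prediction. Written here
# because no AdaBoost regressor is among the package's dependencies.

adaboost_r2_fit <- function(x, y, n_estimators = 50L, maxdepth = 3L, seed = 1L) {
  withr::with_seed(seed, {
    n <- length(y)
    w <- rep(1 / n, n)
    learners <- list()
    betas <- numeric(0)
    df <- data.frame(x = x, y = y)
    ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 1e-4, minsplit = 10, xval = 0)
    for (m in seq_len(n_estimators)) {
      fit <- rpart::rpart(y ~ x, data = df, weights = w * n, method = "anova",
                          control = ctrl)
      pred <- stats::predict(fit, df)
      abs_err <- abs(pred - y)
      emax <- max(abs_err)
      if (emax == 0) { # perfect learner: keep it with full confidence and stop
        learners[[length(learners) + 1L]] <- fit
        betas <- c(betas, 1e-10)
        break
      }
      L <- abs_err / emax
      Lbar <- sum(w * L)
      if (Lbar >= 0.5) break
      beta <- Lbar / (1 - Lbar)
      learners[[length(learners) + 1L]] <- fit
      betas <- c(betas, beta)
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
    if (length(learners) == 0L) { # first learner too weak: fall back to it unweighted
      learners <- list(rpart::rpart(y ~ x, data = df, method = "anova", control = ctrl))
      betas <- 0.5
    }
    structure(list(learners = learners, log_inv_beta = log(1 / betas)),
              class = "wristhrv_adaboost")
  })
}

adaboost_r2_predict <- function(model, x) {
  preds <- vapply(model$learners, function(f) {
    stats::predict(f, data.frame(x = x))
  }, numeric(length(x)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = length(x))
  wts <- model$log_inv_beta
  apply(preds, 1, function(p) weighted_median(p, wts))
}

weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord])
  v[which(cw >= cw[length(cw)] / 2)[1]]
}
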