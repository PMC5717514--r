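.sep_features <- function(n = 40, p = 10, seed = 1) {
  # one strongly informative column among noise
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- y * 4 + rnorm(n, sd = 0.2)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

test_that("metrics follow clinical conventions with patients positive", {
  m <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), scores = c(-2, -1, 1, 2))
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)
  m <- compute_metrics(c(0, 0, 1, 1), c(1, 1, 1, 1))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  # anti-ordered scores give AUC 0
  m <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                       scores = c(2, 1, -1, -2))
  expect_equal(m$auc, 0)
  # absent class flagged as missing, not zero
  m <- compute_metrics(c(1, 1), c(1, 0))
  expect_true(is.na(m$specificity))
  expect_true(m$missing[["specificity"]])
})

test_that("ROC/AUC agree with the pROC oracle on tied and untied scores", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rbinom(60, 1, 0.5)
  for (scores in list(rnorm(60) + y, round(rnorm(60) + y))) {
    auc <- trapezoid_auc(roc_points(y, scores))
    ref <- suppressMessages(pROC::auc(pROC::roc(y, scores, quiet = TRUE)))
    expect_equal(auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("inner optimization returns the sole combination of a 1-point grid", {
  d <- .sep_features()
  g <- optimization_grid(delta_grid = 0.5, lambda_grid = 0.9, c_grid = 2,
                         gamma_grid = 0.1)
  best <- inner_optimize(d$X, d$y, g, seed = 3)
  expect_equal(best[c("delta", "lambda", "cost", "gamma")],
               list(delta = 0.5, lambda = 0.9, cost = 2, gamma = 0.1))
})

test_that("inner optimization is deterministic and separates easy data", {
  d <- .sep_features()
  g <- optimization_grid(delta_grid = c(0.5, 2), lambda_grid = 0.9,
                         c_grid = c(1, 10), gamma_grid = c(0.05, 0.3))
  b1 <- inner_optimize(d$X, d$y, g, seed = 11)
  b2 <- inner_optimize(d$X, d$y, g, seed = 11)
  expect_identical(b1, b2)
  expect_equal(b1$tune_accuracy, 1)
})

test_that("zero-feature combinations score chance instead of failing", {
  d <- .sep_features()
  g <- optimization_grid(delta_grid = c(1e6, 0.5), lambda_grid = 0.9,
                         c_grid = 1, gamma_grid = 0.1)
  best <- inner_optimize(d$X, d$y, g, seed = 2)
  expect_equal(best$delta, 0.5)  # the impossible threshold lost with 0.5
  # with only impossible thresholds, fit_pipeline falls back to majority
  model <- fit_pipeline(d$X, d$y, list(delta = 1e6, lambda = 0.9,
                                       cost = 1, gamma = 0.1))
  pr <- predict(model, d$X[1:3, , drop = FALSE])
  expect_length(pr$pred, 3)
  expect_equal(pr$score, rep(0, 3))
})

test_that("outer CV is stratified, deterministic, and accurate on easy data", {
  d <- .sep_features(n = 40)
  fm <- list(X = d$X, labels = d$y)
  g <- optimization_grid(delta_grid = c(0.5, 2), lambda_grid = 0.9,
                         c_grid = c(1, 10), gamma_grid = 0.1)
  cv1 <- outer_cv(fm, g, n_folds = 10, n_repeats = 2, seed = 5)
  cv2 <- outer_cv(fm, g, n_folds = 10, n_repeats = 2, seed = 5)
  expect_equal(cv1$per_fold, cv2$per_fold)
  expect_equal(cv1$summary, cv2$summary)
  expect_gt(cv1$summary$accuracy, 95)
  expect_gt(cv1$summary$auc, 0.98)
  expect_equal(nrow(cv1$per_fold), 20)
})

test_that("fold assignment preserves class proportions within one sample", {
  set.seed(20)
  y <- rep(c(0, 1), times = c(28, 38))
  fold <- honmst:::.stratified_folds(y, 10)
  for (f in 1:10) {
    n1 <- sum(y[fold == f] == 1)
    n0 <- sum(y[fold == f] == 0)
    expect_lte(abs(n1 - 3.8), 1)
    expect_lte(abs(n0 - 2.8), 1)
  }
})

test_that("per-fold pipelines never look at held-out samples", {
  d <- .sep_features(n = 32, seed = 9)
  tr <- c(1:12, 17:28)
  te <- c(13:16, 29:32)
  g <- optimization_grid(delta_grid = 0.5, lambda_grid = 0.9,
                         c_grid = c(1, 5), gamma_grid = 0.1)
  p1 <- inner_optimize(d$X[tr, ], d$y[tr], g, seed = 4)
  m1 <- fit_pipeline(d$X[tr, ], d$y[tr], p1)
  pred1 <- predict(m1, d$X[te, ])
  # corrupt the held-out rows wildly; training-side results must not move
  X2 <- d$X
  X2[te, ] <- X2[te, ] * 1000 + 77
  p2 <- inner_optimize(X2[tr, ], d$y[tr], g, seed = 4)
  m2 <- fit_pipeline(X2[tr, ], d$y[tr], p2)
  expect_identical(p2, p1)
  expect_equal(m2$selected, m1$selected)
  expect_equal(m2$scaling, m1$scaling)
  expect_equal(predict(m2, d$X[te, ]), pred1)
  # appending copies of a test sample does not change per-sample scores
  Xte_aug <- rbind(d$X[te, ], d$X[te[1], , drop = FALSE])
  pred_aug <- predict(m1, Xte_aug)
  expect_equal(pred_aug$pred[seq_along(te)], pred1$pred)
  expect_equal(pred_aug$score[seq_along(te)], pred1$score)
})

test_that("label permutation drives accuracy to chance", {
  set.seed(33)
  accs <- sapply(1:10, function(k) {
    d <- .sep_features(n = 24, p = 8, seed = 100 + k)
    y_perm <- sample(d$y)
    g <- optimization_grid(delta_grid = 0.5, lambda_grid = 0.9,
                           c_grid = 1, gamma_grid = 0.1)
    outer_cv(list(X = d$X, labels = y_perm), g, n_folds = 6,
             n_repeats = 1, seed = k)$summary$accuracy / 100
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})
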