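.stack_from_Y <- function(Y) {
  # wrap a raw connectivity time-series matrix as a low_order_stack
  P <- nrow(Y)
  R <- (1 + sqrt(1 + 8 * P)) / 2
  structure(list(K = ncol(Y), R = R, matrices = NULL, Y = Y,
                 pair_map = pair_map(R)),
            class = "low_order_stack")
}

test_that("high-order matrix equals pairwise correlations of Y rows", {
  set.seed(17)
  Y <- matrix(rnorm(45 * 50), 45, 50)   # P = 45 (R = 10), K = 50
  hon <- highorder_matrix(.stack_from_Y(Y))
  # independent oracle: direct pairwise correlation formula
  for (idx in list(c(1, 2), c(7, 40), c(44, 45))) {
    a <- Y[idx[1], ]; b <- Y[idx[2], ]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(hon$H[idx[1], idx[2]], oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(diag(hon$H), rep(1, 45), ignore_attr = TRUE)
  expect_equal(hon$H, t(hon$H))
})

test_that("identical, sign-flipped, and constant connectivity rows", {
  set.seed(2)
  Y <- matrix(rnorm(6 * 30), 6, 30)
  Y[2, ] <- Y[1, ]
  Y[3, ] <- -Y[1, ]
  hon <- highorder_matrix(.stack_from_Y(Y))
  expect_equal(hon$H[1, 2], 1)
  expect_equal(hon$H[1, 3], -1)
  Y[4, ] <- 0.7
  expect_error(highorder_matrix(.stack_from_Y(Y)), "constant connectivity")
  expect_error(highorder_matrix(.stack_from_Y(Y[, 1:2])), "K >= 3")
})

test_that("independent Gaussian rows give near-zero mean off-diagonal", {
  set.seed(31)
  Y <- matrix(rnorm(28 * 60), 28, 60)
  hon <- highorder_matrix(.stack_from_Y(Y))
  off <- hon$H[upper.tri(hon$H)]
  expect_lt(abs(mean(off)), 3 / sqrt(length(off)))
})

test_that("correlation p-values follow the t transform", {
  H <- matrix(c(1, 0, 0, 1), 2)
  p <- correlation_pvalues(H, K = 20)
  expect_equal(p[1, 2], 1)
  H <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(correlation_pvalues(H, K = 20)[1, 2], 0)
  # r = 0.5, K = 179: t = 0.5*sqrt(177)/sqrt(0.75) ~ 7.68, p < 1e-11
  H <- matrix(c(1, 0.5, 0.5, 1), 2)
  p <- correlation_pvalues(H, K = 179)
  tstat <- 0.5 * sqrt(177) / sqrt(1 - 0.25)
  expect_equal(tstat, 7.681146, tolerance = 1e-6)
  expect_equal(p[1, 2], 2 * pt(-tstat, 177), tolerance = 1e-15)
  expect_lt(p[1, 2], 1e-11)
  # oracle: cor.test on raw data reproduces the same p
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  H <- cor(cbind(x, y))
  expect_equal(correlation_pvalues(H, K = 30)[1, 2],
               cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(diag(correlation_pvalues(H, K = 30)), c(0, 0),
               ignore_attr = TRUE)
})

test_that("FDR thresholding is a faithful Benjamini-Hochberg step-up", {
  set.seed(12)
  Y <- matrix(rnorm(10 * 40), 10, 40)
  hon <- highorder_matrix(.stack_from_Y(Y))
  # injected p-values exercise the step-up logic directly
  inject <- function(p_up) {
    pv <- matrix(0, 10, 10)
    pv[upper.tri(pv)] <- p_up
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
    pv
  }
  n_up <- 45
  th <- fdr_threshold(hon, 0.05, pvals = inject(rep(0.001, n_up)))
  expect_equal(th$n_retained, n_up)
  expect_equal(th$H_sig, hon$H)
  th <- fdr_threshold(hon, 0.05, pvals = inject(rep(0.9, n_up)))
  expect_equal(th$n_retained, 0)
  expect_equal(th$H_sig[upper.tri(th$H_sig)], rep(0, n_up))
  expect_equal(diag(th$H_sig), rep(1, 10), ignore_attr = TRUE)
  # hand-checked step-up over 45 tests at alpha = 0.05: the largest k
  # with p_(k) <= k*alpha/45 is k = 4 (0.004 <= 4*0.05/45 ~ 0.00444),
  # so exactly the four small p survive; 0.01 alone would not (> alpha/45)
  p_up <- c(0.001, 0.002, 0.003, 0.004, rep(0.9, 41))
  th <- fdr_threshold(hon, 0.05, pvals = inject(p_up))
  expect_equal(th$n_retained, 4)
  th <- fdr_threshold(hon, 0.05, pvals = inject(c(0.01, rep(0.9, 44))))
  expect_equal(th$n_retained, 0)
  # monotone in alpha
  th1 <- fdr_threshold(hon, 0.01)
  th2 <- fdr_threshold(hon, 0.2)
  expect_true(all(th2$mask[th1$mask]))
  expect_error(fdr_threshold(hon, 1.2), "alpha")
})

test_that("high-order networks serialize to dense and edge-list TSV", {
  set.seed(1)
  Y <- matrix(rnorm(6 * 20), 6, 20)
  hon <- highorder_matrix(.stack_from_Y(Y))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_highorder(hon, f1, "dense")
  d <- read.table(f1, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(dim(d), c(6, 7))
  expect_equal(as.matrix(d[, -1]), unname(hon$H), tolerance = 1e-12,
               ignore_attr = TRUE)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_highorder(hon, f2, "edges")
  e <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(e), 15)
  expect_true(all(c("pair_a", "pair_b", "weight", "p_value") %in% names(e)))
})
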