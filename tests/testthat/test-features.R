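test_that("clustering coefficients match closed forms", {
  # centre of a 3-node path, both weights 1: f = 2*2/(3*2*1) = 2/3
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  f <- clustering_coefficients(A)
  expect_equal(f[2], 2 / 3, ignore_attr = TRUE)
  # leaves (one neighbour) are 0 by convention
  expect_equal(f[c(1, 3)], c(0, 0), ignore_attr = TRUE)
  # star centre with 3 neighbours of weight 0.125: 2*3*0.5/(3*3*2) = 1/6
  S <- matrix(0, 4, 4)
  S[1, 2:4] <- S[2:4, 1] <- 0.125
  expect_equal(clustering_coefficients(S)[1], 1 / 6, ignore_attr = TRUE)
  expect_error(clustering_coefficients(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("cube-root scaling and signed-root conventions hold", {
  set.seed(21)
  A <- matrix(0, 7, 7)
  A[upper.tri(A)] <- runif(21) * (rbinom(21, 1, 0.5) * 2 - 1)
  A <- A + t(A)
  f1 <- clustering_coefficients(A)
  f2 <- clustering_coefficients(8 * A)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)  # c^(1/3) with c = 8
  # absolute mode never yields negative values for any input
  expect_true(all(clustering_coefficients(A, "absolute") >= 0))
  # signed mode on an all-negative star centre is negative
  N <- matrix(0, 4, 4)
  N[1, 2:4] <- N[2:4, 1] <- -0.5
  expect_lt(clustering_coefficients(N)[1], 0)
})

test_that("tree features: leaves zero, internal nodes bounded", {
  set.seed(5)
  P <- 12
  H <- matrix(0, P, P)
  H[upper.tri(H)] <- runif(P * (P - 1) / 2, -1, 1)
  H <- H + t(H); diag(H) <- 1
  tr <- kruskal_mst(H)
  f <- clustering_coefficients(tr)
  deg <- tabulate(c(tr$edges$a, tr$edges$b), nbins = P)
  expect_equal(f[deg == 1], rep(0, sum(deg == 1)), ignore_attr = TRUE)
  for (i in which(deg > 1))
    expect_lte(abs(f[i]), 2 * max(abs(tr$edges$weight))^(1 / 3) /
                 (3 * (deg[i] - 1)) + 1e-12)
})

test_that("feature matrices have method-dependent dimensions", {
  co <- tiny_cohort(n_per_group = 2, R = 10, M = 40, seed = 1)
  cfg <- pipeline_config(window_N = 20, window_S = 5)
  fm <- build_feature_matrix(co, "hon_mst", cfg)
  expect_equal(dim(fm$X), c(4, 45))
  expect_equal(fm$feature_names[1], "V01-V02")
  fm_pen <- build_feature_matrix(co, "pen", cfg)
  expect_equal(dim(fm_pen$X), c(4, 10))
  fm_pan <- build_feature_matrix(co, "pan", cfg)
  expect_equal(dim(fm_pan$X), c(4, 10))
  fm_hon <- build_feature_matrix(co, "hon", cfg)
  expect_equal(dim(fm_hon$X), c(4, 45))
  # identical time series give identical feature rows
  co$subjects[[2]]$timeseries <- co$subjects[[1]]$timeseries
  fm2 <- build_feature_matrix(co, "hon_mst", cfg)
  expect_equal(fm2$X[1, ], fm2$X[2, ])
})

test_that("per-region weight aggregation averages incident features", {
  pm <- pair_map(4, c("A", "B", "C", "D"))
  w <- rep(0, 6)
  # feature (A,B) with weight 10 and (A,C) with weight 20
  iAB <- which(pm$i == 1 & pm$j == 2)
  iAC <- which(pm$i == 1 & pm$j == 3)
  w[iAB] <- 10; w[iAC] <- 20
  agg <- roi_weight_aggregation(c(iAB, iAC), w, pm, c("A", "B", "C", "D"))
  expect_equal(agg, c(A = 15, B = 10, C = 20, D = 0))
  # three incident weights as printed for a precuneus-style hub:
  # mean(3110.48, 2322.26, 2200.40) = 2544.38
  w2 <- rep(0, 6)
  sel <- c(iAB, iAC, which(pm$i == 1 & pm$j == 4))
  w2[sel] <- c(3110.48, 2322.26, 2200.40)
  agg2 <- roi_weight_aggregation(sel, w2, pm, c("A", "B", "C", "D"))
  expect_equal(unname(agg2["A"]), 2544.38)
})

test_that("module interaction matrix averages and symmetrizes", {
  pm <- pair_map(6)
  part <- c("frontal", "parietal", "temporal", "temporal", "frontal",
            "occipital")
  w <- rep(0, nrow(pm))
  iFP <- which(pm$i == 1 & pm$j == 2)   # frontal-parietal
  iTT <- which(pm$i == 3 & pm$j == 4)   # temporal-temporal
  iF5 <- which(pm$i == 1 & pm$j == 5)   # frontal-frontal
  w[c(iFP, iTT, iF5)] <- c(8, 4, 6)
  M1 <- module_interaction_matrix(c(iFP, iTT), w, pm, part)
  expect_equal(M1["frontal", "parietal"], 8)
  expect_equal(M1["parietal", "frontal"], 8)
  expect_equal(M1["temporal", "temporal"], 4)
  expect_equal(sum(M1 != 0), 3)
  expect_equal(M1, t(M1))
  # within-module mean over two features
  w[iTT] <- 4
  w2 <- w; w2[iF5] <- 6
  M2 <- module_interaction_matrix(c(iTT, iF5), w2, pm, part)
  expect_equal(M2["temporal", "temporal"], 4)
  expect_equal(M2["frontal", "frontal"], 6)
  i56 <- which(pm$i == 5 & pm$j == 6)
  expect_error(module_interaction_matrix(c(i56), w, pm, part[1:5]),
               "missing")
  expect_error(module_interaction_matrix(c(iFP), w, pm,
                                         replace(part, 1, "limbic")),
               "unknown module")
})

test_that("permuting region labels permutes features consistently", {
  co <- tiny_cohort(n_per_group = 1, R = 6, M = 40, seed = 13)
  cfg <- pipeline_config(window_N = 15, window_S = 5)
  fm <- build_feature_matrix(co, "hon_mst", cfg)
  perm <- c(3, 1, 2, 6, 5, 4)
  co2 <- co
  for (k in seq_along(co2$subjects)) {
    ts <- co2$subjects[[k]]$timeseries[, perm]
    colnames(ts) <- co$roi_codes
    co2$subjects[[k]]$timeseries <- ts
  }
  fm2 <- build_feature_matrix(co2, "hon_mst", cfg)
  pm <- pair_map(6)
  inv <- order(perm)
  # feature of pair (i,j) under the permuted cohort equals the feature
  # of the originally-named pair, matched through the pair map
  lab <- function(i, j, codes) paste0(codes[min(i, j)], "-", codes[max(i, j)])
  for (p in seq_len(nrow(pm))) {
    orig_pair <- sort(c(perm[pm$i[p]], perm[pm$j[p]]))
    q <- which(pm$i == orig_pair[1] & pm$j == orig_pair[2])
    expect_equal(fm2$X[1, p], fm$X[1, q], tolerance = 1e-10)
  }
})
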