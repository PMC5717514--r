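# Shared fixtures and independent oracles for the test suite.

# Small deterministic cohort built directly (no generator).
tiny_cohort <- function(n_per_group = 2, R = 6, M = 40, seed = 42) {
  set.seed(seed)
  roi <- sprintf("V%02d", seq_len(R))
  subj <- function(id, label) {
    x <- matrix(rnorm(M * R), M, R, dimnames = list(NULL, roi))
    list(subject_id = id, timeseries = x, label = label)
  }
  subs <- c(lapply(seq_len(n_per_group), function(k) subj(paste0("a", k), 0L)),
            lapply(seq_len(n_per_group), function(k) subj(paste0("b", k), 1L)))
  fc_cohort(subs, roi)
}

# All spanning trees of the complete graph on P labelled nodes, decoded
# from Prufer sequences; returns a (P-1) x 2 x n_trees array of edges.
# Independent of the package's MST code.
all_spanning_trees <- function(P) {
  if (P == 2) return(array(c(1L, 2L), dim = c(1, 2, 1)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(P)), P - 2L)))
  n <- nrow(seqs)
  out <- array(NA_integer_, dim = c(P - 1L, 2L, n))
  for (s in seq_len(n)) {
    prufer <- seqs[s, ]
    degree <- rep(1L, P)
    for (v in prufer) degree[v] <- degree[v] + 1L
    edges <- matrix(NA_integer_, P - 1L, 2L)
    avail <- degree
    for (k in seq_len(P - 2L)) {
      leaf <- which(avail == 1L)[1L]
      edges[k, ] <- c(leaf, prufer[k])
      avail[leaf] <- 0L
      avail[prufer[k]] <- avail[prufer[k]] - 1L
    }
    edges[P - 1L, ] <- which(avail == 1L)
    out[, , s] <- edges
  }
  out
}

# Linear-index form: (P-1) x n_trees matrix of single indices into a
# P x P matrix, enabling vectorized brute-force costs over many graphs.
tree_edge_index <- function(P, trees = all_spanning_trees(P)) {
  n <- dim(trees)[3]
  idx <- matrix(NA_integer_, P - 1L, n)
  for (s in seq_len(n))
    idx[, s] <- (trees[, 2, s] - 1L) * P + trees[, 1, s]
  idx
}

# Minimum total transformed length over all spanning trees (brute force).
brute_force_mst_cost <- function(D, trees = NULL, idx = NULL) {
  P <- nrow(D)
  if (is.null(idx)) idx <- tree_edge_index(P, trees)
  min(colSums(matrix(D[idx], nrow = P - 1L)))
}

# Compact grid used for synthetic-cohort classification tests; thresholds
# match the Relief weight scale of the 190-feature, 36-training-sample
# problem (weights accumulate over samples).
synth_grid <- function() {
  optimization_grid(delta_grid = c(1, 2, 3, 4), lambda_grid = 0.9,
                    c_grid = c(1, 3, 10),
                    gamma_grid = c(0.005, 0.02, 0.05, 0.2))
}

edge_key <- function(tree) {
  paste(sort(paste(pmin(tree$edges$a, tree$edges$b),
                   pmax(tree$edges$a, tree$edges$b), sep = "-")),
        collapse = ";")
}
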