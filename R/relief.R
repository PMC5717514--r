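#' Relief feature weights (deterministic full pass)
#'
#' Original two-class Relief: for every training sample, find its nearest
#' hit (same class) and nearest miss (other class) by Euclidean distance
#' over range-scaled features, and accumulate per feature
#' \deqn{W_f \mathrel{+}= \mathrm{diff}(f, x, \mathrm{miss})
#'                       - \mathrm{diff}(f, x, \mathrm{hit}),}
#' where \eqn{\mathrm{diff}(f, a, b) = |a_f - b_f| / \mathrm{range}(f)}.
#' Every sample is visited exactly once (no random sub-sampling), so the
#' weights are deterministic; they accumulate without dividing by the
#' sample count, so their scale grows with the training-set size and any
#' weight threshold must be tuned to the data at hand.  Nearest-neighbour
#' ties are broken toward the smallest sample index.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (0/1), one per row of \code{X}.
#' @return numeric vector of feature weights (named from \code{X}'s
#'   columns).
#' @export
relief_weights <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in y")
  rng <- apply(X, 2, function(col) diff(range(col)))
  if (any(rng == 0)) {
    nm <- colnames(X)
    bad <- which(rng == 0)
    stop("zero-range feature(s) on this training set: ",
         paste(if (is.null(nm)) bad else nm[bad], collapse = ", "))
  }
  Xs <- sweep(X, 2, rng, "/")
  D <- as.matrix(stats::dist(Xs))
  diag(D) <- Inf
  W <- numeric(ncol(X))
  for (s in seq_len(n)) {
    same <- which(y == y[s]); same <- same[same != s]
    other <- which(y != y[s])
    hit <- same[which.min(D[s, same])]     # which.min: smallest index on ties
    miss <- other[which.min(D[s, other])]
    W <- W + abs(Xs[s, ] - Xs[miss, ]) - abs(Xs[s, ] - Xs[hit, ])
  }
  stats::setNames(as.numeric(W), colnames(X))
}

#' Select features by Relief weight threshold
#'
#' @param weights Relief weight vector.
#' @param delta weight threshold; features with \code{weight >= delta}
#'   are kept.
#' @return integer feature indices in descending-weight order (ties by
#'   smaller index).
#' @export
select_by_threshold <- function(weights, delta) {
  keep <- which(weights >= delta)
  if (!length(keep))
    stop("no feature reaches the weight threshold delta = ", delta,
         "; lower delta (max weight is ", format(max(weights)), ")")
  keep[order(-weights[keep], keep)]
}

#' Pairwise-redundancy pruning of selected features
#'
#' Walks the selected features in descending-weight order; whenever two
#' retained features correlate with \code{|r| > lambda} across the
#' training samples, the lower-weight member is dropped.  Greedy and
#' deterministic: the highest-weight feature always survives, and a
#' dropped feature cannot eliminate others.
#'
#' @param X samples x features matrix (training data; the correlations
#'   are computed on its columns).
#' @param weights Relief weight vector over all features.
#' @param selected integer indices from \code{\link{select_by_threshold}}
#'   (descending-weight order is enforced internally).
#' @param lambda correlation threshold in (0, 1].
#' @return retained feature indices, descending-weight order.
#' @export
redundancy_prune <- function(X, weights, selected, lambda) {
  if (!length(selected)) stop("'selected' must be non-empty")
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  sel <- selected[order(-weights[selected], selected)]
  if (length(sel) > 1L) {
    Cm <- abs(suppressWarnings(stats::cor(X[, sel, drop = FALSE])))
    Cm[is.na(Cm)] <- 0  # constant column in X: no evidence of redundancy
    alive <- rep(TRUE, length(sel))
    for (a in seq_along(sel)) {
      if (!alive[a]) next
      worse <- which(alive & seq_along(sel) > a & Cm[a, ] > lambda)
      alive[worse] <- FALSE
    }
    sel <- sel[alive]
  }
  sel
}

#' Full selection step: Relief threshold + redundancy pruning
#'
#' @param X samples x features training matrix.
#' @param y binary labels.
#' @param delta Relief weight threshold.
#' @param lambda redundancy correlation threshold.
#' @param weights optional precomputed Relief weights for \code{(X, y)}.
#' @return object of class \code{selection_result}: \code{relief_weights},
#'   \code{delta}, \code{lambda}, \code{selected} (descending-weight
#'   feature indices), \code{feature_names}.
#' @export
select_features <- function(X, y, delta, lambda, weights = NULL) {
  if (is.null(weights)) weights <- relief_weights(X, y)
  sel <- select_by_threshold(weights, delta)
  sel <- redundancy_prune(X, weights, sel, lambda)
  structure(list(relief_weights = weights, delta = delta, lambda = lambda,
                 selected = sel,
                 feature_names = if (!is.null(colnames(X)))
                   colnames(X)[sel] else NULL),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Feature selection: ", length(x$selected), " features retained ",
      "(delta = ", x$delta, ", lambda = ", x$lambda, ")\n", sep = "")
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param sel a \code{selection_result}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(delta = sel$delta, lambda = sel$lambda,
         selected = sel$selected,
         feature_names = sel$feature_names,
         relief_weights = as.list(stats::setNames(
           as.numeric(sel$relief_weights), names(sel$relief_weights)))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
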