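#' Weighted-graph local clustering coefficients
#'
#' For node \code{i} with neighbour set \eqn{\Delta_i} (nodes joined to
#' \code{i} by a nonzero-weight edge) the feature is
#' \deqn{f_i = \frac{2 \sum_{j \in \Delta_i} w_{ij}^{1/3}}
#'                  {3\,|\Delta_i|\,(|\Delta_i| - 1)},}
#' with a sign-preserving cube root for negative weights
#' (\code{sign(w) |w|^{1/3}}, the default) or \code{|w|^{1/3}} when
#' \code{weight_mode = "absolute"}.  Nodes with at most one neighbour
#' (leaves, isolates) get \code{f = 0}: the denominator vanishes there
#' and zero is the continuous extension as the neighbour sum does too.
#' Unlike the triangle-based weighted clustering coefficient -- which is
#' identically zero on any tree -- this degree-normalized neighbour-sum
#' form yields informative values on spanning trees, which is why it is
#' the feature used on the pruned high-order network.
#'
#' @param graph a \code{spanning_tree}, a \code{static_network}, a
#'   \code{thresholded_hon}, or a symmetric numeric weight matrix.  Exact
#'   zeros off the diagonal are treated as absent edges; the diagonal is
#'   ignored.
#' @param weight_mode \code{"signed"} (default) or \code{"absolute"}.
#' @return numeric vector of one coefficient per node.
#' @examples
#' # path graph 1-2-3 with unit weights: centre node -> 2/3, leaves -> 0
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
#' clustering_coefficients(A)
#' @export
clustering_coefficients <- function(graph,
                                    weight_mode = c("signed", "absolute")) {
  weight_mode <- match.arg(weight_mode)
  A <- if (inherits(graph, "spanning_tree")) tree_adjacency(graph)
  else if (inherits(graph, "static_network")) graph$matrix
  else if (inherits(graph, "thresholded_hon")) graph$H_sig
  else as.matrix(graph)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8)
    stop("graph weights must form a symmetric matrix")
  diag(A) <- 0
  croot <- if (weight_mode == "signed") function(w) sign(w) * abs(w)^(1 / 3)
  else function(w) abs(w)^(1 / 3)
  deg <- rowSums(A != 0)
  s <- rowSums(croot(A) * (A != 0))
  f <- ifelse(deg <= 1, 0, 2 * s / (3 * deg * (deg - 1)))
  names(f) <- rownames(A)
  f
}

#' Per-subject network features for a cohort
#'
#' Runs the chosen network-construction pipeline independently for every
#' subject and assembles the subjects x features matrix of weighted
#' clustering coefficients.  Methods:
#' \describe{
#'   \item{\code{pen}}{static Pearson network; R features (one per region).}
#'   \item{\code{pan}}{static partial-correlation network; R features.}
#'   \item{\code{hon}}{FDR-thresholded high-order network; P = R(R-1)/2
#'     features (one per region pair).}
#'   \item{\code{hon_mst}}{spanning tree of the (unthresholded) high-order
#'     network; P features.}
#' }
#'
#' @param cohort an \code{fc_cohort}.
#' @param method one of \code{"pen"}, \code{"pan"}, \code{"hon"},
#'   \code{"hon_mst"}.
#' @param cfg a \code{\link{pipeline_config}} (window length/step, MST
#'   algorithm and edge transform, FDR alpha, shrinkage, weight mode).
#' @return object of class \code{feature_matrix}: \code{X} (subjects x
#'   features), \code{feature_names}, \code{method}, \code{labels},
#'   \code{subject_ids}.
#' @export
build_feature_matrix <- function(cohort,
                                 method = c("hon_mst", "hon", "pen", "pan"),
                                 cfg = pipeline_config()) {
  method <- match.arg(method)
  wcfg <- window_config(cfg$window_N, cfg$window_S)
  rows <- vector("list", length(cohort$subjects))
  for (k in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[k]]
    f <- tryCatch(
      .subject_features(s$timeseries, method, cfg, wcfg),
      error = function(e)
        stop("subject '", s$subject_id, "': ", conditionMessage(e),
             call. = FALSE))
    rows[[k]] <- f
  }
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  structure(list(X = X, feature_names = colnames(X), method = method,
                 labels = cohort_labels(cohort),
                 subject_ids = rownames(X)),
            class = "feature_matrix")
}

.subject_features <- function(ts, method, cfg, wcfg) {
  if (method %in% c("pen", "pan")) {
    net <- if (method == "pen") static_pearson_network(ts)
    else static_partial_network(ts, shrinkage = cfg$shrinkage)
    return(clustering_coefficients(net, cfg$weight_mode))
  }
  stack <- dynamic_stack(ts, wcfg)
  hon <- highorder_matrix(stack)
  g <- if (method == "hon") {
    fdr_threshold(hon, alpha = cfg$fdr_alpha)
  } else {
    if (cfg$mst_algorithm == "kruskal") kruskal_mst(hon, cfg$edge_transform)
    else prim_mst(hon, cfg$edge_transform)
  }
  f <- clustering_coefficients(g, cfg$weight_mode)
  if (is.null(names(f))) names(f) <- hon$pair_map$label
  f
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix (", x$method, "): ", nrow(x$X), " subjects x ",
      ncol(x$X), " features\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as TSV
#' @param fm a \code{feature_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_ids, label = fm$labels,
                   fm$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean selected-feature weight per region
#'
#' For reporting which regions discriminate the groups: each region's
#' score is the mean Relief weight over the *selected* pair features
#' whose region pair contains it; regions appearing in no selected
#' feature score 0.
#'
#' @param selected integer indices of selected features (pair nodes).
#' @param weights Relief weight vector over all features.
#' @param pm \code{\link{pair_map}} of the feature space.
#' @param roi_codes region codes (length R).
#' @return named numeric vector of per-region mean weights.
#' @export
roi_weight_aggregation <- function(selected, weights, pm, roi_codes) {
  R <- length(roi_codes)
  out <- stats::setNames(numeric(R), roi_codes)
  if (!length(selected)) return(out)
  for (r in seq_len(R)) {
    hit <- selected[pm$i[selected] == r | pm$j[selected] == r]
    if (length(hit)) out[r] <- mean(weights[hit])
  }
  out
}

#' Mean selected-feature weight between lobe modules
#'
#' 5 x 5 symmetric module-interaction matrix: cell (m1, m2) is the mean
#' Relief weight over selected pair features whose two regions fall in
#' modules m1 and m2 (in either order); cells with no selected feature
#' are 0.
#'
#' @param selected integer indices of selected pair features.
#' @param weights Relief weight vector over all features.
#' @param pm \code{\link{pair_map}} of the feature space.
#' @param partition character vector mapping each region (by index) to a
#'   module; values from \{frontal, occipital, parietal, subcortical,
#'   temporal\}.
#' @return symmetric 5 x 5 matrix with module dimnames.
#' @export
module_interaction_matrix <- function(selected, weights, pm, partition) {
  mods <- c("frontal", "occipital", "parietal", "subcortical", "temporal")
  bad <- setdiff(unique(partition), mods)
  if (length(bad)) stop("unknown module label(s): ", paste(bad, collapse = ", "))
  M <- matrix(0, 5, 5, dimnames = list(mods, mods))
  cnt <- matrix(0L, 5, 5)
  for (s in selected) {
    m1 <- partition[pm$i[s]]; m2 <- partition[pm$j[s]]
    if (is.na(m1) || is.na(m2))
      stop("region ", pm$i[s], " or ", pm$j[s], " missing from the partition")
    a <- match(m1, mods); b <- match(m2, mods)
    lo <- min(a, b); hi <- max(a, b)
    M[lo, hi] <- M[lo, hi] + weights[s]
    cnt[lo, hi] <- cnt[lo, hi] + 1L
  }
  nz <- cnt > 0
  M[nz] <- M[nz] / cnt[nz]
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}
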