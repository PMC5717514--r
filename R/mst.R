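#' @name spanning_tree
#' @title Spanning-tree pruning of weighted networks
#'
#' @description
#' The high-order network is pruned to a spanning tree: all P pair-nodes
#' are kept, and exactly P-1 edges minimizing the total *transformed*
#' edge length are retained.  Two edge-length orientations are exposed:
#' \describe{
#'   \item{\code{retain_strongest} (default)}{length \code{d = 1 - |w|}:
#'     the tree keeps the strongest (largest-magnitude) correlations, the
#'     usual convention in brain-network spanning-tree analysis.}
#'   \item{\code{literal_minimum}}{length \code{d = w}: the literal
#'     minimum-weight tree over the raw correlation weights.}
#' }
#' Tree edges carry the original weight \code{w} forward (feature
#' computation consumes connectivity weights, not lengths).  Ties in
#' \code{d} are broken deterministically by (smaller node id, larger node
#' id).
NULL

.edge_lengths <- function(w, transform) {
  switch(transform,
         retain_strongest = 1 - abs(w),
         literal_minimum = w,
         stop("unknown transform: ", transform))
}

.as_edge_list <- function(H) {
  if (inherits(H, "high_order_network")) H <- H$H
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) stop("weight matrix must be square")
  if (max(abs(H - t(H))) > 1e-8) stop("weight matrix must be symmetric")
  if (!all(is.finite(H))) stop("weight matrix must be finite")
  P <- nrow(H)
  pm <- pair_map(P)  # enumerates node pairs a < b of the P-node graph
  data.frame(a = pm$i, b = pm$j, w = H[cbind(pm$i, pm$j)])
}

.uf_find <- function(parent, x) {
  root <- x
  while (parent[root] != root) root <- parent[root]
  # path compression
  while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
  root
}

#' Minimum spanning tree by Kruskal's algorithm
#'
#' Sorts all edges by transformed length and grows a forest with a
#' union-find structure (path compression), accepting each edge that
#' joins two components.
#'
#' @param H symmetric weight matrix (or \code{high_order_network}); the
#'   graph is taken as complete over its rows.
#' @param transform \code{"retain_strongest"} (default, length
#'   \code{1 - |w|}) or \code{"literal_minimum"} (length \code{w}).
#' @return object of class \code{spanning_tree}: \code{n_nodes},
#'   \code{edges} (data.frame \code{a}, \code{b}, \code{weight} with
#'   original weights), \code{algorithm}, \code{transform},
#'   \code{total_cost} (sum of transformed lengths).
#' @export
kruskal_mst <- function(H, transform = c("retain_strongest",
                                         "literal_minimum")) {
  transform <- match.arg(transform)
  pm_attr <- if (inherits(H, "high_order_network")) H$pair_map else NULL
  el <- .as_edge_list(H)
  P <- max(el$b)
  d <- .edge_lengths(el$w, transform)
  ord <- order(d, el$a, el$b)
  parent <- seq_len(P)
  find <- function(x) { while (parent[x] != x) {
    parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  take <- integer(P - 1L); nt <- 0L
  for (e in ord) {
    ra <- find(el$a[e]); rb <- find(el$b[e])
    if (ra != rb) {
      parent[ra] <- rb
      nt <- nt + 1L
      take[nt] <- e
      if (nt == P - 1L) break
    }
  }
  if (nt < P - 1L) stop("input graph is disconnected; no spanning tree exists")
  edges <- el[take, , drop = FALSE]
  .new_tree(P, edges, "kruskal", transform, pm_attr)
}

#' Minimum spanning tree by Prim's algorithm
#'
#' Grows the tree from node 1, repeatedly attaching the node with the
#' smallest transformed length to the current tree (dense O(P^2)
#' implementation; ties resolved toward the smallest node id).
#'
#' @inheritParams kruskal_mst
#' @return a \code{spanning_tree} (same contract as
#'   \code{\link{kruskal_mst}}).
#' @export
prim_mst <- function(H, transform = c("retain_strongest",
                                      "literal_minimum")) {
  transform <- match.arg(transform)
  pm_attr <- if (inherits(H, "high_order_network")) H$pair_map else NULL
  if (inherits(H, "high_order_network")) H <- H$H
  H <- as.matrix(H)
  if (max(abs(H - t(H))) > 1e-8) stop("weight matrix must be symmetric")
  if (!all(is.finite(H))) stop("weight matrix must be finite")
  P <- nrow(H)
  D <- .edge_lengths(H, transform)
  in_tree <- logical(P); in_tree[1L] <- TRUE
  best_d <- D[1L, ]; best_from <- rep(1L, P)
  best_d[1L] <- Inf
  ea <- integer(P - 1L); eb <- integer(P - 1L)
  for (k in seq_len(P - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_d[cand])]  # which.min -> smallest id on ties
    u <- best_from[v]
    ea[k] <- min(u, v); eb[k] <- max(u, v)
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best_d
    best_d[upd] <- D[v, upd]
    best_from[upd] <- v
  }
  edges <- data.frame(a = ea, b = eb, w = H[cbind(ea, eb)])
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  .new_tree(P, edges, "prim", transform, pm_attr)
}

.new_tree <- function(P, edges, algorithm, transform, pm_attr) {
  rownames(edges) <- NULL
  names(edges) <- c("a", "b", "weight")
  tree <- structure(list(
    n_nodes = P,
    edges = edges,
    algorithm = algorithm,
    transform = transform,
    total_cost = sum(.edge_lengths(edges$weight, transform))),
    class = "spanning_tree")
  if (!is.null(pm_attr)) attr(tree, "pair_map") <- pm_attr
  tree
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("Spanning tree (", x$algorithm, ", ", x$transform, "): ",
      x$n_nodes, " nodes, ", nrow(x$edges), " edges, total cost ",
      format(x$total_cost), "\n", sep = "")
  invisible(x)
}

#' Check that a spanning tree is a valid tree
#'
#' @param tree a \code{spanning_tree}.
#' @return TRUE iff the edge list has exactly \code{n_nodes - 1} edges,
#'   touches every node, and forms a single acyclic component; otherwise
#'   FALSE (with the reasons as attribute \code{"reasons"}).
#' @export
validate_tree <- function(tree) {
  P <- tree$n_nodes
  e <- tree$edges
  reasons <- character(0)
  if (nrow(e) != P - 1L)
    reasons <- c(reasons, sprintf("expected %d edges, found %d", P - 1L, nrow(e)))
  if (nrow(e) && (min(c(e$a, e$b)) < 1 || max(c(e$a, e$b)) > P))
    reasons <- c(reasons, "edge endpoint out of node range")
  parent <- seq_len(P)
  find <- function(x) { while (parent[x] != x) {
    parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  acyclic <- TRUE
  for (k in seq_len(nrow(e))) {
    ra <- find(e$a[k]); rb <- find(e$b[k])
    if (ra == rb) { acyclic <- FALSE; break }
    parent[ra] <- rb
  }
  if (!acyclic) reasons <- c(reasons, "edge set contains a cycle")
  n_comp <- length(unique(vapply(seq_len(P), find, integer(1))))
  if (acyclic && n_comp != 1L)
    reasons <- c(reasons, sprintf("%d connected components", n_comp))
  ok <- length(reasons) == 0L
  if (!ok) attr(ok, "reasons") <- reasons
  ok
}

#' Spanning tree as a weighted adjacency matrix
#'
#' @param tree a \code{spanning_tree}.
#' @return symmetric \code{n_nodes} x \code{n_nodes} matrix with original
#'   edge weights and zero elsewhere.
#' @export
tree_adjacency <- function(tree) {
  A <- matrix(0, tree$n_nodes, tree$n_nodes)
  A[cbind(tree$edges$a, tree$edges$b)] <- tree$edges$weight
  A[cbind(tree$edges$b, tree$edges$a)] <- tree$edges$weight
  pm <- attr(tree, "pair_map")
  if (!is.null(pm)) dimnames(A) <- list(pm$label, pm$label)
  A
}

#' Write / read a spanning tree as an edge-list TSV
#'
#' @param tree a \code{spanning_tree}.
#' @param path output file.
#' @return \code{path} invisibly (write) or a \code{spanning_tree} (read).
#' @export
write_tree <- function(tree, path) {
  e <- tree$edges
  pm <- attr(tree, "pair_map")
  if (!is.null(pm)) {
    e$label_a <- pm$label[e$a]
    e$label_b <- pm$label[e$b]
  }
  header <- sprintf("# n_nodes=%d algorithm=%s transform=%s",
                    tree$n_nodes, tree$algorithm, tree$transform)
  con <- file(path, "w")
  writeLines(header, con)
  utils::write.table(format(e, digits = 17), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  e <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                         stringsAsFactors = FALSE)
  .new_tree(as.integer(meta[["n_nodes"]]),
            data.frame(a = e$a, b = e$b, w = e$weight),
            meta[["algorithm"]], meta[["transform"]], NULL)
}
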