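#' High-order functional connectivity network
#'
#' Nodes of the high-order network are region *pairs*; the edge weight
#' between pair nodes \code{(i,j)} and \code{(p,q)} is the Pearson
#' correlation between their windowed-connectivity time series, i.e. the
#' correlation of rows of the stack's \code{Y} matrix.  The result is a
#' symmetric P x P matrix with unit diagonal, P = R(R-1)/2.
#'
#' @param stack a \code{low_order_stack} with \code{K >= 3} windows.
#' @return object of class \code{high_order_network} with elements
#'   \code{H} (P x P), \code{pair_map}, \code{K}.
#' @export
highorder_matrix <- function(stack) {
  if (!inherits(stack, "low_order_stack"))
    stop("'stack' must be a low_order_stack")
  if (stack$K < 3L) stop("need at least 3 windows (K >= 3)")
  Y <- stack$Y
  sds <- apply(Y, 1, stats::sd)
  if (any(sds == 0))
    stop("constant connectivity time series for pair(s): ",
         paste(stack$pair_map$label[sds == 0], collapse = ", "),
         " (degenerate dynamics, e.g. duplicated regional signals)")
  H <- stats::cor(t(Y))
  H[H > 1] <- 1; H[H < -1] <- -1
  diag(H) <- 1
  dimnames(H) <- list(stack$pair_map$label, stack$pair_map$label)
  structure(list(H = H, pair_map = stack$pair_map, K = stack$K),
            class = "high_order_network")
}

#' @export
print.high_order_network <- function(x, ...) {
  cat("High-order network:", nrow(x$H), "pair nodes, built from K =",
      x$K, "windows\n")
  invisible(x)
}

#' P-values for high-order correlations
#'
#' Two-sided p-values for each entry of a correlation matrix estimated
#' from \code{K} windows, via \eqn{t = r\sqrt{K-2}/\sqrt{1-r^2}} on
#' \code{K - 2} degrees of freedom.  The diagonal is set to 0 by
#' convention and excluded from any test family.  Note that overlapping
#' windows make successive connectivity values autocorrelated, so the
#' nominal degrees of freedom overstate the effective sample size; no
#' autocorrelation correction is applied.
#'
#' @param H correlation matrix (or \code{high_order_network}).
#' @param K number of windows used to estimate the correlations
#'   (\code{>= 4}); taken from the network object when omitted.
#' @return matrix of p-values with the dimensions of \code{H}.
#' @export
correlation_pvalues <- function(H, K = NULL) {
  if (inherits(H, "high_order_network")) {
    if (is.null(K)) K <- H$K
    H <- H$H
  }
  if (is.null(K) || K < 4) stop("need K >= 4")
  r <- pmin(pmax(H, -1), 1)
  p <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  off <- abs(r) < 1
  tstat <- r[off] * sqrt(K - 2) / sqrt(1 - r[off]^2)
  p[off] <- 2 * stats::pt(-abs(tstat), df = K - 2)
  diag(p) <- 0
  p
}

#' FDR-threshold a high-order network (HON baseline)
#'
#' Benjamini-Hochberg step-up over the P(P-1)/2 upper-triangle p-values at
#' level \code{alpha}; surviving entries keep their correlation value,
#' all others are set to 0.  The retained mask is symmetrized and the
#' unit diagonal preserved.  This thresholded network is the
#' significance-filtered baseline; the spanning-tree pathway consumes the
#' unthresholded matrix instead, since tree pruning replaces significance
#' filtering.
#'
#' @param hon a \code{high_order_network}.
#' @param alpha FDR level in (0, 1).
#' @param pvals optional precomputed p-value matrix (defaults to
#'   \code{\link{correlation_pvalues}} on \code{hon}).
#' @return object of class \code{thresholded_hon} with elements
#'   \code{H_sig}, \code{mask}, \code{alpha}, \code{n_tests},
#'   \code{n_retained}, \code{pair_map}.
#' @export
fdr_threshold <- function(hon, alpha = 0.05, pvals = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!inherits(hon, "high_order_network"))
    stop("'hon' must be a high_order_network")
  if (is.null(pvals)) pvals <- correlation_pvalues(hon)
  H <- hon$H
  ut <- upper.tri(H)
  p_up <- pvals[ut]
  if (any(p_up < 0 | p_up > 1)) stop("p-values must lie in [0, 1]")
  keep_up <- stats::p.adjust(p_up, method = "BH") <= alpha
  mask <- matrix(FALSE, nrow(H), ncol(H))
  mask[ut] <- keep_up
  mask <- mask | t(mask)
  diag(mask) <- TRUE
  H_sig <- ifelse(mask, H, 0)
  dimnames(H_sig) <- dimnames(H)
  structure(list(H_sig = H_sig, mask = mask, alpha = alpha,
                 n_tests = sum(ut), n_retained = sum(keep_up),
                 pair_map = hon$pair_map),
            class = "thresholded_hon")
}

#' @export
print.thresholded_hon <- function(x, ...) {
  cat("FDR-thresholded high-order network: ", x$n_retained, "/", x$n_tests,
      " edges retained at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Write a high-order network to TSV
#'
#' Dense form: the full P x P matrix with pair labels.  Edge-list form:
#' one row per upper-triangle edge with both region pairs spelled out
#' and, when \code{K} is available, the correlation p-value.
#'
#' @param x a \code{high_order_network} or \code{thresholded_hon}.
#' @param path output file.
#' @param format \code{"dense"} or \code{"edges"}.
#' @return \code{path}, invisibly.
#' @export
write_highorder <- function(x, path, format = c("dense", "edges")) {
  format <- match.arg(format)
  H <- if (inherits(x, "thresholded_hon")) x$H_sig else x$H
  pm <- x$pair_map
  if (is.null(pm$label)) pm$label <- paste(pm$i, pm$j, sep = "-")
  if (is.null(rownames(H))) dimnames(H) <- list(pm$label, pm$label)
  if (format == "dense") {
    utils::write.table(data.frame(pair = rownames(H), H,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ut <- which(upper.tri(H), arr.ind = TRUE)
  df <- data.frame(node_a = ut[, 1], node_b = ut[, 2],
                   pair_a = pm$label[ut[, 1]], pair_b = pm$label[ut[, 2]],
                   weight = H[ut])
  if (!is.null(x$K)) {
    pv <- correlation_pvalues(H, x$K)
    df$p_value <- pv[ut]
  }
  if (inherits(x, "thresholded_hon")) df <- df[df$weight != 0, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
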