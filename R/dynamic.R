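#' Number of sliding windows
#'
#' For a series of \code{M} time points cut into windows of length
#' \code{N} advanced by step \code{S} (in TRs),
#' \deqn{K = \lfloor (M - N)/S \rfloor + 1.}
#'
#' @param M series length in time points.
#' @param N window length in time points.
#' @param S step size in time points (>= 1).
#' @return integer window count \code{K >= 1}.
#' @examples
#' count_windows(238, 60, 1)  # 179
#' @export
count_windows <- function(M, N, S) {
  if (N > M) stop("window length N = ", N, " exceeds series length M = ", M)
  if (N < 1 || S < 1) stop("N and S must be >= 1")
  as.integer(floor((M - N) / S) + 1)
}

#' Sliding-window configuration
#'
#' @param N window length in time points (TRs).
#' @param S step size in time points (TRs), default 1.
#' @return list of class \code{window_config}.
#' @export
window_config <- function(N = 60, S = 1) {
  if (N < 1 || S < 1) stop("N and S must be >= 1")
  structure(list(N = as.integer(N), S = as.integer(S)),
            class = "window_config")
}

#' Segment a time series into sliding windows
#'
#' Window \code{k} (k = 0..K-1) covers rows \code{[kS, kS + N)} in 0-based
#' half-open convention, i.e. rows \code{(kS + 1):(kS + N)} of the input.
#'
#' @param ts numeric time x region matrix.
#' @param cfg a \code{\link{window_config}}.
#' @return list of K matrices, each N x region.
#' @export
segment_windows <- function(ts, cfg) {
  ts <- as.matrix(ts)
  K <- count_windows(nrow(ts), cfg$N, cfg$S)
  lapply(0:(K - 1L), function(k) ts[(k * cfg$S + 1L):(k * cfg$S + cfg$N), ,
                                    drop = FALSE])
}

#' Windowed correlation networks and connectivity time series
#'
#' Computes, for every window, the R x R Pearson correlation matrix of
#' the regional series (the low-order network of that window), and
#' assembles the P x K connectivity time-series matrix \code{Y}: row
#' \code{p} of \code{Y} is the sequence of windowed correlations of
#' region pair \code{p} across the K windows, in \code{\link{pair_map}}
#' order.
#'
#' @param windows list of N x R matrices from
#'   \code{\link{segment_windows}}, each with at least 3 rows.
#' @param roi_codes optional region codes for labelling.
#' @return object of class \code{low_order_stack} with elements
#'   \code{K}, \code{R}, \code{matrices} (list of R x R correlation
#'   matrices), \code{Y} (P x K), and \code{pair_map}.
#' @export
windowed_correlations <- function(windows, roi_codes = NULL) {
  K <- length(windows)
  if (K < 1L) stop("no windows supplied")
  R <- ncol(windows[[1L]])
  if (is.null(roi_codes)) roi_codes <- colnames(windows[[1L]])
  if (is.null(roi_codes)) roi_codes <- sprintf("V%d", seq_len(R))
  pm <- pair_map(R, roi_codes)
  idx <- cbind(pm$i, pm$j)
  Y <- matrix(NA_real_, nrow = nrow(pm), ncol = K)
  mats <- vector("list", K)
  for (k in seq_len(K)) {
    w <- windows[[k]]
    if (nrow(w) < 3L)
      stop("window ", k, " has fewer than 3 time points")
    sds <- apply(w, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance region in window ", k, ": ",
           paste(roi_codes[sds == 0], collapse = ", "))
    C <- stats::cor(w)
    C[C > 1] <- 1; C[C < -1] <- -1
    diag(C) <- 1
    dimnames(C) <- list(roi_codes, roi_codes)
    mats[[k]] <- C
    Y[, k] <- C[idx]
  }
  rownames(Y) <- pm$label
  structure(list(K = K, R = R, matrices = mats, Y = Y, pair_map = pm),
            class = "low_order_stack")
}

#' @export
print.low_order_stack <- function(x, ...) {
  cat("Low-order dynamic connectivity stack\n")
  cat("  regions R =", x$R, " pairs P =", nrow(x$Y), " windows K =", x$K, "\n")
  invisible(x)
}

#' Convenience: sliding windows + windowed correlations in one call
#'
#' @param ts numeric time x region matrix.
#' @param cfg a \code{\link{window_config}}.
#' @return a \code{low_order_stack}.
#' @export
dynamic_stack <- function(ts, cfg = window_config()) {
  windowed_correlations(segment_windows(ts, cfg), roi_codes = colnames(ts))
}

#' Static Pearson correlation network (PEN baseline)
#'
#' Full-series Pearson correlation matrix over all time points; identical
#' to a single window spanning the whole series.
#'
#' @param ts numeric time x region matrix (>= 3 rows, no constant column).
#' @return list of class \code{static_network} with \code{kind = "pearson"}
#'   and the R x R \code{matrix}.
#' @export
static_pearson_network <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(which(sds == 0), collapse = ", "))
  C <- stats::cor(ts)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  structure(list(kind = "pearson", matrix = C), class = "static_network")
}

#' Static partial correlation network (PAN baseline)
#'
#' Partial correlations from the (optionally ridge-shrunk) inverse of the
#' correlation matrix:
#' \deqn{r_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}},}
#' with \eqn{\Omega = ((1-s) C + s I)^{-1}}.  The diagonal is set to 0 by
#' convention.
#'
#' @param ts numeric time x region matrix.
#' @param shrinkage ridge weight \code{s} in [0, 1]; default 0.  Required
#'   (> 0) when the correlation matrix is singular, e.g. when the number
#'   of time points does not exceed the number of regions.
#' @return a \code{static_network} with \code{kind = "partial"}.
#' @export
static_partial_network <- function(ts, shrinkage = 0) {
  ts <- as.matrix(ts)
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must lie in [0, 1]")
  C <- static_pearson_network(ts)$matrix
  Cs <- (1 - shrinkage) * C + shrinkage * diag(ncol(C))
  Om <- tryCatch(solve(Cs), error = function(e)
    stop("correlation matrix is singular; increase 'shrinkage' ",
         "(e.g. static_partial_network(ts, shrinkage = 0.1))",
         call. = FALSE))
  d <- sqrt(diag(Om))
  Pmat <- -Om / tcrossprod(d)
  Pmat <- (Pmat + t(Pmat)) / 2
  diag(Pmat) <- 0
  dimnames(Pmat) <- dimnames(C)
  structure(list(kind = "partial", matrix = Pmat), class = "static_network")
}
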