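#' Enumerate region pairs in canonical order
#'
#' High-order networks take region *pairs* as nodes.  This helper fixes the
#' canonical ordering used throughout the package: lexicographic over
#' \code{(i, j)} with \code{i < j}, 1-based region indices, giving
#' \code{P = R(R-1)/2} pairs.  Row \code{p} of every connectivity
#' time-series matrix and row/column \code{p} of every high-order matrix
#' refer to the same pair \code{(i_p, j_p)}.
#'
#' @param R number of regions (>= 2).
#' @param roi_codes optional character vector of length \code{R} of region
#'   abbreviations; when supplied, a \code{label} column \code{"A-B"} is
#'   added.
#' @return data.frame with columns \code{node} (1..P), \code{i}, \code{j}
#'   and optionally \code{label}.
#' @examples
#' pair_map(4)
#' @export
pair_map <- function(R, roi_codes = NULL) {
  if (!is.numeric(R) || length(R) != 1L || R < 2)
    stop("'R' must be a single integer >= 2")
  R <- as.integer(R)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(a) (a + 1L):R), use.names = FALSE)
  pm <- data.frame(node = seq_along(i), i = i, j = j)
  if (!is.null(roi_codes)) {
    if (length(roi_codes) != R)
      stop("'roi_codes' must have length R = ", R)
    pm$label <- paste(roi_codes[i], roi_codes[j], sep = "-")
  }
  pm
}

#' Number of region pairs for R regions
#' @param R number of regions.
#' @return \code{R(R-1)/2}.
#' @export
n_pairs <- function(R) as.integer(R * (R - 1) / 2)
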