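#' Parameters for the synthetic two-group cohort generator
#'
#' The generator emulates the statistical structure that high-order
#' connectivity analysis detects: in the patient group the *temporal
#' co-fluctuation* of selected region-pair connectivities is shared, while
#' in controls the same pairs fluctuate independently.  Mean connectivity
#' strength is matched between groups, so low-order (static) networks
#' carry no planted group signal.
#'
#' Each planted couple \code{((i,j),(p,q))} names two region pairs.  The
#' four regions of a couple share one *static* latent factor \code{w(t)}
#' with loading \code{sqrt(rho_bar)}, \code{rho_bar = coupling_strength/2};
#' on top of it, each pair's residual sources are mixed with a slowly
#' varying correlation so that the pair's total instantaneous correlation
#' is \deqn{\rho(t) = c\,(1 + \sin(2\pi t/T + \phi))/2,}
#' oscillating around its time average \code{rho_bar} while every region
#' keeps constant unit signal variance.  Consequently the *static*
#' (full-series) correlation structure is identical between groups --
#' within-pair and cross-pair correlations both average \code{rho_bar} --
#' and only the *temporal co-fluctuation* of windowed correlations
#' carries the group difference: in group 1 all planted pairs of a
#' subject use one common modulator (one period and one subject-random
#' phase), so their windowed-correlation series rise and fall together
#' -- within couples and across them -- while in group 0 each pair draws
#' an independent modulator (independent phase and period).  All regions additionally receive a weak static global
#' signal (\code{background_coupling}) and white measurement noise.
#' A region may belong to at most one planted pair.
#'
#' @param n_per_group subjects per group.
#' @param R number of regions.
#' @param M time points per subject.
#' @param planted_pairs list of couples; each couple is a list of two
#'   integer vectors \code{c(i, j)} and \code{c(p, q)} (1-based region
#'   indices, i < j).  Default: four disjoint couples over the first 16
#'   regions.
#' @param modulator_period nominal modulator period in time points.
#' @param coupling_strength peak gain of the planted coupling, in [0, 1];
#'   0 removes the planted structure entirely.
#' @param noise_sd standard deviation of the per-region white noise.
#' @param background_coupling gain of the static global signal shared by
#'   all regions (constant over time, identical between groups).
#' @param period_jitter relative half-width of the uniform period draw;
#'   each modulator's period is
#'   \code{modulator_period * U(1 - period_jitter, 1 + period_jitter)}.
#' @param seed integer seed; the generator is fully deterministic given
#'   the seed.
#' @return a list of class \code{synth_params}.
#' @export
synth_params <- function(n_per_group = 20, R = 20, M = 238,
                         planted_pairs = default_planted_pairs(R),
                         modulator_period = 120,
                         coupling_strength = 0.9, noise_sd = 0.2,
                         background_coupling = 0.1,
                         period_jitter = 0.3, seed = 1) {
  p <- list(n_per_group = as.integer(n_per_group), R = as.integer(R),
            M = as.integer(M), planted_pairs = planted_pairs,
            modulator_period = modulator_period,
            coupling_strength = coupling_strength, noise_sd = noise_sd,
            background_coupling = background_coupling,
            period_jitter = period_jitter, seed = as.integer(seed))
  if (p$n_per_group < 1 || p$R < 2 || p$M < 2)
    stop("n_per_group, R and M must be positive (R >= 2, M >= 2)")
  if (p$coupling_strength < 0 || p$coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  if (p$noise_sd <= 0) stop("noise_sd must be > 0")
  seen <- character(0)
  for (cp in p$planted_pairs) {
    if (length(cp) != 2L)
      stop("each planted couple must contain exactly two region pairs")
    for (pr in cp) {
      if (length(pr) != 2L || pr[1] >= pr[2])
        stop("planted pairs must be c(i, j) with i < j")
      if (any(pr > p$R) || any(pr < 1))
        stop("planted region index out of range 1..R = ", p$R)
      key <- paste(pr, collapse = "-")
      if (key %in% seen) stop("planted pairs must be distinct")
      seen <- c(seen, key)
      dup <- intersect(pr, unlist(lapply(seen[-length(seen)], function(k)
        as.integer(strsplit(k, "-")[[1]]))))
      if (length(dup))
        stop("region ", dup[1], " appears in more than one planted pair")
    }
  }
  class(p) <- "synth_params"
  p
}

#' Default planted couples for a synthetic cohort
#'
#' As many disjoint couples as \code{R} allows, four regions each:
#' ((1,2),(3,4)), ((5,6),(7,8)), ... -- five couples over all twenty
#' regions at the default \code{R = 20}.
#'
#' @param R number of regions (>= 4).
#' @return list of couples as used by \code{\link{synth_params}}.
#' @export
default_planted_pairs <- function(R) {
  if (R < 4) stop("need R >= 4 for a planted couple")
  n_couples <- max(1L, R %/% 4L)
  lapply(seq_len(n_couples), function(c) {
    base <- (c - 1L) * 4L
    list(c(base + 1L, base + 2L), c(base + 3L, base + 4L))
  })
}

#' Generate a synthetic two-group cohort with planted high-order structure
#'
#' See \code{\link{synth_params}} for the generative model.  Subjects are
#' ordered controls first (label 0), then patients (label 1); region codes
#' are \code{"R01"}, \code{"R02"}, ...
#'
#' @param params a \code{synth_params} object.
#' @return an \code{fc_cohort}.
#' @export
generate_synthetic_cohort <- function(params = synth_params()) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  set.seed(params$seed)
  R <- params$R; M <- params$M
  roi_codes <- sprintf("R%02d", seq_len(R))
  tt <- seq_len(M)
  draw_modulator <- function() {
    period <- params$modulator_period *
      stats::runif(1, 1 - params$period_jitter, 1 + params$period_jitter)
    phase <- stats::runif(1, 0, 2 * pi)
    sin(2 * pi * tt / period + phase)
  }
  c0 <- params$coupling_strength
  rho_bar <- c0 / 2
  make_subject <- function(id, label) {
    G <- stats::rnorm(M)
    x <- params$background_coupling * matrix(G, M, R) +
      params$noise_sd * matrix(stats::rnorm(M * R), M, R)
    shared <- if (label == 1L) draw_modulator() else NULL
    for (cp in params$planted_pairs) {
      w <- stats::rnorm(M)  # static couple factor, loading sqrt(rho_bar)
      for (pr in cp) {
        m <- if (is.null(shared)) draw_modulator() else shared
        rho <- c0 * (1 + m) / 2
        # residual mixing so that total within-pair correlation is rho(t)
        eta <- if (rho_bar < 1) (rho - rho_bar) / (1 - rho_bar) else 0
        z1 <- stats::rnorm(M); z2 <- stats::rnorm(M)
        x[, pr[1]] <- x[, pr[1]] + sqrt(rho_bar) * w + sqrt(1 - rho_bar) * z1
        x[, pr[2]] <- x[, pr[2]] + sqrt(rho_bar) * w +
          sqrt(1 - rho_bar) * (eta * z1 + sqrt(1 - eta^2) * z2)
      }
    }
    colnames(x) <- roi_codes
    list(subject_id = id, timeseries = x, label = label)
  }
  n <- params$n_per_group
  subjects <- c(
    lapply(seq_len(n), function(k)
      make_subject(sprintf("ctrl%02d", k), 0L)),
    lapply(seq_len(n), function(k)
      make_subject(sprintf("pat%02d", k), 1L)))
  cohort <- fc_cohort(subjects, roi_codes, tr_seconds = 2)
  attr(cohort, "synth_params") <- params
  cohort
}

#' Pair-map node indices of the planted region pairs
#'
#' Convenience for parameter-recovery checks: maps the planted couples of
#' a synthetic cohort onto node indices of \code{\link{pair_map}} (the
#' feature indices of high-order methods).
#'
#' @param params a \code{synth_params} object.
#' @return integer vector of pair-node indices.
#' @export
planted_pair_nodes <- function(params) {
  pm <- pair_map(params$R)
  key <- paste(pm$i, pm$j)
  idx <- unlist(lapply(params$planted_pairs, function(cp)
    vapply(cp, function(pr) match(paste(pr[1], pr[2]), key), integer(1))))
  sort(unique(idx))
}
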