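#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run.  Defaults follow the
#' reference analysis: window length 60 TRs, step 1 TR, Kruskal spanning
#' tree retaining the strongest correlations, FDR alpha 0.05 for the
#' thresholded high-order baseline, 10-fold cross-validation.
#'
#' @param method network/feature method: \code{"hon_mst"} (default),
#'   \code{"hon"}, \code{"pen"} or \code{"pan"}.
#' @param window_N sliding-window length in TRs.
#' @param window_S sliding-window step in TRs.
#' @param mst_algorithm \code{"kruskal"} (default) or \code{"prim"}.
#' @param edge_transform \code{"retain_strongest"} or
#'   \code{"literal_minimum"} (see \code{\link{kruskal_mst}}).
#' @param fdr_alpha FDR level for the thresholded high-order baseline.
#' @param shrinkage ridge shrinkage for the partial-correlation baseline.
#' @param weight_mode cube-root handling of negative weights in
#'   \code{\link{clustering_coefficients}}.
#' @param grid an \code{\link{optimization_grid}}.
#' @param n_folds outer CV folds.
#' @param n_repeats CV repetitions.
#' @param seed top-level seed for CV shuffles (and cohort synthesis in
#'   \code{\link{run_pipeline}}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(method = c("hon_mst", "hon", "pen", "pan"),
                            window_N = 60, window_S = 1,
                            mst_algorithm = c("kruskal", "prim"),
                            edge_transform = c("retain_strongest",
                                               "literal_minimum"),
                            fdr_alpha = 0.05, shrinkage = 0,
                            weight_mode = c("signed", "absolute"),
                            grid = optimization_grid(),
                            n_folds = 10, n_repeats = 10, seed = 1) {
  cfg <- list(method = match.arg(method),
              window_N = as.integer(window_N),
              window_S = as.integer(window_S),
              mst_algorithm = match.arg(mst_algorithm),
              edge_transform = match.arg(edge_transform),
              fdr_alpha = fdr_alpha, shrinkage = shrinkage,
              weight_mode = match.arg(weight_mode),
              grid = grid, n_folds = as.integer(n_folds),
              n_repeats = as.integer(n_repeats), seed = as.integer(seed))
  if (cfg$window_N < 1 || cfg$window_S < 1) stop("window_N and window_S must be >= 1")
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) stop("fdr_alpha must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline and write its artifact bundle
#'
#' Orchestrates build -> prune -> featurize -> select -> classify ->
#' report for one cohort, writing all artifacts under \code{out_dir}:
#' the feature matrix, a descriptive full-cohort feature selection (with
#' per-region and module-interaction weight aggregations when pair
#' features and ROI metadata are available), the nested-CV result, the
#' pooled ROC points, and a JSON run manifest capturing the
#' configuration, seed and package version.  Reruns with an identical
#' configuration and cohort reproduce identical outputs.
#'
#' The full-cohort selection is descriptive reporting only (the
#' counterpart of a published discriminative-connection table); the
#' cross-validated metrics never use it.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param cohort an \code{fc_cohort}, or NULL to synthesize one from
#'   \code{synth} using \code{config$seed}.
#' @param out_dir output directory, created if missing.
#' @param synth \code{\link{synth_params}} used when \code{cohort} is
#'   NULL (its seed is overridden by \code{config$seed}).
#' @param report_delta,report_lambda thresholds for the descriptive
#'   full-cohort selection; \code{report_delta = NULL} uses the 75th
#'   percentile of the full-cohort Relief weights.
#' @param roi_metadata optional data.frame from
#'   \code{\link{read_roi_metadata}} for the module aggregation.
#' @return the \code{cv_result}, invisibly; side effect: files under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = "honmst_run", synth = NULL,
                         report_delta = NULL, report_lambda = 0.9,
                         roi_metadata = NULL) {
  if (is.null(cohort)) {
    if (is.null(synth)) synth <- synth_params()
    synth$seed <- config$seed
    cohort <- generate_synthetic_cohort(synth)
  }
  M_min <- min(vapply(cohort$subjects, function(s) nrow(s$timeseries),
                      integer(1)))
  if (config$method %in% c("hon", "hon_mst") && config$window_N > M_min)
    stop("window_N = ", config$window_N,
         " exceeds the shortest subject series (M = ", M_min, ")")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fm <- build_feature_matrix(cohort, config$method, config)
  write_feature_matrix(fm, file.path(out_dir, "features.tsv"))

  # descriptive full-cohort selection and aggregations
  W <- .relief_safe(fm$X, fm$labels)
  if (is.null(report_delta))
    report_delta <- stats::quantile(W[is.finite(W)], 0.75, names = FALSE)
  sel <- tryCatch(
    select_features(fm$X, fm$labels, report_delta, report_lambda,
                    weights = W),
    error = function(e) NULL)
  if (!is.null(sel)) {
    write_selection(sel, file.path(out_dir, "selection.json"))
    if (config$method %in% c("hon", "hon_mst")) {
      pm <- pair_map(length(cohort$roi_codes), cohort$roi_codes)
      roi_w <- roi_weight_aggregation(sel$selected, W, pm, cohort$roi_codes)
      utils::write.table(
        data.frame(roi_code = names(roi_w), mean_weight = roi_w),
        file.path(out_dir, "roi_weights.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (is.null(roi_metadata))
        roi_metadata <- attr(cohort, "roi_metadata")
      if (!is.null(roi_metadata)) {
        part <- roi_metadata$module[match(cohort$roi_codes,
                                          roi_metadata$roi_code)]
        mim <- module_interaction_matrix(sel$selected, W, pm, part)
        utils::write.table(
          data.frame(module = rownames(mim), mim, check.names = FALSE),
          file.path(out_dir, "module_interaction.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  cv <- outer_cv(fm, config$grid, config$n_folds, config$n_repeats,
                 seed = config$seed)
  jsonlite::write_json(
    list(summary = cv$summary, auc_per_rep = cv$auc_per_rep,
         per_fold = cv$per_fold),
    file.path(out_dir, "cv_result.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)
  utils::write.table(cv$roc_points, file.path(out_dir, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("honmst")),
    config = unclass(config)[setdiff(names(config), "grid")],
    grid = unclass(config$grid),
    n_subjects = length(cohort$subjects),
    n_regions = length(cohort$roi_codes),
    report_delta = report_delta, report_lambda = report_lambda)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cv)
}
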