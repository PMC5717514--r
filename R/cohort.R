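#' Construct a two-group cohort of regional time series
#'
#' A cohort is the basic input object: an ordered list of subjects, each
#' carrying a numeric time x region matrix of regional mean BOLD series,
#' a binary group label (0 = control, 1 = patient), and a shared region
#' ordering.  All subjects must have the same regions in the same order;
#' time-series lengths may differ between subjects.
#'
#' @param subjects list of subject records, each a list with elements
#'   \code{subject_id} (character), \code{timeseries} (numeric matrix,
#'   rows = time points, columns = regions) and \code{label} (0 or 1).
#' @param roi_codes character vector of region abbreviations, one per
#'   column of every time-series matrix.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @return an object of class \code{fc_cohort}.
#' @export
fc_cohort <- function(subjects, roi_codes, tr_seconds = 2) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  roi_codes <- as.character(roi_codes)
  R <- length(roi_codes)
  for (s in subjects) {
    id <- s$subject_id
    ts <- s$timeseries
    if (is.null(id) || !nzchar(id))
      stop("every subject needs a non-empty 'subject_id'")
    if (!is.matrix(ts) || !is.numeric(ts))
      stop("subject '", id, "': timeseries must be a numeric matrix")
    if (ncol(ts) != R)
      stop("subject '", id, "': has ", ncol(ts),
           " regions but the cohort has ", R)
    if (nrow(ts) < 2L)
      stop("subject '", id, "': needs at least 2 time points")
    if (!all(is.finite(ts)))
      stop("subject '", id, "': non-finite values in timeseries")
    if (!is.null(colnames(ts)) && !identical(colnames(ts), roi_codes))
      stop("subject '", id, "': ROI ordering differs from the cohort")
    if (!(identical(s$label, 0) || identical(s$label, 1) ||
          identical(s$label, 0L) || identical(s$label, 1L)))
      stop("subject '", id, "': label must be 0 (control) or 1 (patient)")
  }
  structure(list(subjects = subjects, roi_codes = roi_codes,
                 tr_seconds = tr_seconds),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  M <- vapply(x$subjects, function(s) nrow(s$timeseries), integer(1))
  cat("Functional-connectivity cohort\n")
  cat("  subjects: ", length(x$subjects),
      " (", sum(labs == 0), " control / ", sum(labs == 1), " patient)\n",
      sep = "")
  cat("  regions:  ", length(x$roi_codes), "\n", sep = "")
  cat("  time points per subject: ",
      if (length(unique(M)) == 1L) M[1] else paste(range(M), collapse = "-"),
      " (TR = ", x$tr_seconds, " s)\n", sep = "")
  invisible(x)
}

#' Group labels of a cohort
#' @param cohort an \code{fc_cohort}.
#' @return integer vector of 0/1 labels in subject order.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, function(s) as.integer(s$label), integer(1))
}

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Read a cohort from a manifest file
#'
#' The manifest is a CSV/TSV table with columns \code{subject_id},
#' \code{path} and \code{label}; \code{path} is resolved relative to the
#' manifest's directory unless absolute.  Each referenced file is a
#' numeric CSV/TSV matrix (rows = time points) with a single header row of
#' ROI codes.  All subjects must present the same ROI codes in the same
#' order; labels must be 0 or 1.
#'
#' @param manifest_path path to the manifest table.
#' @param roi_metadata_path optional path to an ROI metadata table (see
#'   \code{\link{read_roi_metadata}}); when given, its \code{roi_code}
#'   column must match the cohort's ROI codes and the metadata is attached
#'   as attribute \code{"roi_metadata"}.
#' @param tr_seconds repetition time in seconds (default 2).
#' @return an \code{fc_cohort}.
#' @export
read_cohort <- function(manifest_path, roi_metadata_path = NULL,
                        tr_seconds = 2) {
  man <- .read_table_auto(manifest_path)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(manifest_path))
  roi_codes <- NULL
  subjects <- vector("list", nrow(man))
  for (r in seq_len(nrow(man))) {
    id <- as.character(man$subject_id[r])
    lab <- man$label[r]
    if (!(is.numeric(lab) || is.integer(lab)) || !(lab %in% c(0, 1)))
      stop("subject '", id, "': label '", lab, "' is not 0 or 1")
    p <- as.character(man$path[r])
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p))
      stop("subject '", id, "': time-series file not found: ", man$path[r])
    tab <- .read_table_auto(p)
    ts <- as.matrix(tab)
    if (!is.numeric(ts))
      stop("subject '", id, "': non-numeric values in time-series file")
    if (is.null(roi_codes)) {
      roi_codes <- colnames(ts)
    } else if (!identical(colnames(ts), roi_codes)) {
      stop("subject '", id, "': ROI header (", ncol(ts),
           " columns) does not match the cohort's ", length(roi_codes),
           " ROI codes")
    }
    subjects[[r]] <- list(subject_id = id, timeseries = ts,
                          label = as.integer(lab))
  }
  cohort <- fc_cohort(subjects, roi_codes, tr_seconds = tr_seconds)
  if (!is.null(roi_metadata_path)) {
    meta <- read_roi_metadata(roi_metadata_path)
    if (!identical(meta$roi_code, cohort$roi_codes))
      stop("ROI metadata codes do not match the cohort's ROI codes")
    attr(cohort, "roi_metadata") <- meta
  }
  cohort
}

#' Write a cohort to disk
#'
#' Writes one TSV per subject (full double precision, ROI-code header) and
#' a \code{manifest.tsv}, so that \code{\link{read_cohort}} round-trips
#' the cohort exactly.
#'
#' @param cohort an \code{fc_cohort}.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$subjects))
  for (k in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[k]]
    fn <- paste0(s$subject_id, ".tsv")
    ts <- s$timeseries
    out <- apply(ts, 2, function(col) format(col, digits = 17, trim = TRUE,
                                             scientific = FALSE))
    out <- rbind(cohort$roi_codes, out)
    con <- file(file.path(dir, fn), "w")
    writeLines(apply(out, 1, paste, collapse = "\t"), con)
    close(con)
    paths[k] <- fn
  }
  man <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    path = paths, label = cohort_labels(cohort))
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}

#' Read ROI metadata (code, name, lobe module, hemisphere)
#'
#' @param path TSV with columns \code{roi_code}, \code{full_name},
#'   \code{module}, \code{hemisphere}.  Defaults to the AAL-90 table
#'   shipped with the package, whose 5-lobe module assignment (frontal,
#'   occipital, parietal, subcortical, temporal) is a documented
#'   convention and can be edited by replacing the file.
#' @return data.frame of ROI metadata.
#' @export
read_roi_metadata <- function(path = system.file("extdata",
                                                 "aal90_modules.tsv",
                                                 package = "honmst")) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("roi_code", "full_name", "module", "hemisphere")
  if (!all(need %in% names(meta)))
    stop("ROI metadata must have columns: ", paste(need, collapse = ", "))
  ok <- c("frontal", "occipital", "parietal", "subcortical", "temporal")
  bad <- setdiff(unique(meta$module), ok)
  if (length(bad))
    stop("unknown module label(s): ", paste(bad, collapse = ", "))
  if (!all(meta$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  meta
}

#' Regress nuisance signals out of regional time series
#'
#' Each region's series is regressed (ordinary least squares, intercept
#' added internally) on the nuisance columns -- e.g. mean CSF and white
#' matter signals and motion parameters -- and replaced by the residual.
#' Residuals are exactly orthogonal to every regressor column.
#'
#' @param ts numeric time x region matrix.
#' @param regressors numeric time x Q matrix of nuisance covariates (may
#'   be NULL or have zero columns, in which case only the mean is
#'   removed).
#' @return residual matrix with the dimensions and dimnames of \code{ts}.
#' @export
residualize_nuisance <- function(ts, regressors = NULL) {
  ts <- as.matrix(ts)
  M <- nrow(ts)
  if (is.null(regressors)) regressors <- matrix(numeric(0), nrow = M, ncol = 0)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != M)
    stop("regressors have ", nrow(regressors), " rows but the time series has ", M)
  X <- cbind(intercept = rep(1, M), regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("regressor matrix is rank-deficient (collinear columns)")
  res <- qr.resid(qrX, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Pearson chi-square test for a 2 x 2 contingency table
#'
#' The uncorrected Pearson statistic
#' \deqn{X^2 = N (ad - bc)^2 / (r_1 r_2 c_1 c_2)}
#' with the p-value from the chi-square distribution on 1 degree of
#' freedom.  Used for demographic comparisons such as a gender split
#' between two diagnostic groups.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return list with \code{statistic} and \code{p_value}.
#' @examples
#' pearson_chi2_2x2(matrix(c(13, 15, 15, 23), 2, byrow = TRUE))
#' @export
pearson_chi2_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("'table' must be 2 x 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("all row and column margins must be positive")
  N <- sum(tab)
  stat <- N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (rs[[1]] * rs[[2]] * cs[[1]] * cs[[2]])
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE))
}
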