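#' Hyper-parameter grid for the nested optimization framework
#'
#' Defaults mirror the grid-search ranges used with the full-scale
#' high-order pipeline: Relief weight threshold
#' \code{delta in 1000..1600 (step 100)}, redundancy threshold
#' \code{lambda in 0.75..0.95 (step 0.05)}, SVM penalty
#' \code{C in 1..10} and RBF kernel width
#' \code{gamma in 0, 0.05, ..., 0.45}.  Relief weights accumulate over
#' training samples, so delta's scale depends on the number of samples
#' and features; override \code{delta_grid} for any other problem size.
#'
#' @param delta_grid numeric vector of Relief weight thresholds.
#' @param lambda_grid numeric vector of redundancy correlation thresholds
#'   in (0, 1].
#' @param c_grid numeric vector of SVM penalty factors (> 0).
#' @param gamma_grid numeric vector of RBF kernel parameters (>= 0).
#' @param inner_split_ratio fraction of the training fold used as the
#'   inner training set B (the rest is the tuning set); default 3:1.
#' @return list of class \code{optimization_grid}.
#' @export
optimization_grid <- function(delta_grid = seq(1000, 1600, by = 100),
                              lambda_grid = seq(0.75, 0.95, by = 0.05),
                              c_grid = 1:10,
                              gamma_grid = seq(0, 0.45, by = 0.05),
                              inner_split_ratio = 0.75) {
  stopifnot(length(delta_grid) >= 1, length(lambda_grid) >= 1,
            length(c_grid) >= 1, length(gamma_grid) >= 1)
  if (any(c_grid <= 0)) stop("all C values must be > 0")
  if (any(gamma_grid < 0)) stop("all gamma values must be >= 0")
  if (any(lambda_grid <= 0 | lambda_grid > 1))
    stop("lambda values must lie in (0, 1]")
  if (inner_split_ratio <= 0 || inner_split_ratio >= 1)
    stop("inner_split_ratio must lie in (0, 1)")
  structure(list(delta_grid = delta_grid, lambda_grid = lambda_grid,
                 c_grid = c_grid, gamma_grid = gamma_grid,
                 inner_split_ratio = inner_split_ratio),
            class = "optimization_grid")
}

# Relief weights that tolerate features constant on this training set:
# such features carry no discriminative information here and are marked
# -Inf so no threshold can select them.
.relief_safe <- function(X, y) {
  rng <- apply(X, 2, function(col) diff(range(col)))
  W <- rep(-Inf, ncol(X))
  names(W) <- colnames(X)
  ok <- rng > 0
  if (any(ok)) W[ok] <- relief_weights(X[, ok, drop = FALSE], y)
  W
}

# Stratified assignment of samples to k folds; assumes the RNG state is
# already seeded by the caller.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

# Stratified single split: TRUE = inner training set B.
.stratified_split <- function(y, frac) {
  in_b <- logical(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    n_b <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    in_b[idx[seq_len(n_b)]] <- TRUE
  }
  in_b
}

.scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

.svm_fit <- function(X, y, cost, gamma) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Decision scores oriented so that larger = more evidence for class 1.
.svm_scores <- function(model, X) {
  pr <- stats::predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos_first <- startsWith(colnames(dv)[1], "1")
  score <- if (pos_first) dv[, 1] else -dv[, 1]
  list(pred = as.integer(as.character(pr)), score = as.numeric(score))
}

#' Inner-loop selection of (delta, lambda, C, gamma)
#'
#' Splits the training data once (stratified) into an inner training set
#' B (about \code{inner_split_ratio}) and a tuning set; computes Relief
#' weights on B; then, for every grid combination, selects features on B
#' (threshold delta, redundancy lambda), z-scores them to B statistics,
#' fits an RBF-SVM (C, gamma) on B, and scores accuracy on the tuning
#' set.  Combinations for which no feature survives score chance (0.5).
#' The arg-max is returned; exact ties are broken toward higher delta,
#' then lower C, lower gamma, lower lambda (sparser, simpler models).
#'
#' @param X_train samples x features training matrix.
#' @param y_train binary labels (0/1).
#' @param grid an \code{\link{optimization_grid}}.
#' @param seed integer seed for the stratified inner split.
#' @return list with \code{delta}, \code{lambda}, \code{cost},
#'   \code{gamma}, \code{tune_accuracy}.
#' @export
inner_optimize <- function(X_train, y_train, grid = optimization_grid(),
                           seed = 1) {
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L)
    stop("both classes must be present in the training data")
  set.seed(seed)
  in_b <- .stratified_split(y_train, grid$inner_split_ratio)
  XB <- X_train[in_b, , drop = FALSE]; yB <- y_train[in_b]
  XC <- X_train[!in_b, , drop = FALSE]; yC <- y_train[!in_b]
  W <- .relief_safe(XB, yB)

  combos <- expand.grid(gamma = grid$gamma_grid, cost = grid$c_grid,
                        lambda = grid$lambda_grid, delta = grid$delta_grid,
                        KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(combos))
  for (dl in grid$delta_grid) {
    keep0 <- which(W >= dl)
    keep0 <- keep0[order(-W[keep0], keep0)]
    for (lm in grid$lambda_grid) {
      rows <- which(combos$delta == dl & combos$lambda == lm)
      if (!length(keep0)) { acc[rows] <- 0.5; next }
      sel <- redundancy_prune(XB, W, keep0, lm)
      sc <- .scale_fit(XB[, sel, drop = FALSE])
      Bs <- .scale_apply(XB[, sel, drop = FALSE], sc)
      Cs <- .scale_apply(XC[, sel, drop = FALSE], sc)
      for (r in rows) {
        fit <- tryCatch(.svm_fit(Bs, yB, combos$cost[r], combos$gamma[r]),
                        error = function(e) NULL)
        acc[r] <- if (is.null(fit)) 0.5 else {
          pr <- .svm_scores(fit, Cs)$pred
          mean(pr == yC)
        }
      }
    }
  }
  ord <- order(-acc, -combos$delta, combos$cost, combos$gamma, combos$lambda)
  best <- ord[1]
  list(delta = combos$delta[best], lambda = combos$lambda[best],
       cost = combos$cost[best], gamma = combos$gamma[best],
       tune_accuracy = acc[best])
}

#' Fit the full selection + SVM pipeline with fixed parameters
#'
#' Relief weights, delta threshold, lambda redundancy pruning, z-scoring
#' to training statistics, and RBF-SVM fit, all on the supplied training
#' data only.  If no feature survives the threshold, a majority-class
#' fallback model is returned.
#'
#' @param X samples x features training matrix.
#' @param y binary labels (0/1).
#' @param params list with \code{delta}, \code{lambda}, \code{cost},
#'   \code{gamma} (as returned by \code{\link{inner_optimize}}).
#' @return object of class \code{hon_svm_model}.
#' @export
fit_pipeline <- function(X, y, params) {
  y <- as.integer(y)
  W <- .relief_safe(X, y)
  keep <- which(W >= params$delta)
  if (length(keep)) {
    keep <- keep[order(-W[keep], keep)]
    sel <- redundancy_prune(X, W, keep, params$lambda)
    sc <- .scale_fit(X[, sel, drop = FALSE])
    fit <- .svm_fit(.scale_apply(X[, sel, drop = FALSE], sc), y,
                    params$cost, params$gamma)
    model <- list(kind = "svm", selected = sel, scaling = sc, fit = fit,
                  relief_weights = W, params = params)
  } else {
    model <- list(kind = "majority",
                  majority = as.integer(mean(y) >= 0.5),
                  relief_weights = W, params = params)
  }
  class(model) <- "hon_svm_model"
  model
}

#' @export
predict.hon_svm_model <- function(object, newdata, ...) {
  if (object$kind == "majority") {
    n <- nrow(newdata)
    return(list(pred = rep(object$majority, n), score = rep(0, n)))
  }
  Xs <- .scale_apply(newdata[, object$selected, drop = FALSE],
                     object$scaling)
  .svm_scores(object$fit, Xs)
}

#' Classification metrics with the patient group as positive class
#'
#' @param y_true true 0/1 labels (1 = patient).
#' @param y_pred predicted 0/1 labels.
#' @param scores optional decision scores (larger = more patient-like);
#'   when given, ROC points and trapezoid AUC are returned.
#' @return list with \code{accuracy}, \code{sensitivity} (TP rate among
#'   patients), \code{specificity} (TN rate among controls) -- NA with a
#'   \code{missing} flag when a class is absent from \code{y_true} --
#'   and, with scores, \code{roc_points} and \code{auc}.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  tp <- sum(y_true == 1 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0); fp <- sum(y_true == 0 & y_pred == 1)
  out <- list(
    accuracy = (tp + tn) / length(y_true),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  out$missing <- c(sensitivity = tp + fn == 0, specificity = tn + fp == 0)
  if (!is.null(scores)) {
    roc <- roc_points(y_true, scores)
    out$roc_points <- roc
    out$auc <- trapezoid_auc(roc)
  }
  out
}

#' ROC curve by threshold sweep
#'
#' @param y_true 0/1 labels (1 = positive).
#' @param scores decision scores, larger = more positive.
#' @return data.frame of \code{fpr}, \code{tpr} from (0,0) to (1,1),
#'   one point per distinct score (ties grouped).
#' @export
roc_points <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  if (np == 0 || nn == 0)
    return(data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]; ss <- scores[ord]
  grp_end <- c(which(diff(ss) != 0), length(ss))
  tp <- cumsum(ys == 1)[grp_end]
  fp <- cumsum(ys == 0)[grp_end]
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

#' Trapezoid-rule area under an ROC curve
#' @param roc data.frame from \code{\link{roc_points}}.
#' @return AUC in [0, 1].
#' @export
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Repeated stratified 10-fold nested cross-validation
#'
#' For every repetition the subjects are shuffled into stratified folds;
#' in every fold, \code{\link{inner_optimize}} chooses
#' (delta, lambda, C, gamma) using only the training part, the full
#' pipeline is refit on the entire training part with those parameters,
#' and the held-out fold is predicted.  No statistic of the held-out
#' samples (scaling, Relief, selection, SVM) ever enters fitting.
#' Decision scores are pooled across folds within each repetition for an
#' ROC curve; AUC is averaged over repetitions.
#'
#' @param fm a \code{feature_matrix} (or a list with \code{X} and
#'   \code{labels}).
#' @param grid an \code{\link{optimization_grid}}.
#' @param n_folds number of outer folds (default 10).
#' @param n_repeats number of repetitions of the whole CV (default 10).
#' @param seed top-level seed; all fold shuffles and inner splits are
#'   derived from it deterministically.
#' @return object of class \code{cv_result}: \code{per_fold} data.frame,
#'   \code{summary} (mean accuracy/sensitivity/specificity in percent,
#'   mean AUC), \code{auc_per_rep}, \code{roc_points} (pooled over all
#'   repetitions), \code{n_folds}, \code{n_repeats}, \code{seed}.
#' @export
outer_cv <- function(fm, grid = optimization_grid(), n_folds = 10,
                     n_repeats = 10, seed = 1) {
  if (n_folds < 1 || n_repeats < 1) stop("n_folds and n_repeats must be >= 1")
  X <- fm$X; y <- as.integer(fm$labels)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_repeats)
  per_fold <- vector("list", n_folds * n_repeats)
  auc_per_rep <- numeric(n_repeats)
  pooled_all <- list(y = integer(0), s = numeric(0))
  row <- 0L
  for (rep in seq_len(n_repeats)) {
    set.seed(rep_seeds[rep])
    fold_of <- .stratified_folds(y, n_folds)
    inner_seeds <- sample.int(2^30, n_folds)
    rep_y <- integer(0); rep_s <- numeric(0)
    for (fold in seq_len(n_folds)) {
      te <- which(fold_of == fold)
      tr <- which(fold_of != fold)
      if (length(te) == 0L) next
      if (length(unique(y[tr])) < 2L)
        stop("fold ", fold, " leaves a single-class training set; ",
             "reduce n_folds")
      params <- inner_optimize(X[tr, , drop = FALSE], y[tr], grid,
                               seed = inner_seeds[fold])
      model <- fit_pipeline(X[tr, , drop = FALSE], y[tr], params)
      pr <- predict(model, X[te, , drop = FALSE])
      m <- compute_metrics(y[te], pr$pred)
      row <- row + 1L
      per_fold[[row]] <- data.frame(
        repetition = rep, fold = fold,
        delta = params$delta, lambda = params$lambda,
        cost = params$cost, gamma = params$gamma,
        n_selected = if (model$kind == "svm") length(model$selected) else 0L,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity)
      rep_y <- c(rep_y, y[te]); rep_s <- c(rep_s, pr$score)
    }
    auc_per_rep[rep] <- trapezoid_auc(roc_points(rep_y, rep_s))
    pooled_all$y <- c(pooled_all$y, rep_y)
    pooled_all$s <- c(pooled_all$s, rep_s)
  }
  per_fold <- do.call(rbind, per_fold[seq_len(row)])
  summary <- list(
    accuracy = 100 * mean(per_fold$accuracy),
    sensitivity = 100 * mean(per_fold$sensitivity, na.rm = TRUE),
    specificity = 100 * mean(per_fold$specificity, na.rm = TRUE),
    auc = mean(auc_per_rep))
  structure(list(per_fold = per_fold, summary = summary,
                 auc_per_rep = auc_per_rep,
                 roc_points = roc_points(pooled_all$y, pooled_all$s),
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Nested cross-validation (", x$n_folds, "-fold x ", x$n_repeats,
      " repetitions)\n", sep = "")
  cat(sprintf("  accuracy    %.2f %%\n", x$summary$accuracy))
  cat(sprintf("  sensitivity %.2f %%\n", x$summary$sensitivity))
  cat(sprintf("  specificity %.2f %%\n", x$summary$specificity))
  cat(sprintf("  AUC         %.3f\n", x$summary$auc))
  invisible(x)
}
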