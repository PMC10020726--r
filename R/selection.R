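#' Univariate regression F-statistic of a feature against a target
#'
#' `F = r^2 (n - 2) / (1 - r^2)` where `r` is the Pearson correlation;
#' equals the F-test of the slope in the simple linear regression of the
#' target on the feature. A constant feature scores 0 (it can never win
#' the ranking).
#'
#' @param y numeric target.
#' @param f numeric feature of the same length.
#' @return scalar F-statistic (`Inf` for a perfectly correlated feature).
#' @export
f_statistic <- function(y, f) {
  n <- length(y)
  if (length(f) != n) stopf("y and f must have equal length")
  if (n < 3L) stopf("need at least 3 observations")
  if (sd(f) == 0 || sd(y) == 0) return(0)
  r2 <- cor(f, y)^2
  if (r2 >= 1) return(Inf)
  r2 * (n - 2L) / (1 - r2)
}

safe_abs_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)  # correlation with a constant
  abs(cor(a, b))
}

#' FCQ score of a candidate feature
#'
#' F-test correlation quotient used by the greedy MRMR ranking: the
#' relevance `F(Y, f)` divided by the mean absolute Pearson correlation
#' between `f` and the already-selected features. With no features
#' selected the score is the plain F-statistic; a zero mean correlation
#' is floored at `eps` so fully novel features keep their relevance.
#'
#' @param f candidate feature (numeric vector).
#' @param y target vector.
#' @param selected matrix (columns = already selected features) or `NULL`.
#' @param eps denominator floor (default 1e-12).
#' @return scalar score.
#' @export
fcq_score <- function(f, y, selected = NULL, eps = 1e-12) {
  fy <- f_statistic(y, f)
  if (is.null(selected) || NCOL(selected) == 0L) return(fy)
  selected <- as.matrix(selected)
  red <- mean(apply(selected, 2L, safe_abs_cor, b = f))
  fy / max(red, eps)
}

#' Greedy MRMR-FCQ feature ranking
#'
#' Maximum-relevance minimum-redundancy ranking, F-test correlation
#' quotient variant: the first pick maximizes the F-statistic against the
#' target; each subsequent pick maximizes [fcq_score()] given the
#' current selection. Ties break deterministically by feature name order.
#'
#' @param x numeric matrix or data.frame of features (named columns).
#' @param y numeric target aligned with the rows of `x`.
#' @param k number of features to rank (default: all).
#' @return object of class `ranked_features`: data.frame with columns
#'   `rank`, `feature`, `score` (the FCQ score at selection time).
#' @export
mrmr_rank <- function(x, y, k = ncol(x)) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stopf("feature names must be unique")
  if (any(!is.finite(x))) stopf("features must be finite (no missing values)")
  if (nrow(x) != length(y)) stopf("x rows and y length differ")
  if (k < 1L || k > ncol(x)) stopf("k must be in [1, %d]", ncol(x))

  nms <- colnames(x)
  remaining <- seq_len(ncol(x))
  sel <- integer(0)
  scores <- numeric(0)
  # incremental running sum of |cor| against selected features
  redsum <- numeric(ncol(x))
  relevance <- vapply(seq_len(ncol(x)), function(j) f_statistic(y, x[, j]),
                      numeric(1L))
  for (step in seq_len(k)) {
    if (length(sel) == 0L) {
      sc <- relevance[remaining]
    } else {
      red <- redsum[remaining] / length(sel)
      sc <- relevance[remaining] / pmax(red, 1e-12)
    }
    best <- remaining[order(-sc, nms[remaining])][1L]
    scores <- c(scores, sc[match(best, remaining)])
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0L)
      redsum[remaining] <- redsum[remaining] +
        vapply(remaining, function(j) safe_abs_cor(x[, j], x[, best]),
               numeric(1L))
  }
  structure(data.frame(rank = seq_len(k), feature = nms[sel], score = scores),
            class = c("ranked_features", "data.frame"))
}

#' Choose how many top-ranked features to keep
#'
#' Sweeps `k` over a grid: for each `k` the top-k MRMR-FCQ features are
#' scored by mean cross-validated R-squared across a set of models fitted
#' with their default hyperparameters, and the `k` with the best mean is
#' returned (ties go to the smallest `k`).
#'
#' @param x feature matrix (named columns).
#' @param y numeric target.
#' @param models character vector of model kinds (see [model_spec()]).
#' @param k_grid integer grid of candidate feature counts.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment and model
#'   initialisation.
#' @return list with `k` (chosen count), `ranking` (full
#'   [mrmr_rank()] result) and `report` (data.frame of mean CV R-squared
#'   per k).
#' @export
choose_k <- function(x, y, models = c("RF", "GBR", "MLP", "MLR", "SVR"),
                     k_grid = NULL, cv_folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(k_grid)) k_grid <- unique(pmin(ncol(x), c(1:10, seq(12, ncol(x), by = 2))))
  if (length(k_grid) < 1L) stopf("k_grid must be nonempty")
  if (any(k_grid < 1L | k_grid > ncol(x))) stopf("k_grid out of range")
  ranking <- mrmr_rank(x, y)
  folds <- cv_fold_ids(length(y), cv_folds, substream_seed(seed, "cv"))
  report <- data.frame(k = k_grid, mean_cv_r2 = NA_real_)
  for (i in seq_along(k_grid)) {
    keep <- ranking$feature[seq_len(k_grid[i])]
    r2s <- vapply(models, function(kind) {
      cv_r2(x[, keep, drop = FALSE], y, kind,
            hyper = NULL, folds = folds, seed = substream_seed(seed, "model"))
    }, numeric(1L))
    report$mean_cv_r2[i] <- mean(r2s)
  }
  ord <- order(-report$mean_cv_r2, report$k)
  list(k = report$k[ord[1L]], ranking = ranking, report = report)
}
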