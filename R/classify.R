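# ROC/threshold machinery, tri-state NMS classification, confusion metrics,
# and fragment-level viability summaries and regression.

#' Stratified k-fold cross-validated AUROC with optimal thresholds
#'
#' Splits cells into `k` folds stratified by the truth label; per fold, the
#' ROC and AUC are computed on the HELD-OUT cells while the optimal operating
#' threshold is computed on the TRAINING cells by maximizing Youden's J
#' (sensitivity + specificity - 1). Higher scores indicate the positive
#' (dead) class; negate the scores to analyze a "more negative = more
#' positive" direction (as for the necroptotic band).
#'
#' @param scores Numeric per-cell scores (e.g. mean NMS).
#' @param truth Logical (or 0/1) per-cell positive-class labels.
#' @param k Number of folds (default 10).
#' @param seed Optional seed controlling the fold assignment.
#' @return An object of class `cv_result`: `fold_auc`, `mean_auc`, `sd_auc`,
#'   `fold_threshold`, `mean_threshold`, `sd_threshold`, `k`, `seed`, `folds`
#'   (the per-cell fold assignment).
#' @export
cv_auroc <- function(scores, truth, k = 10L, seed = NULL) {
  truth <- as.logical(truth)
  ok <- is.finite(scores) & !is.na(truth)
  scores <- scores[ok]; truth <- truth[ok]
  if (length(unique(truth)) < 2)
    stop("cv_auroc requires both classes present")
  if (min(table(truth)) < k)
    stop("fewer positive or negative cells than folds")
  assign_folds <- function() {
    folds <- integer(length(truth))
    for (cl in c(TRUE, FALSE)) {
      idx <- which(truth == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  }
  folds <- if (is.null(seed)) assign_folds() else
    withr::with_seed(seed, assign_folds())
  fold_auc <- fold_thr <- numeric(k)
  for (i in seq_len(k)) {
    te <- folds == i
    roc_te <- pROC::roc(response = truth[te], predictor = scores[te],
                        levels = c(FALSE, TRUE), direction = "<",
                        quiet = TRUE)
    fold_auc[i] <- as.numeric(pROC::auc(roc_te))
    roc_tr <- pROC::roc(response = truth[!te], predictor = scores[!te],
                        levels = c(FALSE, TRUE), direction = "<",
                        quiet = TRUE)
    best <- pROC::coords(roc_tr, "best", best.method = "youden",
                         ret = "threshold", transpose = FALSE)
    fold_thr[i] <- mean(best[["threshold"]])
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 sd_auc = stats::sd(fold_auc),
                 fold_threshold = fold_thr, mean_threshold = mean(fold_thr),
                 sd_threshold = stats::sd(fold_thr),
                 k = k, seed = seed, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds, AUC %.3f +/- %.3f, threshold %.3f +/- %.3f\n",
              x$k, x$mean_auc, x$sd_auc, x$mean_threshold, x$sd_threshold))
  invisible(x)
}

#' Tri-state NMS classification
#'
#' Scores below `t_left` are necroptotic, within `[t_left, t_right]` (closed
#' interval: both endpoints are viable) viable, and above `t_right`
#' apoptotic/necrotic. "Dead" means not viable (either dead class).
#'
#' @param mean_nms Numeric scores (per-cell mean NMS).
#' @param bands A [threshold_bands()].
#' @return Factor with levels `necroptotic`, `viable`, `apoptotic_necrotic`
#'   (NA propagated).
#' @export
tri_state <- function(mean_nms, bands = threshold_bands()) {
  out <- ifelse(mean_nms < bands$t_left, "necroptotic",
                ifelse(mean_nms > bands$t_right, "apoptotic_necrotic",
                       "viable"))
  factor(out, levels = CELL_STATES)
}

#' Confusion metrics for binary dead/alive calls
#'
#' With "dead" as the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n, all in percent.
#'
#' @param pred_dead,truth_dead Logical vectors of equal, nonzero length.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the 2 x 2 `confusion` matrix (truth in rows, prediction in columns).
#' @export
confusion_metrics <- function(pred_dead, truth_dead) {
  pred_dead <- as.logical(pred_dead); truth_dead <- as.logical(truth_dead)
  stopifnot(length(pred_dead) == length(truth_dead), length(pred_dead) > 0)
  tp <- sum(pred_dead & truth_dead)
  tn <- sum(!pred_dead & !truth_dead)
  fp <- sum(pred_dead & !truth_dead)
  fn <- sum(!pred_dead & truth_dead)
  conf <- matrix(c(tn, fn, fp, tp), 2, 2,
                 dimnames = list(truth = c("alive", "dead"),
                                 predicted = c("alive", "dead")))
  list(accuracy = 100 * (tp + tn) / length(pred_dead),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       confusion = conf)
}

#' Fragment-level viability summary
#'
#' Percentage of cells called dead by the label channel (`pi_dead`) and by
#' the NMS tri-state bands (either dead class), per fragment.
#'
#' @param cell_table Cell table from [cell_stats()] (one or more fragments;
#'   grouped by `fragment_id` when present).
#' @param bands A [threshold_bands()].
#' @return A `data.frame` with columns `fragment_id`, `n_cells`,
#'   `pct_dead_pi`, `pct_dead_nms`, `timepoint`.
#' @export
fragment_viability <- function(cell_table, bands = threshold_bands()) {
  stopifnot(nrow(cell_table) >= 1)
  grp <- if ("fragment_id" %in% names(cell_table))
    cell_table$fragment_id else rep(NA, nrow(cell_table))
  if (anyNA(grp)) grp[is.na(grp)] <- "(all)"
  # group in first-appearance order so summaries align with the input
  grp_f <- factor(grp, levels = unique(grp))
  cls <- tri_state(cell_table$mean_nms, bands)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cell_table)), grp_f),
    function(idx) {
      data.frame(
        fragment_id = grp[idx[1]],
        n_cells = length(idx),
        pct_dead_pi = 100 * mean(cell_table$pi_dead[idx]),
        pct_dead_nms = 100 * mean(cls[idx] != "viable"),
        timepoint = if ("timepoint" %in% names(cell_table))
          cell_table$timepoint[idx[1]] else NA,
        stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Regression of NMS-based on label-based fragment death fractions
#'
#' Ordinary least squares of `pct_dead_nms` on `pct_dead_pi` across
#' fragments, with the two-sided t-test p-value on the slope.
#'
#' @param summaries Output of [fragment_viability()] (>= 3 fragments).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
fragment_regression <- function(summaries) {
  stopifnot(nrow(summaries) >= 3)
  if (stats::var(summaries$pct_dead_pi) == 0)
    stop("zero variance in the predictor (pct_dead_pi)")
  fit <- stats::lm(pct_dead_nms ~ pct_dead_pi, data = summaries)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = nrow(summaries))
}
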