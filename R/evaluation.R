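# Class-imbalance-aware evaluation. Accuracy and AUC overestimate
# performance under heavy imbalance (a constant majority predictor can
# top 91% accuracy on a 9%-methylated profile), so the primary metric is
# the F1 score of the minor binarized class, determined per task on the
# evaluation subset.

# Confusion-matrix F1 with `positive` as the positive class.
f1_for_class <- function(pred_cls, true_cls, positive) {
  tp <- sum(pred_cls == positive & true_cls == positive)
  fp <- sum(pred_cls == positive & true_cls != positive)
  fn <- sum(pred_cls != positive & true_cls == positive)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

minor_class <- function(true_cls) {
  n1 <- sum(true_cls == 1)
  n0 <- length(true_cls) - n1
  if (n1 <= n0) 1L else 0L
}

# Minor-class F1 of probabilistic predictions against continuous labels.
f1_minor <- function(prob, labels, threshold = 0.5) {
  true_cls <- binarize(labels, threshold)
  pred_cls <- binarize(prob, threshold)
  f1_for_class(pred_cls, true_cls, minor_class(true_cls))
}

# Average precision (step-wise area under the precision-recall curve)
# with `positive` as the positive class.
auprc_ap <- function(scores, true_cls, positive = 1L) {
  y <- as.integer(true_cls == positive)
  if (positive == 0L) scores <- -scores
  n_pos <- sum(y)
  if (n_pos == 0 || n_pos == length(y)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  # average precision: mean of precision at the rank of each positive
  sum(prec[y == 1]) / n_pos
}

#' Evaluate multi-task predictions
#'
#' Labels are binarized at the threshold (strict `>`); the minor class per
#' task is the binarized value with the smaller count in that task's
#' evaluation set, and F1/precision/recall are computed with it as
#' positive. AUC-ROC and AUPRC use the raw probabilities (oriented toward
#' the minor class) and are reported as `NA` when only one class is
#' present.
#'
#' @param predictions `n x m` probability matrix (or vector for one task).
#' @param labels Matching label matrix of methylation levels.
#' @param mask Logical observation mask (default: all observed).
#' @param binarize_threshold Cutoff (default 0.5).
#' @return A `meth_eval` tibble, one row per task: `task`, `n_eval`,
#'   `minor_class`, `f1_minor`, `precision`, `recall`, `accuracy`,
#'   `auc_roc`, `auprc`.
#' @export
evaluate_predictions <- function(predictions, labels, mask = NULL,
                                 binarize_threshold = 0.5) {
  if (is.null(dim(predictions))) predictions <- cbind(task = predictions)
  if (is.null(dim(labels))) labels <- cbind(task = labels)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(labels), ncol(labels))
  tasks <- colnames(predictions) %||% paste0("task", seq_len(ncol(predictions)))
  rows <- lapply(seq_len(ncol(predictions)), function(j) {
    obs <- mask[, j]
    n <- sum(obs)
    assert_that(n > 0, paste0("task ", tasks[j], " has no observed labels"))
    p <- predictions[obs, j]
    true_cls <- binarize(labels[obs, j], binarize_threshold)
    pred_cls <- binarize(p, binarize_threshold)
    pos <- minor_class(true_cls)
    tp <- sum(pred_cls == pos & true_cls == pos)
    fp <- sum(pred_cls == pos & true_cls != pos)
    fn <- sum(pred_cls != pos & true_cls == pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (tp > 0) 2 * prec * rec / (prec + rec) else 0
    one_class <- length(unique(true_cls)) < 2
    auc <- if (one_class) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(
        response = true_cls, predictor = p, levels = c(0, 1),
        direction = "<", quiet = TRUE)))
    pr <- if (one_class) NA_real_ else auprc_ap(p, true_cls, pos)
    tibble::tibble(task = tasks[j], n_eval = n, minor_class = pos,
                   f1_minor = f1, precision = prec, recall = rec,
                   accuracy = mean(pred_cls == true_cls),
                   auc_roc = auc, auprc = pr)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "binarize_threshold") <- binarize_threshold
  class(out) <- c("meth_eval", class(out))
  out
}

#' Confidence-retention (tau) curve
#'
#' For each confidence threshold `tau`, keeps only predictions with
#' probability strictly above `tau` or strictly below `1 - tau` (a
#' prediction exactly at a boundary is dropped) and recomputes the
#' minor-class F1 on the retained set. Higher `tau` keeps only the more
#' certain calls, so F1 typically rises while the retained fraction
#' falls.
#'
#' @param predictions Probability vector for one task.
#' @param labels Matching methylation levels.
#' @param tau_grid Thresholds in `[0.5, 1)` (default `0.5, 0.55, ..., 0.95`).
#' @param binarize_threshold Label binarization cutoff.
#' @return A `meth_tau_curve` tibble: `tau`, `n_retained`,
#'   `fraction_retained`, `f1_minor` (`NA` with a warning when nothing is
#'   retained).
#' @export
tau_curve <- function(predictions, labels, tau_grid = seq(0.5, 0.95, 0.05),
                      binarize_threshold = 0.5) {
  assert_that(all(tau_grid >= 0.5 & tau_grid < 1),
              "`tau_grid` must lie in [0.5, 1)")
  rows <- lapply(tau_grid, function(tau) {
    keep <- predictions > tau | predictions < 1 - tau
    n <- sum(keep)
    if (n == 0) {
      rlang::warn(sprintf("tau = %.3f retains no predictions", tau))
      return(tibble::tibble(tau = tau, n_retained = 0L,
                            fraction_retained = 0, f1_minor = NA_real_))
    }
    tibble::tibble(tau = tau, n_retained = n,
                   fraction_retained = n / length(predictions),
                   f1_minor = f1_minor(predictions[keep], labels[keep],
                                       binarize_threshold))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("meth_tau_curve", class(out))
  out
}
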