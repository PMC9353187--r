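# Training objectives: logistic loss on binarized labels, KL divergence on
# continuous methylation levels, MSE baselines, and the weighted
# multi-task combination. KL needs no binarization: the observed level
# y in [0,1] and the predicted methylated-probability are compared as
# two-point distributions (y, 1-y) vs (yhat, 1-yhat).

#' Loss configuration
#'
#' @param kind One of `"kl"`, `"logistic"`, `"mse"`, `"mse_sigmoid"`.
#' @param task_weights Per-task weights `alpha_j` (default all 1; recycled
#'   to the number of tasks at training time).
#' @param sample_weight_scheme `"inverse_frequency"` (per-CpG weights
#'   `beta` from the binarized class-label distribution within each
#'   profile, normalized to sum to the profile's example count) or
#'   `"uniform"`.
#' @param epsilon Clipping constant for logarithm arguments.
#' @param reduction `"mean"` over unmasked entries (batch-size-independent
#'   learning rate, the default) or `"sum"` (the literal summed objective).
#' @return A `loss_config` list.
#' @export
loss_config <- function(kind = c("kl", "logistic", "mse", "mse_sigmoid"),
                        task_weights = 1,
                        sample_weight_scheme = c("inverse_frequency",
                                                 "uniform"),
                        epsilon = 1e-6,
                        reduction = c("mean", "sum")) {
  kind <- match.arg(kind)
  assert_that(epsilon > 0 && epsilon < 0.1, "`epsilon` must be in (0, 0.1)")
  assert_that(all(task_weights >= 0), "task weights must be >= 0")
  structure(list(kind = kind, task_weights = task_weights,
                 sample_weight_scheme = match.arg(sample_weight_scheme),
                 epsilon = epsilon, reduction = match.arg(reduction)),
            class = "loss_config")
}

#' Logistic loss
#'
#' `-y log(yhat) - (1 - y) log(1 - yhat)`, summed over the batch. Labels
#' must already be binarized (see [binarize()]): passing a continuous
#' level is an error, because the binarization is the caller's explicit,
#' information-losing step.
#'
#' @param y Binary labels in `{0, 1}`.
#' @param yhat Predicted methylated-probabilities.
#' @param epsilon Clipping for `yhat`.
#' @return Non-negative scalar.
#' @export
logistic_loss <- function(y, yhat, epsilon = 1e-6) {
  assert_that(all(y %in% c(0, 1)),
              "logistic loss requires binary labels; binarize() first")
  p <- clip01(yhat, epsilon)
  sum(-y * log(p) - (1 - y) * log(1 - p))
}

#' Kullback-Leibler divergence loss
#'
#' `y log(y / yhat) + (1 - y) log((1 - y) / (1 - yhat))`, summed over the
#' batch, with the convention `0 * log 0 = 0` for the label terms. Unlike
#' the logistic loss this keeps the full continuous methylation level: a
#' site at 0.51 and one at 0.99 contribute differently.
#'
#' @param y Labels in `[0, 1]` (no binarization).
#' @param yhat Predicted methylated-probabilities.
#' @param epsilon Clipping for `yhat`.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(y, yhat, epsilon = 1e-6) {
  assert_that(all(y >= 0 & y <= 1), "labels must lie in [0, 1]")
  p <- clip01(yhat, epsilon)
  t1 <- ifelse(y > 0, y * log(y / p), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - p)), 0)
  sum(t1 + t2)
}

#' Mean-squared-error loss
#'
#' `(y - yhat)^2`, summed over the batch; with `with_sigmoid = TRUE`,
#' `yhat` is first passed through a sigmoid (for use with a raw,
#' unsquashed head score).
#'
#' @param y Labels in `[0, 1]`.
#' @param yhat Predictions (probabilities, or raw scores when
#'   `with_sigmoid = TRUE`).
#' @param with_sigmoid Apply a final sigmoid mapping to `yhat`.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(y, yhat, with_sigmoid = FALSE) {
  if (with_sigmoid) yhat <- sigmoid(yhat)
  sum((y - yhat)^2)
}

#' Binarize a methylation level
#'
#' Strictly-greater rule: a level above the threshold is methylated (1);
#' exactly at the threshold is unmethylated (0).
#'
#' @param y Levels in `[0, 1]`.
#' @param threshold Cutoff (default 0.5).
#' @return Integer vector of 0/1.
#' @export
binarize <- function(y, threshold = 0.5) {
  as.integer(y > threshold)
}

# Per-entry loss and its derivative with respect to the predicted
# probability (or raw score for kind "mse"). Used by the trainer; exact
# analytic gradients are tested against central differences.
loss_and_grad <- function(y, yhat, kind, epsilon = 1e-6) {
  p <- clip01(yhat, epsilon)
  switch(kind,
    logistic = {
      yb <- as.numeric(y > 0.5)
      list(loss = -yb * log(p) - (1 - yb) * log(1 - p),
           grad = -yb / p + (1 - yb) / (1 - p))
    },
    kl = {
      t1 <- ifelse(y > 0, y * log(y / p), 0)
      t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - p)), 0)
      list(loss = t1 + t2, grad = -y / p + (1 - y) / (1 - p))
    },
    mse = ,
    mse_sigmoid = list(loss = (y - yhat)^2, grad = 2 * (yhat - y)),
    stop_mt(paste0("unknown loss kind: ", kind)))
}

#' Per-CpG sample weights from the class-label distribution
#'
#' For the `inverse_frequency` scheme, each profile's training labels are
#' binarized (only for weighting, never for the labels themselves) and
#' each example receives a weight inversely proportional to its class
#' frequency, normalized so weights sum to the profile's example count.
#' Profiles with a single class fall back to uniform weights.
#'
#' @param labels `n x m` label matrix.
#' @param label_mask `n x m` logical observation mask.
#' @param scheme `"inverse_frequency"` or `"uniform"`.
#' @param threshold Binarization cutoff used for weighting.
#' @return `n x m` weight matrix (0 where unobserved).
#' @export
sample_weights <- function(labels, label_mask,
                           scheme = c("inverse_frequency", "uniform"),
                           threshold = 0.5) {
  scheme <- match.arg(scheme)
  w <- matrix(0, nrow(labels), ncol(labels))
  for (j in seq_len(ncol(labels))) {
    obs <- label_mask[, j]
    n_j <- sum(obs)
    if (n_j == 0) next
    if (scheme == "uniform") {
      w[obs, j] <- 1
    } else {
      cls <- binarize(labels[obs, j], threshold)
      n1 <- sum(cls == 1); n0 <- n_j - n1
      if (n1 == 0 || n0 == 0) {
        w[obs, j] <- 1
      } else {
        w[obs, j] <- ifelse(cls == 1, n_j / (2 * n1), n_j / (2 * n0))
      }
    }
  }
  w
}

#' Weighted multi-task loss
#'
#' Combines per-site, per-task losses as
#' `sum_j alpha_j sum_i beta_ij * loss_ij` over observed entries only,
#' optionally divided by the number of observed entries
#' (`reduction = "mean"`).
#'
#' @param per_site_losses `n x m` matrix of per-entry losses.
#' @param label_mask `n x m` logical mask of observed labels.
#' @param config A [loss_config()]; `task_weights` is recycled to `m`.
#' @param beta Optional `n x m` sample-weight matrix (default all 1; see
#'   [sample_weights()]).
#' @return Scalar loss; an all-masked batch yields 0 with a warning.
#' @export
multi_task_loss <- function(per_site_losses, label_mask, config,
                            beta = NULL) {
  m <- ncol(per_site_losses)
  alpha <- rep_len(config$task_weights, m)
  if (is.null(beta)) beta <- matrix(1, nrow(per_site_losses), m)
  n_obs <- sum(label_mask)
  if (n_obs == 0) {
    rlang::warn("all labels masked; multi-task loss is 0")
    return(0)
  }
  L <- per_site_losses
  L[!label_mask] <- 0                      # masked entries may be NA
  contrib <- sweep(L * beta, 2, alpha, `*`)
  total <- sum(contrib)
  if (config$reduction == "mean") total / n_obs else total
}
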