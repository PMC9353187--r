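# Chromosome-based data splitting, the transfer-setting matrix (five
# source settings, fifteen target settings), and the optimization
# protocol: Adam with decoupled weight decay, explicit l1 penalty,
# mini-batches of 128, early stopping on validation minor-class F1, and a
# learning-rate grid search.

#' Chromosome split plan
#'
#' Defaults follow the bovine-autosome partition used for training /
#' validation / testing: chromosomes 1, 4, 7, ..., 28 train; 3, 6, ..., 27
#' validate; 2, 5, ..., 29 test.
#'
#' @param train_chroms,val_chroms,test_chroms Character vectors of
#'   chromosome names (pairwise disjoint).
#' @return A `split_plan` list.
#' @export
split_plan <- function(train_chroms = as.character(seq(1, 28, by = 3)),
                       val_chroms = as.character(seq(3, 27, by = 3)),
                       test_chroms = as.character(seq(2, 29, by = 3))) {
  all <- c(train_chroms, val_chroms, test_chroms)
  assert_that(!anyDuplicated(all), "split chromosome sets must be disjoint")
  structure(list(train_chroms = as.character(train_chroms),
                 val_chroms = as.character(val_chroms),
                 test_chroms = as.character(test_chroms)),
            class = "split_plan")
}

#' Route encoded examples into train / validation / test streams
#'
#' Assignment is a pure function of the chromosome name. A chromosome
#' carrying data but absent from every split is an error.
#'
#' @param examples An `encoded_examples` object.
#' @param plan A [split_plan()].
#' @return List of three `encoded_examples` (`train`, `val`, `test`) plus
#'   `counts`.
#' @export
split_examples <- function(examples, plan) {
  chrom <- examples$chrom
  unrouted <- setdiff(unique(chrom),
                      c(plan$train_chroms, plan$val_chroms,
                        plan$test_chroms))
  if (length(unrouted))
    stop_mt(paste0("chromosome(s) in data but in no split: ",
                   paste(unrouted, collapse = ", ")))
  out <- list(
    train = slice_examples(examples, which(chrom %in% plan$train_chroms)),
    val = slice_examples(examples, which(chrom %in% plan$val_chroms)),
    test = slice_examples(examples, which(chrom %in% plan$test_chroms)))
  out$counts <- tibble::tibble(split = c("train", "val", "test"),
                               n = vapply(out[1:3], n_examples, integer(1)))
  out
}

## ---- transfer settings ------------------------------------------------

# The single source of truth for every training setting: which feature
# path feeds the heads, which subnetwork groups load pretrained weights,
# and which of those stay fixed. Heads are never transferred (a new task
# set gets fresh heads).
TRANSFER_TABLE <- list(
  # source settings
  Seq     = list(role = "source", mode = "seq", transferred = character(0),
                 frozen = character(0)),
  Met     = list(role = "source", mode = "met", transferred = character(0),
                 frozen = character(0)),
  Full1   = list(role = "source", mode = "full", transferred = character(0),
                 frozen = character(0)),
  Full2   = list(role = "source", mode = "full",
                 transferred = c("sequence", "methylation"),
                 frozen = c("sequence", "methylation")),
  Full3   = list(role = "source", mode = "full",
                 transferred = c("sequence", "methylation"),
                 frozen = character(0)),
  # target settings: predicting from DNA sequence only
  SeqN    = list(role = "target", mode = "seq", transferred = character(0),
                 frozen = character(0)),
  SeqT1   = list(role = "target", mode = "seq", transferred = "sequence",
                 frozen = "sequence"),
  SeqT2   = list(role = "target", mode = "seq", transferred = "sequence",
                 frozen = character(0)),
  # ... from neighboring-CpG methylation only
  MetN    = list(role = "target", mode = "met", transferred = character(0),
                 frozen = character(0)),
  MetT1   = list(role = "target", mode = "met", transferred = "methylation",
                 frozen = "methylation"),
  MetT2   = list(role = "target", mode = "met", transferred = "methylation",
                 frozen = character(0)),
  # ... from both
  FullN   = list(role = "target", mode = "full", transferred = character(0),
                 frozen = character(0)),
  FullTS1 = list(role = "target", mode = "full", transferred = "sequence",
                 frozen = "sequence"),
  FullTS2 = list(role = "target", mode = "full", transferred = "sequence",
                 frozen = character(0)),
  FullTM1 = list(role = "target", mode = "full", transferred = "methylation",
                 frozen = "methylation"),
  FullTM2 = list(role = "target", mode = "full", transferred = "methylation",
                 frozen = character(0)),
  FullTB1 = list(role = "target", mode = "full",
                 transferred = c("sequence", "methylation"),
                 frozen = c("sequence", "methylation")),
  FullTB2 = list(role = "target", mode = "full",
                 transferred = c("sequence", "methylation"),
                 frozen = character(0)),
  FullTA1 = list(role = "target", mode = "full",
                 transferred = c("sequence", "methylation", "joint"),
                 frozen = c("sequence", "methylation", "joint")),
  FullTA2 = list(role = "target", mode = "full",
                 transferred = c("sequence", "methylation", "joint"),
                 frozen = character(0)))

#' Resolve a training setting into a transfer plan
#'
#' Maps a named setting (`Seq`, `Met`, `Full1`-`Full3` for source models;
#' `SeqN` ... `FullTA2` for target models) to its `(mode, transferred
#' groups, frozen groups)` triple. Settings that transfer anything require
#' a source checkpoint; `Full2`/`Full3` take two (the `Seq` and `Met`
#' model checkpoints).
#'
#' @param setting Setting name.
#' @param source_checkpoint Checkpoint directory (or a vector of
#'   directories searched in order for each transferred group).
#' @return A `transfer_plan` list: `setting`, `role`, `mode`,
#'   `transferred`, `frozen`, `source_checkpoint`.
#' @export
resolve_transfer <- function(setting, source_checkpoint = NULL) {
  entry <- TRANSFER_TABLE[[setting]]
  if (is.null(entry))
    stop_mt(paste0("unknown training setting: ", setting, "; known: ",
                   paste(names(TRANSFER_TABLE), collapse = ", ")))
  if (length(entry$transferred) && is.null(source_checkpoint))
    stop_mt(paste0("setting ", setting,
                   " transfers pretrained subnetworks and needs",
                   " `source_checkpoint`"))
  structure(c(entry, list(setting = setting,
                          source_checkpoint = source_checkpoint)),
            class = "transfer_plan")
}

#' List all training settings
#'
#' @return Tibble with one row per setting: name, role, mode, and
#'   comma-separated transferred / frozen groups.
#' @export
transfer_settings <- function() {
  tibble::tibble(
    setting = names(TRANSFER_TABLE),
    role = vapply(TRANSFER_TABLE, `[[`, "", "role"),
    mode = vapply(TRANSFER_TABLE, `[[`, "", "mode"),
    transferred = vapply(TRANSFER_TABLE, function(e)
      paste(e$transferred, collapse = ","), ""),
    frozen = vapply(TRANSFER_TABLE, function(e)
      paste(e$frozen, collapse = ","), ""))
}

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param lr_grid Learning-rate grid for [grid_search_lr()] (default
#'   `0.1 ... 1e-6` by decades).
#' @param batch_size Mini-batch size (default 128).
#' @param l1_coeff,l2_coeff Regularization coefficients; l2 acts as
#'   decoupled weight decay inside the optimizer, l1 is added to the
#'   objective explicitly.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without validation improvement (metric:
#'   mean minor-class F1 over tasks).
#' @param seed Seed governing parameter initialization and batch
#'   shuffling.
#' @param verbose Print one line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001,
                         lr_grid = 10^-(1:6),
                         batch_size = 128,
                         l1_coeff = 1e-4, l2_coeff = 1e-4,
                         max_epochs = 50, patience = 5,
                         seed = 1, verbose = FALSE) {
  structure(list(learning_rate = learning_rate, lr_grid = lr_grid,
                 batch_size = batch_size, l1_coeff = l1_coeff,
                 l2_coeff = l2_coeff, max_epochs = max_epochs,
                 patience = patience, seed = seed, verbose = verbose),
            class = "train_config")
}

## ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = "ANY")
}

# Walks the (nested) parameter list, applying Adam with decoupled weight
# decay; `skip` names top-level groups left untouched (frozen).
adam_step <- function(params, grads, opt, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      skip = character(0)) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk <- function(p, g, o) {
    if (!is.list(p)) {
      o$m <- beta1 * o$m + (1 - beta1) * g
      o$v <- beta2 * o$v + (1 - beta2) * g^2
      p <- p - lr * ((o$m / bc1) / (sqrt(o$v / bc2) + eps) + wd * p)
      return(list(p = p, o = o))
    }
    for (k in names(p)) {
      r <- walk(p[[k]], g[[k]], o[[k]])
      p[[k]] <- r$p
      o[[k]] <- r$o
    }
    list(p = p, o = o)
  }
  for (grp in names(params)) {
    if (grp %in% skip) next
    r <- walk(params[[grp]], grads[[grp]], opt[[grp]])
    params[[grp]] <- r$p
    opt[[grp]] <- r$o
  }
  list(params = params, opt = opt)
}

# Subgradient of the l1 penalty, added to the raw gradients for
# non-frozen groups.
add_l1 <- function(grads, params, l1, skip) {
  if (l1 <= 0) return(grads)
  for (grp in names(params)) {
    if (grp %in% skip) next
    grads[[grp]] <- map_leaves2(grads[[grp]], params[[grp]],
                                function(g, p) g + l1 * sign(p))
  }
  grads
}

map_leaves2 <- function(a, b, f) {
  if (!is.list(a)) return(f(a, b))
  for (k in names(a)) a[[k]] <- map_leaves2(a[[k]], b[[k]], f)
  a
}

## ---- training loop ----------------------------------------------------

#' Train a multi-task methylation model
#'
#' Optimizes the model with Adam on mini-batches, adds the l1 penalty to
#' the objective and applies l2 as weight decay, evaluates validation
#' minor-class F1 once per epoch, stops early after `patience`
#' non-improving epochs, and restores the best-validation parameters.
#' When a [resolve_transfer()] plan is supplied, the transferred groups
#' are loaded from the source checkpoint first and the frozen groups are
#' excluded from every update (bit-identical before/after training).
#'
#' @param model A `meth_model` (or `NULL` to build one from the plan's
#'   mode with `config`).
#' @param streams List with `train` and `val` `encoded_examples` (as from
#'   [split_examples()]).
#' @param config A [train_config()].
#' @param loss A [loss_config()].
#' @param plan Optional `transfer_plan`.
#' @param network_config Used when `model` is `NULL`.
#' @return A `meth_fit`: `model` (best parameters), `history` tibble,
#'   `best_epoch`, `best_val_f1`, `config`, `loss`, `plan`.
#' @export
train_model <- function(model, streams, config = train_config(),
                        loss = loss_config(), plan = NULL,
                        network_config = NULL) {
  if (is.null(model)) {
    assert_that(!is.null(plan) && !is.null(network_config),
                "either `model` or (`plan` + `network_config`) is required")
    model <- new_model(plan$mode, network_config,
                       task_ids = streams$train$profile_ids,
                       window_len = streams$train$window_len,
                       nbr_len = dim(streams$train$nbr)[3],
                       seed = config$seed)
  }
  frozen <- character(0)
  if (!is.null(plan)) {
    assert_that(model$mode == plan$mode,
                "model mode does not match the transfer plan")
    for (g in plan$transferred) {
      ck <- find_checkpoint_with_group(plan$source_checkpoint, g)
      model <- load_parameters(model, ck, groups = g)
    }
    frozen <- plan$frozen
  }
  tr <- streams$train
  n_train <- n_examples(tr)
  assert_that(n_train > 0, "empty training stream")
  assert_that(sum(tr$label_mask) > 0, "no observed training labels")
  set.seed(config$seed)
  beta_tr <- sample_weights(tr$labels, tr$label_mask,
                            loss$sample_weight_scheme)
  opt <- adam_init(model$params)
  best <- list(f1 = -Inf, epoch = 0L, params = model$params,
               state = model$state)
  hist <- list()
  stall <- 0L
  step_t <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_train)
    epoch_loss <- 0
    n_batches <- 0L
    for (s in seq(1, n_train, by = config$batch_size)) {
      idx <- ord[s:min(n_train, s + config$batch_size - 1)]
      batch <- slice_examples(tr, idx)
      fw <- model_forward(model, batch, training = TRUE, frozen = frozen)
      model <- fw$model
      lg <- batch_loss_grads(fw, batch, loss, beta_tr[idx, , drop = FALSE])
      if (!is.finite(lg$loss))
        stop_mt(paste0("non-finite loss at epoch ", epoch,
                       "; try a smaller learning rate"))
      grads <- model_backward(model, fw$cache, lg$dprob, lg$draw)
      grads <- add_l1(grads, model$params, config$l1_coeff, frozen)
      step_t <- step_t + 1L
      upd <- adam_step(model$params, grads, opt, config$learning_rate,
                       config$l2_coeff, step_t, skip = frozen)
      model$params <- upd$params
      opt <- upd$opt
      epoch_loss <- epoch_loss + lg$loss
      n_batches <- n_batches + 1L
    }
    val_f1 <- mean_minor_f1(model, streams$val)
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = epoch_loss / n_batches,
                                    val_f1 = val_f1)
    if (config$verbose)
      message(sprintf("epoch %d  loss %.4f  val F1 %.4f", epoch,
                      epoch_loss / n_batches, val_f1))
    if (is.finite(val_f1) && val_f1 > best$f1) {
      best <- list(f1 = val_f1, epoch = epoch, params = model$params,
                   state = model$state)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > config$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, best_val_f1 = best$f1,
                 config = config, loss = loss, plan = plan),
            class = "meth_fit")
}

find_checkpoint_with_group <- function(paths, group) {
  for (ck in paths) {
    if (file.exists(file.path(ck, paste0(group, ".rds")))) return(ck)
  }
  stop_mt(paste0("no supplied checkpoint contains parameter group '",
                 group, "'"))
}

# Per-batch loss value and gradients w.r.t. head outputs, combining the
# per-entry objective with task weights alpha and sample weights beta.
batch_loss_grads <- function(fw, batch, loss, beta) {
  m <- ncol(fw$prob)
  alpha <- rep_len(loss$task_weights, m)
  yhat <- if (loss$kind == "mse") fw$raw else fw$prob
  y <- batch$labels
  y[!batch$label_mask] <- 0.5           # placeholder; zero-weighted below
  lg <- loss_and_grad(y, yhat, loss$kind, loss$epsilon)
  w <- sweep(beta * batch$label_mask, 2, alpha, `*`)
  n_obs <- sum(batch$label_mask)
  scale <- if (loss$reduction == "mean" && n_obs > 0) 1 / n_obs else 1
  dweighted <- lg$grad * w * scale
  if (loss$kind == "mse") {
    list(loss = sum(lg$loss * w) * scale,
         dprob = matrix(0, nrow(dweighted), m), draw = dweighted)
  } else {
    list(loss = sum(lg$loss * w) * scale, dprob = dweighted, draw = NULL)
  }
}

# Mean minor-class F1 over tasks with evaluable data.
mean_minor_f1 <- function(model, examples) {
  if (n_examples(examples) == 0) return(NA_real_)
  prob <- predict(model, examples)
  f1s <- vapply(seq_len(ncol(prob)), function(j) {
    obs <- examples$label_mask[, j]
    if (!any(obs)) return(NA_real_)
    f1_minor(prob[obs, j], examples$labels[obs, j])
  }, numeric(1))
  if (all(is.na(f1s))) NA_real_ else mean(f1s, na.rm = TRUE)
}

#' Learning-rate grid search
#'
#' Trains one model per learning rate in the grid and selects the one with
#' the best validation minor-class F1; ties break toward the smaller rate.
#'
#' @inheritParams train_model
#' @return List with `fit` (the selected `meth_fit`) and `table` (one row
#'   per learning rate).
#' @export
grid_search_lr <- function(model, streams, config = train_config(),
                           loss = loss_config(), plan = NULL,
                           network_config = NULL) {
  assert_that(length(config$lr_grid) >= 1, "`lr_grid` must be non-empty")
  fits <- list()
  rows <- list()
  for (lr in sort(config$lr_grid, decreasing = TRUE)) {
    cfg <- config
    cfg$learning_rate <- lr
    fit <- train_model(model, streams, cfg, loss, plan, network_config)
    fits[[as.character(lr)]] <- fit
    rows[[as.character(lr)]] <- tibble::tibble(
      learning_rate = lr, best_epoch = fit$best_epoch,
      val_f1 = fit$best_val_f1)
  }
  table <- dplyr::bind_rows(rows)
  f1s <- ifelse(is.na(table$val_f1), -Inf, table$val_f1)
  best_f1 <- max(f1s)
  cand <- which(f1s == best_f1)
  pick <- cand[which.min(table$learning_rate[cand])]
  list(fit = fits[[as.character(table$learning_rate[pick])]], table = table)
}
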