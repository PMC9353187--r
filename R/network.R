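# The multi-task predictor: a Sequence subnetwork (two convolution blocks,
# each a convolution + max pooling, followed by batch normalization, then
# one fully connected layer), a Methylation subnetwork (bidirectional GRU
# over one neighbor vector per profile), a Joint subnetwork (two fully
# connected layers, each followed by batch normalization), and one
# two-class softmax classification head per profile (task). Heads share
# the feature extraction subnetworks; the mode selects which feature path
# feeds them: "seq", "met", or "full".

#' Network configuration
#'
#' Layer sizes for every subnetwork. The defaults follow the scale used by
#' convolutional-recurrent methylation predictors; all sizes are
#' configurable and every downstream computation is size-agnostic.
#'
#' @param conv_block_1,conv_block_2 Lists with `n_filters`, `filter_len`,
#'   `pool_len`.
#' @param seq_fc_units Width of the sequence subnetwork's fully connected
#'   output.
#' @param gru_hidden_units Hidden units per GRU direction; the methylation
#'   feature has length `2 * gru_hidden_units`.
#' @param joint_fc_units Length-2 vector: widths of the two joint layers.
#' @param head_fc_units Width of each classification head's hidden layer.
#' @param use_batch_norm Include batch normalization (default `TRUE`).
#' @return A `network_config` list.
#' @export
network_config <- function(conv_block_1 = list(n_filters = 128,
                                               filter_len = 11,
                                               pool_len = 4),
                           conv_block_2 = list(n_filters = 256,
                                               filter_len = 3,
                                               pool_len = 2),
                           seq_fc_units = 256,
                           gru_hidden_units = 256,
                           joint_fc_units = c(512, 256),
                           head_fc_units = 128,
                           use_batch_norm = TRUE) {
  cfg <- list(conv_block_1 = conv_block_1, conv_block_2 = conv_block_2,
              seq_fc_units = seq_fc_units,
              gru_hidden_units = gru_hidden_units,
              joint_fc_units = joint_fc_units,
              head_fc_units = head_fc_units,
              use_batch_norm = isTRUE(use_batch_norm))
  sizes <- c(unlist(conv_block_1), unlist(conv_block_2), seq_fc_units,
             gru_hidden_units, joint_fc_units, head_fc_units)
  assert_that(all(sizes >= 1), "all layer sizes must be >= 1")
  assert_that(length(joint_fc_units) == 2,
              "`joint_fc_units` must give exactly two layer widths")
  structure(cfg, class = "network_config")
}

# Sequence-path output length after the two convolution blocks.
seq_flat_len <- function(config, window_len) {
  c1 <- config$conv_block_1; c2 <- config$conv_block_2
  l <- window_len - c1$filter_len + 1L
  assert_that(l >= 1, "window shorter than the first convolution filter")
  l <- l %/% c1$pool_len
  assert_that(l >= 1, "window too short for the first pooling layer")
  l <- l - c2$filter_len + 1L
  assert_that(l >= 1, "window too short for the second convolution filter")
  l <- l %/% c2$pool_len
  assert_that(l >= 1, "window too short for the second pooling layer")
  l * c2$n_filters
}

feature_len <- function(config, mode, window_len) {
  switch(mode,
         seq = config$seq_fc_units,
         met = 2L * config$gru_hidden_units,
         full = config$joint_fc_units[2])
}

#' Assemble a multi-task methylation predictor
#'
#' @param mode `"seq"` (predict from DNA sequence only), `"met"`
#'   (neighboring-CpG methylation only) or `"full"` (both, fused by the
#'   joint subnetwork).
#' @param config A [network_config()].
#' @param task_ids Character vector naming the profiles (one
#'   classification head each).
#' @param window_len Sequence window length the model accepts.
#' @param nbr_len Neighbor-vector length (default 100).
#' @param seed Seed for parameter initialization.
#' @return A `meth_model` object.
#' @export
new_model <- function(mode = c("full", "seq", "met"), config = network_config(),
                      task_ids, window_len = 1001, nbr_len = 100,
                      seed = 1) {
  mode <- match.arg(mode)
  assert_that(length(task_ids) >= 1, "need at least one task")
  set.seed(seed)
  params <- list()
  state <- list()
  if (mode %in% c("seq", "full")) {
    flat <- seq_flat_len(config, window_len)
    c1 <- config$conv_block_1; c2 <- config$conv_block_2
    params$sequence <- list(
      conv1_W = glorot(c1$filter_len * 4L, c1$n_filters),
      conv1_b = numeric(c1$n_filters),
      conv2_W = glorot(c2$filter_len * c1$n_filters, c2$n_filters),
      conv2_b = numeric(c2$n_filters),
      fc_W = glorot(flat, config$seq_fc_units),
      fc_b = numeric(config$seq_fc_units))
    state$sequence <- list()
    if (config$use_batch_norm) {
      params$sequence$bn1_gamma <- rep(1, c1$n_filters)
      params$sequence$bn1_beta <- numeric(c1$n_filters)
      params$sequence$bn2_gamma <- rep(1, c2$n_filters)
      params$sequence$bn2_beta <- numeric(c2$n_filters)
      state$sequence <- list(
        bn1 = list(mean = numeric(c1$n_filters), var = rep(1, c1$n_filters)),
        bn2 = list(mean = numeric(c2$n_filters), var = rep(1, c2$n_filters)))
    }
  }
  if (mode %in% c("met", "full")) {
    H <- config$gru_hidden_units
    params$methylation <- list(
      fwd_W = glorot(nbr_len, 3L * H), fwd_U = glorot(H, 3L * H),
      fwd_b = numeric(3L * H),
      bwd_W = glorot(nbr_len, 3L * H), bwd_U = glorot(H, 3L * H),
      bwd_b = numeric(3L * H))
    state$methylation <- list()
  }
  if (mode == "full") {
    j <- config$joint_fc_units
    in_len <- config$seq_fc_units + 2L * config$gru_hidden_units
    params$joint <- list(
      fc1_W = glorot(in_len, j[1]), fc1_b = numeric(j[1]),
      fc2_W = glorot(j[1], j[2]), fc2_b = numeric(j[2]))
    state$joint <- list()
    if (config$use_batch_norm) {
      params$joint$bn1_gamma <- rep(1, j[1])
      params$joint$bn1_beta <- numeric(j[1])
      params$joint$bn2_gamma <- rep(1, j[2])
      params$joint$bn2_beta <- numeric(j[2])
      state$joint <- list(
        bn1 = list(mean = numeric(j[1]), var = rep(1, j[1])),
        bn2 = list(mean = numeric(j[2]), var = rep(1, j[2])))
    }
  }
  fl <- feature_len(config, mode, window_len)
  params$heads <- lapply(task_ids, function(id) list(
    fc_W = glorot(fl, config$head_fc_units),
    fc_b = numeric(config$head_fc_units),
    out_W = glorot(config$head_fc_units, 2L),
    out_b = numeric(2L)))
  names(params$heads) <- task_ids
  structure(list(mode = mode, config = config, params = params,
                 state = state, task_ids = task_ids,
                 window_len = window_len, nbr_len = nbr_len,
                 init_seed = seed),
            class = "meth_model")
}

#' @export
print.meth_model <- function(x, ...) {
  cat("<meth_model> mode=", x$mode, ", ", length(x$task_ids),
      " task(s), window ", x$window_len, " bp\n", sep = "")
  invisible(x)
}

## ---- subnetwork forward/backward -------------------------------------

seq_subnet_fw <- function(p, st, cfg, x, training) {
  cache <- list()
  c1 <- conv1d_fw(x, p$conv1_W, p$conv1_b, cfg$conv_block_1$filter_len)
  r1 <- relu_fw(c1$out)
  m1 <- maxpool_fw(r1$out, cfg$conv_block_1$pool_len)
  h <- m1$out
  if (cfg$use_batch_norm) {
    d <- dim(h); flat <- h; dim(flat) <- c(d[1] * d[2], d[3])
    b1 <- bn_fw(flat, p$bn1_gamma, p$bn1_beta, st$bn1, training)
    st$bn1 <- b1$running
    h <- b1$out; dim(h) <- d
    cache$bn1 <- b1$cache; cache$bn1_dim <- d
  }
  c2 <- conv1d_fw(h, p$conv2_W, p$conv2_b, cfg$conv_block_2$filter_len)
  r2 <- relu_fw(c2$out)
  m2 <- maxpool_fw(r2$out, cfg$conv_block_2$pool_len)
  h2 <- m2$out
  if (cfg$use_batch_norm) {
    d2 <- dim(h2); flat2 <- h2; dim(flat2) <- c(d2[1] * d2[2], d2[3])
    b2 <- bn_fw(flat2, p$bn2_gamma, p$bn2_beta, st$bn2, training)
    st$bn2 <- b2$running
    h2 <- b2$out; dim(h2) <- d2
    cache$bn2 <- b2$cache; cache$bn2_dim <- d2
  }
  d2 <- dim(h2)
  flat_out <- h2; dim(flat_out) <- c(d2[1], d2[2] * d2[3])
  fc <- dense_fw(flat_out, p$fc_W, p$fc_b)
  rf <- relu_fw(fc$out)
  cache <- c(cache, list(c1 = c1$cache, r1 = r1$cache, m1 = m1$cache,
                         c2 = c2$cache, r2 = r2$cache, m2 = m2$cache,
                         fc = fc$cache, rf = rf$cache, out_dim = d2))
  list(out = rf$out, cache = cache, state = st)
}

seq_subnet_bw <- function(dout, cache, p, cfg) {
  g <- list()
  d_fc <- relu_bw(dout, cache$rf)
  fcb <- dense_bw(d_fc, cache$fc, p$fc_W)
  g$fc_W <- fcb$dW; g$fc_b <- fcb$db
  dh2 <- fcb$dx; dim(dh2) <- cache$out_dim
  if (cfg$use_batch_norm) {
    d2 <- cache$bn2_dim
    flat <- dh2; dim(flat) <- c(d2[1] * d2[2], d2[3])
    b2 <- bn_bw(flat, cache$bn2, p$bn2_gamma)
    g$bn2_gamma <- b2$dgamma; g$bn2_beta <- b2$dbeta
    dh2 <- b2$dx; dim(dh2) <- d2
  }
  dm2 <- maxpool_bw(dh2, cache$m2)
  dr2 <- relu_bw(dm2, cache$r2)
  c2b <- conv1d_bw(dr2, cache$c2, p$conv2_W)
  g$conv2_W <- c2b$dW; g$conv2_b <- c2b$db
  dh1 <- c2b$dx
  if (cfg$use_batch_norm) {
    d1 <- cache$bn1_dim
    flat <- dh1; dim(flat) <- c(d1[1] * d1[2], d1[3])
    b1 <- bn_bw(flat, cache$bn1, p$bn1_gamma)
    g$bn1_gamma <- b1$dgamma; g$bn1_beta <- b1$dbeta
    dh1 <- b1$dx; dim(dh1) <- d1
  }
  dm1 <- maxpool_bw(dh1, cache$m1)
  dr1 <- relu_bw(dm1, cache$r1)
  c1b <- conv1d_bw(dr1, cache$c1, p$conv1_W)
  g$conv1_W <- c1b$dW; g$conv1_b <- c1b$db
  g
}

# nbr: (B, m, nbr_len) array -> list of m (B, nbr_len) step inputs.
nbr_steps <- function(nbr) {
  m <- dim(nbr)[2]
  lapply(seq_len(m), function(t) {
    s <- nbr[, t, , drop = FALSE]
    dim(s) <- c(dim(nbr)[1], dim(nbr)[3])
    s
  })
}

met_subnet_fw <- function(p, nbr) {
  xs <- nbr_steps(nbr)
  assert_that(length(xs) >= 1, "methylation subnetwork needs >= 1 profile")
  fw <- gru_fw(xs, p$fwd_W, p$fwd_U, p$fwd_b)
  bw <- gru_fw(rev(xs), p$bwd_W, p$bwd_U, p$bwd_b)
  list(out = cbind(fw$out, bw$out),
       cache = list(fw = fw$cache, bw = bw$cache, m = length(xs),
                    nbr_dim = dim(nbr)))
}

met_subnet_bw <- function(dout, cache, p) {
  H <- cache$fw$H
  dfw <- gru_bw(dout[, seq_len(H), drop = FALSE], cache$fw,
                p$fwd_W, p$fwd_U)
  dbw <- gru_bw(dout[, H + seq_len(H), drop = FALSE], cache$bw,
                p$bwd_W, p$bwd_U)
  g <- list(fwd_W = dfw$dW, fwd_U = dfw$dU, fwd_b = dfw$db,
            bwd_W = dbw$dW, bwd_U = dbw$dU, bwd_b = dbw$db)
  dnbr <- array(0, dim = cache$nbr_dim)
  for (t in seq_len(cache$m)) {
    dx <- dfw$dxs[[t]] + dbw$dxs[[cache$m - t + 1L]]
    dnbr[, t, ] <- dx
  }
  list(grads = g, dnbr = dnbr)
}

joint_subnet_fw <- function(p, st, cfg, x, training) {
  cache <- list()
  f1 <- dense_fw(x, p$fc1_W, p$fc1_b)
  h <- f1$out
  if (cfg$use_batch_norm) {
    b1 <- bn_fw(h, p$bn1_gamma, p$bn1_beta, st$bn1, training)
    st$bn1 <- b1$running; h <- b1$out; cache$bn1 <- b1$cache
  }
  r1 <- relu_fw(h)
  f2 <- dense_fw(r1$out, p$fc2_W, p$fc2_b)
  h2 <- f2$out
  if (cfg$use_batch_norm) {
    b2 <- bn_fw(h2, p$bn2_gamma, p$bn2_beta, st$bn2, training)
    st$bn2 <- b2$running; h2 <- b2$out; cache$bn2 <- b2$cache
  }
  r2 <- relu_fw(h2)
  cache <- c(cache, list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache,
                         r2 = r2$cache))
  list(out = r2$out, cache = cache, state = st)
}

joint_subnet_bw <- function(dout, cache, p, cfg) {
  g <- list()
  dh2 <- relu_bw(dout, cache$r2)
  if (cfg$use_batch_norm) {
    b2 <- bn_bw(dh2, cache$bn2, p$bn2_gamma)
    g$bn2_gamma <- b2$dgamma; g$bn2_beta <- b2$dbeta
    dh2 <- b2$dx
  }
  f2b <- dense_bw(dh2, cache$f2, p$fc2_W)
  g$fc2_W <- f2b$dW; g$fc2_b <- f2b$db
  dh1 <- relu_bw(f2b$dx, cache$r1)
  if (cfg$use_batch_norm) {
    b1 <- bn_bw(dh1, cache$bn1, p$bn1_gamma)
    g$bn1_gamma <- b1$dgamma; g$bn1_beta <- b1$dbeta
    dh1 <- b1$dx
  }
  f1b <- dense_bw(dh1, cache$f1, p$fc1_W)
  g$fc1_W <- f1b$dW; g$fc1_b <- f1b$db
  list(grads = g, dx = f1b$dx)
}

head_fw <- function(p, x) {
  f1 <- dense_fw(x, p$fc_W, p$fc_b)
  r1 <- relu_fw(f1$out)
  f2 <- dense_fw(r1$out, p$out_W, p$out_b)
  sm <- softmax2_fw(f2$out)
  list(prob = sm$p[, 2], raw = f2$out[, 2] - f2$out[, 1],
       cache = list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache,
                    sm = sm$cache))
}

# dprob: dL/d(methylated probability); draw: dL/d(raw score), used by the
# plain-MSE objective which regresses the unsquashed score.
head_bw <- function(dprob, draw, cache, p) {
  dz <- softmax2_bw(dprob, cache$sm)
  if (!is.null(draw)) dz <- dz + cbind(-draw, draw)
  f2b <- dense_bw(dz, cache$f2, p$out_W)
  dr1 <- relu_bw(f2b$dx, cache$r1)
  f1b <- dense_bw(dr1, cache$f1, p$fc_W)
  list(grads = list(fc_W = f1b$dW, fc_b = f1b$db,
                    out_W = f2b$dW, out_b = f2b$db),
       dx = f1b$dx)
}

## ---- full model forward/backward -------------------------------------

# frozen: character subset of {"sequence","methylation","joint"}. Frozen
# groups run in inference mode (their batch-norm statistics are neither
# used from the batch nor updated), so one training step leaves them
# bit-identical.
model_forward <- function(model, batch, training = FALSE,
                          frozen = character(0)) {
  p <- model$params; cfg <- model$config
  cache <- list()
  feat <- NULL
  if (model$mode %in% c("seq", "full")) {
    tr <- training && !("sequence" %in% frozen)
    sq <- seq_subnet_fw(p$sequence, model$state$sequence, cfg,
                        batch$seq, tr)
    if (tr) model$state$sequence <- sq$state
    cache$sequence <- sq$cache
    feat <- sq$out
  }
  if (model$mode %in% c("met", "full")) {
    mt <- met_subnet_fw(p$methylation, batch$nbr)
    cache$methylation <- mt$cache
    feat <- if (model$mode == "met") mt$out else cbind(feat, mt$out)
  }
  if (model$mode == "full") {
    tr <- training && !("joint" %in% frozen)
    jt <- joint_subnet_fw(p$joint, model$state$joint, cfg, feat, tr)
    if (tr) model$state$joint <- jt$state
    cache$joint <- jt$cache
    cache$joint_in_len <- ncol(feat)
    feat <- jt$out
  }
  m <- length(model$task_ids)
  B <- nrow(feat)
  prob <- matrix(0, B, m, dimnames = list(NULL, model$task_ids))
  raw <- prob
  cache$heads <- vector("list", m)
  for (j in seq_len(m)) {
    hd <- head_fw(p$heads[[j]], feat)
    prob[, j] <- hd$prob
    raw[, j] <- hd$raw
    cache$heads[[j]] <- hd$cache
  }
  list(prob = prob, raw = raw, cache = cache, model = model)
}

model_backward <- function(model, cache, dprob, draw = NULL) {
  p <- model$params; cfg <- model$config
  grads <- list(heads = vector("list", length(model$task_ids)))
  names(grads$heads) <- model$task_ids
  dfeat <- NULL
  for (j in seq_along(model$task_ids)) {
    hb <- head_bw(dprob[, j],
                  if (is.null(draw)) NULL else draw[, j],
                  cache$heads[[j]], p$heads[[j]])
    grads$heads[[j]] <- hb$grads
    dfeat <- if (is.null(dfeat)) hb$dx else dfeat + hb$dx
  }
  if (model$mode == "full") {
    jb <- joint_subnet_bw(dfeat, cache$joint, p$joint, cfg)
    grads$joint <- jb$grads
    dfeat <- jb$dx
  }
  if (model$mode == "seq") {
    grads$sequence <- seq_subnet_bw(dfeat, cache$sequence, p$sequence, cfg)
  } else if (model$mode == "met") {
    mb <- met_subnet_bw(dfeat, cache$methylation, p$methylation)
    grads$methylation <- mb$grads
  } else {
    ns <- cfg$seq_fc_units
    grads$sequence <- seq_subnet_bw(dfeat[, seq_len(ns), drop = FALSE],
                                    cache$sequence, p$sequence, cfg)
    mb <- met_subnet_bw(dfeat[, (ns + 1L):ncol(dfeat), drop = FALSE],
                        cache$methylation, p$methylation)
    grads$methylation <- mb$grads
  }
  grads
}

#' Predict methylated-probabilities for encoded examples
#'
#' Runs the model in inference mode (deterministic for fixed parameters).
#'
#' @param object A `meth_model`.
#' @param examples An `encoded_examples` object.
#' @param chunk_size Examples per forward pass.
#' @param ... Unused.
#' @return `n x m` matrix of probabilities in `[0, 1]`, one column per
#'   task.
#' @export
predict.meth_model <- function(object, examples, chunk_size = 4096, ...) {
  n <- n_examples(examples)
  m <- length(object$task_ids)
  out <- matrix(NA_real_, n, m, dimnames = list(NULL, object$task_ids))
  for (s in seq(1, max(n, 1), by = chunk_size)) {
    if (n == 0) break
    idx <- s:min(n, s + chunk_size - 1)
    fw <- model_forward(object, slice_examples(examples, idx),
                        training = FALSE)
    out[idx, ] <- fw$prob
  }
  out
}

## ---- checkpoints ------------------------------------------------------

#' Save / load model parameters by subnetwork group
#'
#' A checkpoint is a directory with one file per parameter group
#' (`sequence`, `methylation`, `joint`, `heads`) plus a JSON sidecar
#' recording the configuration, mode, task ordering and provenance.
#' Loading may be restricted to a subset of the feature-extraction groups
#' (classification heads belong to a task set and are only loaded when
#' `groups` includes `"heads"` explicitly or is `"all"`); group shapes
#' must match the current configuration, and a mismatch is an error
#' naming the group.
#'
#' @param model A `meth_model`.
#' @param path Checkpoint directory.
#' @param meta Optional named list merged into the sidecar (training
#'   provenance).
#' @return `save_parameters()` returns `path` invisibly;
#'   `load_parameters()` returns the updated model.
#' @export
save_parameters <- function(model, path, meta = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (g in names(model$params)) {
    saveRDS(list(params = model$params[[g]], state = model$state[[g]]),
            file.path(path, paste0(g, ".rds")))
  }
  sidecar <- c(list(mode = model$mode, config = unclass(model$config),
                    task_ids = model$task_ids,
                    window_len = model$window_len, nbr_len = model$nbr_len,
                    init_seed = model$init_seed,
                    groups = names(model$params)), meta)
  jsonlite::write_json(sidecar, file.path(path, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_parameters
#' @param groups Character vector of groups to load, or `"all"`.
#' @export
load_parameters <- function(model, path, groups = "all") {
  if (identical(groups, "all")) groups <- names(model$params)
  for (g in groups) {
    f <- file.path(path, paste0(g, ".rds"))
    if (!file.exists(f))
      stop_mt(paste0("checkpoint has no parameter group '", g, "': ", path))
    stored <- readRDS(f)
    check_group_shapes(model$params[[g]], stored$params, g)
    model$params[[g]] <- stored$params
    model$state[[g]] <- stored$state
  }
  model
}

#' Rebuild a model from a checkpoint directory
#'
#' Reads the JSON sidecar to reconstruct the architecture (mode,
#' configuration, task ordering, window length) and loads every stored
#' parameter group, heads included.
#'
#' @param path Checkpoint directory written by [save_parameters()].
#' @return A `meth_model` ready for [predict()] or further training.
#' @export
load_model <- function(path) {
  sc_file <- file.path(path, "checkpoint.json")
  assert_that(file.exists(sc_file),
              paste0("no checkpoint sidecar at ", sc_file))
  sc <- jsonlite::read_json(sc_file, simplifyVector = TRUE)
  cfg <- do.call(network_config, sc$config[names(sc$config) !=
                                             "use_batch_norm"] |>
                   c(list(use_batch_norm = isTRUE(sc$config$use_batch_norm))))
  model <- new_model(sc$mode, cfg, task_ids = sc$task_ids,
                     window_len = sc$window_len, nbr_len = sc$nbr_len,
                     seed = sc$init_seed %||% 1)
  load_parameters(model, path, groups = "all")
}

check_group_shapes <- function(current, stored, group) {
  flat_c <- unlist_dims(current)
  flat_s <- unlist_dims(stored)
  if (!identical(flat_c, flat_s))
    stop_mt(paste0("parameter shape mismatch in group '", group,
                   "': stored checkpoint was created with a different",
                   " network configuration"))
  invisible(TRUE)
}

unlist_dims <- function(x) {
  if (is.list(x)) return(lapply(x, unlist_dims))
  dim(x) %||% length(x)
}
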