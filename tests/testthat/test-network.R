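# Architecture contracts: shapes, probability normalization, inference
# determinism, checkpoint round trips, and an end-to-end gradient check
# of the hand-written backpropagation.

ns <- asNamespace("methtransfer")

tiny_cfg <- function() {
  network_config(conv_block_1 = list(n_filters = 4, filter_len = 5,
                                     pool_len = 2),
                 conv_block_2 = list(n_filters = 3, filter_len = 3,
                                     pool_len = 2),
                 seq_fc_units = 6, gru_hidden_units = 4,
                 joint_fc_units = c(7, 5), head_fc_units = 4)
}

test_that("subnetworks and heads honor their shape contracts", {
  cfg <- tiny_cfg()
  ex <- toy_examples(9, 3, window_len = 21, nbr_len = 12, seed = 1)
  # sequence path: (batch, window, 4) -> (batch, seq_fc_units)
  mseq <- new_model("seq", cfg, task_ids = paste0("p", 1:3),
                    window_len = 21, nbr_len = 12, seed = 2)
  fw <- ns$model_forward(mseq, ex)
  expect_equal(dim(fw$prob), c(9, 3))
  # methylation path: m profiles, hidden H -> feature length 2H
  mmet <- new_model("met", cfg, task_ids = paste0("p", 1:3),
                    window_len = 21, nbr_len = 12, seed = 2)
  mt <- ns$met_subnet_fw(mmet$params$methylation, ex$nbr)
  expect_equal(dim(mt$out), c(9, 2 * cfg$gru_hidden_units))
  # n_tasks heads give n_tasks probability columns
  m7 <- new_model("full", cfg, task_ids = paste0("t", 1:7),
                  window_len = 21, nbr_len = 12, seed = 2)
  fw7 <- ns$model_forward(m7, ex)
  expect_equal(ncol(fw7$prob), 7)
  # window shorter than the receptive field is a construction error
  expect_error(new_model("seq", cfg, "a", window_len = 5, nbr_len = 12),
               "shorter|short")
})

test_that("head probabilities are normalized and finite on degenerate input", {
  cfg <- tiny_cfg()
  m <- new_model("full", cfg, c("a", "b"), window_len = 21, nbr_len = 12,
                 seed = 5)
  ex <- toy_examples(8, 2, seed = 3)
  fw <- ns$model_forward(m, ex)
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  # two-class softmax scores sum to 1: prob of unmethylated = 1 - prob
  expect_equal(ns$sigmoid(fw$raw), fw$prob, tolerance = 1e-12)
  # all-zero window and fully padded neighbors stay finite
  ex$seq[] <- 0
  ex$nbr[] <- 0.5
  fw0 <- ns$model_forward(m, ex)
  expect_true(all(is.finite(fw0$prob)))
})

test_that("inference is deterministic and ignores the unused input path", {
  cfg <- tiny_cfg()
  ex <- toy_examples(6, 2, seed = 4)
  mseq <- new_model("seq", cfg, c("a", "b"), window_len = 21, nbr_len = 12,
                    seed = 7)
  p1 <- predict(mseq, ex)
  p2 <- predict(mseq, ex)
  expect_identical(p1, p2)
  # mode seq ignores neighbor vectors entirely
  ex_perturbed <- ex
  ex_perturbed$nbr[] <- runif(length(ex$nbr))
  expect_identical(predict(mseq, ex_perturbed), p1)
  # mode met ignores the sequence window
  mmet <- new_model("met", cfg, c("a", "b"), window_len = 21, nbr_len = 12,
                    seed = 7)
  pm <- predict(mmet, ex)
  ex_seqper <- ex
  ex_seqper$seq[] <- 1
  expect_identical(predict(mmet, ex_seqper), pm)
})

test_that("for a single profile the bidirectional GRU is order-invariant", {
  cfg <- tiny_cfg()
  m <- new_model("met", cfg, "a", window_len = 21, nbr_len = 12, seed = 9)
  ex <- toy_examples(5, 1, seed = 6)
  p <- predict(m, ex)
  expect_true(all(is.finite(p)))
  expect_equal(dim(ns$met_subnet_fw(m$params$methylation, ex$nbr)$out),
               c(5, 2 * cfg$gru_hidden_units))
})

test_that("checkpoints round-trip bitwise and reject mismatched shapes", {
  cfg <- tiny_cfg()
  m <- new_model("full", cfg, c("a", "b"), window_len = 21, nbr_len = 12,
                 seed = 11)
  ex <- toy_examples(4, 2, seed = 8)
  ck <- withr::local_tempdir()
  save_parameters(m, ck)
  m2 <- new_model("full", cfg, c("a", "b"), window_len = 21, nbr_len = 12,
                  seed = 999)  # different init
  m2 <- load_parameters(m2, ck, groups = "all")
  expect_identical(predict(m2, ex), predict(m, ex))
  # loading only the sequence group leaves methylation parameters alone
  m3 <- new_model("full", cfg, c("a", "b"), window_len = 21, nbr_len = 12,
                  seed = 999)
  met_before <- m3$params$methylation
  m3 <- load_parameters(m3, ck, groups = "sequence")
  expect_identical(m3$params$methylation, met_before)
  expect_identical(m3$params$sequence, m$params$sequence)
  # a different gru size is rejected, naming the group
  cfg2 <- tiny_cfg(); cfg2$gru_hidden_units <- 8
  m4 <- new_model("full", cfg2, c("a", "b"), window_len = 21, nbr_len = 12)
  expect_error(load_parameters(m4, ck, groups = "methylation"),
               "methylation")
  # the sidecar alone reconstructs the full model
  m5 <- load_model(ck)
  expect_identical(predict(m5, ex), predict(m, ex))
})

test_that("backpropagation matches central-difference gradients end to end", {
  cfg <- tiny_cfg()
  set.seed(42)
  ex <- toy_examples(7, 2, window_len = 21, nbr_len = 12, seed = 13)
  ex$label_mask <- matrix(runif(14) > 0.3, 7, 2)
  m <- new_model("full", cfg, c("a", "b"), window_len = 21, nbr_len = 12,
                 seed = 3)
  lossc <- loss_config("kl")
  beta <- sample_weights(ex$labels, ex$label_mask)
  loss_of <- function(model) {
    fw <- ns$model_forward(model, ex, training = TRUE)
    ns$batch_loss_grads(fw, ex, lossc, beta)$loss
  }
  fw <- ns$model_forward(m, ex, training = TRUE)
  lg <- ns$batch_loss_grads(fw, ex, lossc, beta)
  grads <- ns$model_backward(m, fw$cache, lg$dprob, lg$draw)
  # align gradient tree to the parameter tree, then flatten both
  align <- function(g, p) {
    if (!is.list(p)) return(g)
    stats::setNames(lapply(names(p), function(k) align(g[[k]], p[[k]])),
                    names(p))
  }
  flat <- function(x) if (is.list(x)) unlist(lapply(x, flat)) else
    as.numeric(x)
  pvec <- flat(m$params)
  gvec <- flat(align(grads, m$params)[names(m$params)])
  set_flat <- function(params, vec) {
    i <- 0
    walk <- function(p) {
      if (!is.list(p)) {
        n <- length(p); p[] <- vec[(i + 1):(i + n)]; i <<- i + n
        return(p)
      }
      for (k in names(p)) p[[k]] <- walk(p[[k]])
      p
    }
    walk(params)
  }
  set.seed(1)
  idx <- sample(length(pvec), 50)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    v1 <- pvec; v1[i] <- v1[i] + h
    v2 <- pvec; v2[i] <- v2[i] - h
    m1 <- m; m1$params <- set_flat(m$params, v1)
    m2 <- m; m2$params <- set_flat(m$params, v2)
    (loss_of(m1) - loss_of(m2)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(gvec[idx]), num, tolerance = 1e-5)
})
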