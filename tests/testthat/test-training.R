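# Splits, the transfer-setting table, freezing, determinism and the
# learning-rate grid.

test_that("examples are routed to splits purely by chromosome name", {
  plan <- split_plan()  # bovine defaults
  ex <- toy_examples(4, 1, seed = 1)
  ex$chrom <- c("4", "2", "3", "1")
  st <- split_examples(ex, plan)
  expect_equal(sort(st$train$chrom), c("1", "4"))
  expect_equal(st$test$chrom, "2")
  expect_equal(st$val$chrom, "3")
  # empty stream splits into three empty streams
  e0 <- slice_examples(ex, integer(0))
  st0 <- split_examples(e0, plan)
  expect_equal(vapply(st0[1:3], n_examples, integer(1)),
               c(train = 0L, val = 0L, test = 0L))
  # a chromosome in no split is an error
  ex$chrom[1] <- "chrUn"
  expect_error(split_examples(ex, plan), "chrUn")
  expect_error(split_plan("1", "1", "2"), "disjoint")
})

test_that("every source and target setting resolves to its exact transfer triple", {
  expected <- list(
    #          mode    transferred                          frozen
    Seq     = list("seq",  character(0),                        character(0)),
    Met     = list("met",  character(0),                        character(0)),
    Full1   = list("full", character(0),                        character(0)),
    Full2   = list("full", c("sequence", "methylation"),
                   c("sequence", "methylation")),
    Full3   = list("full", c("sequence", "methylation"),        character(0)),
    SeqN    = list("seq",  character(0),                        character(0)),
    SeqT1   = list("seq",  "sequence",                          "sequence"),
    SeqT2   = list("seq",  "sequence",                          character(0)),
    MetN    = list("met",  character(0),                        character(0)),
    MetT1   = list("met",  "methylation",                       "methylation"),
    MetT2   = list("met",  "methylation",                       character(0)),
    FullN   = list("full", character(0),                        character(0)),
    FullTS1 = list("full", "sequence",                          "sequence"),
    FullTS2 = list("full", "sequence",                          character(0)),
    FullTM1 = list("full", "methylation",                       "methylation"),
    FullTM2 = list("full", "methylation",                       character(0)),
    FullTB1 = list("full", c("sequence", "methylation"),
                   c("sequence", "methylation")),
    FullTB2 = list("full", c("sequence", "methylation"),        character(0)),
    FullTA1 = list("full", c("sequence", "methylation", "joint"),
                   c("sequence", "methylation", "joint")),
    FullTA2 = list("full", c("sequence", "methylation", "joint"),
                   character(0)))
  for (s in names(expected)) {
    plan <- resolve_transfer(s, source_checkpoint = "dummy")
    expect_equal(plan$mode, expected[[s]][[1]], label = s)
    expect_setequal(plan$transferred, expected[[s]][[2]])
    expect_setequal(plan$frozen, expected[[s]][[3]])
    expect_true(all(plan$frozen %in% plan$transferred), label = s)
  }
  expect_equal(nrow(transfer_settings()), 20)
  expect_error(resolve_transfer("FullTX9"), "unknown")
  # transfer settings demand a checkpoint
  expect_error(resolve_transfer("FullTA2"), "checkpoint")
  expect_silent(resolve_transfer("FullN"))
})

test_that("training is deterministic under a fixed seed", {
  ex <- toy_examples(40, 2, seed = 10)
  streams <- list(train = slice_examples(ex, 1:30),
                  val = slice_examples(ex, 31:40))
  cfg <- train_config(learning_rate = 1e-2, batch_size = 16,
                      max_epochs = 3, patience = 5, seed = 77)
  net <- network_config(conv_block_1 = list(n_filters = 4, filter_len = 5,
                                            pool_len = 2),
                        conv_block_2 = list(n_filters = 3, filter_len = 3,
                                            pool_len = 2),
                        seq_fc_units = 6, gru_hidden_units = 4,
                        joint_fc_units = c(7, 5), head_fc_units = 4)
  f1 <- train_model(NULL, streams, cfg, loss_config("kl"),
                    plan = resolve_transfer("FullN"), network_config = net)
  f2 <- train_model(NULL, streams, cfg, loss_config("kl"),
                    plan = resolve_transfer("FullN"), network_config = net)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("frozen groups are bit-identical after training while others move", {
  ex <- toy_examples(32, 2, seed = 20)
  streams <- list(train = slice_examples(ex, 1:24),
                  val = slice_examples(ex, 25:32))
  net <- network_config(conv_block_1 = list(n_filters = 4, filter_len = 5,
                                            pool_len = 2),
                        conv_block_2 = list(n_filters = 3, filter_len = 3,
                                            pool_len = 2),
                        seq_fc_units = 6, gru_hidden_units = 4,
                        joint_fc_units = c(7, 5), head_fc_units = 4)
  donor <- new_model("full", net, c("p1", "p2"), window_len = 21,
                     nbr_len = 12, seed = 5)
  ck <- withr::local_tempdir()
  save_parameters(donor, ck)
  fit <- train_model(NULL, streams,
                     train_config(learning_rate = 1e-2, batch_size = 32,
                                  max_epochs = 1, patience = 5, seed = 3),
                     loss_config("kl"),
                     plan = resolve_transfer("FullTB1", ck),
                     network_config = net)
  expect_identical(fit$model$params$sequence, donor$params$sequence)
  expect_identical(fit$model$params$methylation, donor$params$methylation)
  expect_false(identical(fit$model$params$joint, donor$params$joint))
})

test_that("early stopping restores the best-validation parameters", {
  ex <- toy_examples(40, 2, seed = 30)
  streams <- list(train = slice_examples(ex, 1:30),
                  val = slice_examples(ex, 31:40))
  net <- network_config(conv_block_1 = list(n_filters = 4, filter_len = 5,
                                            pool_len = 2),
                        conv_block_2 = list(n_filters = 3, filter_len = 3,
                                            pool_len = 2),
                        seq_fc_units = 6, gru_hidden_units = 4,
                        joint_fc_units = c(7, 5), head_fc_units = 4)
  fit <- train_model(NULL, streams,
                     train_config(learning_rate = 5e-3, batch_size = 16,
                                  max_epochs = 8, patience = 0, seed = 9),
                     loss_config("kl"), plan = resolve_transfer("FullN"),
                     network_config = net)
  # patience 0: stops right after the first non-improving epoch
  expect_lte(nrow(fit$history), 8)
  expect_equal(fit$best_val_f1, max(fit$history$val_f1))
  expect_equal(fit$history$val_f1[fit$best_epoch], fit$best_val_f1)
})

test_that("the learning-rate grid returns one row per rate and picks the best", {
  ex <- toy_examples(30, 1, seed = 40)
  streams <- list(train = slice_examples(ex, 1:22),
                  val = slice_examples(ex, 23:30))
  net <- network_config(conv_block_1 = list(n_filters = 3, filter_len = 5,
                                            pool_len = 2),
                        conv_block_2 = list(n_filters = 2, filter_len = 3,
                                            pool_len = 2),
                        seq_fc_units = 4, gru_hidden_units = 3,
                        joint_fc_units = c(5, 4), head_fc_units = 3)
  cfg <- train_config(lr_grid = c(1e-2, 1e-3), batch_size = 15,
                      max_epochs = 2, patience = 3, seed = 2)
  gs <- grid_search_lr(NULL, streams, cfg, loss_config("kl"),
                       plan = resolve_transfer("FullN"),
                       network_config = net)
  expect_equal(nrow(gs$table), 2)
  expect_equal(sort(gs$table$learning_rate), c(1e-3, 1e-2))
  expect_equal(gs$fit$best_val_f1, max(gs$table$val_f1))
  # a grid of one is plain training
  cfg1 <- train_config(lr_grid = 1e-2, learning_rate = 1e-2,
                       batch_size = 15, max_epochs = 2, patience = 3,
                       seed = 2)
  gs1 <- grid_search_lr(NULL, streams, cfg1, loss_config("kl"),
                        plan = resolve_transfer("FullN"),
                        network_config = net)
  ref <- train_model(NULL, streams, cfg1, loss_config("kl"),
                     plan = resolve_transfer("FullN"), network_config = net)
  expect_identical(gs1$fit$model$params, ref$model$params)
})

test_that("tidy and glance expose the training history and summary", {
  ex <- toy_examples(20, 1, seed = 50)
  streams <- list(train = slice_examples(ex, 1:15),
                  val = slice_examples(ex, 16:20))
  net <- network_config(conv_block_1 = list(n_filters = 3, filter_len = 5,
                                            pool_len = 2),
                        conv_block_2 = list(n_filters = 2, filter_len = 3,
                                            pool_len = 2),
                        seq_fc_units = 4, gru_hidden_units = 3,
                        joint_fc_units = c(5, 4), head_fc_units = 3)
  fit <- train_model(NULL, streams,
                     train_config(batch_size = 15, max_epochs = 2,
                                  patience = 3, seed = 1),
                     loss_config("kl"), plan = resolve_transfer("FullN"),
                     network_config = net)
  expect_equal(names(tidy(fit)), c("epoch", "train_loss", "val_f1"))
  g <- glance(fit)
  expect_equal(g$setting, "FullN")
  expect_equal(g$loss, "kl")
  expect_s3_class(autoplot(fit), "ggplot")
})
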