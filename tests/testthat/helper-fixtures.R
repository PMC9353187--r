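# Shared fixtures, all generated in code. The desk-scale benchmark used
# by the slower tests is memoized per seed so several tests can share one
# build.

# 5 CpG sites at positions 2, 7, 12, 17, 22
toy_genome <- function() genome_index(c("1" = "ACGTTACGTTACGTTACGTTACGTT"))

random_genome <- function(len, seed, n_chroms = 1, gc = 0.4) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chroms), function(i)
    paste0(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
  names(seqs) <- as.character(seq_len(n_chroms))
  genome_index(seqs)
}

# Two replicate Bismark-coverage files over toy_genome(), 10 calls each,
# engineered so that after merging: site 2 is kept methylated (17/20),
# site 7 kept unmethylated (1/18), site 12 is hemi-methylated, site 17
# loses its minus strand to the depth filter (single-strand), site 22 is
# kept with pooled level 9/20 and both strands exactly at/below 0.5.
toy_call_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  row <- function(pos, meth, unmeth)
    sprintf("1\t%d\t%d\t%.4f\t%d\t%d", pos, pos,
            100 * meth / (meth + unmeth), meth, unmeth)
  rep1 <- c(row(2, 4, 1), row(3, 5, 0), row(7, 1, 4), row(8, 0, 4),
            row(12, 5, 0), row(13, 0, 4), row(17, 3, 2), row(18, 1, 1),
            row(22, 2, 3), row(23, 2, 3))
  rep2 <- c(row(2, 4, 1), row(3, 4, 1), row(7, 0, 5), row(8, 0, 4),
            row(12, 4, 1), row(13, 1, 4), row(17, 3, 2), row(18, 1, 0),
            row(22, 3, 2), row(23, 2, 3))
  f1 <- file.path(dir, "rep1.cov"); writeLines(rep1, f1)
  f2 <- file.path(dir, "rep2.cov"); writeLines(rep2, f2)
  c(f1, f2)
}

# Scaled-down network used by every training test.
small_net <- function() {
  network_config(conv_block_1 = list(n_filters = 16, filter_len = 11,
                                     pool_len = 2),
                 conv_block_2 = list(n_filters = 8, filter_len = 3,
                                     pool_len = 2),
                 seq_fc_units = 24, gru_hidden_units = 24,
                 joint_fc_units = c(32, 16), head_fc_units = 16)
}

desk_window <- 61
desk_k <- 15
desk_dist_scale <- 3000

# Memoized desk-scale benchmark: genome, cleaned profiles, encoded
# source/target example splits.
.bench_cache <- new.env(parent = emptyenv())
desk_benchmark <- function(seed = 7) {
  key <- as.character(seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  bm <- make_benchmark(sim_config(seed = seed))
  profiles <- lapply(bm$calls, function(cl) clean_calls(cl, bm$gidx)$profile)
  plan <- split_plan("1", "3", "2")
  src <- profiles[bm$roles == "source"]
  tgt <- profiles[bm$roles == "target"]
  out <- list(
    bm = bm, profiles = profiles, plan = plan, src = src, tgt = tgt,
    src_streams = split_examples(
      build_examples(src, bm$gidx, "covered", window_len = desk_window,
                     k_per_side = desk_k, dist_scale = desk_dist_scale),
      plan),
    tgt_streams = split_examples(
      build_examples(tgt, bm$gidx, "covered", window_len = desk_window,
                     k_per_side = desk_k, dist_scale = desk_dist_scale),
      plan))
  .bench_cache[[key]] <- out
  out
}

# Random encoded-example batch for pure network tests (no genome needed).
toy_examples <- function(n, m, window_len = 21, nbr_len = 12, seed = 1,
                         chrom = "1") {
  set.seed(seed)
  structure(list(
    seq = array(stats::rbinom(n * window_len * 4, 1, 0.25),
                c(n, window_len, 4)),
    nbr = array(stats::runif(n * m * nbr_len), c(n, m, nbr_len)),
    nbr_mask = array(TRUE, c(n, m, nbr_len / 2)),
    labels = matrix(stats::runif(n * m), n, m,
                    dimnames = list(NULL, paste0("p", seq_len(m)))),
    label_mask = matrix(TRUE, n, m),
    chrom = rep_len(chrom, n), pos = seq_len(n),
    profile_ids = paste0("p", seq_len(m)),
    window_len = window_len, k_per_side = nbr_len / 4,
    dist_scale = 1000), class = "encoded_examples")
}
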