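# The generator: determinism, motif manifests, the methylation model's
# moments, observation sampling, and benchmark packaging.

test_that("genome simulation is seed-deterministic with an exact motif manifest", {
  cfg <- sim_config(n_chroms = 2, chrom_len = 5000, seed = 5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$gidx$seqs, g2$gidx$seqs)
  expect_identical(g1$motifs, g2$motifs)
  # every manifest entry is an actual motif occurrence
  for (i in seq_len(nrow(g1$motifs))) {
    ch <- g1$motifs$chrom[i]; p <- g1$motifs$pos[i]
    expect_equal(substr(g1$gidx$seqs[[ch]], p, p + nchar(cfg$motif) - 1),
                 cfg$motif)
  }
  # no C at all means no CpG sites
  g0 <- simulate_genome(sim_config(n_chroms = 1, chrom_len = 2000,
                                   gc_content = 0, motifs_per_kb = 0,
                                   seed = 2))
  expect_equal(nrow(cpg_sites(g0$gidx)), 0)
})

test_that("a degenerate methylation model collapses to the baseline logistic", {
  cfg <- sim_config(n_chroms = 1, chrom_len = 5000, effect_size = 0,
                    field_sd = 0, intermediate_fraction = 0,
                    baseline_logit = 1.3, seed = 6)
  g <- simulate_genome(cfg)
  tr <- simulate_true_methylome(g$gidx, cfg, g$motifs, profile_seed = 1)
  expect_true(all(abs(tr$level - plogis(1.3)) < 1e-12))
})

test_that("sites near planted motifs shift by about the configured effect", {
  cfg <- sim_config(n_chroms = 1, chrom_len = 60000, field_sd = 0.5,
                    intermediate_fraction = 0, seed = 8)
  g <- simulate_genome(cfg)
  tr <- simulate_true_methylome(g$gidx, cfg, g$motifs, profile_seed = 2)
  nm <- asNamespace("methtransfer")$near_motif(
    tr$chrom, tr$pos, g$motifs, nchar(cfg$motif), cfg$motif_radius)
  # analytic gap: logistic(baseline) vs logistic(baseline + effect)
  exp_gap <- plogis(cfg$baseline_logit) -
    plogis(cfg$baseline_logit + cfg$effect_size)
  got_gap <- mean(tr$level[!nm]) - mean(tr$level[nm])
  expect_gt(sum(nm), 200)
  expect_equal(got_gap, exp_gap, tolerance = 0.12)
})

test_that("the spatial field decays at about the configured correlation length", {
  cfg <- sim_config(n_chroms = 1, chrom_len = 60000, effect_size = 0,
                    motifs_per_kb = 0, field_sd = 1.5,
                    spatial_corr_length = 2000,
                    intermediate_fraction = 0, baseline_logit = 0, seed = 9)
  g <- simulate_genome(cfg)
  tr <- simulate_true_methylome(g$gidx, cfg, g$motifs, profile_seed = 3)
  lgt <- qlogis(pmin(pmax(tr$level, 1e-9), 1 - 1e-9))
  # empirical correlogram at two genomic lags: pick index offsets whose
  # mean physical distance is ~500 bp and ~4000 bp
  mean_gap <- mean(diff(tr$pos))
  k1 <- max(1, round(500 / mean_gap))
  k2 <- round(4000 / mean_gap)
  n <- length(lgt)
  r_short <- cor(lgt[1:(n - k1)], lgt[(k1 + 1):n])
  r_long <- cor(lgt[1:(n - k2)], lgt[(k2 + 1):n])
  expect_gt(r_short, exp(-500 / 2000) - 0.15)
  expect_lt(r_long, exp(-4000 / 2000) + 0.25)
  expect_gt(r_short, r_long)
})

test_that("intermediate squashing keeps the stated fraction inside (0.2, 0.8)", {
  cfg <- sim_config(n_chroms = 1, chrom_len = 60000,
                    intermediate_fraction = 0.4, seed = 10)
  g <- simulate_genome(cfg)
  tr <- simulate_true_methylome(g$gidx, cfg, g$motifs, profile_seed = 4)
  frac_mid <- mean(tr$level > 0.2 & tr$level < 0.8)
  expect_gt(frac_mid, 0.35)  # squashed sites land in (0.2, 0.8) by design
})

test_that("observation sampling honors coverage, depth and high-depth consistency", {
  cfg <- sim_config(n_chroms = 1, chrom_len = 60000, mean_depth = 60,
                    hemi_error_rate = 0, intermediate_fraction = 0,
                    seed = 11)
  g <- simulate_genome(cfg)
  tr <- simulate_true_methylome(g$gidx, cfg, g$motifs, profile_seed = 5)
  calls <- simulate_observed_calls(tr, cfg, profile_seed = 6, coverage = 0.3)
  n_sites <- nrow(calls) / 2
  expect_equal(n_sites / nrow(tr), 0.3, tolerance = 0.05)
  expect_true(all(calls$total_reads >= 1))
  # at depth >= 50 the observed level tracks the true level closely
  plus <- calls[calls$strand == "+", ]
  truth_at <- tr$level[match(plus$pos, tr$pos)]
  expect_equal(mean(plus$meth_reads / plus$total_reads), mean(truth_at),
               tolerance = 0.02)
  expect_equal(nrow(simulate_observed_calls(tr, cfg, 7, coverage = 0)), 0)
})

test_that("planted hemi-methylation is removed by cleaning at about its rate", {
  # extreme levels and deep reads so binarized discordance detects
  # essentially every planted error and nothing else
  cfg <- sim_config(n_chroms = 1, chrom_len = 60000, mean_depth = 40,
                    field_sd = 1, baseline_logit = 3, effect_size = 0,
                    motifs_per_kb = 0, intermediate_fraction = 0,
                    hemi_error_rate = 0.1, seed = 12)
  g <- simulate_genome(cfg)
  tr <- simulate_true_methylome(g$gidx, cfg, g$motifs, profile_seed = 8)
  calls <- simulate_observed_calls(tr, cfg, profile_seed = 9, coverage = 0.5)
  res <- merge_strands(calls, g$gidx)
  n_both <- res$report$n_hemi_methylated + res$report$n_sites_kept
  frac_hemi <- res$report$n_hemi_methylated / n_both
  # planted 10%; binomial error around the injected rate
  expect_lt(abs(frac_hemi - 0.1), 3 * sqrt(0.1 * 0.9 / n_both) + 0.01)
})

test_that("benchmarks regenerate identically and honor per-role coverage", {
  cfg <- sim_config(seed = 31)
  b1 <- make_benchmark(cfg)
  b2 <- make_benchmark(cfg)
  expect_identical(b1$calls, b2$calls)
  expect_identical(b1$truth, b2$truth)
  expect_equal(length(b1$calls), cfg$n_source + cfg$n_target)
  n_cpg <- nrow(cpg_sites(b1$gidx))
  for (id in names(b1$calls)) {
    rate <- nrow(b1$calls[[id]]) / 2 / n_cpg
    target_rate <- if (b1$roles[id] == "source") cfg$coverage_source else
      cfg$coverage_target
    se <- sqrt(target_rate * (1 - target_rate) / n_cpg)
    expect_lt(abs(rate - target_rate), 4 * se + 1e-4)
  }
})

test_that("benchmark files round-trip through the standard parsers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_chroms = 1, chrom_len = 8000, n_source = 1,
                    n_target = 1, seed = 41)
  bm <- make_benchmark(cfg, dir = dir)
  gi <- genome_index(bm$paths$genome)
  expect_identical(gi$seqs, bm$gidx$seqs)
  calls <- read_calls(bm$paths$src1, "bismark_cov")
  expect_equal(nrow(calls), nrow(bm$calls$src1))
  expect_equal(sum(calls$meth_reads), sum(bm$calls$src1$meth_reads))
  expect_true(file.exists(bm$paths$tss))
  expect_true(file.exists(bm$paths$cgi))
  cgi <- read_cgi_bed(bm$paths$cgi)
  expect_gt(nrow(cgi), 0)
  truth <- readr::read_tsv(bm$paths$tgt1_truth, show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(cpg_sites(gi)))
})
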