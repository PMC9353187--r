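# Synthetic multi-profile methylomes with the statistical structure the
# predictor assumes: methylation driven by a planted sequence motif
# (shared across profiles, the transferable sequence determinant), a
# smooth profile-specific spatial field (neighbor autocorrelation),
# binomial read sampling at controllable depth, per-profile sparsity, and
# occasional hemi-methylated sites planted as profiling errors. Dense
# "source" and sparse "target" profiles emulate somatic-tissue vs
# oocyte/embryo coverage regimes.

#' Simulation configuration
#'
#' @param n_chroms,chrom_len,gc_content Genome shape. Chromosomes are
#'   named `"1" ... "n_chroms"` so the default [split_plan()] applies.
#' @param motif Planted motif whose proximity shifts methylation odds.
#' @param motifs_per_kb Planted motif density.
#' @param motif_radius A CpG within this many bp of a planted motif feels
#'   its effect.
#' @param effect_size Logit shift near motifs (negative values emulate
#'   CpG-island-like hypomethylation).
#' @param baseline_logit Background methylation logit.
#' @param spatial_corr_length Correlation length (bp) of the smooth
#'   per-profile methylation field.
#' @param field_sd Standard deviation of that field on the logit scale.
#' @param intermediate_fraction Fraction of sites squashed toward 0.5
#'   (into `(0.2, 0.8)`), emulating widespread intermediate methylation.
#' @param mean_depth Mean per-strand read depth (shifted Poisson, >= 1).
#' @param coverage_source,coverage_target Per-CpG observation probability
#'   for dense source and sparse target profiles.
#' @param hemi_error_rate Probability a covered site is planted as
#'   hemi-methylated (one strand's level complemented before sampling).
#' @param n_source,n_target Number of profiles of each role.
#' @param seed Master seed; every stream of randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 3, chrom_len = 70000, gc_content = 0.4,
                       motif = "TACGCGTA", motifs_per_kb = 2,
                       motif_radius = 30,
                       effect_size = -6, baseline_logit = 2,
                       spatial_corr_length = 2000, field_sd = 2,
                       intermediate_fraction = 0.3,
                       mean_depth = 20,
                       coverage_source = 0.35, coverage_target = 0.01,
                       hemi_error_rate = 0.02,
                       n_source = 3, n_target = 2, seed = 1) {
  cfg <- as.list(environment())
  rates <- c(gc_content, intermediate_fraction, coverage_source,
             coverage_target, hemi_error_rate)
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  assert_that(mean_depth >= 1, "`mean_depth` must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with planted motifs
#'
#' Random sequence at the configured GC content, with motif instances
#' planted at recorded positions.
#'
#' @param config A [sim_config()].
#' @return List with `gidx` (a [genome_index()]) and `motifs` (tibble
#'   `chrom`, `pos` of planted instances).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  mlen <- nchar(config$motif)
  seqs <- character(config$n_chroms)
  manifest <- list()
  for (i in seq_len(config$n_chroms)) {
    s <- paste0(sample(names(p), config$chrom_len, replace = TRUE,
                       prob = p), collapse = "")
    n_mot <- round(config$motifs_per_kb * config$chrom_len / 1000)
    if (n_mot > 0 && config$chrom_len > mlen) {
      at <- sort(sample.int(config$chrom_len - mlen, n_mot))
      # drop overlapping placements so the manifest is exact
      keep <- c(TRUE, diff(at) >= mlen)
      at <- at[keep]
      for (a in at) substr(s, a, a + mlen - 1L) <- config$motif
      manifest[[i]] <- tibble::tibble(chrom = as.character(i), pos = at)
    }
    seqs[i] <- s
  }
  names(seqs) <- as.character(seq_len(config$n_chroms))
  empty <- tibble::tibble(chrom = character(), pos = integer())
  list(gidx = genome_index(seqs),
       motifs = dplyr::bind_rows(c(list(empty), manifest)))
}

# TRUE for sites within `radius` bp of any planted motif instance.
near_motif <- function(chrom, pos, motifs, motif_len, radius) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    mp <- sort(motifs$pos[motifs$chrom == ch])
    if (!length(mp)) next
    lo <- findInterval(pos[idx], mp)                  # motif start <= pos
    d_left <- ifelse(lo >= 1, pos[idx] - (mp[pmax(lo, 1)] + motif_len - 1L),
                     Inf)
    hi <- lo + 1L
    d_right <- ifelse(hi <= length(mp), mp[pmin(hi, length(mp))] - pos[idx],
                      Inf)
    out[idx] <- pmin(pmax(d_left, 0), pmax(d_right, 0)) <= radius
  }
  out
}

#' Simulate true per-CpG methylation levels for one profile
#'
#' `level = logistic(baseline_logit + effect_size * motif_near +
#' spatial field)`, where the field is a profile-specific
#' Ornstein-Uhlenbeck process over CpG positions with the configured
#' correlation length; a configured fraction of sites is then squashed
#' into `(0.2, 0.8)` (intermediate methylation). The motif component is a
#' pure function of the genome, so all profiles share the sequence
#' determinants while carrying independent local patterns.
#'
#' @param gidx A [genome_index()].
#' @param config A [sim_config()].
#' @param motifs Motif manifest from [simulate_genome()].
#' @param profile_seed Seed for this profile's field and squash set.
#' @return Tibble `chrom`, `pos`, `level`.
#' @export
simulate_true_methylome <- function(gidx, config, motifs, profile_seed) {
  set.seed(profile_seed)
  sites <- cpg_sites(gidx)
  nm <- near_motif(sites$chrom, sites$pos, motifs, nchar(config$motif),
                   config$motif_radius)
  field <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    n <- length(idx)
    f <- numeric(n)
    f[1] <- stats::rnorm(1, 0, config$field_sd)
    if (n > 1) {
      d <- diff(sites$pos[idx])
      rho <- exp(-d / config$spatial_corr_length)
      innov <- stats::rnorm(n - 1, 0, config$field_sd) *
        sqrt(1 - rho^2)
      for (i in 2:n) f[i] <- rho[i - 1] * f[i - 1] + innov[i - 1]
    }
    field[idx] <- f
  }
  level <- stats::plogis(config$baseline_logit +
                           config$effect_size * nm + field)
  squash <- stats::runif(length(level)) < config$intermediate_fraction
  level[squash] <- 0.5 + (level[squash] - 0.5) * 0.6
  tibble::tibble(chrom = sites$chrom, pos = sites$pos, level = level)
}

#' Simulate observed methylation calls for one profile
#'
#' Each CpG is covered independently with the role's coverage
#' probability; each covered strand draws a shifted-Poisson read depth
#' (always >= 1) and a binomial methylated-read count at the site's true
#' level. With probability `hemi_error_rate` one strand's level is
#' complemented before sampling, planting a hemi-methylated artifact.
#' Minus-strand calls are reported at the G position (`pos + 1`).
#'
#' @param truth Tibble from [simulate_true_methylome()].
#' @param config A [sim_config()].
#' @param profile_seed Seed for this profile's sampling.
#' @param coverage Per-CpG observation probability (e.g.
#'   `config$coverage_source`).
#' @return Call tibble (`chrom`, `pos`, `strand`, `meth_reads`,
#'   `total_reads`).
#' @export
simulate_observed_calls <- function(truth, config, profile_seed, coverage) {
  set.seed(profile_seed)
  covered <- stats::runif(nrow(truth)) < coverage
  t <- truth[covered, ]
  n <- nrow(t)
  if (n == 0)
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character(), meth_reads = integer(),
                          total_reads = integer()))
  hemi <- stats::runif(n) < config$hemi_error_rate
  flip_minus <- stats::runif(n) < 0.5     # which strand carries the error
  lev_plus <- ifelse(hemi & !flip_minus, 1 - t$level, t$level)
  lev_minus <- ifelse(hemi & flip_minus, 1 - t$level, t$level)
  depth_plus <- 1L + stats::rpois(n, config$mean_depth - 1)
  depth_minus <- 1L + stats::rpois(n, config$mean_depth - 1)
  tibble::tibble(
    chrom = rep(t$chrom, 2L),
    pos = c(t$pos, t$pos + 1L),
    strand = rep(c("+", "-"), each = n),
    meth_reads = c(stats::rbinom(n, depth_plus, lev_plus),
                   stats::rbinom(n, depth_minus, lev_minus)),
    total_reads = c(depth_plus, depth_minus))
}

#' Generate a complete source/target benchmark
#'
#' Packages a genome, dense source profiles, sparse target profiles, and
#' the held-out truth that scores imputation at masked target sites.
#' Regeneration with the same configuration is identical. With `dir` set,
#' standard files are written (FASTA genome, Bismark-coverage call files,
#' truth/TSS tables and a CGI-like BED around planted motif clusters) so
#' the real pipeline consumes them unchanged.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `gidx`, `motifs`, `calls` (named list of call
#'   tibbles, sources first), `truth` (named list of true-level tibbles),
#'   `roles` (named vector `"source"`/`"target"`), and, when `dir` is
#'   set, `paths`.
#' @export
make_benchmark <- function(config = sim_config(), dir = NULL) {
  g <- simulate_genome(config)
  ids <- c(paste0("src", seq_len(config$n_source)),
           paste0("tgt", seq_len(config$n_target)))
  roles <- stats::setNames(rep(c("source", "target"),
                               c(config$n_source, config$n_target)), ids)
  truth <- list()
  calls <- list()
  for (k in seq_along(ids)) {
    pseed <- config$seed + 1000L * k
    truth[[ids[k]]] <- simulate_true_methylome(g$gidx, config, g$motifs,
                                               pseed)
    cov <- if (roles[k] == "source") config$coverage_source else
      config$coverage_target
    calls[[ids[k]]] <- simulate_observed_calls(truth[[ids[k]]], config,
                                               pseed + 1L, cov)
  }
  out <- list(gidx = g$gidx, motifs = g$motifs, calls = calls,
              truth = truth, roles = roles, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "genome.fa")
    writeLines(unlist(lapply(names(g$gidx$seqs), function(ch)
      c(paste0(">", ch), g$gidx$seqs[[ch]]))), fasta)
    paths <- list(genome = fasta)
    for (id in ids) {
      f <- file.path(dir, paste0(id, ".cov"))
      cl <- calls[[id]]
      pct <- ifelse(cl$total_reads > 0,
                    100 * cl$meth_reads / cl$total_reads, 0)
      readr::write_tsv(tibble::tibble(chrom = cl$chrom, start = cl$pos,
                                      end = cl$pos, pct = pct,
                                      meth = cl$meth_reads,
                                      unmeth = cl$total_reads - cl$meth_reads),
                       f, col_names = FALSE, progress = FALSE)
      paths[[id]] <- f
    }
    for (id in ids[roles == "target"]) {
      f <- file.path(dir, paste0(id, "_truth.tsv"))
      readr::write_tsv(truth[[id]], f, progress = FALSE)
      paths[[paste0(id, "_truth")]] <- f
    }
    set.seed(config$seed + 99L)
    tss <- dplyr::bind_rows(lapply(names(g$gidx$seqs), function(ch)
      tibble::tibble(gene_id = paste0("g", ch, "_", 1:10), chrom = ch,
                     pos = sort(sample.int(g$gidx$lengths[[ch]], 10)),
                     strand = sample(c("+", "-"), 10, replace = TRUE))))
    readr::write_tsv(tss, file.path(dir, "tss.tsv"), progress = FALSE)
    paths$tss <- file.path(dir, "tss.tsv")
    cgi <- dplyr::mutate(g$motifs,
                         start = pmax(0L, .data$pos - 1L - 100L),
                         end = .data$pos + nchar(config$motif) + 100L)
    readr::write_tsv(cgi[, c("chrom", "start", "end")],
                     file.path(dir, "cgi.bed"), col_names = FALSE,
                     progress = FALSE)
    paths$cgi <- file.path(dir, "cgi.bed")
    out$paths <- paths
  }
  out
}
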