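# Cleaning rules for raw methylation calls: read-depth filter, strand
# inference, exclusion of single-strand and hemi-methylated CpG sites,
# and per-profile summary rates.

#' Filter calls by read depth
#'
#' Removes calls with limited read support. The default keeps calls backed
#' by at least four overlapping reads, i.e. excludes those with a read
#' count no greater than three. The filter is applied per strand, before
#' strand merging.
#'
#' @param calls Call tibble (see [read_calls()]).
#' @param min_reads Minimum `total_reads` to keep (default 4).
#' @return Filtered call tibble.
#' @export
filter_low_depth <- function(calls, min_reads = 4) {
  assert_that(min_reads >= 1, "`min_reads` must be >= 1")
  dplyr::filter(calls, .data$total_reads >= min_reads)
}

#' Merge strand calls into per-CpG-site records
#'
#' Methylation at a CpG is expected symmetric across strands, so each site
#' is kept only when both strand calls survive the depth filter and their
#' binarized states agree; hemi-methylated sites (discordant binarized
#' strands) and single-strand sites are excluded as profiling artifacts.
#' The kept level pools read counts across strands:
#' `(meth+ + meth-) / (total+ + total-)`.
#'
#' Calls with unknown strand (e.g. from Bismark coverage files) are first
#' assigned by the genome: a call at the `C` of a CpG is `+`, one at the
#' following `G` is `-`; calls at positions belonging to no CpG site are
#' counted and dropped with a warning.
#'
#' @param calls Depth-filtered call tibble.
#' @param gidx A [genome_index()].
#' @param binarize_threshold Per-strand binarization cutoff; a strand with
#'   level strictly above it is called methylated (default 0.5).
#' @return A list with `profile` (tibble `chrom`, `pos`, `level`,
#'   `total_reads`, one row per kept CpG site) and `report` (a one-row
#'   [cleaning_report] tibble; `coverage_rate` and `methylation_rate` are
#'   filled in).
#' @export
merge_strands <- function(calls, gidx, binarize_threshold = 0.5) {
  calls <- assign_strand(calls, gidx)
  n_not_cpg <- sum(is.na(calls$site))
  if (n_not_cpg > 0)
    rlang::warn(paste0(n_not_cpg,
                       " call(s) at positions that are not part of any CpG",
                       " site were dropped"))
  calls <- calls[!is.na(calls$site), ]
  per_site <- calls |>
    dplyr::mutate(level = .data$meth_reads / .data$total_reads,
                  state = .data$level > binarize_threshold) |>
    dplyr::group_by(.data$chrom, site = .data$site) |>
    dplyr::summarise(n_strands = dplyr::n_distinct(.data$strand),
                     concordant = dplyr::n_distinct(.data$state) == 1,
                     meth_reads = sum(.data$meth_reads),
                     total_reads = sum(.data$total_reads),
                     .groups = "drop")
  n_single <- sum(per_site$n_strands < 2)
  both <- per_site[per_site$n_strands == 2, ]
  n_hemi <- sum(!both$concordant)
  kept <- both[both$concordant, ]
  profile <- tibble::tibble(chrom = kept$chrom,
                            pos = kept$site,
                            level = kept$meth_reads / kept$total_reads,
                            total_reads = kept$total_reads)
  profile <- profile[order_sites(profile$chrom, profile$pos), ]
  report <- tibble::tibble(
    n_input_calls = nrow(calls) + n_not_cpg,
    n_not_cpg = n_not_cpg,
    n_single_strand = n_single,
    n_hemi_methylated = n_hemi,
    n_sites_kept = nrow(profile),
    coverage_rate = if (nrow(cpg_sites(gidx)))
      nrow(profile) / nrow(cpg_sites(gidx)) else NA_real_,
    methylation_rate = if (nrow(profile))
      mean(profile$level > binarize_threshold) else NA_real_)
  list(profile = profile, report = report)
}

# Map each call to its CpG site (forward-strand C position); NA when the
# position belongs to no CpG site. Calls carrying an explicit strand are
# validated against the genome the same way.
assign_strand <- function(calls, gidx) {
  if (nrow(calls) == 0) return(dplyr::mutate(calls, site = integer()))
  base_at <- function(chrom, pos) {
    purrr::map2_chr(chrom, pos, function(ch, p) {
      s <- gidx$seqs[[ch]]
      if (is.null(s)) stop_mt(paste0("chromosome absent from genome: ", ch))
      if (p < 1 || p > nchar(s)) return("N")
      substr(s, p, p)
    })
  }
  b0 <- base_at(calls$chrom, calls$pos)
  b1 <- base_at(calls$chrom, calls$pos + 1L)
  bm <- base_at(calls$chrom, calls$pos - 1L)
  is_plus <- b0 == "C" & b1 == "G"
  is_minus <- b0 == "G" & bm == "C"
  strand <- ifelse(is_plus, "+", ifelse(is_minus, "-", NA_character_))
  known <- !is.na(calls$strand)
  if (any(known)) {
    clash <- known & !is.na(strand) & calls$strand != strand
    strand[clash] <- NA_character_
  }
  calls$strand <- strand
  calls$site <- ifelse(is.na(strand), NA_integer_,
                       ifelse(strand == "+", calls$pos, calls$pos - 1L))
  calls
}

#' Clean raw calls into a methylome profile
#'
#' The fixed cleaning pipeline: merge replicates, drop low-depth calls
#' (per strand), then merge strands while excluding single-strand and
#' hemi-methylated sites.
#'
#' @param call_sets A call tibble or list of replicate call tibbles.
#' @param gidx A [genome_index()].
#' @param min_reads Per-strand depth cutoff (default 4: keep
#'   `total_reads >= 4`).
#' @param binarize_threshold See [merge_strands()].
#' @return A list with `profile` and `report`; the report additionally
#'   records `n_removed_low_depth`.
#' @export
clean_calls <- function(call_sets, gidx, min_reads = 4,
                        binarize_threshold = 0.5) {
  merged <- merge_replicates(call_sets)
  deep <- filter_low_depth(merged, min_reads)
  res <- merge_strands(deep, gidx, binarize_threshold)
  res$report <- dplyr::mutate(res$report,
                              n_input_calls = nrow(merged),
                              n_removed_low_depth = nrow(merged) - nrow(deep),
                              .before = 1)
  res
}

#' Genome-wide CpG coverage rate of a profile
#'
#' The proportion of all CpG sites in the genome with a profiled
#' methylation state.
#'
#' @param profile Profile tibble.
#' @param gidx A [genome_index()].
#' @return A fraction in `[0, 1]`.
#' @export
coverage_rate <- function(profile, gidx) {
  total <- nrow(cpg_sites(gidx))
  assert_that(total > 0, "genome contains no CpG sites")
  nrow(profile) / total
}

#' Methylation rate of a profile
#'
#' The proportion of covered CpGs that are methylated, i.e. with level
#' strictly above the threshold; a level of exactly 0.5 counts as
#' unmethylated.
#'
#' @param profile Profile tibble.
#' @param threshold Binarization cutoff (default 0.5).
#' @return A fraction in `[0, 1]`.
#' @export
methylation_rate <- function(profile, threshold = 0.5) {
  assert_that(nrow(profile) > 0,
              "methylation rate is undefined for an empty profile")
  mean(profile$level > threshold)
}
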