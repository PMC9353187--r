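# Genomic-feature summaries: 300-bp genome bins, 1001-bp promoters
# centered on TSS, and CpG islands. A feature "has data" when it contains
# at least `min_cpgs_with_data` CpG sites with a known methylation state
# (at least 3 for bins, 10 for the longer promoters/CGIs); after
# imputation, "known" means observed plus retained imputed sites. A CpG
# is inside a feature when its forward-strand C position is.

#' Tile the genome into equal-sized bins
#'
#' Consecutive non-overlapping bins per chromosome; a trailing partial
#' bin is dropped so every bin has exactly `bin_len` bp. Bins never cross
#' chromosomes.
#'
#' @param gidx A [genome_index()].
#' @param bin_len Bin length in bp (default 300).
#' @return A `feature_set` tibble: `feature_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), with attributes `kind = "bin"` and
#'   `min_cpgs_with_data = 3`.
#' @export
tile_genome <- function(gidx, bin_len = 300) {
  rows <- purrr::map_dfr(names(gidx$seqs), function(ch) {
    n_bins <- gidx$lengths[[ch]] %/% bin_len
    if (n_bins == 0) return(NULL)
    start <- (seq_len(n_bins) - 1L) * bin_len + 1L
    tibble::tibble(chrom = ch, start = start,
                   end = start + bin_len - 1L)
  })
  new_feature_set(rows, kind = "bin", min_cpgs = 3L)
}

#' Promoter intervals from a TSS table
#'
#' 1001-bp regions centered at each annotated transcription start site,
#' clipped to chromosome bounds (clipped promoters are shorter and
#' flagged); duplicate TSS rows are deduplicated.
#'
#' @param tss Tibble with columns `chrom`, `pos` (TSS, 1-based) and
#'   optionally `strand`, `gene_id`.
#' @param gidx A [genome_index()].
#' @param half_width Bases on each side of the TSS (default 500, i.e.
#'   1001-bp promoters).
#' @return A `feature_set` tibble with `min_cpgs_with_data = 10` and a
#'   `clipped` flag.
#' @export
promoters_from_tss <- function(tss, gidx, half_width = 500) {
  tss <- dplyr::distinct(tss, .data$chrom, .data$pos, .keep_all = TRUE)
  len <- gidx$lengths[tss$chrom]
  start <- pmax(1L, tss$pos - as.integer(half_width))
  end <- pmin(as.integer(len), tss$pos + as.integer(half_width))
  rows <- tibble::tibble(chrom = tss$chrom, start = start, end = end,
                         clipped = (end - start + 1L) < 2L * half_width + 1L)
  new_feature_set(rows, kind = "promoter", min_cpgs = 10L)
}

#' Read CpG-island intervals from BED
#'
#' BED is 0-based half-open (the UCSC dialect) and is converted to the
#' internal 1-based inclusive convention on read.
#'
#' @param path BED file (first three columns used).
#' @return A `feature_set` tibble with `min_cpgs_with_data = 10`.
#' @export
read_cgi_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  rows <- tibble::tibble(chrom = bed[[1]],
                         start = as.integer(bed[[2]]) + 1L,
                         end = as.integer(bed[[3]]))
  new_feature_set(rows, kind = "cgi", min_cpgs = 10L)
}

new_feature_set <- function(rows, kind, min_cpgs) {
  rows <- rows[order_sites(rows$chrom, rows$start), ]
  out <- tibble::tibble(feature_id = if (nrow(rows))
    paste0(kind, "_", seq_len(nrow(rows))) else character(), rows)
  attr(out, "kind") <- kind
  attr(out, "min_cpgs_with_data") <- min_cpgs
  class(out) <- c("feature_set", class(out))
  out
}

# Per-feature count and mean level of profile CpGs inside each interval.
feature_stats <- function(profile, features) {
  n_cpgs <- integer(nrow(features))
  mean_level <- rep(NA_real_, nrow(features))
  for (ch in unique(features$chrom)) {
    fidx <- which(features$chrom == ch)
    sites <- profile[profile$chrom == ch, ]
    if (nrow(sites) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = sites$pos, width = 1L),
      IRanges::IRanges(start = features$start[fidx],
                       end = features$end[fidx]))
    if (length(hits) == 0) next
    f <- S4Vectors::subjectHits(hits)
    s <- S4Vectors::queryHits(hits)
    cnt <- tapply(sites$level[s], f, length)
    mn <- tapply(sites$level[s], f, mean)
    at <- fidx[as.integer(names(cnt))]
    n_cpgs[at] <- as.integer(cnt)
    mean_level[at] <- as.numeric(mn)
  }
  tibble::tibble(feature_id = features$feature_id, n_cpgs = n_cpgs,
                 mean_level = mean_level)
}

#' Feature coverage of a profile
#'
#' Flags each feature as having data when it contains at least the
#' feature set's `min_cpgs_with_data` CpG sites with known state, and
#' reports the fraction of features with data.
#'
#' @param profile Observed or imputed profile tibble (any tibble with
#'   `chrom`, `pos`, `level`).
#' @param features A `feature_set`.
#' @return List with `fraction` (features with data / total) and
#'   `features` (the feature tibble plus `n_cpgs`, `has_data`).
#' @export
feature_coverage <- function(profile, features) {
  st <- feature_stats(profile, features)
  min_cpgs <- attr(features, "min_cpgs_with_data")
  out <- dplyr::mutate(dplyr::bind_cols(
    features, st[, c("n_cpgs", "mean_level")]),
    has_data = .data$n_cpgs >= min_cpgs)
  list(fraction = mean(out$has_data), features = out)
}

#' Per-feature methylation matrix across profiles
#'
#' Mean CpG methylation level per feature and profile, restricted to
#' features that have data (per the feature set's rule) in every profile.
#'
#' @param profiles Named list of (observed or imputed) profile tibbles.
#' @param features A `feature_set`.
#' @return Tibble: `feature_id`, `chrom`, `start`, `end`, then one column
#'   of mean levels per profile. Zero complete rows is an error.
#' @export
feature_methylation_matrix <- function(profiles, features) {
  assert_that(length(profiles) >= 2 && !is.null(names(profiles)),
              "need at least two named profiles")
  min_cpgs <- attr(features, "min_cpgs_with_data")
  cols <- lapply(profiles, function(p) feature_stats(p, features))
  complete <- Reduce(`&`, lapply(cols, function(s) s$n_cpgs >= min_cpgs))
  if (!any(complete))
    stop_mt(paste0("no feature has data in every profile; impute more",
                   " sites or use a sparser feature set"))
  out <- features[complete, c("feature_id", "chrom", "start", "end")]
  for (id in names(profiles)) out[[id]] <- cols[[id]]$mean_level[complete]
  if (sum(complete) == 1)
    rlang::warn("only one complete feature; correlations are undefined")
  out
}

#' Pairwise Pearson correlation between profiles
#'
#' @param mat A [feature_methylation_matrix()] result.
#' @return Symmetric correlation matrix (diagonal 1), profiles as rows
#'   and columns.
#' @export
profile_correlations <- function(mat) {
  value_cols <- setdiff(names(mat), c("feature_id", "chrom", "start", "end"))
  assert_that(nrow(mat) >= 2,
              "need at least two complete features for correlations")
  stats::cor(as.matrix(mat[, value_cols]), method = "pearson")
}
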