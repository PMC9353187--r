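# Reading/writing methylation call files, reference genomes, and the
# internal profile format. All in-memory coordinates are 1-based inclusive;
# bedGraph inputs (0-based half-open) are converted on read.

#' Load a reference genome and index its CpG sites
#'
#' Reads a FASTA file (plain or gzipped) and enumerates every CpG site:
#' a position `p` on the forward strand with `C` at `p` and `G` at `p + 1`.
#' Positions overlapping an ambiguity code (`N`) are never CpG sites.
#'
#' @param fasta Path to a FASTA file, or a named character vector /
#'   `Biostrings::DNAStringSet` of chromosome sequences.
#' @return A `genome_index` object: chromosome sequences, lengths, and a
#'   tibble of all CpG-site positions.
#' @examples
#' gi <- genome_index(c(chr1 = "ACGTCG"))
#' cpg_sites(gi) # positions 2 and 5
#' @export
genome_index <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  } else if (methods::is(fasta, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(fasta), names(fasta))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    seqs <- toupper(fasta)
  } else {
    stop_mt("`fasta` must be a file path or a named set of sequences")
  }
  assert_that(!anyNA(names(seqs)) && !any(names(seqs) == ""),
              "all chromosomes must be named")
  cpg <- purrr::map2_dfr(names(seqs), seqs, function(chrom, s) {
    hits <- Biostrings::matchPattern("CG", Biostrings::DNAString(s),
                                     fixed = TRUE)
    tibble::tibble(chrom = chrom, pos = BiocGenerics::start(hits))
  })
  if (nrow(cpg)) cpg <- cpg[order_sites(cpg$chrom, cpg$pos), ]
  structure(list(seqs = seqs,
                 lengths = vapply(seqs, nchar, integer(1)),
                 cpg = cpg),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", length(x$seqs), " chromosome(s), ",
      sum(x$lengths), " bp, ", nrow(x$cpg), " CpG sites\n", sep = "")
  invisible(x)
}

#' Enumerate all CpG sites of a genome
#'
#' @param gidx A [genome_index()].
#' @param chroms Optional subset of chromosome names.
#' @return Tibble with columns `chrom`, `pos` (1-based forward-strand C),
#'   sorted by chromosome then position.
#' @export
cpg_sites <- function(gidx, chroms = NULL) {
  assert_that(inherits(gidx, "genome_index"), "`gidx` must be a genome_index")
  out <- gidx$cpg
  if (!is.null(chroms)) {
    missing <- setdiff(chroms, names(gidx$seqs))
    if (length(missing))
      stop_mt(paste0("chromosome(s) absent from genome: ",
                     paste(missing, collapse = ", ")))
    out <- dplyr::filter(out, .data$chrom %in% chroms)
  }
  out
}

#' Read a per-CpG methylation call file
#'
#' Supports two dialects:
#' * `bismark_cov`: `chrom start end pct_meth count_meth count_unmeth`,
#'   1-based with `start == end == position`; strand is unknown and is
#'   inferred later from the genome (see [merge_strands()]).
#' * `bedgraph_counts`: `chrom start end count_meth count_total strand`,
#'   0-based half-open; converted to 1-based on read.
#'
#' Fields may be separated by tabs or spaces; gzipped files are handled
#' transparently. Rows with `count_meth > count_total` are a hard parse
#' error naming the offending line.
#'
#' @param path File path.
#' @param dialect `"bismark_cov"` (default) or `"bedgraph_counts"`.
#' @return Tibble of calls: `chrom`, `pos`, `strand` (`"+"`, `"-"` or `NA`),
#'   `meth_reads`, `total_reads`.
#' @export
read_calls <- function(path, dialect = c("bismark_cov", "bedgraph_counts")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- readr::read_table(path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0) {
    rlang::warn(paste0("empty call file: ", path))
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character(), meth_reads = integer(),
                          total_reads = integer()))
  }
  ncol_need <- if (dialect == "bismark_cov") 6L else 6L
  if (ncol(raw) < ncol_need)
    stop_mt(paste0("expected at least ", ncol_need, " columns, found ",
                   ncol(raw), " in ", path))
  num <- function(j) suppressWarnings(as.numeric(raw[[j]]))
  if (dialect == "bismark_cov") {
    calls <- tibble::tibble(
      chrom = raw[[1]],
      pos = as.integer(num(2)),
      strand = NA_character_,
      meth_reads = as.integer(num(5)),
      total_reads = as.integer(num(5)) + as.integer(num(6)))
  } else {
    calls <- tibble::tibble(
      chrom = raw[[1]],
      pos = as.integer(num(2)) + 1L,
      strand = raw[[6]],
      meth_reads = as.integer(num(4)),
      total_reads = as.integer(num(5)))
  }
  bad <- which(is.na(calls$pos) | is.na(calls$meth_reads) |
                 is.na(calls$total_reads) |
                 calls$meth_reads < 0 | calls$total_reads < 0)
  if (length(bad))
    stop_mt(paste0("malformed call row(s) at line(s): ",
                   paste(utils::head(bad, 10), collapse = ", "),
                   " in ", path))
  over <- which(calls$meth_reads > calls$total_reads)
  if (length(over))
    stop_mt(paste0("meth_reads > total_reads at line(s): ",
                   paste(utils::head(over, 10), collapse = ", "),
                   " in ", path))
  if (dialect == "bedgraph_counts" &&
      !all(calls$strand %in% c("+", "-")))
    stop_mt("bedgraph_counts strand column must be '+' or '-'")
  calls
}

#' Merge replicate call sets
#'
#' Read counts are summed per `(chrom, pos, strand)` across replicates,
#' mirroring the merging of same-tissue replicate profiles within one data
#' source before cleaning.
#'
#' @param call_sets A list of call tibbles (as returned by [read_calls()]),
#'   or several tibbles passed as `...`.
#' @param ... Additional call tibbles.
#' @return One merged call tibble, sorted.
#' @export
merge_replicates <- function(call_sets, ...) {
  if (is.data.frame(call_sets)) call_sets <- list(call_sets, ...)
  assert_that(length(call_sets) >= 1, "need at least one call set")
  dplyr::bind_rows(call_sets) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
    dplyr::summarise(meth_reads = sum(.data$meth_reads),
                     total_reads = sum(.data$total_reads),
                     .groups = "drop") |>
    (\(d) d[order_sites(d$chrom, d$pos), ])() |>
    dplyr::select("chrom", "pos", "strand", "meth_reads", "total_reads")
}

#' Write / read the internal profile format
#'
#' A cleaned methylome profile is a sorted TSV with header
#' `chrom pos level total_reads` (gzipped automatically when `path` ends in
#' `.gz`). The round trip is lossless beyond six decimal places on `level`.
#'
#' @param profile Profile tibble: `chrom`, `pos`, `level`, `total_reads`.
#' @param path Output path.
#' @param sample_id,role Optional metadata stored as attributes on read.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns the profile tibble.
#' @export
write_profile <- function(profile, path) {
  need <- c("chrom", "pos", "level", "total_reads")
  assert_that(all(need %in% names(profile)),
              "profile must have columns chrom, pos, level, total_reads")
  out <- profile[order_sites(profile$chrom, profile$pos), need]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, sample_id = NULL, role = NULL) {
  prof <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", level = "d", total_reads = "i"),
    progress = FALSE)
  prof <- prof[order_sites(prof$chrom, prof$pos), ]
  if (!is.null(sample_id)) attr(prof, "sample_id") <- sample_id
  if (!is.null(role)) attr(prof, "role") <- role
  prof
}

#' Export an imputed profile to bedGraph
#'
#' @param imputed An imputed-profile tibble (see [impute_profile()]).
#' @param path Output path.
#' @export
write_bedgraph <- function(imputed, path) {
  out <- tibble::tibble(chrom = imputed$chrom,
                        start = imputed$pos - 1L,
                        end = imputed$pos,
                        level = imputed$level)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Fetch a subsequence with N padding outside chromosome bounds.
genome_window <- function(gidx, chrom, start, end) {
  s <- gidx$seqs[[chrom]]
  if (is.null(s)) stop_mt(paste0("chromosome absent from genome: ", chrom))
  len <- nchar(s)
  left_pad <- max(0L, 1L - start)
  right_pad <- max(0L, end - len)
  core <- substr(s, max(1L, start), min(len, end))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}
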