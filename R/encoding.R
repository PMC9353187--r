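# Model-input encoding: one-hot DNA windows centered on a CpG and, per
# profile, a vector of neighboring CpG methylation levels and normalized
# distances. Neighbors are always drawn from observed (cleaned) sites,
# never from imputed values.

BASES <- c("A", "C", "G", "T")

#' One-hot encode the sequence window around a CpG site
#'
#' Rows cover positions `pos - (w-1)/2 ... pos + (w-1)/2`; the center row
#' is the target C. Off-chromosome rows and `N` bases are all-zero, so
#' "no information" stays distinguishable from every base.
#'
#' @param gidx A [genome_index()].
#' @param chrom,pos Target CpG site (forward-strand C position).
#' @param window_len Odd window length in bp (default 1001).
#' @return A `window_len x 4` matrix with columns `A`, `C`, `G`, `T`.
#' @export
encode_sequence <- function(gidx, chrom, pos, window_len = 1001) {
  assert_that(window_len %% 2 == 1, "`window_len` must be odd")
  sites <- cpg_sites(gidx, chrom)
  if (!pos %in% sites$pos)
    stop_mt(paste0(chrom, ":", pos, " is not a CpG site"))
  arr <- encode_sequence_batch(gidx, chrom, pos, window_len)
  m <- matrix(arr, nrow = window_len, ncol = 4,
              dimnames = list(NULL, BASES))
  m
}

# Batched one-hot encoding: returns array (n_sites, window_len, 4).
encode_sequence_batch <- function(gidx, chrom, pos, window_len) {
  h <- (window_len - 1L) %/% 2L
  n <- length(pos)
  windows <- character(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    for (i in idx)
      windows[i] <- genome_window(gidx, ch, pos[i] - h, pos[i] + h)
  }
  chars <- strsplit(paste0(windows, collapse = ""), "", fixed = TRUE)[[1]]
  code <- match(chars, BASES)
  arr <- array(0, dim = c(n, window_len, 4))
  keep <- !is.na(code)
  if (any(keep)) {
    i_all <- seq_along(chars) - 1L
    b <- i_all %/% window_len + 1L
    w <- i_all %% window_len + 1L
    arr[cbind(b[keep], w[keep], code[keep])] <- 1
  }
  arr
}

#' Encode the neighboring-CpG methylation vector for one profile
#'
#' Finds the nearest `k_per_side` observed CpG sites on each side of the
#' target (the target itself is excluded) and returns the length-100
#' concatenation of 50 levels and 50 normalized distances, ordered
#' farthest-upstream to nearest-upstream, then nearest-downstream to
#' farthest-downstream. Distances are `|neighbor - pos| / dist_scale`
#' clipped at 1. Missing slots are padded with level 0.5 and distance 1
#' (maximally uninformative) and flagged `FALSE` in the mask.
#'
#' @param profile Observed profile tibble.
#' @param chrom,pos Target site.
#' @param k_per_side Neighbors per side (default 25).
#' @param dist_scale Distance normalization in bp (default 25000).
#' @return List with `vector` (length `4 * k_per_side`: levels then
#'   distances), `levels`, `distances`, and `mask` (length
#'   `2 * k_per_side`, `FALSE` for padded slots).
#' @export
encode_neighbors <- function(profile, chrom, pos, k_per_side = 25,
                             dist_scale = 25000) {
  on_chrom <- profile[profile$chrom == chrom, ]
  ord <- order(on_chrom$pos)
  encode_neighbors_at(on_chrom$pos[ord], on_chrom$level[ord], pos,
                      k_per_side, dist_scale)
}

# Core neighbor lookup over one chromosome's sorted observed sites.
encode_neighbors_at <- function(site_pos, site_level, pos, k, dist_scale) {
  n_slots <- 2L * k
  levels <- rep(0.5, n_slots)
  dists <- rep(1, n_slots)
  mask <- rep(FALSE, n_slots)
  if (length(site_pos)) {
    i_up <- findInterval(pos - 1L, site_pos)        # last site strictly < pos
    up <- seq_len(min(k, i_up))                      # nearest-first offsets
    if (length(up)) {
      sel <- i_up - up + 1L                          # nearest ... farthest
      slot <- k - up + 1L                            # nearest goes to slot k
      levels[slot] <- site_level[sel]
      dists[slot] <- pmin(1, (pos - site_pos[sel]) / dist_scale)
      mask[slot] <- TRUE
    }
    i_dn <- findInterval(pos, site_pos) + 1L         # first site strictly > pos
    dn <- seq_len(min(k, length(site_pos) - i_dn + 1L))
    if (length(dn) && i_dn <= length(site_pos)) {
      sel <- i_dn + dn - 1L
      slot <- k + dn                                 # nearest at slot k + 1
      levels[slot] <- site_level[sel]
      dists[slot] <- pmin(1, (site_pos[sel] - pos) / dist_scale)
      mask[slot] <- TRUE
    }
  }
  list(vector = c(levels, dists), levels = levels, distances = dists,
       mask = mask)
}

#' Build encoded examples for a set of CpG sites
#'
#' Assembles, for each site, the one-hot sequence window plus one neighbor
#' vector per profile, together with per-profile labels (the observed
#' level) and a label mask that is `FALSE` where a profile lacks the site.
#' Examples are deterministically ordered by `(chrom, pos)` and profiles
#' by their name in `profiles` (record the ordering with the model).
#'
#' @param profiles Named list of observed profile tibbles (the task set).
#' @param gidx A [genome_index()].
#' @param sites `"covered"` (sites observed in at least one profile —
#'   training), `"all"` (every genome CpG — imputation), or a tibble with
#'   columns `chrom`, `pos`.
#' @param window_len,k_per_side,dist_scale Encoding parameters (see
#'   [encode_sequence()] and [encode_neighbors()]).
#' @return An `encoded_examples` object: list with `seq`
#'   (`n x window_len x 4`), `nbr` (`n x m x 4k`), `nbr_mask`
#'   (`n x m x 2k`), `labels` and `label_mask` (`n x m`), `chrom`, `pos`,
#'   `profile_ids`.
#' @export
build_examples <- function(profiles, gidx, sites = "covered",
                           window_len = 1001, k_per_side = 25,
                           dist_scale = 25000) {
  assert_that(length(profiles) >= 1 && !is.null(names(profiles)),
              "`profiles` must be a named list with at least one profile")
  if (is.character(sites) && length(sites) == 1) {
    sites <- switch(sites,
      covered = dplyr::distinct(
        dplyr::bind_rows(lapply(profiles, `[`, c("chrom", "pos")))),
      all = cpg_sites(gidx),
      stop_mt("`sites` must be 'covered', 'all', or a tibble"))
  }
  sites <- sites[order_sites(sites$chrom, sites$pos), c("chrom", "pos")]
  n <- nrow(sites)
  m <- length(profiles)
  if (n == 0) rlang::warn("no sites to encode; returning an empty set")
  ex <- list(
    seq = encode_sequence_batch(gidx, sites$chrom, sites$pos, window_len),
    nbr = array(0, dim = c(n, m, 4L * k_per_side)),
    nbr_mask = array(FALSE, dim = c(n, m, 2L * k_per_side)),
    labels = matrix(NA_real_, n, m, dimnames = list(NULL, names(profiles))),
    label_mask = matrix(FALSE, n, m),
    chrom = sites$chrom, pos = sites$pos,
    profile_ids = names(profiles),
    window_len = window_len, k_per_side = k_per_side,
    dist_scale = dist_scale)
  for (j in seq_len(m)) {
    prof <- profiles[[j]]
    for (ch in unique(sites$chrom)) {
      rows <- which(sites$chrom == ch)
      on_chrom <- prof[prof$chrom == ch, ]
      ord <- order(on_chrom$pos)
      sp <- on_chrom$pos[ord]; sl <- on_chrom$level[ord]
      hit <- match(sites$pos[rows], sp)
      ex$labels[rows[!is.na(hit)], j] <- sl[hit[!is.na(hit)]]
      ex$label_mask[rows, j] <- !is.na(hit)
      for (i in rows) {
        nb <- encode_neighbors_at(sp, sl, sites$pos[i], k_per_side,
                                  dist_scale)
        ex$nbr[i, j, ] <- nb$vector
        ex$nbr_mask[i, j, ] <- nb$mask
      }
    }
  }
  structure(ex, class = "encoded_examples")
}

#' @export
print.encoded_examples <- function(x, ...) {
  cat("<encoded_examples> ", length(x$pos), " site(s) x ",
      length(x$profile_ids), " profile(s), window ", x$window_len,
      " bp, ", x$k_per_side, " neighbors/side\n", sep = "")
  invisible(x)
}

#' Subset encoded examples by row index
#'
#' @param ex An `encoded_examples` object.
#' @param idx Integer row indices.
#' @return The subset, same class.
#' @export
slice_examples <- function(ex, idx) {
  out <- ex
  out$seq <- ex$seq[idx, , , drop = FALSE]
  out$nbr <- ex$nbr[idx, , , drop = FALSE]
  out$nbr_mask <- ex$nbr_mask[idx, , , drop = FALSE]
  out$labels <- ex$labels[idx, , drop = FALSE]
  out$label_mask <- ex$label_mask[idx, , drop = FALSE]
  out$chrom <- ex$chrom[idx]
  out$pos <- ex$pos[idx]
  out
}

#' Number of examples in an encoded set
#' @param ex An `encoded_examples` object.
#' @export
n_examples <- function(ex) length(ex$pos)
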