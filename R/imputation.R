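# Completing a target profile: score every genome CpG the profile lacks,
# keep only confident calls (probability above tau or below 1 - tau), and
# merge them with the untouched observed data. Neighbor features use only
# originally observed sites — a single pass, no iterative refinement.

#' Impute the missing CpG sites of a target profile
#'
#' Every genome CpG not observed in the target profile is scored by the
#' trained model's head for that profile; predictions with probability
#' strictly above `tau` or strictly below `1 - tau` are retained. The
#' imputed level is the continuous predicted probability (a binarized
#' `state` column is derivable and included); observed records pass
#' through unchanged and are never re-predicted.
#'
#' @param model A trained `meth_model` (or `meth_fit`).
#' @param profiles Named list of observed profile tibbles, in the model's
#'   task order (must match the model's task count).
#' @param target_id Name of the profile to complete (selects the head).
#' @param gidx A [genome_index()].
#' @param tau Confidence threshold in `[0.5, 1)` (default 0.8).
#' @param window_len,k_per_side,dist_scale Encoding parameters; defaults
#'   are taken from the model.
#' @param chunk_size Sites encoded and scored per chunk.
#' @return An `imputed_profile` tibble: `chrom`, `pos`, `level`, `state`,
#'   `origin` (`"observed"` / `"imputed"`), `confidence` (predicted
#'   probability for imputed rows, `NA` for observed). Attributes record
#'   `target_id`, `tau`, and coverage rates before/after.
#' @export
impute_profile <- function(model, profiles, target_id, gidx, tau = 0.8,
                           window_len = NULL, k_per_side = 25,
                           dist_scale = 25000, chunk_size = 2048) {
  if (inherits(model, "meth_fit")) model <- model$model
  assert_that(tau >= 0.5 && tau < 1, "`tau` must lie in [0.5, 1)")
  assert_that(length(profiles) == length(model$task_ids),
              "model task count does not match the number of profiles")
  assert_that(target_id %in% names(profiles),
              "`target_id` must name one of `profiles`")
  j <- match(target_id, names(profiles))
  window_len <- window_len %||% model$window_len
  target <- profiles[[target_id]]
  all_sites <- cpg_sites(gidx)
  obs_key <- paste(target$chrom, target$pos)
  todo <- all_sites[!(paste(all_sites$chrom, all_sites$pos) %in% obs_key), ]
  imputed <- list()
  n <- nrow(todo)
  s <- 1
  while (s <= n) {
    chunk <- todo[s:min(n, s + chunk_size - 1), ]
    ex <- build_examples(profiles, gidx, sites = chunk,
                         window_len = window_len,
                         k_per_side = k_per_side, dist_scale = dist_scale)
    prob <- predict(model, ex)[, j]
    keep <- prob > tau | prob < 1 - tau
    if (any(keep)) {
      imputed[[length(imputed) + 1]] <- tibble::tibble(
        chrom = ex$chrom[keep], pos = ex$pos[keep],
        level = prob[keep], state = binarize(prob[keep]),
        origin = "imputed", confidence = prob[keep])
    }
    s <- s + chunk_size
  }
  observed <- tibble::tibble(chrom = target$chrom, pos = target$pos,
                             level = target$level,
                             state = binarize(target$level),
                             origin = "observed",
                             confidence = NA_real_)
  out <- dplyr::bind_rows(observed, dplyr::bind_rows(imputed))
  out <- out[order_sites(out$chrom, out$pos), ]
  attr(out, "target_id") <- target_id
  attr(out, "tau") <- tau
  rates <- coverage_gain(target, out, gidx)
  attr(out, "rate_before") <- rates$rate_before
  attr(out, "rate_after") <- rates$rate_after
  class(out) <- c("imputed_profile", class(out))
  out
}

#' Coverage gain from imputation
#'
#' Genome-wide CpG coverage rate before (observed profile) and after
#' (observed plus retained imputed sites).
#'
#' @param before Observed profile tibble.
#' @param after Imputed-profile tibble.
#' @param gidx A [genome_index()].
#' @return Tibble with `rate_before` and `rate_after`.
#' @export
coverage_gain <- function(before, after, gidx) {
  tibble::tibble(rate_before = coverage_rate(before, gidx),
                 rate_after = coverage_rate(after, gidx))
}

#' Write an imputed profile to TSV
#'
#' The internal profile dialect plus `state`, `origin` and `confidence`
#' columns; gzip-aware via the file extension.
#'
#' @param imputed An `imputed_profile` tibble.
#' @param path Output path.
#' @export
write_imputed_profile <- function(imputed, path) {
  readr::write_tsv(as.data.frame(imputed), path, progress = FALSE)
  invisible(path)
}
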