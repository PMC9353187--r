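# Internal helpers shared across modules.

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @importFrom rlang abort warn inform
stop_mt <- function(msg, class = "methtransfer_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_mt(msg)
}

# Chromosome-aware ordering used everywhere a profile or example set is
# sorted: chromosome name (natural order), then position.
order_sites <- function(chrom, pos) {
  order(chrom_rank(chrom), pos)
}

chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  key <- ifelse(is.na(num), Inf, num)
  r <- order(key, u)
  match(chrom, u[r])
}
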