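#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# timestamp used in load columns and transaction logs
tad_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

# stop with a classed condition so callers/tests can match on class
tad_stop <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "tad_error"), ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# chromosome-aware ordering: numeric labels first in numeric order, then
# non-numeric labels (X, MT, scaffolds) lexicographically
chrom_order_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  list(is_named = !is.na(num) * -1L, num = ifelse(is.na(num), Inf, num), lab = chrom)
}

order_by_chrom_pos <- function(chrom, pos) {
  k <- chrom_order_key(chrom)
  order(k$is_named, k$num, k$lab, pos, method = "radix")
}
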