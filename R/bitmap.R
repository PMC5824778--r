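#' Word-aligned run-length encoding of bit vectors
#'
#' The columnar engine indexes low-cardinality columns with one bit vector per
#' distinct value. Bit vectors are compressed with a word-aligned hybrid
#' run-length scheme: the vector is cut into 31-bit groups; a maximal run of
#' all-zero or all-one groups becomes a single *fill* word, any other group is
#' stored verbatim as a *literal* word. Words are kept as doubles (R has no
#' unsigned 32-bit integer): a literal word is its group value in
#' `[0, 2^31 - 1]`; a fill word is `2^31 + fillbit * 2^30 + runlength`.
#'
#' @param bits logical vector (no NAs).
#' @return `bitmap_encode()` returns an object of class `tad_bitmap` with
#'   fields `words` (numeric) and `n` (original bit count); `bitmap_decode()`
#'   returns the original logical vector.
#' @keywords internal
#' @name bitmap-rle
NULL

TAD_WORD_BITS <- 31L
TAD_FILL_FLAG <- 2^31
TAD_FILL_ONE <- 2^30
TAD_FULL_GROUP <- 2^31 - 1

#' @rdname bitmap-rle
bitmap_encode <- function(bits) {
  stopifnot(is.logical(bits), !anyNA(bits))
  n <- length(bits)
  if (n == 0L) {
    return(structure(list(words = numeric(0), n = 0L), class = "tad_bitmap"))
  }
  pad <- (TAD_WORD_BITS - n %% TAD_WORD_BITS) %% TAD_WORD_BITS
  b <- c(bits, rep(FALSE, pad))
  m <- matrix(as.numeric(b), nrow = TAD_WORD_BITS)
  vals <- as.numeric(2^(0:(TAD_WORD_BITS - 1L)) %*% m) # little-endian within group
  is_fill <- vals == 0 | vals == TAD_FULL_GROUP
  words <- numeric(0)
  i <- 1L
  ng <- length(vals)
  while (i <= ng) {
    if (is_fill[i]) {
      j <- i
      while (j < ng && is_fill[j + 1L] && vals[j + 1L] == vals[i]) j <- j + 1L
      fillbit <- if (vals[i] == 0) 0 else TAD_FILL_ONE
      words <- c(words, TAD_FILL_FLAG + fillbit + (j - i + 1L))
      i <- j + 1L
    } else {
      words <- c(words, vals[i])
      i <- i + 1L
    }
  }
  structure(list(words = words, n = n), class = "tad_bitmap")
}

#' @rdname bitmap-rle
#' @param x a `tad_bitmap`.
bitmap_decode <- function(x) {
  stopifnot(inherits(x, "tad_bitmap"))
  if (x$n == 0L) return(logical(0))
  groups <- numeric(0)
  for (w in x$words) {
    if (w >= TAD_FILL_FLAG) {
      fillbit <- (w - TAD_FILL_FLAG) >= TAD_FILL_ONE
      len <- (w - TAD_FILL_FLAG) %% TAD_FILL_ONE
      groups <- c(groups, rep(if (fillbit) TAD_FULL_GROUP else 0, len))
    } else {
      groups <- c(groups, w)
    }
  }
  bits <- as.vector(vapply(
    groups,
    function(v) (v %/% 2^(0:(TAD_WORD_BITS - 1L))) %% 2 == 1,
    logical(TAD_WORD_BITS)
  ))
  bits[seq_len(x$n)]
}

#' Build an equality bitmap index for one column
#'
#' One compressed bit vector per distinct value; bitmaps are pairwise disjoint
#' and cover every row (missing text is the queryable literal `"NULL"`, so it
#' indexes like any other value).
#'
#' @param values character vector of column values (length = row count).
#' @param column column name, carried for reporting.
#' @return object of class `tad_bitmap_index`: fields `column`, `values`
#'   (ordered distinct values), `bitmaps` (named list of `tad_bitmap`), `n`.
#' @keywords internal
bitmap_index_build <- function(values, column) {
  vals <- sort(unique(values), method = "radix")
  bitmaps <- lapply(vals, function(v) bitmap_encode(values == v))
  names(bitmaps) <- vals
  structure(
    list(column = column, values = vals, bitmaps = bitmaps, n = length(values)),
    class = "tad_bitmap_index"
  )
}

# row positions (1-based, strictly increasing) for an equality lookup
bitmap_index_rows <- function(index, value) {
  bm <- index$bitmaps[[value]]
  if (is.null(bm)) return(integer(0))
  which(bitmap_decode(bm))
}

# logical mask for an equality lookup over all rows
bitmap_index_mask <- function(index, value) {
  bm <- index$bitmaps[[value]]
  if (is.null(bm)) return(rep(FALSE, index$n))
  bitmap_decode(bm)
}
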