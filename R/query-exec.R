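#' Execute a parsed query against a partition
#'
#' Equality predicates on columns with a fresh on-disk bitmap index are
#' answered through the index; everything else is a column scan. `LIKE` is
#' case-insensitive with `%` matching any (possibly empty) substring; `=` on
#' strings is case-sensitive. Comparisons on `int`/`double` columns are
#' numeric (a `NaN` never matches), on string columns lexicographic.
#' `ORDER BY` is ascending by default and stable (ties keep insertion order);
#' `LIMIT` applies after ordering. Aggregates are computed per group, with
#' `avg = sum/count` as double and `count(col)` counting non-missing values.
#'
#' @param part a `tad_partition`.
#' @param ast a `tad_query` from [parse_query()] (a query string is also
#'   accepted and parsed).
#' @return a tibble.
#' @export
#' @examples
#' p <- create_partition(file.path(tempdir(), "qdemo"),
#'                       data.frame(name = c("gene", "tpm"),
#'                                  kind = c("key", "double")))
#' append_rows(p, data.frame(gene = c("A", "B", "A"), tpm = c(1, 2, 3)))
#' p <- open_partition(p$path)
#' execute_query(p, "select gene, avg(tpm) group by gene")
execute_query <- function(part, ast) {
  if (is.character(ast)) ast <- parse_query(ast)
  stopifnot(inherits(ast, "tad_query"))
  validate_ast(part$schema$name, ast)
  tbl <- partition_tbl(part)
  mask <- eval_predicates(tbl, ast$predicates, part, use_index = TRUE)
  eval_select(tbl[mask, , drop = FALSE], part$schema, ast)
}

validate_ast <- function(columns, ast) {
  refs <- character(0)
  for (it in ast$projection) {
    if (it$kind == "col") refs <- c(refs, it$column)
    if (it$kind == "agg" && it$column != "*") refs <- c(refs, it$column)
  }
  for (pr in ast$predicates) refs <- c(refs, pr$column)
  refs <- c(refs, ast$group_by)
  unknown <- setdiff(refs, columns)
  if (length(unknown)) {
    tad_stop(paste0("unknown column: ", unknown[1]), "tad_column_error")
  }
  has_agg <- any(vapply(ast$projection, function(i) i$kind == "agg", logical(1)))
  plain <- unlist(lapply(ast$projection, function(i) if (i$kind == "col") i$column))
  if (has_agg && length(ast$group_by) == 0L && length(plain)) {
    tad_stop("plain columns alongside aggregates require GROUP BY",
             "tad_query_error")
  }
  if (has_agg && length(ast$group_by) && length(setdiff(plain, ast$group_by))) {
    tad_stop("projected non-aggregate columns must appear in GROUP BY",
             "tad_query_error")
  }
  if (!is.null(ast$order_by) && !has_agg && !ast$order_by$column %in% columns) {
    tad_stop(paste0("unknown column: ", ast$order_by$column), "tad_column_error")
  }
  invisible(TRUE)
}

# logical row mask for a predicate conjunction
eval_predicates <- function(tbl, predicates, part = NULL, use_index = FALSE) {
  mask <- rep(TRUE, nrow(tbl))
  for (pr in predicates) {
    x <- tbl[[pr$column]]
    hit <- if (pr$op == "=" && use_index && !is.null(part) &&
               is.character(x)) {
      idx <- read_bitmap_index(part, pr$column)
      if (!is.null(idx)) bitmap_index_mask(idx, as.character(pr$value))
      else compare_vals(x, pr$op, pr$value)
    } else {
      compare_vals(x, pr$op, pr$value)
    }
    hit[is.na(hit)] <- FALSE
    mask <- mask & hit
  }
  mask
}

compare_vals <- function(x, op, value) {
  if (op == "like") {
    rx <- paste0("^", gsub("%", ".*", rx_escape(as.character(value))), "$")
    return(grepl(rx, as.character(x), ignore.case = TRUE))
  }
  if (is.numeric(x)) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) return(rep(FALSE, length(x)))
  } else {
    v <- as.character(value)
    x <- as.character(x)
  }
  switch(op,
    "=" = x == v, "!=" = x != v,
    "<" = x < v, "<=" = x <= v, ">" = x > v, ">=" = x >= v,
    tad_stop(paste0("unsupported operator: ", op), "tad_query_error")
  )
}

rx_escape <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

agg_name <- function(it) paste0(it$fn, "(", it$column, ")")

apply_aggregate <- function(it, tbl) {
  if (it$fn == "count") {
    if (it$column == "*") return(nrow(tbl))
    x <- tbl[[it$column]]
    if (is.character(x)) return(sum(x != "NULL"))
    return(sum(!is.na(x) & !is.nan(x)))
  }
  x <- tbl[[it$column]]
  if (!is.numeric(x)) {
    if (it$fn %in% c("sum", "avg")) {
      tad_stop(paste0(it$fn, "() requires a numeric column, but ", it$column,
                      " is not numeric"), "tad_query_error")
    }
    x <- as.character(x)
    x <- x[x != "NULL"]
    if (!length(x)) return(NA_character_)
    return(if (it$fn == "min") min(x) else max(x))
  }
  x <- x[!is.na(x) & !is.nan(x)]
  if (!length(x)) return(NaN)
  switch(it$fn,
    sum = sum(x),
    avg = sum(x) / length(x),
    min = min(x),
    max = max(x)
  )
}

eval_select <- function(tbl, schema, ast) {
  has_agg <- any(vapply(ast$projection, function(i) i$kind == "agg", logical(1)))
  if (has_agg) {
    out <- eval_aggregates(tbl, ast)
  } else {
    cols <- character(0)
    for (it in ast$projection) {
      cols <- c(cols, if (it$kind == "star") schema$name else it$column)
    }
    out <- tbl[, cols, drop = FALSE]
  }
  if (!is.null(ast$order_by)) {
    key <- out[[ast$order_by$column]]
    if (is.null(key) && !has_agg) key <- tbl[[ast$order_by$column]]
    if (is.null(key)) {
      tad_stop(paste0("ORDER BY column not in result: ", ast$order_by$column),
               "tad_column_error")
    }
    ord <- order(key, decreasing = ast$order_by$desc, method = "radix",
                 na.last = TRUE)
    out <- out[ord, , drop = FALSE]
  }
  if (!is.null(ast$limit)) out <- utils::head(out, ast$limit)
  as_tibble(out)
}

eval_aggregates <- function(tbl, ast) {
  aggs <- Filter(function(i) i$kind == "agg", ast$projection)
  if (length(ast$group_by) == 0L) {
    vals <- lapply(aggs, apply_aggregate, tbl = tbl)
    names(vals) <- vapply(aggs, agg_name, character(1))
    return(as_tibble(vals))
  }
  keydf <- tbl[, ast$group_by, drop = FALSE]
  if (nrow(keydf) == 0L) {
    out <- keydf
    for (it in aggs) out[[agg_name(it)]] <- numeric(0)
    proj_cols <- vapply(ast$projection, function(i) {
      if (i$kind == "agg") agg_name(i) else i$column
    }, character(1))
    return(out[, proj_cols, drop = FALSE])
  }
  keys <- do.call(paste, c(unname(as.list(keydf)), sep = "\r"))
  ord_keys <- sort(unique(keys), method = "radix") # deterministic group order
  rows <- lapply(ord_keys, function(k) {
    sub <- tbl[keys == k, , drop = FALSE]
    row <- as.list(sub[1L, ast$group_by, drop = FALSE])
    for (it in aggs) row[[agg_name(it)]] <- apply_aggregate(it, sub)
    row
  })
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  # honour the projection's column order
  proj_cols <- vapply(ast$projection, function(i) {
    if (i$kind == "agg") agg_name(i) else i$column
  }, character(1))
  out[, proj_cols, drop = FALSE]
}
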