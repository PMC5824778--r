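#' Parse an SQL-subset query for the columnar engine
#'
#' The columnar query language is the familiar `SELECT` surface without a
#' mandatory `FROM` clause (the partition is chosen separately; a `FROM`
#' clause is tolerated and recorded but ignored):
#'
#' ```
#' select <col, ... | * | fn(col), ...>
#'   [from <name>]
#'   [where <col> <op> <literal> [and ...]]
#'   [group by <col, ...>]
#'   [order by <col> [asc|desc]]
#'   [limit <n>]
#' ```
#'
#' Operators are `=`, `!=`, `<`, `<=`, `>`, `>=` and `like` (case-insensitive,
#' `%` matches any substring). Aggregates are `count`, `sum`, `avg`, `min`,
#' `max`. Predicates combine with `and` only; `or`, `join` and subqueries are
#' rejected explicitly.
#'
#' @param text query string.
#' @return a `tad_query` AST: list with `projection` (list of items with
#'   `kind` = "col"/"agg"/"star", `fn`, `column`), `predicates` (list of
#'   `(column, op, value, is_string)`), `group_by`, `order_by`
#'   (`list(column, desc)`), `limit`, `from`.
#' @export
#' @examples
#' ast <- parse_query("select genename, avg(fpkm) where tpm > 1 group by genename")
#' length(ast$projection)
parse_query <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) {
    tad_stop("empty query", "tad_parse_error")
  }
  toks <- tokenize_query(text)
  p <- new.env(parent = emptyenv())
  p$toks <- toks
  p$i <- 1L
  p$text <- text

  expect_kw(p, "select")
  projection <- parse_projection(p)
  from <- NULL
  if (peek_kw(p, "from")) {
    advance(p)
    from <- expect_type(p, "ident")$value
  }
  predicates <- list()
  if (peek_kw(p, "where")) {
    advance(p)
    predicates <- parse_predicates(p)
  }
  group_by <- character(0)
  if (peek_kw(p, "group")) {
    advance(p); expect_kw(p, "by")
    group_by <- parse_column_list(p)
  }
  order_by <- NULL
  if (peek_kw(p, "order")) {
    advance(p); expect_kw(p, "by")
    col <- expect_type(p, "ident")$value
    desc <- FALSE
    if (peek_kw(p, "desc")) { advance(p); desc <- TRUE }
    else if (peek_kw(p, "asc")) advance(p)
    order_by <- list(column = col, desc = desc)
  }
  limit <- NULL
  if (peek_kw(p, "limit")) {
    advance(p)
    limit <- as.integer(expect_type(p, "number")$value)
  }
  tok <- current(p)
  if (!is.null(tok)) {
    parse_fail(p, paste0("unexpected token \"", tok$value, "\""))
  }
  structure(
    list(projection = projection, predicates = predicates, group_by = group_by,
         order_by = order_by, limit = limit, from = from),
    class = "tad_query"
  )
}

QUERY_KEYWORDS <- c("select", "from", "where", "and", "or", "group", "by",
                    "order", "asc", "desc", "limit", "like", "join", "not",
                    "in", "union")
QUERY_AGGREGATES <- c("count", "sum", "avg", "min", "max")

tokenize_query <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { i <- i + nchar(ws); next }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^('[^']*'|\"[^\"]*\")", rest))
    if (length(m)) {
      toks[[length(toks) + 1L]] <- list(type = "string",
                                        value = substr(m, 2, nchar(m) - 1L), pos = i)
      i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^(-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?)", rest))
    if (length(m)) {
      toks[[length(toks) + 1L]] <- list(type = "number", value = m, pos = i)
      i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^(!\\s*=|<=|>=|<>|=|<|>)", rest))
    if (length(m)) {
      op <- gsub("\\s+", "", m)
      if (op == "<>") op <- "!="
      toks[[length(toks) + 1L]] <- list(type = "op", value = op, pos = i)
      i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.]*", rest))
    if (length(m)) {
      type <- if (tolower(m) %in% QUERY_KEYWORDS) "kw" else "ident"
      toks[[length(toks) + 1L]] <- list(type = type, value = m, pos = i)
      i <- i + nchar(m); next
    }
    ch <- substr(text, i, i)
    if (ch %in% c(",", "(", ")", "*")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L; next
    }
    tad_stop(paste0("syntax error at position ", i, ": unexpected character \"", ch, "\""),
             "tad_parse_error")
  }
  toks
}

current <- function(p) if (p$i <= length(p$toks)) p$toks[[p$i]] else NULL
advance <- function(p) { t <- current(p); p$i <- p$i + 1L; t }
peek_kw <- function(p, kw) {
  t <- current(p)
  !is.null(t) && t$type == "kw" && tolower(t$value) == kw
}
parse_fail <- function(p, msg) {
  t <- current(p)
  pos <- if (is.null(t)) nchar(p$text) + 1L else t$pos
  tad_stop(paste0("syntax error at position ", pos, ": ", msg), "tad_parse_error")
}
expect_kw <- function(p, kw) {
  if (!peek_kw(p, kw)) {
    t <- current(p)
    got <- if (is.null(t)) "end of query" else paste0("token \"", t$value, "\"")
    parse_fail(p, paste0("expected ", toupper(kw), ", got ", got))
  }
  advance(p)
}
expect_type <- function(p, type) {
  t <- current(p)
  if (is.null(t) || t$type != type) {
    got <- if (is.null(t)) "end of query" else paste0("\"", t$value, "\"")
    parse_fail(p, paste0("expected ", type, ", got ", got))
  }
  advance(p)
}

parse_projection <- function(p) {
  items <- list()
  repeat {
    t <- current(p)
    if (is.null(t)) parse_fail(p, "expected projection item")
    if (t$type == "*") {
      advance(p)
      items[[length(items) + 1L]] <- list(kind = "star")
    } else if (t$type == "ident" && tolower(t$value) %in% QUERY_AGGREGATES &&
               p$i < length(p$toks) && p$toks[[p$i + 1L]]$type == "(") {
      fn <- tolower(advance(p)$value)
      advance(p) # (
      inner <- current(p)
      if (!is.null(inner) && inner$type == "*") {
        if (fn != "count") parse_fail(p, paste0(fn, "(*) is not supported"))
        advance(p)
        col <- "*"
      } else {
        col <- expect_type(p, "ident")$value
      }
      t2 <- current(p)
      if (is.null(t2) || t2$type != ")") parse_fail(p, "expected )")
      advance(p)
      items[[length(items) + 1L]] <- list(kind = "agg", fn = fn, column = col)
    } else if (t$type == "ident") {
      advance(p)
      items[[length(items) + 1L]] <- list(kind = "col", column = t$value)
    } else {
      parse_fail(p, paste0("expected column, got \"", t$value, "\""))
    }
    t <- current(p)
    if (!is.null(t) && t$type == ",") { advance(p); next }
    break
  }
  items
}

parse_column_list <- function(p) {
  cols <- character(0)
  repeat {
    cols <- c(cols, expect_type(p, "ident")$value)
    t <- current(p)
    if (!is.null(t) && t$type == ",") { advance(p); next }
    break
  }
  cols
}

parse_predicates <- function(p) {
  preds <- list()
  repeat {
    col <- expect_type(p, "ident")$value
    t <- current(p)
    op <- NULL
    if (!is.null(t) && t$type == "op") {
      op <- advance(p)$value
    } else if (peek_kw(p, "like")) {
      advance(p)
      op <- "like"
    } else {
      parse_fail(p, "expected comparison operator")
    }
    lit <- current(p)
    if (is.null(lit) || !lit$type %in% c("string", "number")) {
      parse_fail(p, "expected literal")
    }
    advance(p)
    preds[[length(preds) + 1L]] <- list(
      column = col, op = op,
      value = if (lit$type == "number") as.numeric(lit$value) else lit$value,
      is_string = lit$type == "string"
    )
    if (peek_kw(p, "and")) { advance(p); next }
    if (peek_kw(p, "or")) parse_fail(p, "OR predicates are not supported (conjunctions only)")
    break
  }
  preds
}
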