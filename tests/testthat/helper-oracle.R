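# Independent naive reference evaluator for the SQL subset: a plain row
# filter + base-R aggregation over the in-memory data frame, sharing no code
# with the engine's execution path.

naive_like <- function(x, pattern) {
  pieces <- strsplit(pattern, "%", fixed = TRUE)[[1]]
  if (!length(pieces)) pieces <- ""
  if (endsWith(pattern, "%")) pieces <- c(pieces, "")
  rx <- paste0("^", paste(vapply(pieces, function(s) {
    gsub("([^A-Za-z0-9 _])", "\\\\\\1", s)
  }, character(1)), collapse = ".*"), "$")
  grepl(rx, tolower(as.character(x)))
}

naive_filter <- function(df, predicates) {
  keep <- rep(TRUE, nrow(df))
  for (pr in predicates) {
    x <- df[[pr$column]]
    ok <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      xi <- x[i]
      ok[i] <- if (pr$op == "like") {
        naive_like(xi, tolower(as.character(pr$value)))
      } else if (is.numeric(x)) {
        v <- as.numeric(pr$value)
        !is.na(xi) && !is.nan(xi) && switch(pr$op,
          "=" = xi == v, "!=" = xi != v, "<" = xi < v, "<=" = xi <= v,
          ">" = xi > v, ">=" = xi >= v)
      } else {
        v <- as.character(pr$value)
        switch(pr$op,
          "=" = xi == v, "!=" = xi != v, "<" = xi < v, "<=" = xi <= v,
          ">" = xi > v, ">=" = xi >= v)
      }
    }
    keep <- keep & ok
  }
  df[keep, , drop = FALSE]
}

naive_agg_one <- function(fn, col, sub) {
  if (fn == "count") {
    if (col == "*") return(nrow(sub))
    x <- sub[[col]]
    if (is.character(x)) return(sum(x != "NULL"))
    return(sum(!is.na(x) & !is.nan(x)))
  }
  x <- sub[[col]]
  x <- x[!is.na(x) & !is.nan(x)]
  if (!length(x)) return(NaN)
  switch(fn, sum = sum(x), avg = mean(x), min = min(x), max = max(x))
}

naive_eval <- function(df, ast) {
  sub <- naive_filter(df, ast$predicates)
  aggs <- Filter(function(i) i$kind == "agg", ast$projection)
  if (length(aggs)) {
    if (length(ast$group_by)) {
      if (nrow(sub) == 0L) {
        out <- sub[, ast$group_by, drop = FALSE]
        for (a in aggs) out[[paste0(a$fn, "(", a$column, ")")]] <- numeric(0)
        proj <- vapply(ast$projection, function(i) {
          if (i$kind == "agg") paste0(i$fn, "(", i$column, ")") else i$column
        }, character(1))
        return(tibble::as_tibble(out[, proj, drop = FALSE]))
      }
      key <- do.call(paste, c(unname(as.list(sub[, ast$group_by, drop = FALSE])),
                              sep = "\r"))
      out_rows <- lapply(sort(unique(key), method = "radix"), function(k) {
        g <- sub[key == k, , drop = FALSE]
        row <- as.list(g[1, ast$group_by, drop = FALSE])
        for (a in aggs) {
          row[[paste0(a$fn, "(", a$column, ")")]] <-
            naive_agg_one(a$fn, a$column, g)
        }
        tibble::as_tibble(row)
      })
      out <- dplyr::bind_rows(out_rows)
      proj <- vapply(ast$projection, function(i) {
        if (i$kind == "agg") paste0(i$fn, "(", i$column, ")") else i$column
      }, character(1))
      out <- out[, proj, drop = FALSE]
    } else {
      vals <- lapply(aggs, function(a) naive_agg_one(a$fn, a$column, sub))
      names(vals) <- vapply(aggs, function(a) paste0(a$fn, "(", a$column, ")"),
                            character(1))
      out <- tibble::as_tibble(vals)
    }
  } else {
    cols <- character(0)
    for (it in ast$projection) {
      cols <- c(cols, if (it$kind == "star") names(df) else it$column)
    }
    out <- sub[, cols, drop = FALSE]
  }
  if (!is.null(ast$order_by)) {
    out <- out[order(out[[ast$order_by$column]],
                     decreasing = ast$order_by$desc, method = "radix",
                     na.last = TRUE), , drop = FALSE]
  }
  if (!is.null(ast$limit)) out <- utils::head(out, ast$limit)
  tibble::as_tibble(out)
}

# random query text over the random_partition schema
random_query <- function() {
  cols <- c("id", "chrom", "gene", "pos", "score")
  proj <- sample(cols, sample(1:4, 1))
  q <- paste("select", paste(proj, collapse = ", "))
  use_agg <- stats::runif(1) < 0.3
  grpq <- ""
  if (use_agg) {
    grp <- sample(c("chrom", "gene", "id"), 1)
    fn <- sample(c("count", "sum", "avg", "min", "max"), 1)
    acol <- if (fn == "count" && stats::runif(1) < 0.4) "*"
    else sample(c("pos", "score"), 1)
    q <- paste0("select ", grp, ", ", fn, "(", acol, ")")
    grpq <- paste0(" group by ", grp)
    ordq <- ""
  } else {
    ordq <- if (stats::runif(1) < 0.5) {
      paste(" order by", sample(proj, 1),
            if (stats::runif(1) < 0.5) "desc" else "")
    } else ""
  }
  preds <- character(0)
  n_pred <- sample(0:2, 1)
  if (n_pred > 0) {
    for (i in seq_len(n_pred)) {
      pc <- sample(cols, 1)
      preds <- c(preds, switch(pc,
        id = paste0("id ", sample(c("=", "!="), 1), " 'S00",
                    sample.int(9L, 1), "'"),
        chrom = paste0("chrom = '", sample(1:4, 1), "'"),
        gene = sample(c(paste0("gene != 'NULL'"),
                        paste0("gene like 'gene0", sample.int(8L, 1), "'"),
                        paste0("gene like 'GENE%'")), 1),
        pos = paste0("pos ", sample(c("<", "<=", ">", ">="), 1), " ",
                     sample.int(10000L, 1)),
        score = paste0("score ", sample(c("<", ">", ">=", "<="), 1), " ",
                       sample(20:80, 1))
      ))
    }
  }
  where <- if (length(preds)) paste(" where", paste(preds, collapse = " and ")) else ""
  lim <- if (!use_agg && stats::runif(1) < 0.3) paste(" limit", sample.int(20L, 1)) else ""
  # grammar order: where, then group by, then order/limit
  paste0(q, where, grpq, if (!use_agg) ordq else "", lim)
}

canonical_sort <- function(df) {
  if (!nrow(df)) return(df)
  df[do.call(order, c(unname(as.list(df)), list(method = "radix"))), , drop = FALSE]
}

expect_query_equivalence <- function(part, df, qtext) {
  ast <- parse_query(qtext)
  got <- execute_query(part, ast)
  want <- naive_eval(df, ast)
  # without an explicit ORDER BY both sides preserve insertion order and the
  # comparison is exact; with one, ties keep insertion order in both
  expect_equal(names(got), names(want), info = qtext)
  expect_equal(nrow(got), nrow(want), info = qtext)
  for (cn in names(got)) {
    g <- got[[cn]]; w <- want[[cn]]
    if (is.numeric(g)) {
      expect_equal(g, as.numeric(w), tolerance = 1e-9, info = paste(qtext, cn))
    } else {
      expect_equal(as.character(g), as.character(w), info = paste(qtext, cn))
    }
  }
}
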