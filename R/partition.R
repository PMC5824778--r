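#' Append-only column-oriented partitions
#'
#' A partition is a directory holding one plain-text file per column
#' (`<name>.col`, one serialized value per line), a descriptor `-part.txt`
#' listing row count and `(name, kind)` pairs in order, and optional
#' `<name>.idx` bitmap-index files. Column kinds follow the querying-system
#' field types: `text`, `key` and `char` store strings (`key` marks
#' low-cardinality columns indexed by default), `int` stores integers and
#' `double` stores doubles. Missing values are the queryable literal `"NULL"`
#' for string kinds, `NaN` for doubles and `NA` for integers. Doubles are
#' serialized with 17 significant digits so a read-back is bit-exact.
#'
#' Appends only ever add lines to the column files; compaction happens solely
#' through [delete_rows()], which rewrites the partition.
#'
#' @name partition
NULL

TAD_KINDS <- c("text", "key", "char", "int", "double")

part_descriptor <- function(path) file.path(path, "-part.txt")
part_colfile <- function(path, name) file.path(path, paste0(name, ".col"))
part_idxfile <- function(path, name) file.path(path, paste0(name, ".idx"))

#' Create an empty partition
#'
#' @param path directory to create (must not already contain a partition).
#' @param schema data frame with columns `name` and `kind`; kinds from
#'   `text`, `key`, `char`, `int`, `double`; names unique.
#' @return a `tad_partition` handle (list with `path`, `schema`, `row_count`).
#' @export
#' @examples
#' p <- create_partition(file.path(tempdir(), "demo_part"),
#'                       data.frame(name = c("gene", "tpm"),
#'                                  kind = c("key", "double")))
#' p$row_count
create_partition <- function(path, schema) {
  schema <- as_tibble(as.data.frame(schema, stringsAsFactors = FALSE))
  if (nrow(schema) == 0L) tad_stop("schema must have at least one column", "tad_schema_error")
  if (anyDuplicated(schema$name)) {
    dup <- schema$name[duplicated(schema$name)][1]
    tad_stop(paste0("duplicate column name: ", dup), "tad_schema_error")
  }
  bad <- setdiff(schema$kind, TAD_KINDS)
  if (length(bad)) tad_stop(paste0("unknown column kind: ", bad[1]), "tad_schema_error")
  if (file.exists(part_descriptor(path))) {
    tad_stop(paste0("partition already exists at ", path), "tad_exists_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in schema$name) file.create(part_colfile(path, nm))
  part <- structure(
    list(path = path, schema = schema[, c("name", "kind")], row_count = 0L),
    class = "tad_partition"
  )
  write_part_descriptor(part)
  part
}

write_part_descriptor <- function(part) {
  lines <- c(
    paste0("rows\t", part$row_count),
    paste0("column\t", part$schema$name, "\t", part$schema$kind)
  )
  writeLines(lines, part_descriptor(part$path))
}

#' Open an existing partition
#' @param path partition directory.
#' @return a `tad_partition` handle.
#' @export
open_partition <- function(path) {
  f <- part_descriptor(path)
  if (!file.exists(f)) tad_stop(paste0("no partition at ", path), "tad_missing_error")
  lines <- readLines(f)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- as.integer(parts[[1]][2])
  cols <- parts[-1]
  schema <- tibble(
    name = vapply(cols, `[`, character(1), 2L),
    kind = vapply(cols, `[`, character(1), 3L)
  )
  structure(list(path = path, schema = schema, row_count = rows),
            class = "tad_partition")
}

#' @export
print.tad_partition <- function(x, ...) {
  cat("<tad_partition> ", x$path, "\n  ", x$row_count, " rows x ",
      nrow(x$schema), " columns\n", sep = "")
  invisible(x)
}

part_kind <- function(part, name) {
  k <- part$schema$kind[match(name, part$schema$name)]
  if (is.na(k)) tad_stop(paste0("unknown column: ", name), "tad_column_error")
  k
}

serialize_col <- function(x, kind) {
  switch(kind,
    text = , key = , char = {
      x <- as.character(x)
      x[is.na(x)] <- "NULL"
      x
    },
    int = {
      out <- as.character(as.integer(x))
      out[is.na(out)] <- "NA"
      out
    },
    double = {
      x <- as.numeric(x)
      x[is.na(x)] <- NaN
      sprintf("%.17g", x)
    }
  )
}

deserialize_col <- function(lines, kind) {
  switch(kind,
    text = , key = , char = lines,
    int = {
      out <- suppressWarnings(as.integer(lines))
      out
    },
    double = as.numeric(lines)
  )
}

#' Read one column of a partition as a typed vector
#' @param part a `tad_partition`.
#' @param name column name.
#' @return typed vector of length `row_count` (strings keep the `"NULL"`
#'   literal; missing doubles are `NaN`; missing integers are `NA`).
#' @export
read_column <- function(part, name) {
  kind <- part_kind(part, name)
  lines <- readLines(part_colfile(part$path, name))
  if (length(lines) != part$row_count) {
    tad_stop(paste0("column ", name, " holds ", length(lines),
                    " values but partition has ", part$row_count, " rows"),
             "tad_corrupt_error")
  }
  deserialize_col(lines, kind)
}

#' Materialize a partition as a tibble
#' @inheritParams read_column
#' @export
partition_tbl <- function(part) {
  cols <- lapply(part$schema$name, function(nm) read_column(part, nm))
  names(cols) <- part$schema$name
  as_tibble(cols)
}

# coerce one input column to its kind; error names the offending row
coerce_col <- function(x, kind, column) {
  if (kind %in% c("text", "key", "char")) return(as.character(x))
  was_na <- is.na(x)
  if (is.numeric(x)) {
    out <- if (kind == "int") suppressWarnings(as.integer(x)) else as.numeric(x)
  } else if (kind == "int") {
    out <- suppressWarnings(as.integer(as.character(x)))
  } else {
    out <- suppressWarnings(as.numeric(as.character(x)))
  }
  bad <- which(is.na(out) & !was_na)
  if (length(bad)) {
    tad_stop(paste0("cannot coerce value '", as.character(x)[bad[1]],
                    "' in row ", bad[1], ", column ", column, " to ", kind),
             "tad_coerce_error")
  }
  out
}

#' Append rows to a partition
#'
#' Values are coerced to each column's kind; a value that cannot be coerced
#' aborts the whole append (nothing is written). Existing bytes of the column
#' files are never touched; any on-disk bitmap indexes become stale and are
#' rebuilt on next use.
#'
#' @param part a `tad_partition`.
#' @param rows data frame supplying a value (or NA) for every column.
#' @return number of rows appended (invisibly returns the updated handle as
#'   attribute `partition`).
#' @export
append_rows <- function(part, rows) {
  rows <- as_tibble(rows)
  if (nrow(rows) == 0L) return(0L)
  missing <- setdiff(part$schema$name, names(rows))
  if (length(missing)) {
    tad_stop(paste0("rows lack column(s): ", paste(missing, collapse = ", ")),
             "tad_column_error")
  }
  # coerce everything first: all-or-nothing
  ser <- vector("list", nrow(part$schema))
  for (i in seq_len(nrow(part$schema))) {
    nm <- part$schema$name[i]
    kind <- part$schema$kind[i]
    ser[[i]] <- serialize_col(coerce_col(rows[[nm]], kind, nm), kind)
  }
  for (i in seq_len(nrow(part$schema))) {
    con <- file(part_colfile(part$path, part$schema$name[i]), open = "a")
    writeLines(ser[[i]], con)
    close(con)
  }
  part$row_count <- part$row_count + nrow(rows)
  write_part_descriptor(part)
  n <- nrow(rows)
  attr(n, "partition") <- part
  n
}

#' Build (and persist) a bitmap equality index for a column
#'
#' @param part a `tad_partition`.
#' @param column a string-kind column (`key`, `char` or `text`).
#' @return a `tad_bitmap_index`.
#' @export
build_bitmap_index <- function(part, column) {
  kind <- part_kind(part, column)
  if (!kind %in% c("key", "char", "text")) {
    tad_stop(paste0("column ", column, " has kind ", kind,
                    "; bitmap indexes require a string kind"),
             "tad_column_error")
  }
  values <- as.character(read_column(part, column))
  idx <- bitmap_index_build(values, column)
  write_bitmap_index(part, idx)
  idx
}

write_bitmap_index <- function(part, idx) {
  lines <- c(paste0("rows\t", idx$n))
  for (v in idx$values) {
    bm <- idx$bitmaps[[v]]
    lines <- c(lines, paste0(v, "\t", bm$n, "\t",
                             paste(sprintf("%.0f", bm$words), collapse = ",")))
  }
  writeLines(lines, part_idxfile(part$path, idx$column))
}

# returns NULL when absent or stale (row count mismatch)
read_bitmap_index <- function(part, column) {
  f <- part_idxfile(part$path, column)
  if (!file.exists(f)) return(NULL)
  lines <- readLines(f)
  n <- as.integer(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]][2])
  if (n != part$row_count) return(NULL) # stale after append
  entries <- strsplit(lines[-1], "\t", fixed = TRUE)
  vals <- vapply(entries, `[`, character(1), 1L)
  bitmaps <- lapply(entries, function(e) {
    words <- if (is.na(e[3]) || e[3] == "") numeric(0) else as.numeric(strsplit(e[3], ",", fixed = TRUE)[[1]])
    structure(list(words = words, n = as.integer(e[2])), class = "tad_bitmap")
  })
  names(bitmaps) <- vals
  structure(list(column = column, values = vals, bitmaps = bitmaps, n = n),
            class = "tad_bitmap_index")
}

#' Delete rows matching a predicate conjunction, compacting the partition
#'
#' The partition is rewritten without the matching rows and all persisted
#' bitmap indexes are rebuilt. This is the one operation that rewrites files;
#' the append-only contract holds between deletions.
#'
#' @param part a `tad_partition`.
#' @param predicates either a predicate string such as
#'   `"sampleid = 'GGA_UD_1004'"` (the `where` grammar of [parse_query()]) or
#'   `NULL` to delete nothing.
#' @return number of rows removed.
#' @export
delete_rows <- function(part, predicates) {
  if (is.null(predicates)) return(0L)
  ast <- parse_query(paste("select * where", predicates))
  tbl <- partition_tbl(part)
  mask <- eval_predicates(tbl, ast$predicates, part, use_index = FALSE)
  removed <- sum(mask)
  if (removed == 0L) return(0L)
  keep <- tbl[!mask, , drop = FALSE]
  had_idx <- part$schema$name[file.exists(part_idxfile(part$path, part$schema$name))]
  for (i in seq_len(nrow(part$schema))) {
    nm <- part$schema$name[i]
    kind <- part$schema$kind[i]
    writeLines(serialize_col(keep[[nm]], kind), part_colfile(part$path, nm))
  }
  part$row_count <- nrow(keep)
  write_part_descriptor(part)
  for (nm in had_idx) {
    file.remove(part_idxfile(part$path, nm))
    build_bitmap_index(part, nm)
  }
  removed
}
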