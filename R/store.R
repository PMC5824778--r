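#' Store handles and installation
#'
#' A store is a directory holding the relational database file, a columnar
#' root (default folder name `transatlasfb`) with the three partitions
#' `variant`, `expression` and `readcount`, a flat `settings.txt` recording
#' the paths, and a `logs/` directory of transaction logs.
#'
#' @name tad-store
NULL

TAD_SETTINGS_FILE <- "settings.txt"
TAD_DEFAULT_COLUMNAR <- "transatlasfb"
TAD_PARTITIONS <- c("variant", "expression", "readcount")

# Table 4A: one row per variant-annotation observation
variant_schema <- function() tibble(
  name = c("sampleid", "chrom", "position", "refallele", "altallele",
           "quality", "dbsnpvariant", "variantclass", "zygosity", "source",
           "consequence", "geneid", "genename", "transcript", "feature",
           "genetype", "proteinposition", "aachange", "codonchange",
           "organism", "tissue"),
  kind = c("text", "key", "int", "char", "char",
           "double", "text", "key", "key", "text",
           "text", "text", "text", "text", "text",
           "text", "int", "text", "text",
           "text", "text")
)

# Table 4B: per-gene abundance
expression_schema <- function() tibble(
  name = c("sampleid", "chrom", "start", "stop", "genename", "geneid",
           "coverage", "tpm", "fpkm", "fpkmconflow", "fpkmconfhigh",
           "fpkmstatus", "organism", "tissue"),
  kind = c("text", "key", "int", "int", "text", "text",
           "double", "double", "double", "double", "double",
           "char", "text", "text")
)

# Table 4C: per-gene raw counts
readcount_schema <- function() tibble(
  name = c("sampleid", "genename", "readcount", "organism", "tissue"),
  kind = c("text", "text", "int", "text", "text")
)

partition_schemas <- function() list(
  variant = variant_schema(),
  expression = expression_schema(),
  readcount = readcount_schema()
)

# columns indexed by default: every "key" column plus sampleid
default_indexed_columns <- function(schema) {
  unique(c("sampleid", schema$name[schema$kind == "key"]))
}

#' Install a complete store (relational schema + columnar partitions)
#'
#' @param store_path directory for the store.
#' @param columnar_path columnar root; default is a folder named
#'   `transatlasfb` inside the store directory.
#' @param overwrite replace an existing store.
#' @return a `tad_store` handle, invisibly a `tad_schema_report` as
#'   attribute `schema_report`.
#' @export
tad_install <- function(store_path, columnar_path = NULL, overwrite = FALSE) {
  report <- create_schema(store_path, overwrite = overwrite)
  columnar_path <- columnar_path %||% file.path(store_path, TAD_DEFAULT_COLUMNAR)
  dir.create(columnar_path, recursive = TRUE, showWarnings = FALSE)
  schemas <- partition_schemas()
  for (nm in TAD_PARTITIONS) {
    pdir <- file.path(columnar_path, nm)
    if (overwrite && dir.exists(pdir)) unlink(pdir, recursive = TRUE)
    if (!file.exists(part_descriptor(pdir))) create_partition(pdir, schemas[[nm]])
  }
  logdir <- file.path(store_path, "logs")
  dir.create(logdir, showWarnings = FALSE)
  write_settings(store_path, list(
    relational = file.path(store_path, TAD_DB_FILE),
    columnar = columnar_path,
    logs = logdir
  ))
  store <- open_store(store_path)
  attr(store, "schema_report") <- report
  store
}

write_settings <- function(store_path, settings) {
  lines <- paste0(names(settings), "=", unlist(settings))
  writeLines(lines, file.path(store_path, TAD_SETTINGS_FILE))
}

read_settings <- function(store_path) {
  f <- file.path(store_path, TAD_SETTINGS_FILE)
  if (!file.exists(f)) tad_stop(paste0("no settings file at ", f), "tad_missing_error")
  lines <- readLines(f)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  stats::setNames(
    as.list(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))),
    vapply(kv, `[`, character(1), 1L)
  )
}

#' Open an installed store
#' @param store_path store directory.
#' @return a `tad_store` handle.
#' @export
open_store <- function(store_path) {
  settings <- read_settings(store_path)
  if (!file.exists(settings$relational)) {
    tad_stop(paste0("relational database missing: ", settings$relational),
             "tad_missing_error")
  }
  structure(
    list(path = store_path, settings = settings),
    class = "tad_store"
  )
}

as_tad_store <- function(store) {
  if (inherits(store, "tad_store")) store else open_store(store)
}

#' @export
print.tad_store <- function(x, ...) {
  cat("<tad_store> ", x$path, "\n  relational: ", x$settings$relational,
      "\n  columnar:   ", x$settings$columnar, "\n", sep = "")
  invisible(x)
}

# run fn(con) on a foreign-key-enforcing connection
with_store_con <- function(store, fn) {
  store <- as_tad_store(store)
  con <- DBI::dbConnect(RSQLite::SQLite(), store$settings$relational)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  fn(con)
}

store_partition <- function(store, name) {
  store <- as_tad_store(store)
  open_partition(file.path(store$settings$columnar, name))
}

# one timestamped line per transaction event
tad_log <- function(store, action, sample = "-", stage = "-",
                    parsed = NA, stored = NA, status = "ok") {
  store <- as_tad_store(store)
  logdir <- store$settings$logs
  dir.create(logdir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(logdir, "transactions.log")
  line <- sprintf("(%s) %s %s %s parsed=%s stored=%s %s",
                  tad_now(), action, sample, stage,
                  ifelse(is.na(parsed), "-", parsed),
                  ifelse(is.na(stored), "-", stored), status)
  cat(line, "\n", sep = "", file = f, append = TRUE)
  invisible(f)
}

read_log <- function(store) {
  f <- file.path(as_tad_store(store)$settings$logs, "transactions.log")
  if (!file.exists(f)) character(0) else readLines(f)
}
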