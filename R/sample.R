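#' Parse a sample name into its naming-scheme parts
#'
#' Sample names preferably follow the consortium naming scheme: short species
#' code, laboratory or institute short name, and an alphanumeric sample id,
#' joined by underscores — e.g. `GGA_UD_1004` is a *Gallus gallus* sample
#' from the University of Delaware with id 1004.
#'
#' @param name sample name.
#' @return tibble with columns `species_code`, `lab_code`, `sample_id`.
#' @export
#' @examples
#' parse_sample_name("GGA_UD_1004")
parse_sample_name <- function(name) {
  stopifnot(is_string(name))
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3L || any(!nzchar(parts))) {
    tad_stop(paste0(
      "sample name \"", name, "\" does not follow the naming scheme ",
      "<species>_<lab>_<id> (three underscore-separated parts)"),
      "tad_naming_error")
  }
  tibble(species_code = parts[1], lab_code = parts[2], sample_id = parts[3])
}

# Table 1 display names for validation messages
TAD_META_REQUIRED <- c(
  sample_name = "Sample name",
  derived_from = "Derived from",
  organism = "Organism",
  organism_part = "Organism part"
)
TAD_META_OPTIONAL <- c(
  description = "Sample description",
  first_name = "First name",
  middle_initial = "Middle initial",
  last_name = "Last name",
  organization = "Organization"
)

validate_sample_record <- function(record) {
  for (fld in names(TAD_META_REQUIRED)) {
    v <- record[[fld]]
    if (is.null(v) || is.na(v) || !nzchar(trimws(as.character(v)))) {
      tad_stop(paste0("missing required field \"", TAD_META_REQUIRED[[fld]], "\""),
               "tad_validation_error", field = TAD_META_REQUIRED[[fld]])
    }
  }
  invisible(record)
}

get_or_create <- function(con, table, key_col, value, id_col) {
  if (is.null(value) || is.na(value) || !nzchar(as.character(value))) return(NA_integer_)
  row <- DBI::dbGetQuery(
    con, sprintf("SELECT %s AS id FROM %s WHERE %s = :v", id_col, table, key_col),
    params = list(v = value))
  if (nrow(row)) return(as.integer(row$id[1]))
  DBI::dbExecute(
    con, sprintf("INSERT INTO %s (%s) VALUES (:v)", table, key_col),
    params = list(v = value))
  as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1])
}

sample_key <- function(con, sample_name) {
  row <- DBI::dbGetQuery(con, "SELECT sampleid FROM Sample WHERE samplename = :s",
                         params = list(s = sample_name))
  if (!nrow(row)) return(NA_integer_)
  as.integer(row$sampleid[1])
}

insert_sample_con <- function(con, record) {
  record <- as.list(record)
  validate_sample_record(record)
  if (!is.na(sample_key(con, record$sample_name))) {
    tad_stop(paste0("sample \"", record$sample_name, "\" already exists"),
             "tad_unique_error")
  }
  # naming-scheme check warns but does not block the import
  tryCatch(parse_sample_name(record$sample_name),
           tad_naming_error = function(e) warn(conditionMessage(e)))
  organismid <- get_or_create(con, "Organism", "organism", record$organism, "organismid")
  tissueid <- get_or_create(con, "Tissue", "tissue", record$organism_part, "tissueid")
  breedid <- get_or_create(con, "Breed", "breed", record$breed %||% NA, "breedid")
  sexid <- get_or_create(con, "Sex", "sex", record$sex %||% NA, "sexid")
  stageid <- get_or_create(con, "DevelopmentalStage", "stage",
                           record$developmental_stage %||% NA, "stageid")
  statusid <- get_or_create(con, "HealthStatus", "status",
                            record$health_status %||% NA, "statusid")
  materialid <- get_or_create(con, "Material", "material",
                              record$material %||% NA, "materialid")

  animal <- DBI::dbGetQuery(con, "SELECT animalid FROM Animal WHERE animalname = :a",
                            params = list(a = record$derived_from))
  if (nrow(animal)) {
    animalid <- as.integer(animal$animalid[1])
  } else {
    DBI::dbExecute(con,
      "INSERT INTO Animal (animalname, organismid, breedid, sexid, stageid, statusid)
       VALUES (:a, :o, :b, :x, :st, :h)",
      params = list(a = record$derived_from, o = organismid, b = breedid,
                    x = sexid, st = stageid, h = statusid))
    animalid <- as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1])
  }
  DBI::dbExecute(con,
    "INSERT INTO Sample (samplename, animalid, tissueid, materialid, description, loaddate)
     VALUES (:s, :a, :t, :m, :d, :l)",
    params = list(s = record$sample_name, a = animalid, t = tissueid,
                  m = materialid, d = record$description %||% NA,
                  l = tad_now()))
  sid <- as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1])

  has_person <- any(nzchar(trimws(as.character(
    c(record$first_name %||% "", record$last_name %||% "")))))
  if (has_person) {
    p <- DBI::dbGetQuery(con,
      "SELECT personid FROM Person
       WHERE COALESCE(firstname,'') = COALESCE(:f,'')
         AND COALESCE(middleinitial,'') = COALESCE(:m,'')
         AND COALESCE(lastname,'') = COALESCE(:l,'')",
      params = list(f = record$first_name %||% NA, m = record$middle_initial %||% NA,
                    l = record$last_name %||% NA))
    if (nrow(p)) personid <- as.integer(p$personid[1]) else {
      DBI::dbExecute(con,
        "INSERT INTO Person (firstname, middleinitial, lastname) VALUES (:f, :m, :l)",
        params = list(f = record$first_name %||% NA,
                      m = record$middle_initial %||% NA,
                      l = record$last_name %||% NA))
      personid <- as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1])
    }
    DBI::dbExecute(con, "INSERT INTO SamplePerson (sampleid, personid) VALUES (:s, :p)",
                   params = list(s = sid, p = personid))
  }
  orgid <- get_or_create(con, "Organization", "organizationname",
                         record$organization %||% NA, "organizationid")
  if (!is.na(orgid)) {
    DBI::dbExecute(con,
      "INSERT INTO SampleOrganization (sampleid, organizationid) VALUES (:s, :o)",
      params = list(s = sid, o = orgid))
  }
  sid
}

#' Insert one sample record into the relational store
#'
#' Dimension rows (organism, tissue, breed, person, organization, ...) are
#' get-or-created by exact, case-sensitive match, so N samples sharing an
#' organism yield exactly one Organism row.
#'
#' @param store a `tad_store`.
#' @param record named list or one-row data frame with fields `sample_name`,
#'   `derived_from`, `organism`, `organism_part` (required) and
#'   `description`, `first_name`, `middle_initial`, `last_name`,
#'   `organization`, `breed`, `sex`, `developmental_stage`, `health_status`,
#'   `material` (optional).
#' @return internal integer sample key.
#' @export
insert_sample <- function(store, record) {
  store <- as_tad_store(store)
  if (is.data.frame(record)) record <- as.list(record[1L, , drop = FALSE])
  with_store_con(store, function(con) insert_sample_con(con, record))
}

# header-name normalization shared by the TSV and workbook readers
normalize_meta_names <- function(nms) {
  canon <- c(TAD_META_REQUIRED, TAD_META_OPTIONAL)
  key <- tolower(gsub("[^a-z]", "", tolower(nms)))
  lookup <- stats::setNames(names(canon), tolower(gsub("[^a-z]", "", tolower(canon))))
  out <- unname(lookup[key])
  ifelse(is.na(out), nms, out)
}

#' Parse a sample-metadata file into sample records
#'
#' Accepts either the two-sheet (Animal + Specimen) consortium workbook or a
#' tab-delimited file whose header carries at least the four required
#' columns: `Sample name`, `Derived from`, `Organism`, `Organism part`.
#' Unknown columns are ignored with a warning.
#'
#' @param path metadata file.
#' @param format `"auto"` (by extension), `"faang"` (xlsx workbook) or
#'   `"tsv"`.
#' @return tibble of sample records (one per specimen).
#' @export
parse_sample_metadata <- function(path, format = c("auto", "faang", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) tad_stop(paste0("no such file: ", path), "tad_missing_error")
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "faang" else "tsv"
  }
  if (format == "faang") parse_metadata_workbook(path) else parse_metadata_tsv(path)
}

parse_metadata_tsv <- function(path) {
  df <- suppressMessages(readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                                         progress = FALSE))
  if (nrow(df) == 0L && ncol(df) == 0L) tad_stop("empty metadata file", "tad_validation_error")
  nms <- normalize_meta_names(names(df))
  unknown <- names(df)[!nms %in% c(names(TAD_META_REQUIRED), names(TAD_META_OPTIONAL))]
  if (length(unknown)) {
    warn(paste0("ignoring unknown metadata column(s): ",
                paste(unknown, collapse = ", ")))
  }
  names(df) <- nms
  for (fld in names(TAD_META_REQUIRED)) {
    if (!fld %in% names(df)) {
      tad_stop(paste0("missing required column \"", TAD_META_REQUIRED[[fld]], "\""),
               "tad_validation_error", field = TAD_META_REQUIRED[[fld]])
    }
  }
  keep <- intersect(c(names(TAD_META_REQUIRED), names(TAD_META_OPTIONAL)), names(df))
  out <- as_tibble(df[, keep, drop = FALSE])
  purrr::walk(seq_len(nrow(out)), function(i) validate_sample_record(as.list(out[i, ])))
  out
}

parse_metadata_workbook <- function(path) {
  sheets <- readxl::excel_sheets(path)
  for (needed in c("Animal", "Specimen")) {
    if (!needed %in% sheets) {
      tad_stop(paste0("workbook lacks required sheet \"", needed, "\""),
               "tad_validation_error")
    }
  }
  animal <- readxl::read_excel(path, sheet = "Animal", col_types = "text")
  specimen <- readxl::read_excel(path, sheet = "Specimen", col_types = "text")
  names(animal) <- normalize_meta_names(names(animal))
  names(specimen) <- normalize_meta_names(names(specimen))
  for (fld in c("sample_name", "organism")) {
    if (!fld %in% names(animal)) {
      tad_stop(paste0("Animal sheet lacks column \"",
                      c(TAD_META_REQUIRED, TAD_META_OPTIONAL)[[fld]], "\""),
               "tad_validation_error")
    }
  }
  for (fld in c("sample_name", "derived_from", "organism_part")) {
    if (!fld %in% names(specimen)) {
      tad_stop(paste0("Specimen sheet lacks column \"",
                      TAD_META_REQUIRED[[fld]], "\""), "tad_validation_error")
    }
  }
  # specimen rows are the samples; 'Derived from' links to an Animal row
  animal_small <- tibble(
    derived_from = animal$sample_name,
    organism = animal$organism,
    breed = if ("breed" %in% names(animal)) animal$breed else NA_character_,
    sex = if ("sex" %in% names(animal)) animal$sex else NA_character_
  )
  out <- dplyr::left_join(as_tibble(specimen), animal_small, by = "derived_from")
  if ("organism.y" %in% names(out)) {
    out$organism <- dplyr::coalesce(out$organism.y, out$organism.x)
    out$organism.x <- out$organism.y <- NULL
  }
  keep <- intersect(c(names(TAD_META_REQUIRED), names(TAD_META_OPTIONAL),
                      "breed", "sex"), names(out))
  out <- out[, keep, drop = FALSE]
  purrr::walk(seq_len(nrow(out)), function(i) validate_sample_record(as.list(out[i, ])))
  out
}

#' Import a metadata file: one relational sample per specimen row
#' @param store a `tad_store`.
#' @param path metadata file (workbook or TSV).
#' @inheritParams parse_sample_metadata
#' @return tibble with `sample_name` and internal `key`.
#' @export
import_metadata <- function(store, path, format = "auto") {
  store <- as_tad_store(store)
  records <- parse_sample_metadata(path, format)
  keys <- integer(nrow(records))
  with_store_con(store, function(con) {
    DBI::dbWithTransaction(con, {
      for (i in seq_len(nrow(records))) {
        keys[i] <<- insert_sample_con(con, as.list(records[i, ]))
      }
    })
  })
  tad_log(store, "metadata", sample = paste(records$sample_name, collapse = ","),
          stage = "metadata", parsed = nrow(records), stored = nrow(records))
  tibble(sample_name = records$sample_name, key = keys)
}
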