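#' Relational schema: 23 tables, 6 views, 4 named procedures
#'
#' The relational side of a store is an embedded SQLite database holding
#' sample metadata, lookup dimensions (organism, breed, sex, developmental
#' stage, health status, material, tissue), per-sample analysis summaries
#' (MapStats, Metadata, CommandSyntax, GeneStats, ReadCounts, VarSummary) and
#' the per-variant detail tables (VarResult, VarAnnotation), tied together by
#' parent-child foreign keys. Six views and four named parameterized queries
#' ("procedures" `usp_vall`, `usp_vchrom`, `usp_vchrposition`, `usp_vgene`)
#' are registered on top.
#'
#' @name relational-schema
NULL

TAD_DB_FILE <- "relational.sqlite"

tad_tables_ddl <- function() c(
  Organism = "CREATE TABLE Organism (
    organismid INTEGER PRIMARY KEY,
    organism TEXT NOT NULL UNIQUE)",
  Breed = "CREATE TABLE Breed (
    breedid INTEGER PRIMARY KEY,
    breed TEXT NOT NULL UNIQUE)",
  Sex = "CREATE TABLE Sex (
    sexid INTEGER PRIMARY KEY,
    sex TEXT NOT NULL UNIQUE)",
  DevelopmentalStage = "CREATE TABLE DevelopmentalStage (
    stageid INTEGER PRIMARY KEY,
    stage TEXT NOT NULL UNIQUE)",
  HealthStatus = "CREATE TABLE HealthStatus (
    statusid INTEGER PRIMARY KEY,
    status TEXT NOT NULL UNIQUE)",
  Material = "CREATE TABLE Material (
    materialid INTEGER PRIMARY KEY,
    material TEXT NOT NULL UNIQUE)",
  Tissue = "CREATE TABLE Tissue (
    tissueid INTEGER PRIMARY KEY,
    tissue TEXT NOT NULL UNIQUE)",
  Animal = "CREATE TABLE Animal (
    animalid INTEGER PRIMARY KEY,
    animalname TEXT NOT NULL UNIQUE,
    organismid INTEGER NOT NULL REFERENCES Organism(organismid),
    breedid INTEGER REFERENCES Breed(breedid),
    sexid INTEGER REFERENCES Sex(sexid),
    stageid INTEGER REFERENCES DevelopmentalStage(stageid),
    statusid INTEGER REFERENCES HealthStatus(statusid))",
  AnimalStats = "CREATE TABLE AnimalStats (
    animalstatid INTEGER PRIMARY KEY,
    animalid INTEGER NOT NULL REFERENCES Animal(animalid),
    attribute TEXT NOT NULL,
    value TEXT)",
  Sample = "CREATE TABLE Sample (
    sampleid INTEGER PRIMARY KEY,
    samplename TEXT NOT NULL UNIQUE,
    animalid INTEGER NOT NULL REFERENCES Animal(animalid),
    tissueid INTEGER NOT NULL REFERENCES Tissue(tissueid),
    materialid INTEGER REFERENCES Material(materialid),
    description TEXT,
    loaddate TEXT)",
  SampleStats = "CREATE TABLE SampleStats (
    samplestatid INTEGER PRIMARY KEY,
    sampleid INTEGER NOT NULL REFERENCES Sample(sampleid),
    attribute TEXT NOT NULL,
    value TEXT)",
  Person = "CREATE TABLE Person (
    personid INTEGER PRIMARY KEY,
    firstname TEXT,
    middleinitial TEXT,
    lastname TEXT)",
  Organization = "CREATE TABLE Organization (
    organizationid INTEGER PRIMARY KEY,
    organizationname TEXT NOT NULL UNIQUE)",
  SamplePerson = "CREATE TABLE SamplePerson (
    sampleid INTEGER NOT NULL REFERENCES Sample(sampleid),
    personid INTEGER NOT NULL REFERENCES Person(personid),
    PRIMARY KEY (sampleid, personid))",
  SampleOrganization = "CREATE TABLE SampleOrganization (
    sampleid INTEGER NOT NULL REFERENCES Sample(sampleid),
    organizationid INTEGER NOT NULL REFERENCES Organization(organizationid),
    PRIMARY KEY (sampleid, organizationid))",
  MapStats = "CREATE TABLE MapStats (
    sampleid INTEGER PRIMARY KEY REFERENCES Sample(sampleid),
    totalreads INTEGER,
    mappedreads INTEGER,
    alignmentrate REAL,
    mappername TEXT,
    rundate TEXT,
    loaddate TEXT)",
  Metadata = "CREATE TABLE Metadata (
    sampleid INTEGER PRIMARY KEY REFERENCES Sample(sampleid),
    mappername TEXT,
    quantifiername TEXT,
    countername TEXT,
    callername TEXT,
    annotationsource TEXT,
    loaddate TEXT)",
  CommandSyntax = "CREATE TABLE CommandSyntax (
    syntaxid INTEGER PRIMARY KEY,
    sampleid INTEGER NOT NULL REFERENCES Sample(sampleid),
    stage TEXT NOT NULL CHECK (stage IN
      ('alignment','expression','counts','variants','annotation')),
    toolname TEXT,
    invocation TEXT)",
  GeneStats = "CREATE TABLE GeneStats (
    sampleid INTEGER PRIMARY KEY REFERENCES Sample(sampleid),
    genesquantified INTEGER,
    quantifiername TEXT,
    units TEXT,
    loaddate TEXT)",
  ReadCounts = "CREATE TABLE ReadCounts (
    sampleid INTEGER PRIMARY KEY REFERENCES Sample(sampleid),
    genescounted INTEGER,
    countername TEXT,
    specialrows INTEGER,
    loaddate TEXT)",
  VarSummary = "CREATE TABLE VarSummary (
    sampleid INTEGER PRIMARY KEY REFERENCES Sample(sampleid),
    totalvariants INTEGER,
    snpcount INTEGER,
    insertioncount INTEGER,
    deletioncount INTEGER,
    othercount INTEGER DEFAULT 0,
    callername TEXT,
    annotationsource TEXT,
    loaddate TEXT)",
  VarResult = "CREATE TABLE VarResult (
    varid INTEGER PRIMARY KEY,
    sampleid INTEGER NOT NULL REFERENCES Sample(sampleid),
    chrom TEXT,
    position INTEGER,
    refallele TEXT,
    altallele TEXT,
    quality REAL,
    dbsnpvariant TEXT,
    variantclass TEXT,
    zygosity TEXT)",
  VarAnnotation = "CREATE TABLE VarAnnotation (
    varannoid INTEGER PRIMARY KEY,
    varid INTEGER NOT NULL REFERENCES VarResult(varid),
    source TEXT,
    consequence TEXT,
    geneid TEXT,
    genename TEXT,
    transcript TEXT,
    feature TEXT,
    genetype TEXT,
    proteinposition INTEGER,
    aachange TEXT,
    codonchange TEXT)"
)

tad_views_ddl <- function() c(
  vw_sample = "CREATE VIEW vw_sample AS
    SELECT s.samplename, s.description, a.animalname, o.organism, t.tissue,
           p.firstname, p.middleinitial, p.lastname, g.organizationname
    FROM Sample s
    JOIN Animal a ON a.animalid = s.animalid
    JOIN Organism o ON o.organismid = a.organismid
    JOIN Tissue t ON t.tissueid = s.tissueid
    LEFT JOIN SamplePerson sp ON sp.sampleid = s.sampleid
    LEFT JOIN Person p ON p.personid = sp.personid
    LEFT JOIN SampleOrganization so ON so.sampleid = s.sampleid
    LEFT JOIN Organization g ON g.organizationid = so.organizationid",
  vw_sampleinfo = "CREATE VIEW vw_sampleinfo AS
    SELECT s.samplename, o.organism, t.tissue,
           m.totalreads, m.mappedreads, m.alignmentrate, m.mappername,
           e.genesquantified, e.quantifiername,
           v.totalvariants, v.snpcount, v.insertioncount, v.deletioncount,
           v.callername, v.annotationsource
    FROM Sample s
    JOIN Animal a ON a.animalid = s.animalid
    JOIN Organism o ON o.organismid = a.organismid
    JOIN Tissue t ON t.tissueid = s.tissueid
    LEFT JOIN MapStats m ON m.sampleid = s.sampleid
    LEFT JOIN GeneStats e ON e.sampleid = s.sampleid
    LEFT JOIN VarSummary v ON v.sampleid = s.sampleid",
  vw_seqstats = "CREATE VIEW vw_seqstats AS
    SELECT s.samplename, ms.mappername, ms.totalreads, ms.mappedreads,
           ms.alignmentrate, ms.rundate, md.quantifiername, md.countername,
           md.callername, md.annotationsource
    FROM Sample s
    LEFT JOIN MapStats ms ON ms.sampleid = s.sampleid
    LEFT JOIN Metadata md ON md.sampleid = s.sampleid",
  vw_vanno = "CREATE VIEW vw_vanno AS
    SELECT s.samplename, r.chrom, r.position, r.refallele, r.altallele,
           r.quality, r.dbsnpvariant, r.variantclass, r.zygosity,
           an.source, an.consequence, an.geneid, an.genename, an.transcript,
           an.feature, an.genetype, an.proteinposition, an.aachange,
           an.codonchange
    FROM VarResult r
    JOIN VarAnnotation an ON an.varid = r.varid
    JOIN Sample s ON s.sampleid = r.sampleid",
  vw_vvcf = "CREATE VIEW vw_vvcf AS
    SELECT r.chrom, r.position, r.dbsnpvariant, r.refallele, r.altallele,
           r.quality, an.source, an.consequence, an.geneid, an.genename,
           an.transcript, an.feature, an.genetype, an.proteinposition,
           an.aachange, an.codonchange,
           s.samplename, o.organism, t.tissue
    FROM VarResult r
    LEFT JOIN VarAnnotation an ON an.varid = r.varid
    JOIN Sample s ON s.sampleid = r.sampleid
    JOIN Animal a ON a.animalid = s.animalid
    JOIN Organism o ON o.organismid = a.organismid
    JOIN Tissue t ON t.tissueid = s.tissueid",
  vw_nosql = "CREATE VIEW vw_nosql AS
    SELECT s.samplename AS sampleid, r.chrom, r.position, r.refallele,
           r.altallele, r.quality, r.dbsnpvariant, r.variantclass,
           r.zygosity, an.source, an.consequence, an.geneid, an.genename,
           an.transcript, an.feature, an.genetype, an.proteinposition,
           an.aachange, an.codonchange, o.organism, t.tissue
    FROM VarResult r
    LEFT JOIN VarAnnotation an ON an.varid = r.varid
    JOIN Sample s ON s.sampleid = r.sampleid
    JOIN Animal a ON a.animalid = s.animalid
    JOIN Organism o ON o.organismid = a.organismid
    JOIN Tissue t ON t.tissueid = s.tissueid"
)

# the four named procedures: parameterized selects over vw_nosql
tad_procedures <- function() list(
  usp_vall = list(
    sql = "SELECT * FROM vw_nosql",
    params = character(0)
  ),
  usp_vchrom = list(
    sql = "SELECT * FROM vw_nosql WHERE chrom = :chrom",
    params = "chrom"
  ),
  usp_vchrposition = list(
    sql = "SELECT * FROM vw_nosql WHERE chrom = :chrom
           AND position >= :start AND position <= :stop",
    params = c("chrom", "start", "stop")
  ),
  usp_vgene = list(
    sql = "SELECT * FROM vw_nosql WHERE genename LIKE :genename",
    params = "genename"
  )
)

# (child table, child fk column, parent table, parent key column)
tad_relationships <- function() {
  rel <- rbind(
    c("Animal", "organismid", "Organism", "organismid", "required"),
    c("Animal", "breedid", "Breed", "breedid", "optional"),
    c("Animal", "sexid", "Sex", "sexid", "optional"),
    c("Animal", "stageid", "DevelopmentalStage", "stageid", "optional"),
    c("Animal", "statusid", "HealthStatus", "statusid", "optional"),
    c("AnimalStats", "animalid", "Animal", "animalid", "required"),
    c("Sample", "animalid", "Animal", "animalid", "required"),
    c("Sample", "tissueid", "Tissue", "tissueid", "required"),
    c("Sample", "materialid", "Material", "materialid", "optional"),
    c("SampleStats", "sampleid", "Sample", "sampleid", "required"),
    c("SamplePerson", "sampleid", "Sample", "sampleid", "required"),
    c("SamplePerson", "personid", "Person", "personid", "required"),
    c("SampleOrganization", "sampleid", "Sample", "sampleid", "required"),
    c("SampleOrganization", "organizationid", "Organization", "organizationid", "required"),
    c("MapStats", "sampleid", "Sample", "sampleid", "required"),
    c("Metadata", "sampleid", "Sample", "sampleid", "required"),
    c("CommandSyntax", "sampleid", "Sample", "sampleid", "required"),
    c("GeneStats", "sampleid", "Sample", "sampleid", "required"),
    c("ReadCounts", "sampleid", "Sample", "sampleid", "required"),
    c("VarSummary", "sampleid", "Sample", "sampleid", "required"),
    c("VarResult", "sampleid", "Sample", "sampleid", "required"),
    c("VarAnnotation", "varid", "VarResult", "varid", "required")
  )
  tibble(child = rel[, 1], fk = rel[, 2], parent = rel[, 3], pk = rel[, 4],
         required = rel[, 5] == "required")
}

#' Create the relational schema of a new store
#'
#' Creates the store directory (if needed) and an embedded relational
#' database with all 23 tables, 6 views and 4 registered named queries.
#'
#' @param store_path directory for the store.
#' @param overwrite replace an existing relational database.
#' @return a `tad_schema_report`: list with `table_names`, `view_names`,
#'   `procedure_names`.
#' @export
#' @examples
#' rep <- create_schema(file.path(tempdir(), "schema_demo"), overwrite = TRUE)
#' length(rep$table_names)
create_schema <- function(store_path, overwrite = FALSE) {
  db <- file.path(store_path, TAD_DB_FILE)
  if (file.exists(db)) {
    if (!overwrite) tad_stop(paste0("store exists at ", store_path), "tad_exists_error")
    file.remove(db)
  }
  dir.create(store_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(store_path)) {
    tad_stop(paste0("cannot create store directory ", store_path), "tad_io_error")
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con))
  for (ddl in tad_tables_ddl()) DBI::dbExecute(con, ddl)
  for (ddl in tad_views_ddl()) DBI::dbExecute(con, ddl)
  report <- structure(
    list(
      table_names = sort(names(tad_tables_ddl())),
      view_names = sort(names(tad_views_ddl())),
      procedure_names = names(tad_procedures())
    ),
    class = "tad_schema_report"
  )
  report
}

#' @export
print.tad_schema_report <- function(x, ...) {
  cat("<tad_schema_report>\n",
      " tables:     ", length(x$table_names), "\n",
      " views:      ", length(x$view_names), "\n",
      " procedures: ", length(x$procedure_names), "\n", sep = "")
  invisible(x)
}

#' Report referential-integrity violations
#'
#' Centralized check of every parent-child key relationship in the schema.
#' Runs explicit anti-joins rather than relying on the engine's own
#' constraint state, so orphans introduced by raw row surgery are caught.
#'
#' @param store a `tad_store` (or store path).
#' @return tibble with columns `child_table`, `row_key`, `fk_column`,
#'   `missing_parent`; zero rows when the store is consistent.
#' @export
check_referential_integrity <- function(store) {
  store <- as_tad_store(store)
  rel <- tad_relationships()
  out <- list()
  with_store_con(store, function(con) {
    for (i in seq_len(nrow(rel))) {
      sql <- sprintf(
        "SELECT c.rowid AS row_key, c.%s AS fk_value FROM %s c
         LEFT JOIN %s p ON p.%s = c.%s
         WHERE c.%s IS NOT NULL AND p.%s IS NULL",
        rel$fk[i], rel$child[i], rel$parent[i], rel$pk[i], rel$fk[i],
        rel$fk[i], rel$pk[i]
      )
      bad <- DBI::dbGetQuery(con, sql)
      if (nrow(bad)) {
        out[[length(out) + 1L]] <<- tibble(
          child_table = rel$child[i],
          row_key = as.integer(bad$row_key),
          fk_column = rel$fk[i],
          missing_parent = rel$parent[i]
        )
      }
    }
  })
  if (length(out)) dplyr::bind_rows(out) else {
    tibble(child_table = character(0), row_key = integer(0),
           fk_column = character(0), missing_parent = character(0))
  }
}
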