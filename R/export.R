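#' Run one of the six registered views
#'
#' @param store a `tad_store`.
#' @param view_name one of `vw_sample`, `vw_nosql`, `vw_sampleinfo`,
#'   `vw_seqstats`, `vw_vanno`, `vw_vvcf`.
#' @return tibble of the view's rows.
#' @export
run_view <- function(store, view_name) {
  store <- as_tad_store(store)
  if (!view_name %in% names(tad_views_ddl())) {
    tad_stop(paste0("unknown view \"", view_name, "\"; available: ",
                    paste(names(tad_views_ddl()), collapse = ", ")),
             "tad_unknown_view_error")
  }
  with_store_con(store, function(con) {
    as_tibble(DBI::dbGetQuery(con, paste0("SELECT * FROM ", view_name)))
  })
}

#' Run a raw SQL query against the relational store
#' @param store a `tad_store`.
#' @param sql a select statement.
#' @return tibble.
#' @export
store_query <- function(store, sql) {
  with_store_con(as_tad_store(store), function(con) {
    as_tibble(DBI::dbGetQuery(con, sql))
  })
}

#' Select variants by scope (the four named procedures)
#'
#' One selector implements the four registered procedures: all variants
#' (`usp_vall`), one chromosome (`usp_vchrom`), an inclusive 1-based
#' chromosomal region (`usp_vchrposition`) and a gene (`usp_vgene`, matched
#' by the fuzzy rule: case-insensitive substring, or exact match with
#' `fuzzy = FALSE`).
#'
#' @param store a `tad_store`.
#' @param scope `"all"`, or a named list: `list(chrom = "1")`,
#'   `list(chrom = "1", start = 100, stop = 200)` or `list(gene = "OPTN")`.
#' @param fuzzy substring gene matching (default TRUE).
#' @return tibble in columnar field order (sampleid ... tissue).
#' @export
variants_select <- function(store, scope = "all", fuzzy = TRUE) {
  store <- as_tad_store(store)
  procs <- tad_procedures()
  with_store_con(store, function(con) {
    if (identical(scope, "all")) {
      return(as_tibble(DBI::dbGetQuery(con, procs$usp_vall$sql)))
    }
    if (!is.list(scope)) tad_stop("scope must be \"all\" or a named list", "tad_scope_error")
    if (!is.null(scope$gene)) {
      pat <- if (fuzzy) paste0("%", scope$gene, "%") else scope$gene
      return(as_tibble(DBI::dbGetQuery(con, procs$usp_vgene$sql,
                                       params = list(genename = pat))))
    }
    if (!is.null(scope$chrom) && !is.null(scope$start)) {
      if (scope$start > scope$stop) {
        tad_stop("region start must not exceed stop", "tad_scope_error")
      }
      return(as_tibble(DBI::dbGetQuery(con, procs$usp_vchrposition$sql,
        params = list(chrom = scope$chrom, start = scope$start, stop = scope$stop))))
    }
    if (!is.null(scope$chrom)) {
      return(as_tibble(DBI::dbGetQuery(con, procs$usp_vchrom$sql,
                                       params = list(chrom = scope$chrom))))
    }
    tad_stop("unknown scope kind", "tad_scope_error")
  })
}

expression_nonnull <- function(store) {
  tbl <- partition_tbl(store_partition(as_tad_store(store), "expression"))
  tbl$abundance <- ifelse(is.nan(tbl$fpkm), tbl$tpm, tbl$fpkm)
  tbl$abundance_units <- ifelse(is.nan(tbl$fpkm), "TPM", "FPKM")
  tbl
}

#' Per-tissue expression summary of selected genes
#'
#' One row per (gene, tissue) with the minimum, arithmetic mean and maximum
#' abundance over the samples of that tissue (FPKM when the quantifier
#' provides it, TPM otherwise); samples with missing abundance are excluded
#' from all three statistics; empty groups are omitted.
#'
#' @param store a `tad_store`.
#' @param genes character vector of gene names (fuzzy-matched).
#' @param fuzzy substring matching (default TRUE).
#' @return tibble `genename`, `tissue`, `sample_count`, `min_fpkm`,
#'   `avg_fpkm`, `max_fpkm`.
#' @export
export_avgfpkm <- function(store, genes, fuzzy = TRUE) {
  stopifnot(length(genes) >= 1L)
  tbl <- expression_nonnull(store)
  hit <- rep(FALSE, nrow(tbl))
  for (g in genes) {
    hit <- hit | if (fuzzy) {
      grepl(g, tbl$genename, ignore.case = TRUE, fixed = FALSE)
    } else tbl$genename == g
  }
  tbl <- tbl[hit & !is.nan(tbl$abundance) & tbl$genename != "NULL", , drop = FALSE]
  if (!nrow(tbl)) {
    warn(paste0("no gene matches: ", paste(genes, collapse = ", ")))
    return(tibble(genename = character(0), tissue = character(0),
                  sample_count = integer(0), min_fpkm = numeric(0),
                  avg_fpkm = numeric(0), max_fpkm = numeric(0)))
  }
  tbl |>
    dplyr::group_by(.data$genename, .data$tissue) |>
    dplyr::summarise(
      sample_count = dplyr::n(),
      min_fpkm = min(.data$abundance),
      avg_fpkm = sum(.data$abundance) / dplyr::n(),
      max_fpkm = max(.data$abundance),
      .groups = "drop"
    )
}

#' Gene-by-sample expression matrix for one organism
#'
#' Rows are genes, columns the selected samples of the organism, cells the
#' FPKM (or TPM when FPKM is absent). Genes missing from a sample come back
#' as NA (or 0 with `absent = "zero"`).
#'
#' @param store a `tad_store`.
#' @param organism organism name (must exist in the store).
#' @param samples optional sample names to keep (must belong to organism).
#' @param absent `"na"` or `"zero"` for genes not quantified in a sample.
#' @return tibble with `genename` plus one column per sample.
#' @export
export_genexp <- function(store, organism, samples = NULL,
                          absent = c("na", "zero")) {
  absent <- match.arg(absent)
  store <- as_tad_store(store)
  known <- store_query(store,
    "SELECT s.samplename, o.organism FROM Sample s
     JOIN Animal a ON a.animalid = s.animalid
     JOIN Organism o ON o.organismid = a.organismid")
  if (!organism %in% known$organism) {
    tad_stop(paste0("unknown organism \"", organism, "\""), "tad_unknown_error")
  }
  org_samples <- known$samplename[known$organism == organism]
  if (is.null(samples)) {
    samples <- org_samples
  } else {
    bad <- setdiff(samples, org_samples)
    if (length(bad)) {
      tad_stop(paste0("sample ", bad[1], " does not belong to organism ",
                      organism), "tad_scope_error")
    }
  }
  tbl <- expression_nonnull(store)
  tbl <- tbl[tbl$organism == organism & tbl$sampleid %in% samples &
               tbl$genename != "NULL", , drop = FALSE]
  wide <- tbl |>
    dplyr::distinct(.data$genename, .data$sampleid, .keep_all = TRUE) |>
    dplyr::select("genename", "sampleid", "abundance") |>
    tidyr::pivot_wider(names_from = "sampleid", values_from = "abundance")
  for (s in setdiff(samples, names(wide))) wide[[s]] <- NA_real_
  wide <- wide[, c("genename", samples), drop = FALSE]
  if (absent == "zero") {
    wide <- dplyr::mutate(wide, dplyr::across(-"genename",
                                              ~ ifelse(is.na(.x), 0, .x)))
  }
  dplyr::arrange(wide, .data$genename)
}

#' Per-sample, per-chromosome variant counts
#'
#' Counts distinct variants (position, ref, alt) per sample and chromosome,
#' optionally restricted to selected chromosomes. Unrestricted per-sample
#' totals equal the stored VarSummary totals and the per-sample distinct
#' variant count of the columnar partition.
#'
#' @param store a `tad_store`.
#' @param chroms optional chromosome labels.
#' @return tibble `sampleid`, `chrom`, `variant_count`.
#' @export
export_chrvar <- function(store, chroms = NULL) {
  tbl <- partition_tbl(store_partition(as_tad_store(store), "variant"))
  if (!nrow(tbl)) {
    return(tibble(sampleid = character(0), chrom = character(0),
                  variant_count = integer(0)))
  }
  if (!is.null(chroms)) tbl <- tbl[tbl$chrom %in% chroms, , drop = FALSE]
  tbl |>
    dplyr::distinct(.data$sampleid, .data$chrom, .data$position,
                    .data$refallele, .data$altallele) |>
    dplyr::count(.data$sampleid, .data$chrom, name = "variant_count")
}

#' Export variants with annotations as TSV rows or an annotated VCF
#'
#' The TSV form returns the columnar field set joined with annotations. The
#' VCF form writes one record per (sample, chrom, position, ref, alt) with
#' every annotation of the variant packed into the INFO key `CSQ`
#' (comma-separated entries; `|`-separated subfields in the header-declared
#' order source|consequence|geneid|genename|transcript|feature|genetype|
#' proteinposition|aachange|codonchange) and the sample metadata in `MTD`
#' (`sampleid|organism|tissue`); records are sorted by chromosome then
#' position.
#'
#' @param store a `tad_store`.
#' @param genes,chroms,organism selector (exactly one; `organism` may also
#'   be NULL with the others to export everything).
#' @param format `"tsv"` or `"vcf"`.
#' @param path output file; required for `"vcf"`, optional for `"tsv"`
#'   (the tibble is returned either way).
#' @param fuzzy substring gene matching.
#' @return tibble of exported rows (TSV) or the output path (VCF),
#'   invisibly for files.
#' @export
export_varanno <- function(store, genes = NULL, chroms = NULL, organism = NULL,
                           format = c("tsv", "vcf"), path = NULL, fuzzy = TRUE) {
  format <- match.arg(format)
  store <- as_tad_store(store)
  rows <- variants_select(store, "all")
  if (!is.null(genes)) {
    hit <- rep(FALSE, nrow(rows))
    for (g in genes) {
      hit <- hit | if (fuzzy) grepl(g, rows$genename, ignore.case = TRUE)
      else rows$genename == g
    }
    hit[is.na(hit)] <- FALSE
    rows <- rows[hit, , drop = FALSE]
  }
  if (!is.null(chroms)) rows <- rows[rows$chrom %in% chroms, , drop = FALSE]
  if (!is.null(organism)) rows <- rows[rows$organism == organism, , drop = FALSE]
  if (format == "tsv") {
    if (!is.null(path)) write_tsv_table(rows, path)
    return(rows)
  }
  stopifnot(!is.null(path))
  write_varanno_vcf(rows, path)
  invisible(path)
}

CSQ_ORDER <- c("source", "consequence", "geneid", "genename", "transcript",
               "feature", "genetype", "proteinposition", "aachange",
               "codonchange")

write_varanno_vcf <- function(rows, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Predicted ",
           "functional annotation. Format: ",
           paste(CSQ_ORDER, collapse = "|"), "\">"),
    paste0("##INFO=<ID=MTD,Number=.,Type=String,Description=\"Sample ",
           "metadata. Format: sampleid|organism|tissue\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(rows) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    # INFO fields must not contain reserved characters
    gsub("[;,|=\t ]", "_", x)
  }
  key <- paste(rows$sampleid, rows$chrom, rows$position, rows$refallele,
               rows$altallele, sep = "\r")
  grp <- split(seq_len(nrow(rows)), key)
  recs <- purrr::map(grp, function(ix) {
    first <- rows[ix[1], ]
    ann <- rows[ix, , drop = FALSE]
    has_anno <- !is.na(ann$source)
    csq <- if (any(has_anno)) {
      ents <- purrr::map_chr(which(has_anno), function(i) {
        paste(clean(unlist(ann[i, CSQ_ORDER])), collapse = "|")
      })
      paste0("CSQ=", paste(ents, collapse = ","))
    } else NULL
    mtd <- paste0("MTD=", paste(clean(c(first$sampleid, first$organism,
                                        first$tissue)), collapse = "|"))
    info <- paste(c(csq, mtd), collapse = ";")
    list(chrom = first$chrom, pos = first$position,
         line = paste(first$chrom, first$position,
                      ifelse(is.na(first$dbsnpvariant), ".", first$dbsnpvariant),
                      first$refallele, first$altallele,
                      ifelse(is.na(first$quality), ".",
                             format(first$quality, trim = TRUE)),
                      ".", info, sep = "\t"))
  })
  chroms <- vapply(recs, `[[`, character(1), "chrom")
  pos <- vapply(recs, function(r) as.numeric(r$pos), numeric(1))
  ord <- order_by_chrom_pos(chroms, pos)
  writeLines(c(header, vapply(recs[ord], `[[`, character(1), "line")), path)
  invisible(path)
}

#' Write a table as a tab-delimited file
#'
#' UTF-8, header row first, NA rendered as `NULL`, no quoting; a value that
#' itself contains a tab or newline is rejected.
#'
#' @param table data frame with unique column names.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tsv_table <- function(table, path) {
  if (anyDuplicated(names(table))) {
    tad_stop("table column names must be unique", "tad_validation_error")
  }
  for (col in names(table)) {
    x <- as.character(table[[col]])
    if (any(grepl("[\t\n\r]", x[!is.na(x)]))) {
      tad_stop(paste0("column ", col, " contains a tab or newline"),
               "tad_validation_error")
    }
  }
  readr::write_tsv(table, path, na = "NULL", quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

#' Read back a tab-delimited export
#' @param path file written by [write_tsv_table()].
#' @return tibble with `NULL` literals restored to NA.
#' @export
read_tsv_table <- function(path) {
  suppressMessages(readr::read_tsv(path, na = "NULL", progress = FALSE,
                                   show_col_types = FALSE))
}

#' Read the CSQ/MTD entries back out of an exported VCF
#'
#' Companion reader for round-tripping [export_varanno()] output: returns
#' one row per CSQ entry per record (or one row with NA annotation fields
#' when a record has no CSQ key).
#'
#' @param path VCF written by `export_varanno(format = "vcf")`.
#' @return tibble with chrom, position, refallele, altallele, the CSQ
#'   subfields and the MTD subfields.
#' @export
read_varanno_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(tibble(chrom = character(0), position = integer(0),
                  refallele = character(0), altallele = character(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  out <- purrr::map(f, function(x) {
    info <- strsplit(x[8], ";", fixed = TRUE)[[1]]
    csq <- sub("^CSQ=", "", grep("^CSQ=", info, value = TRUE))
    mtd <- sub("^MTD=", "", grep("^MTD=", info, value = TRUE))
    mtd_parts <- if (length(mtd)) strsplit(mtd, "|", fixed = TRUE)[[1]] else rep(NA, 3)
    base <- tibble(chrom = x[1], position = as.integer(x[2]),
                   dbsnpvariant = ifelse(x[3] == ".", NA, x[3]),
                   refallele = x[4], altallele = x[5],
                   sampleid = mtd_parts[1], organism = mtd_parts[2],
                   tissue = mtd_parts[3])
    if (!length(csq)) {
      for (nm in CSQ_ORDER) base[[nm]] <- NA_character_
      return(base)
    }
    ents <- strsplit(csq, ",", fixed = TRUE)[[1]]
    dplyr::bind_rows(purrr::map(ents, function(e) {
      sub_ <- strsplit(e, "|", fixed = TRUE)[[1]]
      length(sub_) <- length(CSQ_ORDER)
      row <- base
      for (j in seq_along(CSQ_ORDER)) {
        row[[CSQ_ORDER[j]]] <- ifelse(!nzchar(sub_[j]) | is.na(sub_[j]),
                                      NA_character_, sub_[j])
      }
      row
    }))
  })
  dplyr::bind_rows(out)
}
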