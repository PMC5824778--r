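#' Discover the analysis files of a per-sample directory
#'
#' Assigns file roles by suffix: `align_summary.txt`/`*summary.txt`/`*.sam`
#' (alignment), `genes.fpkm_tracking` (cufflinks), `*gene_abund*.tab`
#' (stringtie), `abundance.tsv` (kallisto), `quant.sf` (salmon),
#' `*ReadsPerGene*.tab` (STAR counts), `*featureCounts*`/`*.fc.txt`
#' (featureCounts), `*.counts` (htseq), `*.vcf` (variants), `*.vep.txt`
#' (VEP), `*.multianno.txt` (ANNOVAR). Two candidates for the same role is
#' an error naming them.
#'
#' @param path sample directory.
#' @param sample_name sample the directory belongs to.
#' @return a `tad_manifest`: list with `sample_name`, `files` (named list of
#'   paths), `quantifier`, `counter`.
#' @export
discover_sample_dir <- function(path, sample_name) {
  if (!dir.exists(path)) tad_stop(paste0("no such directory: ", path), "tad_missing_error")
  files <- list.files(path, full.names = TRUE)
  base <- basename(files)

  pick <- function(mask, role) {
    hits <- files[mask]
    if (length(hits) > 1L) {
      tad_stop(paste0("ambiguous ", role, " file in ", path, ": ",
                      paste(basename(hits), collapse = ", ")),
               "tad_ambiguous_error")
    }
    if (length(hits)) hits else NULL
  }

  vep <- pick(endsWith(base, ".vep.txt"), "VEP annotation")
  annovar <- pick(endsWith(base, ".multianno.txt"), "ANNOVAR annotation")
  vcf <- pick(endsWith(base, ".vcf"), "variant")
  alignment <- pick(base == "align_summary.txt" |
                      (endsWith(base, "summary.txt") & !endsWith(base, ".vep.txt")) |
                      endsWith(base, ".sam"), "alignment summary")

  quant_masks <- list(
    cufflinks = base == "genes.fpkm_tracking",
    stringtie = grepl("gene_abund.*\\.tab$", base),
    kallisto = base == "abundance.tsv",
    salmon = base == "quant.sf"
  )
  quant_hits <- purrr::map(quant_masks, function(m) files[m])
  n_quant <- sum(lengths(quant_hits) > 0)
  if (n_quant > 1L) {
    tad_stop(paste0("ambiguous expression file in ", path, ": ",
                    paste(basename(unlist(quant_hits)), collapse = ", ")),
             "tad_ambiguous_error")
  }
  quantifier <- if (n_quant) names(quant_hits)[lengths(quant_hits) > 0] else NA_character_
  expression <- if (n_quant) pick(quant_masks[[quantifier]], "expression") else NULL

  count_masks <- list(
    featurecounts = grepl("featureCounts", base) | endsWith(base, ".fc.txt"),
    star_quantmode = grepl("ReadsPerGene.*\\.tab$", base),
    htseq = endsWith(base, ".counts")
  )
  count_hits <- purrr::map(count_masks, function(m) files[m])
  n_count <- sum(lengths(count_hits) > 0)
  if (n_count > 1L) {
    tad_stop(paste0("ambiguous read-count file in ", path, ": ",
                    paste(basename(unlist(count_hits)), collapse = ", ")),
             "tad_ambiguous_error")
  }
  counter <- if (n_count) names(count_hits)[lengths(count_hits) > 0] else "none"
  readcounts <- if (n_count) pick(count_masks[[counter]], "read counts") else NULL

  if (!is.null(vep) && !is.null(annovar)) {
    tad_stop(paste0("both VEP and ANNOVAR annotations present in ", path),
             "tad_ambiguous_error")
  }

  structure(
    list(
      sample_name = sample_name,
      files = list(alignment_summary = alignment, expression = expression,
                   readcounts = readcounts, vcf = vcf, vep = vep,
                   annovar = annovar),
      quantifier = quantifier,
      counter = counter
    ),
    class = "tad_manifest"
  )
}

#' @export
print.tad_manifest <- function(x, ...) {
  cat("<tad_manifest> ", x$sample_name, "\n", sep = "")
  for (nm in names(x$files)) {
    cat("  ", format(nm, width = 18), if (is.null(x$files[[nm]])) "-"
        else basename(x$files[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

sample_denorm <- function(con, sample_name) {
  row <- DBI::dbGetQuery(con,
    "SELECT s.sampleid, s.samplename, o.organism, t.tissue
     FROM Sample s JOIN Animal a ON a.animalid = s.animalid
     JOIN Organism o ON o.organismid = a.organismid
     JOIN Tissue t ON t.tissueid = s.tissueid
     WHERE s.samplename = :s", params = list(s = sample_name))
  if (!nrow(row)) {
    tad_stop(paste0("unknown sample \"", sample_name,
                    "\"; import metadata first"), "tad_unknown_sample_error")
  }
  row
}

#' Import the analysis results of one sample into both stores
#'
#' Parses everything up front, writes the relational summaries inside one
#' transaction, then appends the large result sets to the columnar
#' partitions with (sampleid, organism, tissue) denormalized from the
#' relational join. The double-entry rule — rows parsed must equal rows
#' stored per stage — is verified after writing; any failure rolls the whole
#' sample import back. A sample's results can only be imported once per
#' scope; delete first to re-import.
#'
#' @param store a `tad_store`.
#' @param manifest a `tad_manifest` from [discover_sample_dir()].
#' @param scope `"all"`, `"gene"` (expression + counts) or `"variant"`.
#' @return an `tad_import_report` tibble: one row per stage with `parsed`,
#'   `stored`, `status`; attribute `ok` is TRUE when every stage checks out.
#' @export
import_sample <- function(store, manifest, scope = c("all", "gene", "variant")) {
  scope <- match.arg(scope)
  store <- as_tad_store(store)
  stopifnot(inherits(manifest, "tad_manifest"))
  want_gene <- scope %in% c("all", "gene")
  want_var <- scope %in% c("all", "variant")

  info <- with_store_con(store, function(con) sample_denorm(con, manifest$sample_name))
  sid <- info$sampleid[1]
  already <- with_store_con(store, function(con) {
    gene_done <- DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM GeneStats WHERE sampleid = :s",
                                 params = list(s = sid))$n > 0
    var_done <- DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM VarSummary WHERE sampleid = :s",
                                params = list(s = sid))$n > 0
    c(gene = gene_done, variant = var_done)
  })
  if ((want_gene && already["gene"]) || (want_var && already["variant"])) {
    tad_stop(paste0("sample \"", manifest$sample_name,
                    "\" already imported; results can only be imported once ",
                    "(delete the sample to re-import)"), "tad_reimport_error")
  }
  if (want_gene && is.null(manifest$files$expression)) {
    tad_stop("expression file absent from manifest", "tad_missing_error")
  }
  if (want_var && is.null(manifest$files$vcf)) {
    tad_stop("variant file absent from manifest", "tad_missing_error")
  }

  # ---- parse phase: any failure here leaves both stores untouched ----
  parsed <- list()
  if (!is.null(manifest$files$alignment_summary)) {
    parsed$mapstats <- summarize_alignment(manifest$files$alignment_summary)
  }
  if (want_gene) {
    parsed$expression <- parse_expression(manifest$files$expression, manifest$quantifier)
    if (!is.null(manifest$files$readcounts)) {
      parsed$readcounts <- parse_readcounts(manifest$files$readcounts, manifest$counter)
    }
  }
  if (want_var) {
    vcf <- parse_vcf(manifest$files$vcf)
    vcf$variantclass <- classify_variant(vcf$refallele, vcf$altallele)
    vcf$zygosity <- call_zygosity(vcf$genotype)
    anno <- NULL
    if (!is.null(manifest$files$vep)) anno <- parse_vep(manifest$files$vep)
    if (!is.null(manifest$files$annovar)) anno <- parse_annovar(manifest$files$annovar)
    parsed$variants <- vcf
    parsed$annotation <- anno
  }

  report <- import_write(store, info, manifest, parsed, want_gene, want_var)
  for (i in seq_len(nrow(report))) {
    tad_log(store, "data2db", manifest$sample_name, report$stage[i],
            report$parsed[i], report$stored[i], report$status[i])
  }
  report
}

import_write <- function(store, info, manifest, parsed, want_gene, want_var) {
  sid <- info$sampleid[1]
  sname <- info$samplename[1]
  stages <- list()
  before <- purrr::map_int(TAD_PARTITIONS,
                           function(p) store_partition(store, p)$row_count)
  names(before) <- TAD_PARTITIONS

  undo_columnar <- function() {
    for (p in TAD_PARTITIONS) {
      part <- store_partition(store, p)
      if (part$row_count > before[[p]]) {
        delete_rows(part, paste0("sampleid = '", sname, "'"))
      }
    }
  }

  res <- tryCatch({
    with_store_con(store, function(con) {
      DBI::dbWithTransaction(con, {
        now <- tad_now()
        if (!is.null(parsed$mapstats)) {
          m <- parsed$mapstats
          DBI::dbExecute(con,
            "INSERT INTO MapStats (sampleid, totalreads, mappedreads,
             alignmentrate, mappername, rundate, loaddate)
             VALUES (:s, :t, :m, :r, :n, :d, :l)",
            params = list(s = sid, t = m$total_reads, m = m$mapped_reads,
                          r = m$alignment_rate, n = m$mapper_name,
                          d = m$date, l = now))
          DBI::dbExecute(con,
            "INSERT INTO CommandSyntax (sampleid, stage, toolname, invocation)
             VALUES (:s, 'alignment', :t, :i)",
            params = list(s = sid, t = m$mapper_name,
                          i = manifest$files$alignment_summary))
          stored <- DBI::dbGetQuery(con,
            "SELECT COUNT(*) n FROM MapStats WHERE sampleid = :s",
            params = list(s = sid))$n
          stages$alignment <<- c(parsed = 1L, stored = as.integer(stored))
        }
        if (want_gene) {
          ex <- parsed$expression
          rows <- dplyr::mutate(ex, sampleid = sname,
                                organism = info$organism[1], tissue = info$tissue[1])
          part <- store_partition(store, "expression")
          append_rows(part, rows[, expression_schema()$name])
          units <- c(if (any(!is.na(ex$fpkm))) "FPKM",
                     if (any(!is.na(ex$tpm))) "TPM")
          DBI::dbExecute(con,
            "INSERT INTO GeneStats (sampleid, genesquantified, quantifiername,
             units, loaddate) VALUES (:s, :g, :q, :u, :l)",
            params = list(s = sid, g = nrow(ex), q = manifest$quantifier,
                          u = paste(units, collapse = ","), l = now))
          DBI::dbExecute(con,
            "INSERT INTO CommandSyntax (sampleid, stage, toolname, invocation)
             VALUES (:s, 'expression', :t, :i)",
            params = list(s = sid, t = manifest$quantifier,
                          i = manifest$files$expression))
          after <- store_partition(store, "expression")$row_count
          stages$expression <<- c(parsed = nrow(ex),
                                  stored = after - before[["expression"]])
          if (!is.null(parsed$readcounts)) {
            rc <- parsed$readcounts
            rcrows <- tibble(sampleid = sname, genename = rc$genename,
                             readcount = rc$readcount,
                             organism = info$organism[1], tissue = info$tissue[1])
            append_rows(store_partition(store, "readcount"), rcrows)
            DBI::dbExecute(con,
              "INSERT INTO ReadCounts (sampleid, genescounted, countername,
               specialrows, loaddate) VALUES (:s, :g, :c, :x, :l)",
              params = list(s = sid, g = nrow(rc), c = manifest$counter,
                            x = attr(rc, "special_rows") %||% 0L, l = now))
            DBI::dbExecute(con,
              "INSERT INTO CommandSyntax (sampleid, stage, toolname, invocation)
               VALUES (:s, 'counts', :t, :i)",
              params = list(s = sid, t = manifest$counter,
                            i = manifest$files$readcounts))
            afterc <- store_partition(store, "readcount")$row_count
            stages$counts <<- c(parsed = nrow(rc),
                                stored = afterc - before[["readcount"]])
          }
        }
        if (want_var) {
          v <- parsed$variants
          anno <- parsed$annotation
          annotationsource <- if (is.null(anno)) "none" else anno$source[1]
          for (i in seq_len(nrow(v))) {
            DBI::dbExecute(con,
              "INSERT INTO VarResult (sampleid, chrom, position, refallele,
               altallele, quality, dbsnpvariant, variantclass, zygosity)
               VALUES (:s, :c, :p, :r, :a, :q, :d, :v, :z)",
              params = list(s = sid, c = v$chrom[i], p = v$position[i],
                            r = v$refallele[i], a = v$altallele[i],
                            q = v$quality[i], d = v$dbsnpvariant[i],
                            v = v$variantclass[i], z = v$zygosity[i]))
          }
          varids <- DBI::dbGetQuery(con,
            "SELECT varid, chrom, position, altallele FROM VarResult
             WHERE sampleid = :s", params = list(s = sid))
          n_anno_stored <- 0L
          if (!is.null(anno) && nrow(anno)) {
            key <- paste(varids$chrom, varids$position, varids$altallele, sep = "\r")
            akey <- paste(anno$chrom, anno$position, anno$altallele, sep = "\r")
            hit <- match(akey, key)
            matched <- anno[!is.na(hit), , drop = FALSE]
            matched$varid <- varids$varid[hit[!is.na(hit)]]
            for (i in seq_len(nrow(matched))) {
              DBI::dbExecute(con,
                "INSERT INTO VarAnnotation (varid, source, consequence, geneid,
                 genename, transcript, feature, genetype, proteinposition,
                 aachange, codonchange)
                 VALUES (:v, :s, :c, :g, :n, :t, :f, :y, :p, :a, :o)",
                params = list(v = matched$varid[i], s = matched$source[i],
                              c = matched$consequence[i], g = matched$geneid[i],
                              n = matched$genename[i], t = matched$transcript[i],
                              f = matched$feature[i], y = matched$genetype[i],
                              p = matched$proteinposition[i],
                              a = matched$aachange[i], o = matched$codonchange[i]))
            }
            n_anno_stored <- nrow(matched)
          }
          # columnar: one row per variant-annotation observation
          nosql <- DBI::dbGetQuery(con,
            "SELECT * FROM vw_nosql WHERE sampleid = :s", params = list(s = sname))
          append_rows(store_partition(store, "variant"), nosql)
          classes <- table(factor(v$variantclass,
                                  levels = c("SNP", "insertion", "deletion", "complex")))
          DBI::dbExecute(con,
            "INSERT INTO VarSummary (sampleid, totalvariants, snpcount,
             insertioncount, deletioncount, othercount, callername,
             annotationsource, loaddate)
             VALUES (:s, :t, :sn, :i, :d, :o, :c, :a, :l)",
            params = list(s = sid, t = nrow(v), sn = classes[["SNP"]],
                          i = classes[["insertion"]], d = classes[["deletion"]],
                          o = classes[["complex"]], c = "VCF",
                          a = annotationsource, l = now))
          DBI::dbExecute(con,
            "INSERT INTO CommandSyntax (sampleid, stage, toolname, invocation)
             VALUES (:s, 'variants', 'VCF', :i)",
            params = list(s = sid, i = manifest$files$vcf))
          if (!is.null(anno)) {
            DBI::dbExecute(con,
              "INSERT INTO CommandSyntax (sampleid, stage, toolname, invocation)
               VALUES (:s, 'annotation', :t, :i)",
              params = list(s = sid, t = annotationsource,
                            i = manifest$files$vep %||% manifest$files$annovar))
          }
          storedv <- DBI::dbGetQuery(con,
            "SELECT COUNT(*) n FROM VarResult WHERE sampleid = :s",
            params = list(s = sid))$n
          aftern <- store_partition(store, "variant")$row_count
          stages$variants <<- c(parsed = nrow(v), stored = as.integer(storedv))
          stages$nosql <<- c(parsed = nrow(nosql),
                             stored = aftern - before[["variant"]])
          if (!is.null(anno)) {
            stages$annotation <<- c(parsed = nrow(anno), stored = n_anno_stored)
          }
        }
        DBI::dbExecute(con,
          "INSERT OR REPLACE INTO Metadata (sampleid, mappername, quantifiername,
           countername, callername, annotationsource, loaddate)
           VALUES (:s, :m, :q, :c, :v, :a, :l)",
          params = list(
            s = sid,
            m = if (!is.null(parsed$mapstats)) parsed$mapstats$mapper_name else NA,
            q = if (want_gene) manifest$quantifier else NA,
            c = if (want_gene) manifest$counter else NA,
            v = if (want_var) "VCF" else NA,
            a = if (want_var && !is.null(parsed$annotation)) parsed$annotation$source[1] else NA,
            l = now))
        # double-entry check: parsed must equal stored in every stage
        # (annotation rows may legitimately drop unmatched entries, so the
        # annotation stage passes when stored <= parsed)
        for (stg in names(stages)) {
          p <- stages[[stg]][["parsed"]]
          s <- stages[[stg]][["stored"]]
          ok <- if (stg == "annotation") s <= p else p == s
          if (!ok) {
            tad_stop(paste0("double-entry mismatch in stage ", stg,
                            ": parsed ", p, " != stored ", s),
                     "tad_doubleentry_error")
          }
        }
      })
    })
    TRUE
  }, error = function(e) {
    undo_columnar()
    rlang::abort(conditionMessage(e), class = class(e), parent = e)
  })

  report <- dplyr::bind_rows(purrr::imap(stages, function(x, stg) {
    tibble(sample_name = sname, stage = stg,
           parsed = x[["parsed"]], stored = x[["stored"]],
           status = if ((stg == "annotation" && x[["stored"]] <= x[["parsed"]]) ||
                          x[["parsed"]] == x[["stored"]]) "ok" else "mismatch")
  }))
  attr(report, "ok") <- all(report$status == "ok")
  class(report) <- c("tad_import_report", class(report))
  report
}

#' Delete a sample and every result that references it, everywhere
#'
#' Removes the columnar rows, the relational result and cross-reference
#' rows, and the sample row itself (shared dimension rows stay). The
#' referential-integrity check passes afterwards and the once-only import
#' rule resets.
#'
#' @param store a `tad_store`.
#' @param sample_name the sample to delete.
#' @return tibble of per-store removed-row counts.
#' @export
delete_sample <- function(store, sample_name) {
  store <- as_tad_store(store)
  removed <- with_store_con(store, function(con) {
    sid <- sample_key(con, sample_name)
    if (is.na(sid)) {
      tad_stop(paste0("unknown sample \"", sample_name, "\""),
               "tad_unknown_sample_error")
    }
    DBI::dbWithTransaction(con, {
      n <- integer(0)
      n["VarAnnotation"] <- DBI::dbExecute(con,
        "DELETE FROM VarAnnotation WHERE varid IN
         (SELECT varid FROM VarResult WHERE sampleid = :s)", params = list(s = sid))
      for (tb in c("VarResult", "VarSummary", "GeneStats", "ReadCounts",
                   "MapStats", "Metadata", "CommandSyntax", "SampleStats",
                   "SamplePerson", "SampleOrganization")) {
        n[tb] <- DBI::dbExecute(con,
          sprintf("DELETE FROM %s WHERE sampleid = :s", tb), params = list(s = sid))
      }
      n["Sample"] <- DBI::dbExecute(con, "DELETE FROM Sample WHERE sampleid = :s",
                                    params = list(s = sid))
      n
    })
  })
  pred <- paste0("sampleid = '", sample_name, "'")
  for (p in TAD_PARTITIONS) {
    removed[paste0("partition_", p)] <- delete_rows(store_partition(store, p), pred)
  }
  tad_log(store, "delete", sample_name, stage = "all",
          parsed = NA, stored = sum(removed), status = "ok")
  tibble(target = names(removed), removed = as.integer(removed))
}
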