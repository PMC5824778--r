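#' Deterministic synthetic-study generator
#'
#' Generates complete, internally consistent input trees in every accepted
#' dialect — metadata sheet, per-sample directories with aligner summary,
#' one quantifier dialect per sample (rotating across cufflinks, stringtie,
#' kallisto, salmon), a counter file (rotating htseq, featureCounts, STAR),
#' a VCF with genotypes, and matching VEP or ANNOVAR annotations — plus a
#' bookkeeping ledger recording every generated count and value so tests
#' can assert against known truth. All randomness flows from one seed;
#' the same configuration yields byte-identical trees.
#'
#' Gene abundances are drawn log-normal (meanlog 2, sdlog 1, the typical
#' right-skewed shape of bulk expression); variant positions are uniform
#' within per-gene intervals; genotypes and variant classes are drawn with
#' SNP-heavy weights (80/10/10).
#'
#' @param seed integer seed.
#' @param organisms data frame with `name` and `code` columns.
#' @param samples_per_organism samples generated per organism.
#' @param tissues tissue names cycled across samples.
#' @param genes_per_sample genes quantified per sample.
#' @param variants_per_sample variant records per sample.
#' @param lab_code laboratory short name used in sample names.
#' @return a `tad_study_config` list.
#' @export
study_config <- function(seed = 1L,
                         organisms = data.frame(
                           name = c("Gallus gallus", "Canis familiaris"),
                           code = c("GGA", "CFA")),
                         samples_per_organism = 2L,
                         tissues = c("Pituitary gland", "Liver"),
                         genes_per_sample = 60L,
                         variants_per_sample = 25L,
                         lab_code = "UD") {
  stopifnot(samples_per_organism >= 0L, genes_per_sample >= 0L,
            variants_per_sample >= 0L)
  structure(
    list(seed = as.integer(seed), organisms = as_tibble(organisms),
         samples_per_organism = samples_per_organism, tissues = tissues,
         genes_per_sample = genes_per_sample,
         variants_per_sample = variants_per_sample, lab_code = lab_code),
    class = "tad_study_config"
  )
}

fmt_num <- function(x, digits = 6L) sprintf(paste0("%.", digits, "f"), x)

#' Generate a synthetic study tree
#'
#' @param config a `tad_study_config`.
#' @param dir output directory (created).
#' @param workbook also emit the two-sheet metadata workbook (requires the
#'   `python` + openpyxl toolchain; off by default because xlsx archives
#'   embed timestamps and would break byte-identical regeneration).
#' @return tibble ledger (also written to `<dir>/ledger.tsv`): one row per
#'   (sample, metric, value).
#' @export
generate_study <- function(config = study_config(), dir, workbook = FALSE) {
  stopifnot(inherits(config, "tad_study_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  quantifiers <- c("cufflinks", "stringtie", "kallisto", "salmon")
  counters <- c("htseq", "featurecounts", "star_quantmode")
  annotators <- c("vep", "annovar")

  meta <- list()
  ledger <- list()
  si <- 0L
  for (oi in seq_len(nrow(config$organisms))) {
    org <- config$organisms$name[oi]
    code <- config$organisms$code[oi]
    genes <- gene_catalog(config$genes_per_sample)
    for (k in seq_len(config$samples_per_organism)) {
      si <- si + 1L
      sname <- paste0(code, "_", config$lab_code, "_", 1000L + si)
      tissue <- config$tissues[(si - 1L) %% length(config$tissues) + 1L]
      meta[[si]] <- tibble(
        `Sample name` = sname,
        `Sample description` = paste0("synthetic specimen ", si),
        `Derived from` = paste0(code, "_ANIMAL_", oi, "_", k),
        Organism = org, `Organism part` = tissue,
        `First name` = "Ada", `Middle initial` = "B", `Last name` = "Lovelace",
        Organization = "Synthetic Institute"
      )
      sdir <- file.path(dir, sname)
      dir.create(sdir, showWarnings = FALSE)
      led <- generate_sample_dir(
        sdir, sname, genes,
        quantifier = quantifiers[(si - 1L) %% 4L + 1L],
        counter = counters[(si - 1L) %% 3L + 1L],
        annotator = annotators[(si - 1L) %% 2L + 1L],
        n_variants = config$variants_per_sample
      )
      ledger[[si]] <- led
    }
  }
  meta <- dplyr::bind_rows(meta)
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"), progress = FALSE)
  if (workbook) write_faang_workbook(meta, file.path(dir, "metadata.xlsx"))
  ledger <- dplyr::bind_rows(ledger)
  readr::write_tsv(ledger, file.path(dir, "ledger.tsv"), progress = FALSE)
  ledger
}

gene_catalog <- function(n) {
  if (n == 0L) {
    return(tibble(genename = character(0), geneid = character(0),
                  chrom = character(0), start = integer(0), stop = integer(0)))
  }
  start <- sort(sample.int(5e6L, n)) + 1000L
  tibble(
    genename = sprintf("GENE%04d", seq_len(n)),
    geneid = sprintf("ENSG%08d", seq_len(n)),
    chrom = as.character(sample(1:5, n, replace = TRUE)),
    start = start,
    stop = start + sample(2000:20000, n, replace = TRUE)
  )
}

generate_sample_dir <- function(sdir, sname, genes, quantifier, counter,
                                annotator, n_variants) {
  n <- nrow(genes)
  fpkm <- round(stats::rlnorm(n, meanlog = 2, sdlog = 1), 6)
  tpm <- if (n > 0 && sum(fpkm) > 0) round(fpkm / sum(fpkm) * 1e6, 6) else fpkm
  coverage <- round(fpkm * stats::runif(n, 5, 15), 6)
  counts <- stats::rnbinom(n, mu = 500, size = 2)

  total_reads <- 2e5L + sample.int(1e5L, 1L)
  rate <- round(stats::runif(1, 0.9, 0.99), 4)
  writeLines(c(
    paste0(total_reads, " reads; of these:"),
    paste0("  ", total_reads, " (100.00%) were unpaired; of these:"),
    paste0("    ", round(total_reads * (1 - rate)), " (",
           fmt_num((1 - rate) * 100, 2), "%) aligned 0 times"),
    paste0(fmt_num(rate * 100, 2), "% overall alignment rate")
  ), file.path(sdir, "align_summary.txt"))

  expr <- tibble(genename = genes$genename, geneid = genes$geneid,
                 chrom = genes$chrom, start = genes$start, stop = genes$stop,
                 coverage = coverage, fpkm = fpkm, tpm = tpm)
  write_quantifier(expr, quantifier, sdir)
  cnt <- tibble(genename = genes$genename, readcount = counts)
  write_counter(cnt, counter, sdir)

  vars <- simulate_variants(genes, n_variants)
  write_sim_vcf(vars, file.path(sdir, paste0(sname, ".vcf")))
  if (annotator == "vep") {
    write_sim_vep(vars, file.path(sdir, paste0(sname, ".vep.txt")))
  } else {
    write_sim_annovar(vars, file.path(sdir, paste0(sname, ".multianno.txt")))
  }

  tibble(sample = sname, metric = c(
    "genes", "fpkm_sum", "tpm_sum", "counts_sum", "counts_genes",
    "reads_total", "alignment_rate", "variants", "snp", "insertion",
    "deletion", "quantifier", "counter", "annotator"
  ), value = as.character(c(
    n, fmt_num(sum(fpkm)), fmt_num(sum(tpm)), sum(counts), n,
    total_reads, rate, nrow(vars), sum(vars$class == "SNP"),
    sum(vars$class == "insertion"), sum(vars$class == "deletion"),
    quantifier, counter, annotator
  )))
}

BASES <- c("A", "C", "G", "T")

simulate_variants <- function(genes, n_variants) {
  if (n_variants == 0L || nrow(genes) == 0L) {
    return(tibble(chrom = character(0), position = integer(0),
                  ref = character(0), alt = character(0), qual = numeric(0),
                  id = character(0), gt = character(0), class = character(0),
                  genename = character(0), geneid = character(0),
                  consequence = character(0)))
  }
  gi <- sample.int(nrow(genes), n_variants, replace = TRUE)
  pos <- genes$start[gi] +
    vapply(gi, function(i) sample.int(genes$stop[i] - genes$start[i], 1L), integer(1))
  class <- sample(c("SNP", "insertion", "deletion"), n_variants,
                  replace = TRUE, prob = c(0.8, 0.1, 0.1))
  ref <- character(n_variants); alt <- character(n_variants)
  for (i in seq_len(n_variants)) {
    b <- sample(BASES, 1L)
    if (class[i] == "SNP") {
      ref[i] <- b
      alt[i] <- sample(setdiff(BASES, b), 1L)
    } else if (class[i] == "insertion") {
      ref[i] <- b
      alt[i] <- paste0(b, paste(sample(BASES, 2L, replace = TRUE), collapse = ""))
    } else {
      ref[i] <- paste0(b, paste(sample(BASES, 2L, replace = TRUE), collapse = ""))
      alt[i] <- b
    }
  }
  out <- tibble(
    chrom = genes$chrom[gi], position = as.integer(pos), ref = ref, alt = alt,
    qual = round(stats::runif(n_variants, 30, 60), 1),
    id = ifelse(stats::runif(n_variants) < 0.3,
                sprintf("rs%06d", sample.int(999999L, n_variants)), "."),
    gt = sample(c("0/1", "1/1"), n_variants, replace = TRUE, prob = c(0.6, 0.4)),
    class = class,
    genename = genes$genename[gi], geneid = genes$geneid[gi],
    consequence = ifelse(class == "SNP",
      sample(c("synonymous_variant", "missense_variant", "intron_variant"),
             n_variants, replace = TRUE),
      ifelse(class == "insertion", "frameshift_variant", "inframe_deletion"))
  )
  # one record per site: drop duplicate (chrom, position) draws
  out <- out[!duplicated(paste(out$chrom, out$position)), , drop = FALSE]
  dplyr::arrange(out, .data$chrom, .data$position)
}

#' Serialize expression rows in one of the accepted quantifier dialects
#' @keywords internal
write_quantifier <- function(expr, dialect, sdir) {
  n <- nrow(expr)
  switch(dialect,
    cufflinks = {
      df <- tibble(
        tracking_id = expr$geneid, class_code = "-", nearest_ref_id = "-",
        gene_id = expr$geneid, gene_short_name = expr$genename, tss_id = "-",
        locus = paste0(expr$chrom, ":", expr$start, "-", expr$stop),
        length = expr$stop - expr$start, coverage = fmt_num(expr$coverage),
        FPKM = fmt_num(expr$fpkm),
        FPKM_conf_lo = fmt_num(pmax(0, expr$fpkm * 0.8)),
        FPKM_conf_hi = fmt_num(expr$fpkm * 1.2),
        FPKM_status = rep("OK", n)
      )
      readr::write_tsv(df, file.path(sdir, "genes.fpkm_tracking"), progress = FALSE)
    },
    stringtie = {
      df <- tibble(
        `Gene ID` = expr$geneid, `Gene Name` = expr$genename,
        Reference = expr$chrom, Strand = rep("+", n), Start = expr$start,
        End = expr$stop, Coverage = fmt_num(expr$coverage),
        FPKM = fmt_num(expr$fpkm), TPM = fmt_num(expr$tpm)
      )
      readr::write_tsv(df, file.path(sdir, "gene_abund.tab"), progress = FALSE)
    },
    kallisto = {
      df <- tibble(
        target_id = expr$genename, length = expr$stop - expr$start,
        eff_length = expr$stop - expr$start - 100L,
        est_counts = fmt_num(expr$coverage), tpm = fmt_num(expr$tpm)
      )
      readr::write_tsv(df, file.path(sdir, "abundance.tsv"), progress = FALSE)
    },
    salmon = {
      df <- tibble(
        Name = expr$genename, Length = expr$stop - expr$start,
        EffectiveLength = expr$stop - expr$start - 100L,
        TPM = fmt_num(expr$tpm), NumReads = fmt_num(expr$coverage)
      )
      readr::write_tsv(df, file.path(sdir, "quant.sf"), progress = FALSE)
    },
    tad_stop(paste0("unknown quantifier dialect ", dialect), "tad_dialect_error")
  )
  invisible(sdir)
}

#' Serialize count rows in one of the accepted counter dialects
#' @keywords internal
write_counter <- function(cnt, dialect, sdir) {
  switch(dialect,
    htseq = {
      lines <- c(paste0(cnt$genename, "\t", cnt$readcount),
                 paste0("__no_feature\t", 50L),
                 paste0("__ambiguous\t", 10L),
                 paste0("__not_aligned\t", 25L))
      writeLines(lines, file.path(sdir, "sample.counts"))
    },
    featurecounts = {
      lines <- c(
        "# Program:featureCounts v2.0; Command:\"featureCounts\" \"-a\" \"ann.gtf\"",
        "Geneid\tChr\tStart\tEnd\tStrand\tLength\tsample.bam",
        paste(cnt$genename, "1", "1", "1000", "+", "1000", cnt$readcount,
              sep = "\t")
      )
      writeLines(lines, file.path(sdir, "sample.fc.txt"))
    },
    star_quantmode = {
      lines <- c(
        paste0("N_unmapped\t100\t100\t100"),
        paste0("N_multimapping\t50\t50\t50"),
        paste0("N_noFeature\t25\t25\t25"),
        paste0("N_ambiguous\t10\t10\t10"),
        paste(cnt$genename, cnt$readcount, cnt$readcount, cnt$readcount,
              sep = "\t")
      )
      writeLines(lines, file.path(sdir, "ReadsPerGene.out.tab"))
    },
    tad_stop(paste0("unknown counter dialect ", dialect), "tad_dialect_error")
  )
  invisible(sdir)
}

write_sim_vcf <- function(vars, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample"
  )
  body <- if (nrow(vars)) {
    paste(vars$chrom, vars$position, vars$id, vars$ref, vars$alt,
          fmt_num(vars$qual, 1), "PASS", ".", "GT", vars$gt, sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
}

write_sim_vep <- function(vars, path) {
  header <- c(
    "## ENSEMBL VARIANT EFFECT PREDICTOR",
    "## Output produced at synthetic time",
    paste("#Uploaded_variation", "Location", "Allele", "Gene", "Feature",
          "Feature_type", "Consequence", "cDNA_position", "CDS_position",
          "Protein_position", "Amino_acids", "Codons", "Existing_variation",
          "Extra", sep = "\t")
  )
  body <- if (nrow(vars)) {
    pp <- ifelse(vars$class == "SNP", as.character((vars$position %% 300) + 1L), "-")
    aa <- ifelse(vars$consequence == "synonymous_variant", "K",
                 ifelse(vars$consequence == "missense_variant", "K/R", "-"))
    codons <- ifelse(vars$consequence == "synonymous_variant", "aaA/aaG",
                     ifelse(vars$consequence == "missense_variant", "Aag/Agg", "-"))
    paste(paste0("var", seq_len(nrow(vars))),
          paste0(vars$chrom, ":", vars$position), vars$alt, vars$geneid,
          sprintf("NM_%06d", seq_len(nrow(vars))), "Transcript",
          vars$consequence, "-", "-", pp, aa, codons, "-",
          paste0("SYMBOL=", vars$genename), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
}

write_sim_annovar <- function(vars, path) {
  header <- paste("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
                  "Gene.refGene", "GeneDetail.refGene", "ExonicFunc.refGene",
                  "AAChange.refGene", sep = "\t")
  body <- if (nrow(vars)) {
    exonic <- ifelse(vars$consequence == "synonymous_variant", "synonymous SNV",
              ifelse(vars$consequence == "missense_variant", "nonsynonymous SNV",
              ifelse(vars$consequence == "frameshift_variant",
                     "frameshift insertion",
              ifelse(vars$consequence == "inframe_deletion",
                     "nonframeshift deletion", "."))))
    func <- ifelse(vars$consequence == "intron_variant", "intronic", "exonic")
    exonic[func == "intronic"] <- "."
    pp <- (vars$position %% 300) + 1L
    aach <- ifelse(func == "exonic" & vars$class == "SNP",
                   paste0(vars$genename, ":", sprintf("NM_%06d", seq_len(nrow(vars))),
                          ":exon2:c.", pp * 3L, "A>G:p.K", pp, "K"),
                   ".")
    paste(vars$chrom, vars$position, vars$position, vars$ref, vars$alt,
          func, vars$genename, ".", exonic, aach, sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
}

# emit the two-sheet metadata workbook through python + openpyxl
write_faang_workbook <- function(meta, path) {
  animal <- unique(tibble(
    `Sample Name` = meta$`Derived from`,
    Organism = meta$Organism
  ))
  specimen <- tibble(
    `Sample Name` = meta$`Sample name`,
    `Sample Description` = meta$`Sample description`,
    `Derived From` = meta$`Derived from`,
    `Organism Part` = meta$`Organism part`
  )
  tmp_a <- tempfile(fileext = ".tsv"); tmp_s <- tempfile(fileext = ".tsv")
  readr::write_tsv(animal, tmp_a, progress = FALSE)
  readr::write_tsv(specimen, tmp_s, progress = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "wb = Workbook()",
    "def sheet(ws, path):",
    "    with open(path) as fh:",
    "        for row in csv.reader(fh, delimiter='\\t'):",
    "            ws.append(row)",
    "ws = wb.active; ws.title = 'Animal'",
    sprintf("sheet(ws, %s)", shQuote(tmp_a)),
    "ws2 = wb.create_sheet('Specimen')",
    sprintf("sheet(ws2, %s)", shQuote(tmp_s)),
    sprintf("wb.save(%s)", shQuote(path))
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) {
    tad_stop(paste0("workbook generation failed: ",
                    paste(status, collapse = "; ")), "tad_io_error")
  }
  invisible(path)
}

#' Generate the two-sample optineurin use-case fixture
#'
#' Two *Gallus gallus* pituitary-gland samples: `GGA_UD_1004` expresses the
#' OPTN gene and carries exactly one synonymous SNP in the OPTN region;
#' `GGA_UD_1014` does not express OPTN (FPKM 0) yet carries several
#' synonymous SNPs along the same region. A control gene with identical
#' abundance in both samples exercises the min = avg = max summary. OPTN
#' coordinates are synthetic (the region, chromosome 6 here, is a label,
#' not an annotation-derived locus).
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return tibble ledger; metric `optn_syn_1014` records the number k of
#'   synonymous OPTN SNPs in GGA_UD_1014 (`optn_syn_1004` is 1).
#' @export
generate_optn_scenario <- function(seed = 1L, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  genes <- tibble(
    genename = c("OPTN", "CTRLEQ", "GENEA", "GENEB"),
    geneid = c("ENSGALG0000OPTN", "ENSGALG0000CTRL", "ENSGALG0000GENA",
               "ENSGALG0000GENB"),
    chrom = c("6", "1", "2", "3"),
    start = c(10000L, 5000L, 8000L, 12000L),
    stop = c(30000L, 9000L, 15000L, 20000L)
  )
  meta <- tibble(
    `Sample name` = c("GGA_UD_1004", "GGA_UD_1014"),
    `Sample description` = c("pituitary specimen 1004", "pituitary specimen 1014"),
    `Derived from` = c("GGA_ANIMAL_1", "GGA_ANIMAL_2"),
    Organism = "Gallus gallus", `Organism part` = "Pituitary gland",
    `First name` = "Ada", `Middle initial` = "B", `Last name` = "Lovelace",
    Organization = "Synthetic Institute"
  )
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"), progress = FALSE)

  k <- 6L # synonymous OPTN SNPs carried by GGA_UD_1014
  fpkm_1004 <- c(OPTN = 8.4, CTRLEQ = 12.5, GENEA = 3.2, GENEB = 21.7)
  fpkm_1014 <- c(OPTN = 0, CTRLEQ = 12.5, GENEA = 5.9, GENEB = 14.3)

  mk_sample <- function(sname, fpkm, quantifier, optn_syn_pos, other_vars) {
    sdir <- file.path(dir, sname)
    dir.create(sdir, showWarnings = FALSE)
    writeLines(c("100000 reads; of these:",
                 "95.50% overall alignment rate"),
               file.path(sdir, "align_summary.txt"))
    expr <- tibble(genename = genes$genename, geneid = genes$geneid,
                   chrom = genes$chrom, start = genes$start, stop = genes$stop,
                   coverage = fpkm * 10, fpkm = unname(fpkm),
                   tpm = if (sum(fpkm) > 0) unname(fpkm / sum(fpkm) * 1e6) else unname(fpkm))
    write_quantifier(expr, quantifier, sdir)
    write_counter(tibble(genename = genes$genename,
                         readcount = as.integer(round(fpkm * 100))),
                  "htseq", sdir)
    optn <- tibble(
      chrom = "6", position = as.integer(optn_syn_pos),
      ref = "A", alt = "G", qual = 45.0, id = ".", gt = "0/1",
      class = "SNP", genename = "OPTN", geneid = "ENSGALG0000OPTN",
      consequence = "synonymous_variant"
    )
    vars <- dplyr::arrange(dplyr::bind_rows(optn, other_vars),
                           .data$chrom, .data$position)
    write_sim_vcf(vars, file.path(sdir, paste0(sname, ".vcf")))
    write_sim_vep(vars, file.path(sdir, paste0(sname, ".vep.txt")))
    nrow(vars)
  }

  other <- tibble(
    chrom = "2", position = 9000L, ref = "C", alt = "T", qual = 50.0,
    id = "rs000111", gt = "1/1", class = "SNP", genename = "GENEA",
    geneid = "ENSGALG0000GENA", consequence = "missense_variant"
  )
  n1 <- mk_sample("GGA_UD_1004", fpkm_1004, "cufflinks",
                  optn_syn_pos = 15000L, other_vars = other)
  n2 <- mk_sample("GGA_UD_1014", fpkm_1014, "stringtie",
                  optn_syn_pos = seq(12000L, by = 2500L, length.out = k),
                  other_vars = other)

  ledger <- tibble(
    sample = c("GGA_UD_1004", "GGA_UD_1014", "GGA_UD_1004", "GGA_UD_1014",
               "GGA_UD_1004", "GGA_UD_1014", "GGA_UD_1004", "GGA_UD_1014"),
    metric = c("optn_syn", "optn_syn", "variants", "variants",
               "optn_fpkm", "optn_fpkm", "ctrleq_fpkm", "ctrleq_fpkm"),
    value = as.character(c(1L, k, n1, n2, fpkm_1004[["OPTN"]],
                           fpkm_1014[["OPTN"]], fpkm_1004[["CTRLEQ"]],
                           fpkm_1014[["CTRLEQ"]]))
  )
  readr::write_tsv(ledger, file.path(dir, "ledger.tsv"), progress = FALSE)
  ledger
}

#' Install a store and import a generated study directory end to end
#'
#' Convenience wrapper: installs a fresh store, imports `metadata.tsv`, then
#' imports every per-sample directory with scope `"all"`.
#'
#' @param study_dir directory produced by [generate_study()] or
#'   [generate_optn_scenario()].
#' @param store_path where to install the store.
#' @return the opened `tad_store`.
#' @export
import_study <- function(study_dir, store_path) {
  store <- tad_install(store_path, overwrite = TRUE)
  import_metadata(store, file.path(study_dir, "metadata.tsv"))
  dirs <- list.dirs(study_dir, recursive = FALSE)
  for (d in dirs) {
    manifest <- discover_sample_dir(d, basename(d))
    import_sample(store, manifest, "all")
  }
  for (pname in TAD_PARTITIONS) {
    part <- store_partition(store, pname)
    if (part$row_count > 0) {
      for (col in default_indexed_columns(partition_schemas()[[pname]])) {
        build_bitmap_index(part, col)
      }
    }
  }
  store
}
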