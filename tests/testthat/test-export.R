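test_that("views summarize per-sample state with NULLs for absent stages", {
  store <- tad_install(new_tmp("views"), overwrite = TRUE)
  insert_sample(store, toy_record("GGA_UD_1004"))
  insert_sample(store, toy_record("GGA_UD_1014",
                                  derived_from = "GGA_ANIMAL_2"))
  si <- run_view(store, "vw_sampleinfo")
  expect_equal(nrow(si), 2)
  # metadata-only samples: alignment fields are NULL
  expect_true(all(is.na(si$totalreads)))
  expect_true(all(is.na(si$genesquantified)))
  expect_error(run_view(store, "vw_bogus"), "unknown view")
})

test_that("vw_vanno row count equals variants having at least one annotation", {
  ss <- study_store()
  va <- run_view(ss$store, "vw_vanno")
  annotated <- rnadepot:::store_query(ss$store,
    "SELECT COUNT(*) n FROM VarResult r
     WHERE EXISTS (SELECT 1 FROM VarAnnotation a WHERE a.varid = r.varid)")$n
  # (one annotation per variant in the generated study)
  expect_equal(nrow(va), annotated)
  expect_gt(nrow(va), 0)
})

test_that("variant selection honours inclusive region bounds and gene scope", {
  oc <- optn_store()
  store <- oc$store
  all_rows <- variants_select(store, "all")
  part_rows <- rnadepot:::store_partition(store, "variant")$row_count
  expect_equal(nrow(all_rows), part_rows)

  v1 <- all_rows[all_rows$sampleid == "GGA_UD_1004" & all_rows$chrom == "6", ][1, ]
  exact <- variants_select(store, list(chrom = "6", start = v1$position,
                                       stop = v1$position))
  expect_true(all(exact$position == v1$position))
  expect_gte(nrow(exact), 1)
  expect_error(variants_select(store, list(chrom = "6", start = 10, stop = 5)),
               "start")

  gene_rows <- variants_select(store, list(gene = "OPTN"))
  expect_setequal(unique(gene_rows$sampleid), c("GGA_UD_1004", "GGA_UD_1014"))
  syn <- gene_rows[gene_rows$consequence == "synonymous_variant", ]
  expect_equal(sum(syn$sampleid == "GGA_UD_1004"), 1)
  k <- as.integer(ledger_value(oc$ledger, "GGA_UD_1014", "optn_syn"))
  expect_equal(sum(syn$sampleid == "GGA_UD_1014"), k)
})

test_that("procedure results equal columnar queries on the mirrored data", {
  oc <- optn_store()
  part <- rnadepot:::store_partition(oc$store, "variant")
  for (chrom in c("2", "6")) {
    proc <- variants_select(oc$store, list(chrom = chrom))
    colq <- execute_query(part, paste0(
      "select * where chrom = '", chrom, "' order by position"))
    proc <- proc[order(proc$position, proc$sampleid), ]
    colq <- colq[order(colq$position, colq$sampleid), ]
    expect_equal(nrow(proc), nrow(colq))
    expect_equal(proc$position, colq$position)
    expect_equal(proc$sampleid, colq$sampleid)
    expect_equal(proc$refallele, colq$refallele)
  }
})

test_that("avgfpkm is the per-tissue arithmetic mean with min/max bounds", {
  store <- tad_install(new_tmp("avg"), overwrite = TRUE)
  insert_sample(store, toy_record("T_A_1"))
  insert_sample(store, toy_record("T_A_2", derived_from = "GGA_ANIMAL_2"))
  insert_sample(store, toy_record("T_A_3", derived_from = "GGA_ANIMAL_3"))
  part <- rnadepot:::store_partition(store, "expression")
  rows <- tibble::tibble(
    sampleid = c("T_A_1", "T_A_2", "T_A_3"), chrom = "1", start = 1L,
    stop = 2L, genename = "GX", geneid = "GX", coverage = 1,
    tpm = NA, fpkm = c(10, 20, 30), fpkmconflow = NA, fpkmconfhigh = NA,
    fpkmstatus = "OK", organism = "Gallus gallus", tissue = "Pituitary gland"
  )
  append_rows(part, rows)
  got <- export_avgfpkm(store, "GX")
  expect_equal(got$min_fpkm, 10)
  expect_equal(got$avg_fpkm, 20)
  expect_equal(got$max_fpkm, 30)
  expect_equal(got$sample_count, 3L)
  expect_warning(out <- export_avgfpkm(store, "NOPE"), "no gene matches")
  expect_equal(nrow(out), 0)
})

test_that("avgfpkm rows equal brute-force recomputation on the study", {
  ss <- study_store()
  got <- export_avgfpkm(ss$store, "GENE")
  tbl <- partition_tbl(rnadepot:::store_partition(ss$store, "expression"))
  tbl$ab <- ifelse(is.nan(tbl$fpkm), tbl$tpm, tbl$fpkm)
  tbl <- tbl[!is.nan(tbl$ab) & grepl("GENE", tbl$genename), ]
  expect_gt(nrow(got), 0)
  for (i in seq_len(nrow(got))) {
    vals <- tbl$ab[tbl$genename == got$genename[i] & tbl$tissue == got$tissue[i]]
    expect_equal(got$min_fpkm[i], min(vals), tolerance = 1e-9)
    expect_equal(got$avg_fpkm[i], mean(vals), tolerance = 1e-9)
    expect_equal(got$max_fpkm[i], max(vals), tolerance = 1e-9)
  }
  expect_true(all(got$min_fpkm <= got$avg_fpkm + 1e-12 &
                    got$avg_fpkm <= got$max_fpkm + 1e-12))
})

test_that("the expression matrix matches per-sample lookups", {
  oc <- optn_store()
  m <- export_genexp(oc$store, "Gallus gallus", absent = "zero")
  expect_true(all(c("GGA_UD_1004", "GGA_UD_1014") %in% names(m)))
  optn <- m[m$genename == "OPTN", ]
  expect_gt(optn$GGA_UD_1004, 0)
  expect_equal(optn$GGA_UD_1014, 0)
  one <- export_genexp(oc$store, "Gallus gallus", samples = "GGA_UD_1004")
  expect_equal(names(one), c("genename", "GGA_UD_1004"))
  # cells equal direct partition lookups
  tbl <- partition_tbl(rnadepot:::store_partition(oc$store, "expression"))
  for (i in seq_len(nrow(m))) {
    for (s in c("GGA_UD_1004", "GGA_UD_1014")) {
      v <- tbl$fpkm[tbl$genename == m$genename[i] & tbl$sampleid == s]
      expect_equal(m[[s]][i], v, tolerance = 1e-9)
    }
  }
  expect_error(export_genexp(oc$store, "No such beast"), "unknown organism")
  expect_error(export_genexp(oc$store, "Gallus gallus", samples = "CFA_X_1"),
               "belong")
})

test_that("chromosome variant counts are conserved against VarSummary", {
  ss <- study_store()
  chrvar <- export_chrvar(ss$store)
  totals <- chrvar |> dplyr::count(.data$sampleid, wt = .data$variant_count,
                                   name = "total")
  vs <- rnadepot:::store_query(ss$store,
    "SELECT x.samplename, v.totalvariants FROM VarSummary v
     JOIN Sample x ON x.sampleid = v.sampleid")
  merged <- dplyr::inner_join(totals, vs, by = c(sampleid = "samplename"))
  expect_equal(nrow(merged), nrow(vs))
  expect_equal(merged$total, merged$totalvariants)
  # restriction equals a full-scan predicate count
  part <- rnadepot:::store_partition(ss$store, "variant")
  one <- export_chrvar(ss$store, chroms = "1")
  for (i in seq_len(nrow(one))) {
    scan <- execute_query(part, paste0(
      "select count(*) where chrom = '1' and sampleid = '", one$sampleid[i], "'"))[[1]]
    expect_equal(one$variant_count[i], scan)
  }
  empty <- tad_install(new_tmp("emptystore"), overwrite = TRUE)
  expect_equal(nrow(export_chrvar(empty)), 0)
})

test_that("VCF export packs CSQ entries and round-trips through the parsers", {
  store <- tad_install(new_tmp("vcfexp"), overwrite = TRUE)
  insert_sample(store, toy_record("GGA_UD_1004"))
  con <- DBI::dbConnect(RSQLite::SQLite(), store$settings$relational)
  DBI::dbExecute(con,
    "INSERT INTO VarResult (sampleid, chrom, position, refallele, altallele,
     quality, variantclass, zygosity) VALUES (1, '6', 15000, 'A', 'G', 45,
     'SNP', 'heterozygous')")
  for (cons in c("synonymous_variant", "upstream_gene_variant")) {
    DBI::dbExecute(con, sprintf(
      "INSERT INTO VarAnnotation (varid, source, consequence, genename)
       VALUES (1, 'VEP', '%s', 'OPTN')", cons))
  }
  DBI::dbDisconnect(con)
  # mirror into the columnar side the way import does
  nosql <- rnadepot:::store_query(store, "SELECT * FROM vw_nosql")
  append_rows(rnadepot:::store_partition(store, "variant"), nosql)

  out <- file.path(new_tmp("vcfout"), "x.vcf")
  export_varanno(store, genes = "OPTN", format = "vcf", path = out)
  lines <- readLines(out)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1) # one record despite two annotations
  csq <- sub(".*CSQ=([^;]*).*", "\\1", body)
  entries <- strsplit(csq, ",", fixed = TRUE)[[1]]
  expect_length(entries, 2)
  # every entry has the header-declared arity
  expect_true(all(lengths(gregexpr("\\|", entries)) ==
                    length(rnadepot:::CSQ_ORDER) - 1))
  rt <- read_varanno_vcf(out)
  expect_setequal(rt$consequence,
                  c("synonymous_variant", "upstream_gene_variant"))
  expect_equal(unique(rt$position), 15000L)
  reparsed <- suppressWarnings(parse_vcf(out)) # no GT column in the export
  expect_equal(reparsed$chrom, "6")
  expect_equal(reparsed$position, 15000L)
})

test_that("exported VCF of the use-case store satisfies a strict reader", {
  oc <- optn_store()
  out <- file.path(new_tmp("strictvcf"), "all.vcf")
  export_varanno(oc$store, format = "vcf", path = out)
  # independent strict parser
  vcf <- VariantAnnotation::readVcf(out)
  expect_equal(length(vcf), length(readLines(out)) - 4)
  info <- VariantAnnotation::info(vcf)
  expect_true(all(c("CSQ", "MTD") %in% names(info)))
  # records sorted by chrom then position
  body <- readLines(out)
  body <- body[!startsWith(body, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, character(1), 1)
  pos <- as.integer(vapply(f, `[`, character(1), 2))
  for (ch in unique(chrom)) expect_false(is.unsorted(pos[chrom == ch]))
  # round trip reproduces the original tuples exactly
  rt <- read_varanno_vcf(out)
  orig <- variants_select(oc$store, "all")
  key <- function(d) sort(paste(d$chrom, d$position, d$refallele,
                                d$altallele, d$consequence))
  expect_equal(key(rt[!is.na(rt$consequence), ]),
               key(orig[!is.na(orig$consequence), ]))
  # gene selector equals the gene procedure joined to annotations
  tsv <- export_varanno(oc$store, genes = "OPTN", format = "tsv")
  proc <- variants_select(oc$store, list(gene = "OPTN"))
  expect_equal(nrow(tsv), nrow(proc))

  # empty result still writes a valid header-only file
  out2 <- file.path(new_tmp("strictvcf2"), "none.vcf")
  export_varanno(oc$store, genes = "NOSUCHGENE", format = "vcf", path = out2)
  expect_equal(sum(!startsWith(readLines(out2), "#")), 0)
})

test_that("tab-delimited writer renders NULLs, rejects tabs, round-trips", {
  d <- new_tmp("tsv")
  f <- file.path(d, "t.tsv")
  tbl <- tibble::tibble(a = c("x", NA), b = c(1.5, 2.5))
  write_tsv_table(tbl, f)
  lines <- readLines(f)
  expect_length(lines, 3) # header + 2 rows
  expect_equal(lines[3], "NULL\t2.5")
  back <- read_tsv_table(f)
  expect_equal(back$a, tbl$a)
  expect_equal(back$b, tbl$b)
  # header-only
  write_tsv_table(tbl[0, ], f)
  expect_length(readLines(f), 1)
  expect_error(write_tsv_table(tibble::tibble(a = "x\ty"), f), "tab")
  expect_error(write_tsv_table(stats::setNames(tibble::tibble(1, 2),
                                               c("a", "a")), f), "unique")
})
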