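test_that("a full import passes double entry and matches file bookkeeping", {
  ss <- study_store()
  store <- ss$store
  led <- ss$ledger
  for (s in unique(led$sample)) {
    genes <- as.integer(ledger_value(led, s, "genes"))
    got <- rnadepot:::store_query(store, sprintf(
      "SELECT genesquantified FROM GeneStats g
       JOIN Sample x ON x.sampleid = g.sampleid
       WHERE x.samplename = '%s'", s))
    expect_equal(got$genesquantified, genes)
    # expression partition holds exactly the file's gene count for the sample
    part <- rnadepot:::store_partition(store, "expression")
    n_expr <- execute_query(part,
      paste0("select count(*) where sampleid = '", s, "'"))[[1]]
    expect_equal(n_expr, genes)
  }
  expect_equal(nrow(check_referential_integrity(store)), 0)
})

test_that("per-sample TPM sums survive the round trip into the store", {
  ss <- study_store()
  part <- rnadepot:::store_partition(ss$store, "expression")
  tbl <- partition_tbl(part)
  for (s in unique(ss$ledger$sample)) {
    q <- ledger_value(ss$ledger, s, "quantifier")
    if (q == "cufflinks") next # dialect carries FPKM only
    want <- as.numeric(ledger_value(ss$ledger, s, "tpm_sum"))
    got <- sum(tbl$tpm[tbl$sampleid == s])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("re-import is refused until the sample is deleted", {
  ss <- study_store()
  s <- unique(ss$ledger$sample)[1]
  manifest <- discover_sample_dir(file.path(ss$study_dir, s), s)
  expect_error(import_sample(ss$store, manifest, "all"),
               class = "tad_reimport_error")
})

test_that("a truncated VCF rolls the whole sample import back", {
  d <- new_tmp("atomic")
  cfg <- study_config(seed = 21, organisms = data.frame(
    name = "Gallus gallus", code = "GGA"), samples_per_organism = 2L,
    genes_per_sample = 10L, variants_per_sample = 5L)
  generate_study(cfg, d)
  store <- tad_install(new_tmp("atomic_store"), overwrite = TRUE)
  import_metadata(store, file.path(d, "metadata.tsv"))
  samples <- list.dirs(d, recursive = FALSE)
  # first sample imports cleanly
  import_sample(store, discover_sample_dir(samples[1], basename(samples[1])), "all")
  counts_before <- vapply(rnadepot:::TAD_PARTITIONS, function(p) {
    rnadepot:::store_partition(store, p)$row_count
  }, integer(1))
  tables_before <- vapply(c("MapStats", "GeneStats", "VarResult", "VarSummary"),
    function(tb) rnadepot:::store_query(store,
      paste0("SELECT COUNT(*) n FROM ", tb))$n, numeric(1))
  # corrupt the second sample's VCF mid-file
  vcf <- list.files(samples[2], pattern = "\\.vcf$", full.names = TRUE)
  lines <- readLines(vcf)
  lines[length(lines)] <- "1\t"
  writeLines(lines, vcf)
  expect_error(import_sample(
    store, discover_sample_dir(samples[2], basename(samples[2])), "all"))
  counts_after <- vapply(rnadepot:::TAD_PARTITIONS, function(p) {
    rnadepot:::store_partition(store, p)$row_count
  }, integer(1))
  tables_after <- vapply(c("MapStats", "GeneStats", "VarResult", "VarSummary"),
    function(tb) rnadepot:::store_query(store,
      paste0("SELECT COUNT(*) n FROM ", tb))$n, numeric(1))
  expect_identical(counts_after, counts_before)
  expect_identical(tables_after, tables_before)
  expect_equal(nrow(check_referential_integrity(store)), 0)
})

test_that("columnar denormalization matches the relational sample join", {
  ss <- study_store()
  rel <- rnadepot:::store_query(ss$store,
    "SELECT s.samplename, o.organism, t.tissue FROM Sample s
     JOIN Animal a ON a.animalid = s.animalid
     JOIN Organism o ON o.organismid = a.organismid
     JOIN Tissue t ON t.tissueid = s.tissueid")
  for (p in rnadepot:::TAD_PARTITIONS) {
    tbl <- partition_tbl(rnadepot:::store_partition(ss$store, p))
    merged <- dplyr::left_join(tbl, rel, by = c(sampleid = "samplename"),
                               suffix = c("", ".rel"))
    expect_true(all(merged$organism == merged$organism.rel), info = p)
    expect_true(all(merged$tissue == merged$tissue.rel), info = p)
  }
})

test_that("VarSummary class arithmetic is recomputable from the partition", {
  ss <- study_store()
  vs <- rnadepot:::store_query(ss$store,
    "SELECT x.samplename, v.totalvariants, v.snpcount, v.insertioncount,
            v.deletioncount, v.othercount
     FROM VarSummary v JOIN Sample x ON x.sampleid = v.sampleid")
  expect_true(all(vs$snpcount + vs$insertioncount + vs$deletioncount +
                    vs$othercount == vs$totalvariants))
  tbl <- partition_tbl(rnadepot:::store_partition(ss$store, "variant"))
  recomputed <- tbl |>
    dplyr::distinct(.data$sampleid, .data$chrom, .data$position,
                    .data$refallele, .data$altallele, .data$variantclass) |>
    dplyr::count(.data$sampleid, .data$variantclass) |>
    tidyr::pivot_wider(names_from = "variantclass", values_from = "n",
                       values_fill = 0L)
  for (i in seq_len(nrow(vs))) {
    row <- recomputed[recomputed$sampleid == vs$samplename[i], ]
    expect_equal(if (is.null(row$SNP)) 0L else row$SNP, vs$snpcount[i])
    if ("insertion" %in% names(row)) {
      expect_equal(row$insertion, vs$insertioncount[i])
    }
    if ("deletion" %in% names(row)) {
      expect_equal(row$deletion, vs$deletioncount[i])
    }
  }
})

test_that("deleting one sample leaves every other sample untouched", {
  d <- new_tmp("deltest")
  generate_optn_scenario(7, d)
  store <- import_study(d, new_tmp("deltest_store"))
  other_counts <- function() {
    vapply(rnadepot:::TAD_PARTITIONS, function(p) {
      execute_query(rnadepot:::store_partition(store, p),
                    "select count(*) where sampleid = 'GGA_UD_1014'")[[1]]
    }, integer(1))
  }
  before <- other_counts()
  res <- delete_sample(store, "GGA_UD_1004")
  expect_gt(sum(res$removed), 0)
  expect_identical(other_counts(), before)
  expect_equal(rnadepot:::store_query(store,
    "SELECT COUNT(*) n FROM Sample")$n, 1)
  expect_equal(nrow(check_referential_integrity(store)), 0)
  # the once-only rule resets: re-import after delete succeeds
  insert_sample(store, toy_record("GGA_UD_1004"))
  expect_error(insert_sample(store, toy_record("GGA_UD_1014")),
               "already exists")
  m <- discover_sample_dir(file.path(d, "GGA_UD_1004"), "GGA_UD_1004")
  rep <- import_sample(store, m, "all")
  expect_true(attr(rep, "ok"))
  expect_error(delete_sample(store, "NO_SUCH_1"),
               class = "tad_unknown_sample_error")
})
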