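test_that("sample names split into species, lab and id on underscores", {
  p <- parse_sample_name("GGA_UD_1004")
  expect_equal(p$species_code, "GGA")
  expect_equal(p$lab_code, "UD")
  expect_equal(p$sample_id, "1004")
  expect_equal(unlist(parse_sample_name("A_B_C"), use.names = FALSE),
               c("A", "B", "C"))
  expect_error(parse_sample_name("GGA-UD-1004"), class = "tad_naming_error")
  expect_error(parse_sample_name("GGA_UD_1004_X"), class = "tad_naming_error")
})

test_that("tab-delimited metadata parses, validates and flags unknowns", {
  f <- file.path(new_tmp("meta"), "m.tsv")
  writeLines(c(
    "Sample name\tDerived from\tOrganism\tOrganism part",
    "GGA_UD_1004\tGGA_ANIMAL_1\tGallus gallus\tPituitary gland",
    "GGA_UD_1014\tGGA_ANIMAL_2\tGallus gallus\tPituitary gland"
  ), f)
  recs <- parse_sample_metadata(f)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$organism, rep("Gallus gallus", 2))

  f2 <- file.path(new_tmp("meta2"), "m.tsv")
  writeLines(c("Sample name\tOrganism\tOrganism part",
               "S_A_1\tx\ty"), f2)
  err <- tryCatch(parse_sample_metadata(f2), error = identity)
  expect_s3_class(err, "tad_validation_error")
  expect_match(conditionMessage(err), "Derived from")

  f3 <- file.path(new_tmp("meta3"), "m.tsv")
  writeLines(c(
    "Sample name\tDerived from\tOrganism\tOrganism part\tWeird col",
    "S_A_1\ta\tx\ty\tz"), f3)
  expect_warning(parse_sample_metadata(f3), "Weird col")
})

test_that("the two-sheet metadata workbook imports like its TSV twin", {
  d <- new_tmp("wb")
  cfg <- study_config(seed = 3, samples_per_organism = 1L,
                      genes_per_sample = 5L, variants_per_sample = 2L)
  generate_study(cfg, d, workbook = TRUE)
  from_wb <- parse_sample_metadata(file.path(d, "metadata.xlsx"))
  from_tsv <- parse_sample_metadata(file.path(d, "metadata.tsv"))
  expect_setequal(from_wb$sample_name, from_tsv$sample_name)
  expect_equal(nrow(from_wb), 2)
  expect_equal(sort(unique(from_wb$organism)),
               c("Canis familiaris", "Gallus gallus"))
  expect_equal(from_wb$organism_part[from_wb$sample_name == "GGA_UD_1001"],
               from_tsv$organism_part[from_tsv$sample_name == "GGA_UD_1001"])
})

test_that("SAM flag statistics follow primary/mapped semantics", {
  d <- new_tmp("sam")
  sam <- file.path(d, "aln.sam")
  rec <- function(name, flag) {
    paste(name, flag, "chr1", "100", "60", "10M", "*", "0", "0",
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t")
  }
  writeLines(c("@HD\tVN:1.6", rec("r1", 0), rec("r2", 16), rec("r3", 4)), sam)
  m <- summarize_alignment(sam)
  expect_equal(m$total_reads, 3)
  expect_equal(m$mapped_reads, 2)
  expect_equal(m$alignment_rate, 2 / 3, tolerance = 1e-4)

  # only a secondary alignment: nothing primary to count
  writeLines(c("@HD\tVN:1.6", rec("r1", 256)), sam)
  m2 <- summarize_alignment(sam)
  expect_equal(m2$total_reads, 0)
  expect_equal(m2$mapped_reads, 0)
  expect_equal(m2$alignment_rate, 0)
})

test_that("aligner summary dialects are recognized; others rejected", {
  d <- new_tmp("summ")
  f <- file.path(d, "align_summary.txt")
  writeLines(c("10000 reads; of these:",
               "95.50% overall alignment rate"), f)
  m <- summarize_alignment(f)
  expect_equal(m$total_reads, 10000)
  expect_equal(m$alignment_rate, 0.955)
  expect_equal(m$mapped_reads, 9550)

  writeLines(c("Reads:", "  Input  :  5000", "  Mapped :  4500 (90.0% of input)",
               "90.0% overall read mapping rate."), f)
  m2 <- summarize_alignment(f)
  expect_equal(m2$total_reads, 5000)
  expect_equal(m2$mapped_reads, 4500)
  expect_equal(m2$alignment_rate, 0.9)

  writeLines("some unrelated text", f)
  err <- tryCatch(summarize_alignment(f), error = identity)
  expect_s3_class(err, "tad_dialect_error")
  expect_match(conditionMessage(err), "SAM")
})

test_that("abundance dialects normalize onto the columnar field set", {
  d <- new_tmp("expr")
  expr <- tibble::tibble(
    genename = c("OPTN", "G2"), geneid = c("ID1", "ID2"),
    chrom = c("6", "1"), start = c(100L, 500L), stop = c(400L, 900L),
    coverage = c(5, 2), fpkm = c(12.5, 0), tpm = c(800000, 200000)
  )
  rnadepot:::write_quantifier(expr, "cufflinks", d)
  cuff <- parse_expression(file.path(d, "genes.fpkm_tracking"), "cufflinks")
  expect_equal(cuff$fpkm, c(12.5, 0))
  expect_equal(cuff$fpkmconflow, c(10, 0))
  expect_equal(cuff$fpkmconfhigh, c(15, 0))
  expect_equal(cuff$fpkmstatus, c("OK", "OK"))
  expect_true(all(is.na(cuff$tpm)))
  expect_equal(cuff$chrom, c("6", "1"))
  expect_equal(cuff$start, c(100L, 500L))

  rnadepot:::write_quantifier(expr, "kallisto", d)
  kal <- parse_expression(file.path(d, "abundance.tsv"), "kallisto")
  expect_equal(kal$tpm, c(800000, 200000))
  expect_true(all(is.na(kal$fpkm)))

  # wrong header for the requested dialect
  expect_error(parse_expression(file.path(d, "abundance.tsv"), "salmon"),
               class = "tad_dialect_error")
})

test_that("the same abundance vector is value-identical across dialects", {
  d <- new_tmp("crossdialect")
  set.seed(8)
  expr <- tibble::tibble(
    genename = sprintf("G%03d", 1:20), geneid = sprintf("ID%03d", 1:20),
    chrom = "1", start = 1:20 * 1000L, stop = 1:20 * 1000L + 500L,
    coverage = round(stats::runif(20, 1, 50), 6),
    fpkm = round(stats::rlnorm(20, 2, 1), 6),
    tpm = round(stats::rlnorm(20, 3, 1), 6)
  )
  rnadepot:::write_quantifier(expr, "stringtie", d)
  rnadepot:::write_quantifier(expr, "salmon", d)
  st <- parse_expression(file.path(d, "gene_abund.tab"), "stringtie")
  sa <- parse_expression(file.path(d, "quant.sf"), "salmon")
  expect_equal(st$tpm, sa$tpm, tolerance = 1e-9)
  expect_equal(st$genename, sa$genename)
})

test_that("count dialects exclude QC rows and validate integer counts", {
  d <- new_tmp("counts")
  f <- file.path(d, "s.counts")
  writeLines(c("G1\t10", "G2\t0", "G3\t7", "__no_feature\t50"), f)
  ht <- parse_readcounts(f, "htseq")
  expect_equal(nrow(ht), 3)
  expect_equal(ht$readcount, c(10L, 0L, 7L))
  expect_equal(attr(ht, "special_rows"), 1L)

  cnt <- tibble::tibble(genename = sprintf("G%02d", 1:20),
                        readcount = sample.int(100L, 20))
  rnadepot:::write_counter(cnt, "featurecounts", d)
  fc <- parse_readcounts(file.path(d, "sample.fc.txt"), "featurecounts")
  expect_equal(fc$readcount, cnt$readcount)

  rnadepot:::write_counter(cnt, "star_quantmode", d)
  st <- parse_readcounts(file.path(d, "ReadsPerGene.out.tab"), "star_quantmode")
  expect_equal(st$readcount, cnt$readcount)
  expect_equal(attr(st, "special_rows"), 4L)

  writeLines("G1\t2.5", f)
  expect_error(parse_readcounts(f, "htseq"), "non-integer")
  writeLines(character(0), f)
  expect_warning(out <- parse_readcounts(f, "htseq"), "empty")
  expect_equal(nrow(out), 0)
})

test_that("VCF records parse per ALT allele with genotype and ids", {
  d <- new_tmp("vcf")
  f <- file.path(d, "s.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t1000\trs123\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "1\t2000\t.\tC\tG,T\t.\tPASS\t.\tGT\t1/2"
  ), f)
  v <- parse_vcf(f)
  expect_equal(nrow(v), 3)
  expect_equal(v$position, c(1000L, 2000L, 2000L))
  expect_equal(v$altallele, c("G", "G", "T"))
  expect_equal(v$quality, c(50, NA, NA))
  expect_equal(v$dbsnpvariant, c("rs123", NA, NA))
  expect_equal(v$genotype, c("0/1", "1/2", "1/2"))

  writeLines(c("1\t1000\t.\tA\tG\t50\tPASS\t."), f)
  expect_error(parse_vcf(f), "#CHROM")
})

test_that("variant classification and zygosity follow the length/GT rules", {
  expect_equal(classify_variant(c("A", "A", "AT", "AT"),
                                c("G", "AT", "A", "GC")),
               c("SNP", "insertion", "deletion", "complex"))
  expect_error(classify_variant("", "G"), "empty allele")
  expect_equal(call_zygosity(c("1/1", "0/1", "./1", "0|0")),
               c("homozygous", "heterozygous", NA, "homozygous"))
  expect_error(call_zygosity("0/x"), "malformed")
})

test_that("VEP tables parse locations, ranges and dash-null fields", {
  d <- new_tmp("vep")
  f <- file.path(d, "s.vep.txt")
  writeLines(c(
    "## VEP output",
    paste("#Uploaded_variation", "Location", "Allele", "Gene", "Feature",
          "Feature_type", "Consequence", "cDNA_position", "CDS_position",
          "Protein_position", "Amino_acids", "Codons", "Existing_variation",
          "Extra", sep = "\t"),
    paste("v1", "1:1000", "G", "ENSG1", "NM_001", "Transcript",
          "synonymous_variant", "-", "-", "45", "K", "aaA/aaG", "-",
          "SYMBOL=OPTN", sep = "\t"),
    paste("v2", "1:1000-1001", "T", "ENSG2", "NM_002", "Transcript",
          "frameshift_variant", "-", "-", "-", "-", "-", "-", "-", sep = "\t")
  ), f)
  a <- parse_vep(f)
  expect_equal(nrow(a), 2)
  expect_equal(a$position, c(1000L, 1000L)) # range start for the indel
  expect_equal(a$consequence[1], "synonymous_variant")
  expect_equal(a$proteinposition[1], 45L)
  expect_equal(a$aachange[1], "K")
  expect_equal(a$codonchange[1], "aaA/aaG")
  expect_equal(a$genename[1], "OPTN")
  expect_true(is.na(a$aachange[2]))
  expect_equal(a$source, c("VEP", "VEP"))

  writeLines(c("Chr\tStart", "1\t2"), f)
  expect_error(parse_vep(f), class = "tad_dialect_error")
})

test_that("ANNOVAR tables split AAChange into its annotation sub-fields", {
  d <- new_tmp("annovar")
  f <- file.path(d, "s.multianno.txt")
  writeLines(c(
    paste("Chr", "Start", "End", "Ref", "Alt", "Func.refGene", "Gene.refGene",
          "GeneDetail.refGene", "ExonicFunc.refGene", "AAChange.refGene",
          sep = "\t"),
    paste("1", "1000", "1000", "A", "G", "exonic", "OPTN", ".",
          "synonymous SNV", "OPTN:NM_001:c.135A>G:p.K45K", sep = "\t"),
    paste("2", "500", "500", "C", "T", "intergenic", "NONE(dist=1)", ".",
          ".", ".", sep = "\t")
  ), f)
  a <- parse_annovar(f)
  expect_equal(a$consequence[1], "synonymous SNV")
  expect_equal(a$genename[1], "OPTN")
  expect_equal(a$transcript[1], "NM_001")
  expect_equal(a$proteinposition[1], 45L)
  expect_equal(a$aachange[1], "K45K")
  expect_equal(a$codonchange[1], "135A>G")
  # intergenic: consequence NULL, gene-relative location retained
  expect_true(is.na(a$consequence[2]))
  expect_equal(a$genetype[2], "intergenic")
  expect_equal(a$source[1], "ANNOVAR")
})

test_that("manifests assign roles by suffix and reject ambiguity", {
  d <- new_tmp("mani")
  file.create(file.path(d, c("align_summary.txt", "genes.fpkm_tracking",
                             "sample.vcf", "sample.vep.txt")))
  m <- discover_sample_dir(d, "GGA_UD_1004")
  expect_equal(m$quantifier, "cufflinks")
  expect_false(is.null(m$files$vep))
  expect_true(is.null(m$files$annovar))

  file.create(file.path(d, "quant.sf"))
  expect_error(discover_sample_dir(d, "x"), class = "tad_ambiguous_error")
})
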