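#' Parse a single-sample VCF v4 file
#'
#' Multi-allelic records are exploded to one row per ALT allele. The ID field
#' supplies the dbSNP membership (`.` becomes NA), QUAL `.` becomes NA, and
#' the genotype is taken from the GT subfield of the first sample column
#' (absent GT yields NA zygosity with a warning). FILTER is ignored.
#'
#' @param path VCF text file with a `#CHROM` header line.
#' @return tibble with `chrom`, `position`, `refallele`, `altallele`,
#'   `quality`, `dbsnpvariant`, `genotype`.
#' @export
parse_vcf <- function(path) {
  if (!file.exists(path)) tad_stop(paste0("no such file: ", path), "tad_missing_error")
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "#CHROM"))) {
    tad_stop(paste0(path, " has no #CHROM header line; not a VCF"), "tad_dialect_error")
  }
  body_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nf <- lengths(strsplit(body_lines, "\t", fixed = TRUE))
  if (length(body_lines) && any(nf < 8L)) {
    tad_stop(paste0(path, " is truncated: record ", which(nf < 8L)[1],
                    " has fewer than the 8 mandatory VCF fields"),
             "tad_parse_error")
  }
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)),
    error = function(e) {
      tad_stop(paste0("failed to parse VCF ", path, ": ", conditionMessage(e)),
               "tad_parse_error")
    }
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(chrom = character(0), position = integer(0),
                  refallele = character(0), altallele = character(0),
                  quality = numeric(0), dbsnpvariant = character(0),
                  genotype = character(0)))
  }
  gt <- if (ncol(v@gt) >= 2L) {
    fmt <- strsplit(v@gt[, 1L], ":", fixed = TRUE)
    val <- strsplit(v@gt[, 2L], ":", fixed = TRUE)
    mapply(function(f, x) {
      i <- match("GT", f)
      if (is.na(i) || i > length(x)) NA_character_ else x[i]
    }, fmt, val, USE.NAMES = FALSE)
  } else {
    warn(paste0(path, ": no genotype column; zygosity will be NULL"))
    rep(NA_character_, nrow(fix))
  }
  if (anyNA(gt)) warn(paste0(path, ": GT absent for some records; zygosity NULL"))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  tibble(
    chrom = fix$CHROM[idx],
    position = as.integer(fix$POS[idx]),
    refallele = fix$REF[idx],
    altallele = unlist(alts),
    quality = suppressWarnings(as.numeric(ifelse(fix$QUAL[idx] == ".", NA, fix$QUAL[idx]))),
    dbsnpvariant = ifelse(is.na(fix$ID[idx]) | fix$ID[idx] == ".", NA_character_, fix$ID[idx]),
    genotype = gt[idx]
  )
}

#' Classify a variant from its REF and ALT alleles
#'
#' Single-base substitution is a SNP; a length increase with REF a prefix of
#' ALT is an insertion; a length decrease with ALT a prefix of REF is a
#' deletion; anything else is complex.
#'
#' @param ref,alt allele strings (non-empty).
#' @return one of `"SNP"`, `"insertion"`, `"deletion"`, `"complex"`
#'   (vectorized).
#' @export
#' @examples
#' classify_variant(c("A", "A", "AT", "AT"), c("G", "AT", "A", "GC"))
classify_variant <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    tad_stop("empty allele", "tad_validation_error")
  }
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  out <- rep("complex", n)
  out[nchar(ref) == 1L & nchar(alt) == 1L] <- "SNP"
  ins <- nchar(alt) > nchar(ref) & substr(alt, 1L, nchar(ref)) == ref
  del <- nchar(ref) > nchar(alt) & substr(ref, 1L, nchar(alt)) == alt
  out[ins] <- "insertion"
  out[del] <- "deletion"
  out
}

#' Call zygosity from a VCF GT string
#'
#' @param genotype GT of the form `a/b` or `a|b`; any `.` allele yields NA.
#' @return `"homozygous"`, `"heterozygous"` or NA (vectorized).
#' @export
#' @examples
#' call_zygosity(c("1/1", "0/1", "./1"))
call_zygosity <- function(genotype) {
  out <- rep(NA_character_, length(genotype))
  parts <- strsplit(genotype, "[/|]")
  for (i in seq_along(genotype)) {
    g <- genotype[i]
    if (is.na(g)) next
    p <- parts[[i]]
    if (length(p) != 2L || !all(grepl("^([0-9]+|\\.)$", p))) {
      tad_stop(paste0("malformed genotype \"", g, "\""), "tad_validation_error")
    }
    if (any(p == ".")) next
    out[i] <- if (p[1] == p[2]) "homozygous" else "heterozygous"
  }
  out
}

#' Parse a default-format VEP annotation table
#'
#' Expects the tab-delimited output: `##` metadata lines, a
#' `#Uploaded_variation` header, and per-consequence rows. Records are keyed
#' by (chrom, position, alt) parsed from Location/Allele; a range Location
#' (`chrom:start-stop`, indels) takes the range start. `-` values become NA.
#'
#' @param path `.vep.txt` file.
#' @return tibble with `chrom`, `position`, `altallele`, `consequence`,
#'   `geneid`, `genename`, `transcript`, `feature`, `genetype`,
#'   `proteinposition`, `aachange`, `codonchange`, `source` (always "VEP").
#' @export
parse_vep <- function(path) {
  if (!file.exists(path)) tad_stop(paste0("no such file: ", path), "tad_missing_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#Uploaded_variation")) {
    tad_stop(paste0(path, " is not a default-format VEP table ",
                    "(missing #Uploaded_variation header)"), "tad_dialect_error")
  }
  hdr <- sub("^#", "", lines[1])
  df <- suppressMessages(readr::read_tsv(
    I(c(hdr, lines[-1])), col_types = readr::cols(.default = "c"), progress = FALSE))
  needed <- c("Location", "Allele", "Gene", "Feature", "Feature_type",
              "Consequence", "Protein_position", "Amino_acids", "Codons")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    tad_stop(paste0(path, " lacks VEP column ", missing[1]), "tad_dialect_error")
  }
  dash_na <- function(x) ifelse(is.na(x) | x == "-", NA_character_, x)
  loc <- strsplit(df$Location, ":", fixed = TRUE)
  chrom <- vapply(loc, `[`, character(1), 1L)
  posstr <- vapply(loc, `[`, character(1), 2L)
  position <- as.integer(sub("-.*$", "", posstr)) # range start for indels
  sym <- if ("SYMBOL" %in% names(df)) {
    dash_na(df$SYMBOL)
  } else if ("Extra" %in% names(df)) {
    # default output carries the gene symbol as SYMBOL=... in Extra
    vapply(seq_along(df$Extra), function(i) {
      hit <- regmatches(df$Extra[i], regexpr("SYMBOL=[^;]+", df$Extra[i]))
      if (length(hit)) sub("^SYMBOL=", "", hit) else NA_character_
    }, character(1))
  } else NA_character_
  tibble(
    chrom = chrom,
    position = position,
    altallele = dash_na(df$Allele),
    consequence = dash_na(df$Consequence),
    geneid = dash_na(df$Gene),
    genename = dplyr::coalesce(rep_len(sym, nrow(df)), dash_na(df$Gene)),
    transcript = dash_na(df$Feature),
    feature = dash_na(df$Feature_type),
    genetype = if ("BIOTYPE" %in% names(df)) dash_na(df$BIOTYPE) else NA_character_,
    proteinposition = suppressWarnings(as.integer(sub("[-/].*$", "", dash_na(df$Protein_position)))),
    aachange = dash_na(df$Amino_acids),
    codonchange = dash_na(df$Codons),
    source = "VEP"
  )
}

#' Parse an ANNOVAR multianno annotation table
#'
#' Expects the `.multianno.txt` TSV with Chr/Start/End/Ref/Alt plus
#' `Func.<db>`, `Gene.<db>`, `ExonicFunc.<db>` and `AAChange.<db>` columns
#' for one annotation database. `Func` maps to the variant's gene-relative
#' location (genetype), `ExonicFunc` to consequence, and the first AAChange
#' entry is split into transcript, protein position, amino-acid change and
#' codon change. `.` values become NA.
#'
#' @param path `.multianno.txt` file.
#' @return tibble with the same columns as [parse_vep()], `source` always
#'   "ANNOVAR".
#' @export
parse_annovar <- function(path) {
  if (!file.exists(path)) tad_stop(paste0("no such file: ", path), "tad_missing_error")
  df <- suppressMessages(readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                                         progress = FALSE))
  needed <- c("Chr", "Start", "End", "Ref", "Alt")
  missing <- setdiff(needed, names(df))
  func_col <- grep("^Func\\.", names(df), value = TRUE)
  gene_col <- grep("^Gene\\.", names(df), value = TRUE)
  exonic_col <- grep("^ExonicFunc\\.", names(df), value = TRUE)
  aach_col <- grep("^AAChange\\.", names(df), value = TRUE)
  if (length(missing) || !length(func_col) || !length(gene_col)) {
    tad_stop(paste0(path, " is not an ANNOVAR multianno table"), "tad_dialect_error")
  }
  dot_na <- function(x) ifelse(is.na(x) | x == ".", NA_character_, x)
  aach <- if (length(aach_col)) dot_na(df[[aach_col[1]]]) else rep(NA_character_, nrow(df))
  split_aa <- lapply(aach, parse_annovar_aachange)
  tibble(
    chrom = df$Chr,
    position = as.integer(df$Start),
    altallele = df$Alt,
    consequence = if (length(exonic_col)) dot_na(df[[exonic_col[1]]]) else NA_character_,
    geneid = dot_na(df[[gene_col[1]]]),
    genename = dot_na(df[[gene_col[1]]]),
    transcript = vapply(split_aa, `[[`, character(1), "transcript"),
    feature = NA_character_,
    genetype = dot_na(df[[func_col[1]]]),
    proteinposition = vapply(split_aa, `[[`, integer(1), "proteinposition"),
    aachange = vapply(split_aa, `[[`, character(1), "aachange"),
    codonchange = vapply(split_aa, `[[`, character(1), "codonchange"),
    source = "ANNOVAR"
  )
}

# "GENE:TRANSCRIPT[:exonN]:c.135A>G:p.K45K" -> components
parse_annovar_aachange <- function(x) {
  out <- list(transcript = NA_character_, proteinposition = NA_integer_,
              aachange = NA_character_, codonchange = NA_character_)
  if (is.na(x)) return(out)
  first <- strsplit(x, ",", fixed = TRUE)[[1]][1]
  parts <- strsplit(first, ":", fixed = TRUE)[[1]]
  if (length(parts) >= 2L) out$transcript <- parts[2]
  cpart <- grep("^c\\.", parts, value = TRUE)
  if (length(cpart)) out$codonchange <- sub("^c\\.", "", cpart[1])
  ppart <- grep("^p\\.", parts, value = TRUE)
  if (length(ppart)) {
    out$aachange <- sub("^p\\.", "", ppart[1])
    pp <- regmatches(out$aachange, regexpr("[0-9]+", out$aachange))
    if (length(pp)) out$proteinposition <- as.integer(pp)
  }
  out
}
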