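#' Parse a gene-abundance file into normalized expression rows
#'
#' Supports the four quantifier dialects: the `genes.fpkm_tracking` table
#' (FPKM with confidence bounds and status, locus as `chrom:start-stop`),
#' the gene-abundance table with Coverage/FPKM/TPM columns, the
#' pseudo-alignment `abundance.tsv` (tpm, est_counts) and `quant.sf`
#' (TPM, NumReads). Fields a dialect lacks come back as NA and are stored as
#' NULL; negative abundances are a validation error.
#'
#' @param path abundance file.
#' @param dialect one of `"cufflinks"`, `"stringtie"`, `"kallisto"`,
#'   `"salmon"`.
#' @return tibble with columns `chrom`, `start`, `stop`, `genename`,
#'   `geneid`, `coverage`, `tpm`, `fpkm`, `fpkmconflow`, `fpkmconfhigh`,
#'   `fpkmstatus`.
#' @export
parse_expression <- function(path, dialect = c("cufflinks", "stringtie",
                                               "kallisto", "salmon")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) tad_stop(paste0("no such file: ", path), "tad_missing_error")
  df <- suppressMessages(readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                                         progress = FALSE))
  out <- switch(dialect,
    cufflinks = parse_expr_cufflinks(df, path),
    stringtie = parse_expr_stringtie(df, path),
    kallisto = parse_expr_kallisto(df, path),
    salmon = parse_expr_salmon(df, path)
  )
  for (col in c("coverage", "tpm", "fpkm", "fpkmconflow", "fpkmconfhigh")) {
    bad <- which(!is.na(out[[col]]) & out[[col]] < 0)
    if (length(bad)) {
      tad_stop(paste0("negative abundance in ", col, " at row ", bad[1]),
               "tad_validation_error")
    }
  }
  out
}

expr_dialect_check <- function(df, needed, dialect, path) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    tad_stop(paste0(path, " does not look like a ", dialect,
                    " abundance file (missing column ", missing[1], ")"),
             "tad_dialect_error")
  }
}

num <- function(x) suppressWarnings(as.numeric(x))

empty_expr <- function(n) tibble(
  chrom = rep(NA_character_, n), start = rep(NA_integer_, n),
  stop = rep(NA_integer_, n), genename = rep(NA_character_, n),
  geneid = rep(NA_character_, n), coverage = rep(NA_real_, n),
  tpm = rep(NA_real_, n), fpkm = rep(NA_real_, n),
  fpkmconflow = rep(NA_real_, n), fpkmconfhigh = rep(NA_real_, n),
  fpkmstatus = rep(NA_character_, n)
)

parse_expr_cufflinks <- function(df, path) {
  expr_dialect_check(df, c("tracking_id", "gene_short_name", "locus", "FPKM",
                           "FPKM_conf_lo", "FPKM_conf_hi", "FPKM_status"),
                     "cufflinks", path)
  out <- empty_expr(nrow(df))
  loc <- str_match_locus(df$locus)
  out$chrom <- loc$chrom
  out$start <- loc$start
  out$stop <- loc$stop
  out$genename <- df$gene_short_name
  out$geneid <- df$gene_id %||% df$tracking_id
  out$coverage <- num(df$coverage %||% NA)
  out$fpkm <- num(df$FPKM)
  out$fpkmconflow <- num(df$FPKM_conf_lo)
  out$fpkmconfhigh <- num(df$FPKM_conf_hi)
  out$fpkmstatus <- df$FPKM_status
  out
}

parse_expr_stringtie <- function(df, path) {
  expr_dialect_check(df, c("Gene ID", "Gene Name", "Reference", "Start", "End",
                           "Coverage", "FPKM", "TPM"), "stringtie", path)
  out <- empty_expr(nrow(df))
  out$chrom <- df$Reference
  out$start <- as.integer(num(df$Start))
  out$stop <- as.integer(num(df$End))
  out$genename <- df$`Gene Name`
  out$geneid <- df$`Gene ID`
  out$coverage <- num(df$Coverage)
  out$fpkm <- num(df$FPKM)
  out$tpm <- num(df$TPM)
  out
}

parse_expr_kallisto <- function(df, path) {
  expr_dialect_check(df, c("target_id", "length", "eff_length", "est_counts", "tpm"),
                     "kallisto", path)
  out <- empty_expr(nrow(df))
  out$genename <- df$target_id
  out$geneid <- df$target_id
  out$tpm <- num(df$tpm)
  out
}

parse_expr_salmon <- function(df, path) {
  expr_dialect_check(df, c("Name", "Length", "EffectiveLength", "TPM", "NumReads"),
                     "salmon", path)
  out <- empty_expr(nrow(df))
  out$genename <- df$Name
  out$geneid <- df$Name
  out$tpm <- num(df$TPM)
  out
}

# "chrom:start-stop" locus strings; anything else -> NA triple
str_match_locus <- function(locus) {
  m <- regexec("^([^:]+):([0-9]+)-([0-9]+)$", locus %||% character(0))
  parts <- regmatches(locus, m)
  chrom <- vapply(parts, function(p) if (length(p)) p[2] else NA_character_, character(1))
  start <- vapply(parts, function(p) if (length(p)) as.integer(p[3]) else NA_integer_, integer(1))
  stop <- vapply(parts, function(p) if (length(p)) as.integer(p[4]) else NA_integer_, integer(1))
  list(chrom = chrom, start = start, stop = stop)
}

#' Parse a per-gene read-count file
#'
#' Dialects: the two-column count output (special rows prefixed `__`, e.g.
#' `__no_feature`, are excluded from gene rows but tallied), the
#' featureCounts table (`#`-comment line then Geneid..counts columns), and
#' the per-gene counts table from the aligner's quantification mode
#' (4 columns, `N_`-prefixed QC rows, unstranded counts in column 2).
#'
#' @param path counts file.
#' @param dialect `"htseq"`, `"featurecounts"` or `"star_quantmode"`.
#' @return tibble with `genename`, `readcount`; attribute `special_rows`
#'   holds the tally of excluded QC rows.
#' @export
parse_readcounts <- function(path, dialect = c("htseq", "featurecounts",
                                               "star_quantmode")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) tad_stop(paste0("no such file: ", path), "tad_missing_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn(paste0("empty counts file: ", path))
    out <- tibble(genename = character(0), readcount = integer(0))
    attr(out, "special_rows") <- 0L
    return(out)
  }
  out <- switch(dialect,
    htseq = {
      f <- strsplit(lines, "\t", fixed = TRUE)
      if (any(vapply(f, length, integer(1)) < 2L)) {
        tad_stop(paste0(path, " is not a two-column count file"), "tad_dialect_error")
      }
      genes <- vapply(f, `[`, character(1), 1L)
      counts <- vapply(f, `[`, character(1), 2L)
      special <- startsWith(genes, "__")
      res <- tibble(genename = genes[!special], readcount = counts[!special])
      attr(res, "special_rows") <- sum(special)
      res
    },
    featurecounts = {
      lines2 <- lines[!startsWith(lines, "#")]
      f <- strsplit(lines2, "\t", fixed = TRUE)
      hdr <- f[[1]]
      if (hdr[1] != "Geneid" || length(hdr) < 7L) {
        tad_stop(paste0(path, " is not a featureCounts table"), "tad_dialect_error")
      }
      body <- f[-1]
      res <- tibble(
        genename = vapply(body, `[`, character(1), 1L),
        readcount = vapply(body, `[`, character(1), length(hdr))
      )
      attr(res, "special_rows") <- 0L
      res
    },
    star_quantmode = {
      f <- strsplit(lines, "\t", fixed = TRUE)
      if (any(vapply(f, length, integer(1)) != 4L)) {
        tad_stop(paste0(path, " is not a 4-column per-gene counts table"),
                 "tad_dialect_error")
      }
      genes <- vapply(f, `[`, character(1), 1L)
      counts <- vapply(f, `[`, character(1), 2L) # column 2: unstranded
      special <- startsWith(genes, "N_")
      res <- tibble(genename = genes[!special], readcount = counts[!special])
      attr(res, "special_rows") <- sum(special)
      res
    }
  )
  sp <- attr(out, "special_rows")
  counts <- suppressWarnings(as.numeric(out$readcount))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    tad_stop(paste0("non-integer or negative count \"", out$readcount[bad[1]],
                    "\" for gene ", out$genename[bad[1]]), "tad_validation_error")
  }
  out$readcount <- as.integer(counts)
  attr(out, "special_rows") <- sp
  out
}
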