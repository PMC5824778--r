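#' Summarize read alignment from a SAM text file or an aligner summary
#'
#' For SAM input, total reads are the primary records (FLAG bits 0x100
#' *secondary* and 0x800 *supplementary* unset) and mapped reads are those
#' with bit 0x4 *unmapped* additionally unset. Summary input accepts the
#' spliced-aligner report dialects: the `align_summary.txt` style
#' (`Input:`/`Mapped:` lines with an `overall read mapping rate`) and the
#' newer style (`N reads; of these:` with an `overall alignment rate`).
#'
#' @param path SAM text file or summary text file.
#' @return tibble with `total_reads`, `mapped_reads`, `alignment_rate`
#'   (0 when no primary records), `mapper_name`, `date` (file mtime,
#'   ISO date).
#' @export
summarize_alignment <- function(path) {
  if (!file.exists(path)) tad_stop(paste0("no such file: ", path), "tad_missing_error")
  lines <- readLines(path, warn = FALSE)
  fdate <- format(as.Date(file.info(path)$mtime), "%Y-%m-%d")
  res <- parse_sam_flags(lines) %||%
    parse_hisat_summary(lines) %||%
    parse_tophat_summary(lines)
  if (is.null(res)) {
    tad_stop(paste0(
      "unrecognized alignment file dialect for ", path,
      " (tried: SAM text, overall-alignment-rate summary, align_summary.txt)"),
      "tad_dialect_error")
  }
  res$date <- fdate
  as_tibble(res)
}

parse_sam_flags <- function(lines) {
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (!length(body)) return(NULL)
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 11L)) return(NULL)
  flags <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  if (anyNA(flags)) return(NULL)
  primary <- bitwAnd(flags, 0x100L) == 0L & bitwAnd(flags, 0x800L) == 0L
  total <- sum(primary)
  mapped <- sum(primary & bitwAnd(flags, 0x4L) == 0L)
  list(total_reads = total, mapped_reads = mapped,
       alignment_rate = if (total > 0) mapped / total else 0,
       mapper_name = "SAM")
}

parse_hisat_summary <- function(lines) {
  m <- regmatches(lines, regexpr("^\\s*([0-9]+) reads; of these:", lines))
  rate_line <- grep("overall alignment rate", lines, value = TRUE)
  if (!length(m) || !length(rate_line)) return(NULL)
  total <- as.numeric(sub("^\\s*([0-9]+) reads.*", "\\1", m[1]))
  rate <- as.numeric(sub(".*?([0-9.]+)% overall alignment rate.*", "\\1", rate_line[1])) / 100
  list(total_reads = total, mapped_reads = round(total * rate),
       alignment_rate = rate, mapper_name = "HISAT2")
}

parse_tophat_summary <- function(lines) {
  inp <- grep("^\\s*Input\\s*:", lines, value = TRUE)
  map <- grep("^\\s*Mapped\\s*:", lines, value = TRUE)
  if (!length(inp) || !length(map)) return(NULL)
  total <- as.numeric(sub("^[^:]*:\\s*([0-9]+).*", "\\1", inp[1]))
  mapped <- as.numeric(sub("^[^:]*:\\s*([0-9]+).*", "\\1", map[1]))
  rate_line <- grep("overall read mapping rate", lines, value = TRUE)
  rate <- if (length(rate_line)) {
    as.numeric(sub(".*?([0-9.]+)% overall read mapping rate.*", "\\1", rate_line[1])) / 100
  } else if (total > 0) mapped / total else 0
  list(total_reads = total, mapped_reads = mapped,
       alignment_rate = rate, mapper_name = "TopHat2")
}
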