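#' Plot per-sample, per-chromosome variant counts
#'
#' Bar chart of [export_chrvar()] output, one panel per sample.
#'
#' @param chrvar tibble from [export_chrvar()].
#' @return a ggplot object.
#' @export
plot_chrvar <- function(chrvar) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    tad_stop("plotting requires the ggplot2 package", "tad_missing_error")
  }
  ggplot2::ggplot(chrvar, ggplot2::aes(x = .data$chrom, y = .data$variant_count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sampleid)) +
    ggplot2::labs(x = "chromosome", y = "variants",
                  title = "Variant distribution by chromosome")
}

#' Plot per-tissue expression summaries of selected genes
#'
#' Point-range plot of [export_avgfpkm()] output (min, mean, max abundance
#' per gene and tissue).
#'
#' @param avgfpkm tibble from [export_avgfpkm()].
#' @return a ggplot object.
#' @export
plot_avgfpkm <- function(avgfpkm) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    tad_stop("plotting requires the ggplot2 package", "tad_missing_error")
  }
  ggplot2::ggplot(avgfpkm, ggplot2::aes(x = .data$genename, y = .data$avg_fpkm,
                                        ymin = .data$min_fpkm,
                                        ymax = .data$max_fpkm,
                                        colour = .data$tissue)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "abundance (FPKM/TPM)",
                  title = "Expression summary by tissue")
}

#' One-row summary of a store's contents
#'
#' Broom-style glance: sample count, per-partition row counts, and log line
#' count.
#'
#' @param x a `tad_store`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.tad_store <- function(x, ...) {
  samples <- store_query(x, "SELECT COUNT(*) AS n FROM Sample")$n
  tibble(
    samples = as.integer(samples),
    variant_rows = store_partition(x, "variant")$row_count,
    expression_rows = store_partition(x, "expression")$row_count,
    readcount_rows = store_partition(x, "readcount")$row_count,
    log_lines = length(read_log(x))
  )
}

#' @export
glance <- function(x, ...) UseMethod("glance")
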