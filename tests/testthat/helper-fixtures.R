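# shared fixture builders: everything is generated in code at test time

new_tmp <- function(...) {
  d <- file.path(tempfile("tadtest"), ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# small typed partition used across columnar tests
toy_partition <- function(dir = new_tmp("part")) {
  p <- create_partition(dir, data.frame(
    name = c("gene", "chrom", "tpm", "pos"),
    kind = c("text", "key", "double", "int")
  ))
  append_rows(p, tibble::tibble(
    gene = c("OPTN", "G2", "OPTN", NA, "g5", "G2"),
    chrom = c("1", "2", "1", "2", "3", "1"),
    tpm = c(1.5, 0, 2.25, NA, 10, 4),
    pos = c(10L, 20L, 30L, NA, 50L, 60L)
  ))
  open_partition(dir)
}

# random partition + data for oracle-equivalence property tests
random_partition <- function(n, dir = new_tmp("rand")) {
  df <- tibble::tibble(
    id = sprintf("S%03d", sample.int(20L, n, replace = TRUE)),
    chrom = as.character(sample(1:4, n, replace = TRUE)),
    gene = sample(c(sprintf("GENE%02d", 1:8), "NULL"), n, replace = TRUE),
    pos = sample.int(10000L, n, replace = TRUE),
    score = round(stats::rnorm(n, 50, 20), 3)
  )
  p <- create_partition(dir, data.frame(
    name = names(df), kind = c("text", "key", "text", "int", "double")
  ))
  append_rows(p, df)
  list(part = open_partition(dir), df = df)
}

# an installed store pre-loaded with the two-sample optineurin scenario
optn_store <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sdir <- new_tmp("optn_study")
      generate_optn_scenario(seed = 42, dir = sdir)
      cache <<- list(
        store = import_study(sdir, new_tmp("optn_store")),
        study_dir = sdir,
        ledger = read_tsv_table(file.path(sdir, "ledger.tsv"))
      )
    }
    cache
  }
})

# a generated multi-organism study imported into a fresh store
study_store <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sdir <- new_tmp("gen_study")
      cfg <- study_config(seed = 11, genes_per_sample = 30L,
                          variants_per_sample = 15L)
      generate_study(cfg, sdir)
      cache <<- list(
        store = import_study(sdir, new_tmp("gen_store")),
        study_dir = sdir, config = cfg,
        ledger = read_tsv_table(file.path(sdir, "ledger.tsv"))
      )
    }
    cache
  }
})

ledger_value <- function(ledger, sample, metric) {
  ledger$value[ledger$sample == sample & ledger$metric == metric]
}

# minimal valid sample record
toy_record <- function(name = "GGA_UD_1004", ...) {
  utils::modifyList(list(
    sample_name = name, derived_from = "GGA_ANIMAL_1",
    organism = "Gallus gallus", organism_part = "Pituitary gland",
    first_name = "Ada", last_name = "Lovelace",
    organization = "Synthetic Institute"
  ), list(...))
}
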