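Package: rnadepot
Title: Hybrid Relational and Columnar Warehouse for RNA-Seq Expression,
    Metadata and Variant Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stores, validates, queries and exports RNA-seq sample metadata,
    gene-expression quantifications and gene-associated variants with their
    predicted functional annotations. Sample metadata and per-sample analysis
    summaries live in an embedded relational store with enforced referential
    integrity, views and named queries; the large per-gene and per-variant
    result sets live in an append-only column-oriented store with compressed
    bitmap equality indexes and an SQL-subset query engine. Parsers are
    provided for FAANG-template sample sheets, aligner summaries and SAM text,
    Cufflinks/StringTie/kallisto/Salmon abundance files, htseq-count,
    featureCounts and STAR per-gene counts, VCF v4, and VEP or ANNOVAR
    annotation tables. Exports include tab-delimited research summaries and
    annotated VCF with CSQ/MTD INFO keys, plus a command-line toolkit and a
    deterministic synthetic-study generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    purrr,
    readr,
    readxl,
    rlang,
    tibble,
    tidyr,
    vcfR
Suggests:
    VariantAnnotation,
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
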