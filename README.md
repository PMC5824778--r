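# rnadepot

A desk-scale warehouse for RNA-seq analysis results: sample metadata,
gene-expression quantifications and gene-associated variants with their
predicted functional annotations, stored once and queried uniformly.

Transcriptome studies leave behind a sprawl of per-sample result files —
aligner summaries, abundance tables in whichever quantifier dialect the lab
used that year, per-gene read counts, VCFs and annotation tables. `rnadepot`
is for the scientist who wants those results in one consistent, queryable
place. It follows the hybrid storage pattern used by transcriptome
warehouses:

- a **relational store** (embedded SQLite) holds the small, integrity-critical
  data: samples, animals, organisms, tissues, people, per-sample analysis
  summaries — 23 tables tied together by parent–child foreign keys, plus 6
  views and 4 registered named queries (`usp_vall`, `usp_vchrom`,
  `usp_vchrposition`, `usp_vgene`);
- a **column-oriented store** holds the large result sets (per-gene
  expression, per-gene read counts, per-variant annotations) as append-only
  partitions with one file per column and compressed **bitmap equality
  indexes** — per distinct value *v* of a column, a bit vector
  `b[i] = 1 ⇔ row i has value v`, run-length encoded in 31-bit aligned
  words — queried through an SQL subset
  (`select … where … group by … order by … limit …`, conjunctive predicates,
  no FROM clause needed).

Every columnar row is denormalized with `(sampleid, organism, tissue)` from
the relational side, so both stores answer the same questions; the
relational side guarantees the integrity the columnar side gives up for
speed.

## Worked example

The package ships a deterministic study generator, so the example is fully
reproducible:

```r
library(rnadepot)

study <- file.path(tempdir(), "study")
generate_study(study_config(seed = 7), study)   # 2 organisms x 2 samples
store <- import_study(study, file.path(tempdir(), "store"))

glance(store)
#> # A tibble: 1 × 5
#>   samples variant_rows expression_rows readcount_rows log_lines
#>     <int>        <int>           <int>          <int>     <int>
#> 1       4          100             240            240        25
```

Four samples were imported end to end: 240 expression rows (4 samples × 60
genes), 100 variant rows, and one transaction-log line per import stage.
Query the columnar side directly:

```r
part <- rnadepot:::store_partition(store, "expression")
execute_query(part,
  "select genename, avg(fpkm) where tpm > 100 group by genename order by genename limit 3")
```

or use the research exports — `export_avgfpkm()` (per-tissue min/mean/max of
selected genes), `export_genexp()` (gene × sample matrix), `export_chrvar()`
(variant counts by chromosome) and `export_varanno()` (variants plus
annotations as TSV, or as VCF v4 with annotations packed into the INFO keys
`CSQ` and `MTD`, `|`-separated subfields declared in the header).

The two-sample optineurin scenario shows the intended style of analysis: a
gene whose per-tissue summary shows identical min/avg/max values turns out,
per sample, to be unexpressed in one sample — and the variant view then
shows that sample carrying several synonymous SNPs in the gene region:

```r
sc <- file.path(tempdir(), "optn"); generate_optn_scenario(1, sc)
s2 <- import_study(sc, file.path(tempdir(), "optn_store"))
export_genexp(s2, "Gallus gallus", absent = "zero")
#> # A tibble: 4 × 3
#>   genename GGA_UD_1004 GGA_UD_1014
#> 1 CTRLEQ          12.5        12.5
#> 2 GENEA            3.2         5.9
#> 3 GENEB           21.7        14.3
#> 4 OPTN             8.4         0
dplyr::count(
  subset(variants_select(s2, list(gene = "OPTN")),
         consequence == "synonymous_variant"), sampleid)
#>   sampleid        n
#> 1 GGA_UD_1004     1
#> 2 GGA_UD_1014     6
```

A command-line wrapper lives at `inst/cli/tad.R`
(`Rscript tad.R install|import|export|interact <store> [flags]`), with
`--metadata`, `--data2db`, `--all/--gene/--variant`, `--delete`, `--query`
and `--db2data` flags and a seven-choice interactive menu.

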