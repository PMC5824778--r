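---
title: "Methods: hybrid storage for RNA-seq results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid storage for RNA-seq results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadepot)
```

## The storage model and its assumptions

RNA-seq result warehousing faces two opposite pressures. Sample metadata is
small, heavily cross-referenced and must stay consistent: a result row whose
sample no longer exists is worse than useless. Per-gene and per-variant
result sets are large, write-once and queried by simple predicates. The
package therefore splits storage:

* **Relational side** (embedded SQLite). Samples, animals, organisms,
  tissues, people, organizations and the per-sample summaries (alignment,
  expression, counts, variants) live in 23 tables with declared parent–child
  foreign keys. Dimension rows are get-or-created by case-sensitive exact
  match, so two samples from *Gallus gallus* share one Organism row. Six
  views expose the common joins; the four variant procedures are registered
  named queries run by the package with bound parameters — observably
  identical to stored procedures, without requiring a server-side procedure
  language.
* **Columnar side**. Three append-only partitions (`variant`, `expression`,
  `readcount`) store one plain-text file per column plus a descriptor.
  Each partition's schema mirrors the relational field vocabulary, and every
  row carries `(sampleid, organism, tissue)` denormalized from the
  relational join at import time. Denormalization is an assumption, not an
  invariant the store enforces continuously — it holds because imports are
  the only writer and deletes remove whole samples from both sides.

The model assumes single-writer, desk-scale use: one process imports or
deletes at a time. Multi-user locking, authentication and network access are
out of scope.

## Bitmap indexes

Equality-heavy queries (`chrom = '6'`, `sampleid = 'GGA_UD_1004'`) are
served by bitmap indexes: for each distinct value of a column, a bit vector
over all rows. Vectors are compressed with a word-aligned run-length scheme
(31-bit groups; maximal all-zero or all-one runs collapse to one fill word,
mixed groups are stored literally). The contract is scan-equivalence: an
index may only ever return exactly the rows a full scan returns, which the
tests enforce directly, with and without indexes built. Indexes record the
row count they were built at; an append makes them stale and the engine
falls back to scanning until they are rebuilt (deletion rebuilds them
eagerly, since deletion already rewrites the partition).

Missing values are *queryable*: string columns store the literal `NULL`
(so `genename != 'NULL'` is a meaningful predicate), doubles store `NaN`,
integers an `NA` sentinel. Doubles are serialized with 17 significant
digits, making read-back bit-exact.

## The query subset

The engine parses `select` statements with projections, `count/sum/avg/
min/max` aggregates, conjunctive predicates (`=`, `!=`, `<`, `<=`, `>`,
`>=`, `like`), `group by`, `order by` and `limit`. A `from` clause is
tolerated and ignored for columnar targets — the partition is chosen
separately. `or` is rejected with an explicit message rather than silently
mis-handled, as are joins: cross-partition joins belong to the relational
side, where the views implement them.

Numeric comparison is numeric on `int`/`double` columns and lexicographic
on strings; `like` is case-insensitive with `%` matching any (possibly
empty) substring, while `=` stays case-sensitive — mirroring the default
behaviour of the relational engine so the two query surfaces agree.
Ordering is ascending by default and stable (ties keep insertion order);
`limit` applies after ordering; `avg` is `sum/count` in double precision.

## Import discipline

`import_sample()` parses every input file *before* touching either store.
Relational writes then happen inside one transaction; columnar appends are
verified by the double-entry rule (rows parsed must equal rows stored, per
stage) before the transaction commits, and a failure deletes the appended
columnar rows and rolls the transaction back. A truncated VCF therefore
leaves both stores byte-identical to their pre-import state. Results import
once per sample; re-import requires an explicit delete, which removes the
sample everywhere and resets the rule.

Annotations join variants on `(chrom, position, alt allele)`, taking the
range start as the position for indel annotations. Annotation rows that
match no variant are dropped (counted in the report); a variant with
several annotations contributes several variant-partition rows, so
conservation checks count *distinct* `(position, ref, alt)` triples.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `samples_per_organism` | 2 | samples generated per organism |
| `genes_per_sample` | 60 | genes quantified per sample |
| `variants_per_sample` | 25 | variant records per sample (before site dedup) |
| abundance distribution | log-normal(2, 1) | right-skewed bulk expression shape |
| variant class weights | 0.8/0.1/0.1 | SNP/insertion/deletion mix |
| `absent` (`export_genexp`) | `"na"` | unquantified gene cells: NA or 0 |
| `fuzzy` (gene selectors) | `TRUE` | case-insensitive substring match |

Fuzzy gene matching is deliberately generous (substring containment) — it is
a discovery aid, with `fuzzy = FALSE` for exact lookups.

## What the generator emulates, and what it does not

`generate_study()` produces internally consistent trees in all accepted
dialects — metadata sheet (TSV always, two-sheet workbook on request),
aligner summary, one quantifier file per sample rotating across the four
dialects, a counter file rotating across the three count dialects, VCF with
genotypes, and one VEP or ANNOVAR annotation per variant — with a ledger
recording every generated count so tests assert against known truth. Sizes
default to desk scale (a few samples, tens of genes) so the full suite runs
in well under a minute.

It does *not* emulate: multi-annotation VEP output (one consequence per
variant is generated; multi-annotation packing is exercised by a dedicated
unit fixture), biological sequence content, linkage between expression and
variant dosage, or ragged/malformed files beyond the deliberate truncation
tests. Passing tests show the plumbing is correct on well-formed inputs of
every dialect, not that the parsers survive arbitrarily damaged files.

The two-sample scenario pins the use-case contrasts exactly: one sample
expresses OPTN and carries one synonymous SNP in its region, the other has
FPKM 0 and carries six; a control gene has identical abundance in both so
its per-tissue summary shows min = avg = max. Its OPTN coordinates are
synthetic — a labelled stand-in, not real genome annotation.

## Numerical and design choices

* **Workbook emission is off by default** in the generator: xlsx archives
  embed timestamps, which would break the byte-identical-trees determinism
  property; the TSV twin is always written. (Workbook writing shells out to
  the Python openpyxl toolchain, the one xlsx writer available here;
  reading uses readxl.)
* **View set**: the six views are `vw_sample`, `vw_nosql`, `vw_sampleinfo`,
  `vw_seqstats`, `vw_vanno`, `vw_vvcf`. `vw_nosql` is the columnar-template
  view (variant rows in partition column order); `vw_sample` is the
  sample-details join.
* **VCF export** fixes the version string at `VCFv4.2`, packs all of a
  variant's annotations into comma-separated `CSQ` entries
  (`source|consequence|geneid|genename|transcript|feature|genetype|`
  `proteinposition|aachange|codonchange`, order declared in the header) and
  emits one record per sample sharing a variant, since `MTD`
  (`sampleid|organism|tissue`) is single-valued. Reserved INFO characters
  inside subfields are replaced by `_`. Records sort by chromosome
  (numeric labels first, in numeric order) then position.
* **Variant classes**: equal-length single bases are SNPs; prefix-preserving
  length changes are insertions/deletions; anything else is `complex`,
  tallied in VarSummary's `othercount` so the SNP+ins+del+other total always
  reconciles.
* **Naming-scheme violations warn rather than fail**: the
  `<species>_<lab>_<id>` convention is recommended, but free-form
  tab-delimited metadata is accepted.
* **AnimalStats/SampleStats** are key–value attribute tables: their exact
  column inventories are open-ended by design, and key–value rows accept
  any future attribute without schema migration.
* **Interactive menu**: seven choices spanning the documented query surface
  (sample summary, sequencing stats, per-tissue gene summary, expression
  matrix, variants by gene, variants by region, raw query), previews
  truncated at 20 rows.

## Known limitations

* The SQL subset has no `or`, no joins, no subqueries, no `distinct`; the
  relational side covers those needs.
* Bitmap indexes accelerate equality only; range predicates always scan.
* The columnar store trusts its descriptor; concurrent writers can corrupt
  a partition (single-writer assumption).
* BAM input is accepted only as SAM text (flag statistics need no binary
  decoding); alignment summaries cover the two mainstream spliced-aligner
  report dialects.
* Deletion compacts partitions by rewrite, which is O(partition size) —
  appropriate at desk scale, not for archival-size partitions.
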