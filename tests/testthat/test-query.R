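test_that("the parser captures projection, predicates, ordering and limit", {
  ast <- parse_query(paste(
    "select sampleid, chrom, start, stop, genename",
    "where organism like 'Canis familia%' and genename != 'NULL'",
    "order by chrom limit 10"))
  expect_length(ast$projection, 5)
  expect_length(ast$predicates, 2)
  expect_equal(ast$predicates[[1]]$op, "like")
  expect_equal(ast$predicates[[2]]$op, "!=")
  expect_equal(ast$order_by, list(column = "chrom", desc = FALSE))
  expect_equal(ast$limit, 10L)

  agg <- parse_query("select count(*)")
  expect_equal(agg$projection[[1]],
               list(kind = "agg", fn = "count", column = "*"))
  expect_length(agg$predicates, 0)
})

test_that("syntax errors report position; unsupported constructs are named", {
  err <- tryCatch(parse_query("select * wehre x = 1"), error = identity)
  expect_s3_class(err, "tad_parse_error")
  expect_match(conditionMessage(err), "position 10")
  expect_match(conditionMessage(err), "wehre")
  expect_error(parse_query("select a where x = 1 or y = 2"), "OR predicates")
  expect_error(parse_query(""), "empty query")
  expect_error(parse_query("select a where x ~ 1"), "syntax error")
})

test_that("a FROM clause is tolerated and recorded but does not change execution", {
  p <- toy_partition()
  with_from <- execute_query(p, "select gene from whatever where chrom = '1'")
  without <- execute_query(p, "select gene where chrom = '1'")
  expect_equal(with_from, without)
  expect_equal(parse_query("select gene from vtable")$from, "vtable")
})

test_that("grouped aggregates match hand-computed means on a toy table", {
  d <- new_tmp("agg6")
  p <- create_partition(d, data.frame(name = c("genename", "fpkm"),
                                      kind = c("text", "double")))
  append_rows(p, tibble::tibble(
    genename = c("A", "A", "B", "B", "B", "C"),
    fpkm = c(1.5, 2.5, 10, 20, 40, 7)
  ))
  p <- open_partition(d)
  got <- execute_query(p, "select genename, avg(fpkm) group by genename")
  # hand-computed: A (1.5+2.5)/2, B (10+20+40)/3, C 7
  expect_equal(got$genename, c("A", "B", "C"))
  expect_equal(got$`avg(fpkm)`, c(2.0, 70 / 3, 7.0), tolerance = 1e-9)
  expect_equal(execute_query(p, "select sum(fpkm)")[[1]], 81)
  expect_error(execute_query(p, "select avg(genename)"), "numeric")
})

test_that("count on an empty partition is zero", {
  d <- new_tmp("empty")
  p <- create_partition(d, data.frame(name = "x", kind = "int"))
  expect_equal(execute_query(p, "select count(*)")[[1]], 0L)
})

test_that("LIKE is case-insensitive, '=' case-sensitive, LIMIT after ORDER", {
  p <- toy_partition()
  expect_equal(nrow(execute_query(p, "select gene where gene like 'optn'")), 2)
  expect_equal(nrow(execute_query(p, "select gene where gene like 'g%'")), 3)
  expect_equal(nrow(execute_query(p, "select gene where gene = 'g2'")), 0)
  top <- execute_query(p, "select gene, tpm where tpm >= 0 order by tpm desc limit 2")
  expect_equal(top$tpm, c(10, 4))
  # NULL text is queryable literally
  expect_equal(nrow(execute_query(p, "select gene where gene != 'NULL'")), 5)
})

test_that("unknown columns and invalid aggregate mixes are rejected", {
  p <- toy_partition()
  expect_error(execute_query(p, "select nosuch"), "unknown column: nosuch")
  expect_error(execute_query(p, "select gene, count(*)"), "GROUP BY")
})

test_that("seeded random queries match the naive full-scan evaluator", {
  set.seed(314)
  rp <- random_partition(400)
  # without indexes
  queries <- replicate(40, random_query())
  for (q in queries) expect_query_equivalence(rp$part, rp$df, q)
  # with bitmap indexes on the string columns
  for (col in c("id", "chrom", "gene")) build_bitmap_index(rp$part, col)
  for (q in queries) expect_query_equivalence(rp$part, rp$df, q)
})

test_that("indexed equality answers exactly match scan answers after appends", {
  set.seed(99)
  rp <- random_partition(200)
  build_bitmap_index(rp$part, "chrom")
  more <- tibble::tibble(
    id = "S999", chrom = "4", gene = "GENE01", pos = 1L, score = 0.5)
  append_rows(rp$part, more)
  p <- open_partition(rp$part$path)
  # index is stale after the append: engine must fall back to scan
  got <- execute_query(p, "select count(*) where chrom = '4'")[[1]]
  df <- rbind(rp$df, more)
  expect_equal(got, sum(df$chrom == "4"))
  build_bitmap_index(p, "chrom")
  expect_equal(execute_query(p, "select count(*) where chrom = '4'")[[1]],
               sum(df$chrom == "4"))
})
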