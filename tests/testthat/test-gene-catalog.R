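test_that("BED and GTF dialects yield identical gene lengths", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tgA", "chr1\t1000\t1800\tgB"), bed)
  rec_bed <- read_gene_annotation(bed)
  expect_equal(rec_bed$length_bp, c(500, 800))
  expect_equal(rec_bed$gene_id, c("gA", "gB"))

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t101\t600\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t1";'),
    paste0("chr1\tsrc\ttranscript\t1001\t1800\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "gB.t1";')
  ), gtf)
  rec_gtf <- read_gene_annotation(gtf)
  expect_equal(rec_gtf$length_bp, rec_bed$length_bp)
  expect_equal(rec_gtf$start, rec_bed$start)
  expect_equal(rec_gtf$end, rec_bed$end)
})

test_that("longest transcript per gene wins, ties broken by transcript id", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ts\ttranscript\t101\t600\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.short";'),
    paste0("chr1\ts\ttranscript\t101\t900\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.long";'),
    # two spans of 300 for gB; "gB.a" sorts before "gB.b"
    paste0("chr1\ts\ttranscript\t2001\t2300\t.\t+\t.\t",
           'gene_id "gB"; transcript_id "gB.b";'),
    paste0("chr1\ts\ttranscript\t3001\t3300\t.\t+\t.\t",
           'gene_id "gB"; transcript_id "gB.a";')
  ), gtf)
  rec <- read_gene_annotation(gtf)
  expect_equal(rec$length_bp[rec$gene_id == "gA"], 800)
  expect_equal(rec$start[rec$gene_id == "gB"], 3000)  # 0-based from gB.a
})

test_that("unparseable annotation errors and empty files error", {
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines("not a gtf line at all", bad)
  expect_error(read_gene_annotation(bad), "failed to parse")
})

test_that("length and expression filters match the catalog inclusion rules", {
  genes <- tibble::tibble(
    gene_id = c("short", "ok", "long", "silent"),
    length_bp = c(4999, 6000, 750001, 10000),
    expression_raw = c(5, 5, 5, 0)
  )
  out <- suppressMessages(
    filter_genes(genes, min_length_bp = 5000, max_length_bp = 750000,
                 require_expressed = TRUE)
  )
  expect_equal(out$gene_id, "ok")
  expect_equal(unname(attr(out, "removed")),
               c(1L, 1L, 1L))
  # boundary genes are retained (filters are inclusive)
  keep <- suppressMessages(filter_genes(
    tibble::tibble(gene_id = c("five", "sevenfifty"),
                   length_bp = c(5000, 750000), expression_raw = c(1, 1)),
    max_length_bp = 750000
  ))
  expect_equal(nrow(keep), 2L)
  expect_error(suppressMessages(filter_genes(genes, min_length_bp = 1e9)),
               "empty")
})

test_that("filtering is idempotent", {
  set.seed(4)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:200),
    length_bp = round(runif(200, 1000, 1e6)),
    expression_raw = rpois(200, 2)
  )
  once <- suppressMessages(filter_genes(genes, 5000, 750000, TRUE))
  twice <- suppressMessages(filter_genes(once, 5000, 750000, TRUE))
  expect_equal(twice, once, ignore_attr = TRUE)
  expect_equal(sum(attr(twice, "removed")), 0L)
})

test_that("build_catalog computes alpha and q and enforces invariants", {
  cat <- build_catalog(
    tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(1e5, 5e4),
                   expression_raw = c(30, 10)),
    genome_length = 3.2e9
  )
  expect_equal(cat$alpha, c(0.75, 0.25))
  expect_equal(cat$q[1], 1e5 / (4 * 3.2e9))
  expect_equal(cat$q[1], 7.8125e-6)
  expect_true(validate_catalog(cat))

  expect_error(build_catalog(
    tibble::tibble(gene_id = "g", length_bp = 2e9, expression_raw = 1),
    genome_length = 1e9
  ), "exceeds the genome length")
  expect_error(build_catalog(
    tibble::tibble(gene_id = "g", length_bp = 1e4, expression_raw = 0),
    genome_length = 1e9
  ), "all-zero")
  expect_error(build_catalog(
    tibble::tibble(gene_id = c("g", "g"), length_bp = c(1, 2),
                   expression_raw = c(1, 1)),
    genome_length = 1e9
  ), "unique")
})

test_that("weights renormalize after a filter-then-rebuild cycle", {
  set.seed(9)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:100),
    length_bp = round(runif(100, 2000, 4e5)),
    expression_raw = rlnorm(100)
  )
  cat1 <- build_catalog(genes, 1e9)
  kept <- suppressMessages(filter_genes(cat1, min_length_bp = 50000))
  cat2 <- build_catalog(
    tibble::tibble(gene_id = kept$gene_id, length_bp = kept$length_bp,
                   expression_raw = kept$expression_raw), 1e9)
  expect_equal(sum(cat2$alpha), 1, tolerance = 1e-12)
  expect_true(all(cat2$length_bp >= 50000))
})

test_that("catalog TSV round trip preserves weights and genome length", {
  cat <- toy_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read_catalog(path)
  expect_equal(genome_length(back), genome_length(cat))
  expect_equal(back$alpha, cat$alpha)
  expect_equal(back$q, cat$q)
})

test_that("expression joins by gene id with zero or drop for missing genes", {
  rec <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(1e4, 2e4))
  cts <- tibble::tibble(gene_id = "a", count = 7)
  expect_equal(add_expression(rec, cts)$expression_raw, c(7, 0))
  expect_equal(nrow(add_expression(rec, cts, missing = "drop")), 1L)
  expect_error(add_expression(rec, tibble::tibble(gene_id = "a", count = -1)),
               "negative")
})
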