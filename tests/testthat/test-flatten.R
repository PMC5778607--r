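test_that("a single disjoint transcript flattens to its own exons", {
  ex <- data.frame(chrom = "chr1", start = c(100, 300), end = c(200, 400),
                   strand = "+", gene_id = "g1", transcript_id = "t1")
  m <- flattenGeneModels(ex)
  gr <- regions(m)
  expect_equal(length(gr), 2L)
  expect_equal(GenomicRanges::start(gr), c(100, 300))
  expect_equal(GenomicRanges::end(gr), c(200, 400))
  expect_equal(gr$region_id, c("E001", "E002"))
})

test_that("overlapping transcripts partition at every exon boundary", {
  ex <- data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 250),
                   strand = "+", gene_id = "g1",
                   transcript_id = c("t1", "t2"))
  m <- flattenGeneModels(ex)
  gr <- regions(m)
  expect_equal(GenomicRanges::start(gr), c(100, 150, 201))
  expect_equal(GenomicRanges::end(gr), c(149, 200, 250))
  # widths partition the union exactly
  expect_equal(sum(GenomicRanges::width(gr)), 250 - 100 + 1)
  expect_equal(flattenMismatches(m, ex), 0)
})

test_that("overlapping genes are merged into aggregates (or dropped)", {
  ex <- data.frame(chrom = "chr1",
                   start = c(100, 180), end = c(220, 300), strand = "+",
                   gene_id = c("gB", "gA"),
                   transcript_id = c("gBt1", "gAt1"))
  m <- flattenGeneModels(ex)
  gr <- regions(m)
  expect_true(all(gr$gene_id == "gA+gB"))
  expect_equal(unname(aggregateMap(m)[c("gA", "gB")]),
               c("gA+gB", "gA+gB"))
  expect_equal(flattenMismatches(m, ex), 0)
  # same-coordinate genes on opposite strands stay separate by default
  ex2 <- ex; ex2$strand <- c("+", "-")
  m2 <- flattenGeneModels(ex2)
  expect_setequal(unique(regions(m2)$gene_id), c("gA", "gB"))
  m3 <- flattenGeneModels(ex2, ignoreStrand = TRUE)
  expect_true(all(regions(m3)$gene_id == "gA+gB"))
  expect_error(flattenGeneModels(ex, aggregate = FALSE), "overlapping")
})

test_that("flattening equals the per-base partition oracle on random input", {
  set.seed(421)
  for (k in 1:25) {
    ex <- randomAnnotation(nGenes = sample(1:4, 1))
    m <- flattenGeneModels(ex)
    expect_equal(flattenMismatches(m, ex), 0)
    # partition property: per gene group, total width equals exon-union size
    gr <- regions(m)
    for (g in unique(gr$gene_id)) {
      sub <- gr[gr$gene_id == g]
      genes <- strsplit(g, "+", fixed = TRUE)[[1]]
      un <- GenomicRanges::reduce(GenomicRanges::GRanges(
        ex$chrom[ex$gene_id %in% genes],
        IRanges::IRanges(ex$start[ex$gene_id %in% genes],
                         ex$end[ex$gene_id %in% genes])))
      expect_equal(sum(GenomicRanges::width(sub)),
                   sum(GenomicRanges::width(un)))
    }
  }
})

test_that("malformed annotation is rejected", {
  bad <- data.frame(chrom = "c", start = 100, end = 50, strand = "+",
                    gene_id = "g", transcript_id = "t")
  expect_error(flattenGeneModels(bad), "malformed")
  bad2 <- data.frame(chrom = "c", start = 1, end = 50, strand = "x",
                     gene_id = "g", transcript_id = "t")
  expect_error(flattenGeneModels(bad2), "strand")
})

test_that("flattened GFF round-trips and is byte-deterministic", {
  ex <- data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 250),
                   strand = "+", gene_id = "g1",
                   transcript_id = c("t1", "t2"))
  m <- flattenGeneModels(ex)
  f <- tempfile(fileext = ".gff")
  writeFlattenedGFF(m, f)
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, "#")), 4L)  # 1 gene + 3 regions
  m2 <- readFlattenedGFF(f)
  expect_equal(GenomicRanges::start(regions(m2)),
               GenomicRanges::start(regions(m)))
  expect_equal(GenomicRanges::end(regions(m2)),
               GenomicRanges::end(regions(m)))
  expect_equal(regions(m2)$gene_id, regions(m)$gene_id)
  expect_equal(regions(m2)$region_id, regions(m)$region_id)
  expect_equal(aggregateMap(m2), aggregateMap(m))
  f2 <- tempfile(fileext = ".gff")
  writeFlattenedGFF(m, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("round-trip holds for random and empty models", {
  set.seed(99)
  ex <- randomAnnotation(3)
  m <- flattenGeneModels(ex)
  f <- tempfile(fileext = ".gff")
  m2 <- readFlattenedGFF(writeFlattenedGFF(m, f))
  expect_equal(as.character(regions(m2)), as.character(regions(m)))
  expect_equal(regions(m2)$gene_id, regions(m)$gene_id)
  expect_equal(aggregateMap(m2), aggregateMap(m))
  # empty model: header-only file round-trips to an empty model
  writeLines("##gff-version 3", f)
  empty <- readFlattenedGFF(f)
  expect_equal(length(empty), 0L)
  writeFlattenedGFF(empty, f)
  expect_equal(readLines(f), "##gff-version 3")
})
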