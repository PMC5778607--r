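# a 3-region gene on chrT: E001 [100,199], E002 [300,399], E003 [500,599]
toyModel <- function() {
  gr <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(100, 300, 500), c(199, 399, 599)), strand = "+",
    gene_id = "g1", region_id = c("E001", "E002", "E003"))
  names(gr) <- paste0("g1:", gr$region_id)
  new("FlattenedGeneModel", regions = gr,
      aggregateMap = c(g1 = "g1"))
}

frag <- function(id, starts, ends, sample = "s1", chrom = "chrT",
                 unique = TRUE) {
  data.frame(fragment_id = id, sample_id = sample, chrom = chrom,
             start = starts, end = ends, strand = "*", unique = unique,
             stringsAsFactors = FALSE)
}

test_that("containment, multi-block and no-overlap fragments count correctly", {
  m <- toyModel()
  fr <- rbind(frag("a", 320, 380),                 # inside E002
              frag("b", c(150, 550), c(199, 560)), # blocks in E001 and E003
              frag("c", 220, 280))                 # overlaps nothing
  cf <- countFragments(fr, m, samples = "s1")
  expect_equal(unname(cf$inclusion[, 1]), c(1L, 1L, 1L))
  expect_equal(cf$nUnassigned, 1L)
  # fragment b skips E002: gap [200,549] contains it, blocks flank it
  expect_equal(unname(cf$skipping[, 1]), c(0L, 1L, 0L))
  expect_equal(unname(cf$geneTotals["g1", 1]), 2L)
})

test_that("ungapped fragments and partially covered gaps never skip", {
  m <- toyModel()
  cf <- countFragments(frag("a", 150, 350), m, samples = "s1")
  expect_true(all(cf$skipping == 0L))
  # gap covers only part of E002: no skip credit
  fr <- frag("b", c(150, 350), c(199, 560))
  cf2 <- countFragments(fr, m, samples = "s1")
  expect_true(all(cf2$skipping == 0L))
})

test_that("non-unique and gene-ambiguous fragments are discarded", {
  gr <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(100, 300), c(199, 399)), strand = "+",
    gene_id = c("g1", "g2"), region_id = "E001")
  names(gr) <- paste0(gr$gene_id, ":E001")
  m2 <- new("FlattenedGeneModel", regions = gr,
            aggregateMap = c(g1 = "g1", g2 = "g2"))
  fr <- rbind(frag("x", c(150, 350), c(199, 399)),  # touches both genes
              frag("y", 150, 160, unique = FALSE))
  cf <- countFragments(fr, m2, samples = "s1")
  expect_true(all(cf$inclusion == 0L))
  expect_equal(cf$nAmbiguous, 1L)
  expect_equal(cf$nNonUnique, 1L)
  # fragments on chromosomes absent from the model are logged, not an error
  cf2 <- countFragments(frag("z", 1, 50, chrom = "chrZ"), toyModel(),
                        samples = "s1")
  expect_equal(cf2$nSkippedChrom, 1L)
})

test_that("rest counts complement inclusion within the gene", {
  m <- toyModel()
  inc <- matrix(c(5L, 3L, 2L), 3, 1,
                dimnames = list(names(regions(m)), "s1"))
  pairs <- buildReucPairs(inc, m)
  expect_equal(unname(pairs$k0[, 1]), c(5L, 7L, 8L))
  # single-region gene: k0 is zero
  gr1 <- regions(m)[1]
  m1 <- new("FlattenedGeneModel", regions = gr1, aggregateMap = c(g1 = "g1"))
  p1 <- buildReucPairs(inc[1, , drop = FALSE], m1)
  expect_equal(unname(p1$k0[, 1]), 0L)
  expect_error(buildReucPairs(matrix(1L, 1, 1,
                                     dimnames = list("nogene", "s1"))),
               "gene")
})

test_that("fragment-level accounting conserves distinct fragments per gene", {
  sim <- simulateStudy(nIndividuals = 2, nTissues = 2, nGenes = 4,
                       meanLog = log(20), seed = 5)
  fr <- simulateFragments(sim)
  cf <- countFragments(fr, sim$model,
                       samples = colnames(SummarizedExperiment::assay(sim$counts)))
  # oracle: tally distinct fragment ids per gene directly from the stream
  gr <- regions(sim$model)
  bl <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(fr$start, fr$end))
  hit <- GenomicRanges::findOverlaps(bl, gr)
  tally <- unique(data.frame(
    f = fr$fragment_id[S4Vectors::queryHits(hit)],
    g = gr$gene_id[S4Vectors::subjectHits(hit)],
    s = fr$sample_id[S4Vectors::queryHits(hit)]))
  expect_equal(sum(cf$geneTotals), nrow(tally))
  # pairwise: inclusion + rest == geneTotal per region/sample
  pairs <- buildReucPairs(cf$inclusion, sim$model, cf$geneTotals)
  gene <- gr$gene_id
  expect_true(all(pairs$k1 + pairs$k0 ==
                  cf$geneTotals[gene, colnames(pairs$k1)]))
})

test_that("counting is invariant to fragment stream order", {
  sim <- simulateStudy(nIndividuals = 2, nTissues = 2, nGenes = 4,
                       meanLog = log(15), seed = 8)
  fr <- simulateFragments(sim)
  samples <- colnames(SummarizedExperiment::assay(sim$counts))
  cf1 <- countFragments(fr, sim$model, samples = samples)
  set.seed(1)
  perm <- sample(unique(fr$fragment_id))
  fr2 <- fr[order(match(fr$fragment_id, perm), fr$start), ]
  cf2 <- countFragments(fr2, sim$model, samples = samples)
  expect_equal(cf1$inclusion, cf2$inclusion)
  expect_equal(cf1$skipping, cf2$skipping)
  expect_equal(cf1$geneTotals, cf2$geneTotals)
})

test_that("SAM and fragment-TSV inputs count identically", {
  sim <- simulateStudy(nIndividuals = 2, nTissues = 2, nGenes = 3,
                       meanLog = log(10), seed = 13)
  fr <- simulateFragments(sim)
  one <- fr[fr$sample_id == fr$sample_id[1], ]
  ftsv <- tempfile(fileext = ".tsv")
  writeFragmentsTSV(one, ftsv)
  back <- readFragmentsTSV(ftsv)
  fsam <- tempfile(fileext = ".sam")
  writeFragmentsSAM(one, fsam)
  fromSam <- readFragmentsSAM(fsam, sample_id = one$sample_id[1])
  cf1 <- countFragments(back, sim$model, samples = one$sample_id[1])
  cf2 <- countFragments(fromSam, sim$model, samples = one$sample_id[1])
  expect_equal(cf1$inclusion, cf2$inclusion)
  expect_equal(cf1$skipping, cf2$skipping)
})
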