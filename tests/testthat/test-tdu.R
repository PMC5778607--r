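test_that("usage z-scores follow the median/sd definition", {
  d <- toyDesign(3, 2)
  # tissue T1 entries all 1, tissue T2 entries all 0
  beta <- ifelse(d$tissue == "T1", 1, 0)
  z <- tissueZScores(beta)
  expect_equal(unname(z[d$tissue == "T1"][1]), 0.5 / sqrt(0.3))
  expect_equal(unname(z[d$tissue == "T2"][1]), -0.5 / sqrt(0.3))
  # location invariance and the sigma guard
  expect_equal(tissueZScores(beta + 7), z)
  expect_equal(unname(tissueZScores(rep(3, 6))), rep(0, 6))
})

test_that("the tissue score is the max absolute per-tissue mean z", {
  d <- toyDesign(3, 2)
  beta <- ifelse(d$tissue == "T1", 1, 0)
  s <- tissueScore(tissueZScores(beta), d)
  expect_equal(s$score, 0.5 / sqrt(0.3))
  expect_equal(s$score, 0.9128709, tolerance = 1e-6)
  expect_equal(tissueScore(rep(0, 6), d)$score, 0)
})

test_that("the score is invariant to individual relabeling and equivariant "
, {
  set.seed(3)
  d <- toyDesign(4, 3)
  beta <- rnorm(12)
  s1 <- tissueScore(tissueZScores(beta), d)
  d2 <- d
  d2$individual <- factor(d2$individual,
                          labels = c("I4", "I3", "I2", "I1"))
  s2 <- tissueScore(tissueZScores(beta), checkDesign(d2))
  expect_equal(s2$score, s1$score)
  # tissue relabeling: argmax follows the permutation
  d3 <- d
  d3$tissue <- factor(d3$tissue, levels = c("T1", "T2", "T3"),
                      labels = c("T2", "T3", "T1"))
  s3 <- tissueScore(tissueZScores(beta), checkDesign(d3))
  expect_equal(s3$score, s1$score)
  map <- c(T1 = "T2", T2 = "T3", T3 = "T1")
  expect_equal(s3$argmaxTissue, unname(map[s1$argmaxTissue]))
})

test_that("the LRT statistic equals twice the re-evaluated log-likelihoods", {
  set.seed(41)
  d <- toyDesign(5, 3)
  k1 <- rnbinom(15, mu = 80, size = 10)
  k0 <- rnbinom(15, mu = 240, size = 10)
  r <- lrtTissueDependence(k1, k0, d, rep(1, 15), alpha = 0.05)
  expect_equal(r$stat, 2 * (r$llFull - r$llReduced), tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$pvalue, pchisq(r$stat, 2, lower.tail = FALSE))
  expect_gte(r$stat, 0)
  # with-individual variant has the same df and a valid p-value
  r2 <- lrtTissueDependence(k1, k0, d, rep(1, 15), alpha = 0.05,
                            withIndividual = TRUE)
  expect_equal(r2$df, 2)
  expect_true(r2$pvalue >= 0 && r2$pvalue <= 1)
})

test_that("a strong planted tissue effect is detected by the LRT", {
  set.seed(47)
  d <- toyDesign(6, 3)
  shift <- ifelse(d$tissue == "T2", exp(1.5), 1)
  k1 <- rnbinom(18, mu = 100 * shift, size = 20)
  k0 <- rnbinom(18, mu = 400, size = 20)
  a <- estimateDispersion(k1, k0, rep(1, 18), design = d)$alpha
  r <- lrtTissueDependence(k1, k0, d, rep(1, 18), alpha = a)
  expect_lt(r$pvalue, 1e-6)
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(adjustBH(0.03), 0.03)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
  p <- adjustBH(c(0.04, 0.001, 0.2))
  expect_true(all(p >= c(0.04, 0.001, 0.2)))
})

test_that("TDU calls require both FDR and a strictly exceeded score", {
  res <- callTDU(c(0.001, 0.001, 0.15, 0.5), c(1.2, 1.0, 3, 0.2),
                 fdr = 0.1, scoreMin = 1.0)
  # padj = (0.004, 0.004, 0.2, 0.5)
  expect_equal(res$isTDU, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(S4Vectors::metadata(res)$fdr, 0.1)
  expect_true(all(res$padj >= res$pvalue))
  expect_error(callTDU(c(0.1, 0.2), 1), "mismatch")
})

test_that("the same machinery tests TSS-cluster usage per gene", {
  # rows are TSS clusters of genes; inclusion = cluster counts, rest =
  # other clusters of the same gene
  # with a clean balanced pattern the score approaches sqrt(nTissues - 1),
  # so >= 3 tissues are needed for the score > 1 criterion to be reachable
  d <- toyDesign(4, 3)
  set.seed(19)
  shift <- ifelse(d$tissue == "T2", 6, 1)
  inc <- rbind(
    "gA:TSS01" = rnbinom(12, mu = 50 * shift, size = 30),
    "gA:TSS02" = rnbinom(12, mu = 120, size = 30),
    "gB:TSS01" = rnbinom(12, mu = 80, size = 30),
    "gB:TSS02" = rnbinom(12, mu = 90, size = 30))
  colnames(inc) <- d$sample_id
  storage.mode(inc) <- "integer"
  pairs <- buildReucPairs(inc)
  eue <- ExonUsageExperiment(inclusion = inc, design = d, rest = pairs$k0)
  uc <- estimateREUCs(eue)
  res <- testTissueDependence(eue, uc)
  expect_true(res["gA:TSS01", "isTDU"])
  expect_false(res["gB:TSS01", "isTDU"])
  expect_equal(res$gene_id, c("gA", "gA", "gB", "gB"))
})
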