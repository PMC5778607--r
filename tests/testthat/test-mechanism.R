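test_that("partial R2 handles the degenerate and textbook cases", {
  # coefficients depending only on individual: tissue explains nothing
  m1 <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  expect_equal(partialR2(m1)$r2, 0)
  # depending only on tissue: full model exact, reduced not
  m2 <- matrix(rep(c(1, 5, 9, 2), each = 3), 3, 4)
  expect_equal(partialR2(m2)$r2, 1)
  # 2x2 hand example with tissue columns (1,2) and (3,5)
  m3 <- matrix(c(1, 2, 3, 5), 2, 2)
  p <- partialR2(m3)
  expect_equal(p$rssFull, 0.25, tolerance = 1e-10)
  expect_equal(p$rssReduced, 6.5, tolerance = 1e-10)
  expect_equal(p$r2, 1 - 0.25 / 6.5, tolerance = 1e-10)
  expect_error(partialR2(matrix(c(1, NA, 2, 3), 2, 2)), "crossed")
})

test_that("partial R2 agrees with the closed-form balanced ANOVA oracle", {
  set.seed(61)
  for (k in 1:20) {
    m <- matrix(rnorm(30), 5, 6)
    p <- partialR2(m)
    o <- oraclePartialR2(m)
    expect_equal(p$rssFull, o$rssFull, tolerance = 1e-8)
    expect_equal(p$rssReduced, o$rssReduced, tolerance = 1e-8)
    expect_equal(p$r2, o$r2, tolerance = 1e-8)
    # nested-model guarantee
    expect_lte(p$rssFull, p$rssReduced + 1e-12)
    expect_true(p$r2 >= 0 && p$r2 <= 1)
  }
})

test_that("skipping-evidence strata use strict boundaries", {
  s <- rep(1, 4)
  expect_equal(as.character(skippingEvidenceClass(rep(0, 4), s)$stratum),
               "none")
  expect_equal(as.character(skippingEvidenceClass(rep(1L, 4), s)$stratum),
               "weak")
  # mean exactly 10: moderate, not strong
  expect_equal(as.character(skippingEvidenceClass(rep(10L, 4), s)$stratum),
               "moderate")
  expect_equal(as.character(skippingEvidenceClass(rep(25L, 4), s)$stratum),
               "strong")
  # normalization matters: raw mean 10 with size factors 0.5 normalizes to 20
  cl <- skippingEvidenceClass(rep(10L, 4), rep(0.5, 4))
  expect_equal(as.character(cl$stratum), "strong")
  expect_equal(cl$mean, 20)
  raw <- skippingEvidenceClass(rep(10L, 4), normalized = FALSE)
  expect_equal(as.character(raw$stratum), "moderate")
})

test_that("REUC-RSIC correlation matches the covariance formula", {
  expect_equal(reucRsicCorrelation(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  r <- reucRsicCorrelation(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "constant")
  r2 <- reucRsicCorrelation(c(1, NA, 3), c(2, 4, 7))
  expect_true(is.na(r2))
  expect_equal(attr(r2, "reason"), "insufficient_overlap")
  # direct formula for (1,2,3) vs (2,4,7)
  expect_equal(reucRsicCorrelation(c(1, 2, 3), c(2, 4, 7)),
               2.5 / (1 * sqrt(19 / 3)))
})

test_that("the attribution rule combines strata, correlation and R2", {
  d <- toyDesign(4, 3)
  n <- nrow(d)
  mk <- function(vals) matrix(vals, 3, n, byrow = FALSE,
                              dimnames = list(paste0("g", 1:3, ":E001"),
                                              d$sample_id))
  set.seed(9)
  patt <- ifelse(d$tissue == "T2", 1, -0.5) + rnorm(n, 0, 0.05)
  beta <- rbind(patt, patt, patt)
  rownames(beta) <- paste0("g", 1:3, ":E001")
  colnames(beta) <- d$sample_id
  mkUC <- function(scheme, beta, flags = rep("ok", 3))
    new("UsageCoefficients", scheme = scheme,
        beta = beta, meanUsage = rep(0, 3), sexEffect = rep(0, 3),
        dispersion = rep(0.01, 3),
        priorVariance = c(interaction = 1, sex = 1),
        flags = flags, design = d)
  re <- mkUC("REUC", beta)
  rsB <- beta; rsB[2, ] <- NA  # region 2: no RSIC
  rs <- mkUC("RSIC", rsB, c("ok", "unestimable", "ok"))
  tdu <- S4Vectors::DataFrame(region_id = rep("E001", 3),
                              gene_id = paste0("g", 1:3),
                              pvalue = 1e-5, padj = 1e-4, tissueScore = 2,
                              isTDU = c(TRUE, TRUE, TRUE),
                              row.names = rownames(beta))
  # skipping: region 1 strong (mean 25), region 2 none, region 3 moderate
  skip <- mk(0L); skip[1, ] <- 25L; skip[3, ] <- 5L
  res <- attributeMechanism(tdu, re, rs, skip, rep(1, n))
  expect_equal(res$label, c("TDU-AS", "TDU-NAS", "unresolved"))
  expect_equal(as.character(res$stratum), c("strong", "none", "moderate"))
  expect_true(res$pearsonR[1] > 0.99)
  expect_true(is.na(res$r2Rsic[2]))
})
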