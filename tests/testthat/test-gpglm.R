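test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(3L, 3L, 7L, 7L, 20L, 20L), 3, 2, byrow = TRUE)
  expect_equal(unname(estimateSizeFactors(m)), c(1, 1))
  # hand oracle for [[2,4],[4,8],[8,16]]: every ratio is 1/sqrt(2), sqrt(2)
  m2 <- matrix(c(2, 4, 4, 8, 8, 16), 3, 2, byrow = TRUE)
  expect_equal(unname(estimateSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)))
  # doubling one column doubles its factor relative to the others
  m3 <- m2; m3[, 2] <- m3[, 2] * 2
  s2 <- estimateSizeFactors(m2); s3 <- estimateSizeFactors(m3)
  expect_equal(unname(s3[2] / s3[1]), unname(2 * s2[2] / s2[1]))
  expect_error(estimateSizeFactors(matrix(c(0, 1, 1, 0), 2, 2)), "zero")
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  m <- matrix(rnbinom(600, mu = 50, size = 5), 100, 6)
  expect_equal(unname(estimateSizeFactors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("Cox-Reid dispersion estimation recovers the truth", {
  set.seed(301)
  n <- 500
  s <- rep(1, n)
  # Poisson data: estimate collapses to the floor
  k1 <- rpois(n, 60); k0 <- rpois(n, 200)
  d <- estimateDispersion(k1, k0, s, tissueInDesign = FALSE)
  expect_lte(d$alpha, 1e-4)
  # constant counts (variance < mean): no interior optimum
  dc <- estimateDispersion(rep(20L, n), rep(80L, n), s,
                           tissueInDesign = FALSE)
  expect_lte(dc$alpha, 1e-4)
  expect_true(dc$atFloor)
  # alpha = 0.1: within +-0.03 in at least 90% of replicates
  hits <- vapply(1:100, function(r) {
    k1 <- rnbinom(n, mu = 100, size = 10)
    k0 <- rnbinom(n, mu = 300, size = 10)
    a <- estimateDispersion(k1, k0, s, tissueInDesign = FALSE)$alphaRaw
    abs(a - 0.1) <= 0.03
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(estimateDispersion(rep(0L, 4), rep(0L, 4), rep(1, 4)),
               "all-zero")
})

test_that("the saturated Poisson fit reproduces the observed usage ratio", {
  d <- toyDesign(2, 2)
  f <- fitGPGLM(rep(2L, 4), rep(8L, 4), d, rep(1, 4), alpha = 0,
                priorVariance = Inf)
  expect_equal(exp(f$betaE), 0.25, tolerance = 1e-4)
  expect_lt(max(abs(f$betaUT)), 1e-4)
  expect_error(fitGPGLM(rep(2L, 4), rep(8L, 4), d, rep(1, 4), alpha = -1),
               "negative")
})

test_that("sex enters the linear predictor as -1/2 (male), +1/2 (female)", {
  d <- toyDesign(4, 2)   # sexes alternate male, female across individuals
  female <- d$sex > 0
  k1 <- ifelse(female, 40L, 10L)
  k0 <- rep(80L, 8)
  f <- fitGPGLM(k1, k0, d, rep(1, 8), alpha = 0,
                priorVariance = 0.5, priorVarianceSex = 1e6)
  # usage differs by log(4) between sexes; with x = +-1/2 the coefficient
  # spans exactly that difference
  expect_equal(f$betaSex, log(4), tolerance = 0.05)
  dflip <- d; dflip$sex <- -d$sex
  f2 <- fitGPGLM(k1, k0, dflip, rep(1, 8), alpha = 0,
                 priorVariance = 0.5, priorVarianceSex = 1e6)
  expect_equal(f2$betaSex, -log(4), tolerance = 0.05)
})

test_that("penalized fits match a generic optimizer oracle", {
  set.seed(91)
  for (k in 1:4) {
    d <- toyDesign(2, 2)
    k1 <- rnbinom(4, mu = 30, size = 20)
    k0 <- rnbinom(4, mu = 90, size = 20)
    s <- exp(runif(4, -0.3, 0.3))
    f <- fitGPGLM(k1, k0, d, s, alpha = 0.05, priorVariance = 1)
    o <- oracleGPGLM(k1, k0, d, s, alpha = 0.05, pv = 1)
    expect_lt(max(abs(c(f$betaS - o$betaS, f$betaE - o$betaE,
                        f$betaSex - o$betaSex, f$betaUT - o$betaUT))),
              1e-4)
  }
})

test_that("shrinkage is monotone and vanishes as the prior widens", {
  set.seed(17)
  d <- toyDesign(3, 2)
  k1 <- rnbinom(6, mu = exp(log(50) + c(1, 1, 1, 0, 0, 0)), size = 20)
  k0 <- rnbinom(6, mu = 150, size = 20)
  pvs <- c(1e6, 10, 1, 0.1, 0.01)
  mags <- vapply(pvs, function(pv)
    max(abs(fitGPGLM(k1, k0, d, rep(1, 6), 0.05,
                     priorVariance = pv)$betaUT)), numeric(1))
  expect_true(all(diff(mags) <= 1e-8))
  fInf <- fitGPGLM(k1, k0, d, rep(1, 6), 0.05, priorVariance = Inf)
  fBig <- fitGPGLM(k1, k0, d, rep(1, 6), 0.05, priorVariance = 1e8)
  expect_lt(max(abs(fInf$betaUT - fBig$betaUT)), 1e-3)
})

test_that("fits are invariant to rescaling a sample and its size factor", {
  set.seed(23)
  d <- toyDesign(3, 2)
  k1 <- rnbinom(6, mu = 40, size = 10)
  k0 <- rnbinom(6, mu = 120, size = 10)
  s <- rep(1, 6)
  # exact for the Poisson member of the family (the NB likelihood with
  # fixed alpha is not count-scale equivariant)
  f1 <- fitGPGLM(k1, k0, d, s, 0, priorVariance = 1e4)
  k1b <- k1; k0b <- k0; sb <- s
  k1b[3] <- k1[3] * 3L; k0b[3] <- k0[3] * 3L; sb[3] <- 3
  f2 <- fitGPGLM(k1b, k0b, d, sb, 0, priorVariance = 1e4)
  expect_lt(max(abs(f1$betaUT - f2$betaUT)), 1e-6)
  expect_lt(abs(f1$betaE - f2$betaE), 1e-6)
})

test_that("the shrinkage prior is recovered by upper-quantile matching", {
  expect_equal(estimateShrinkagePrior(rep(0, 200)), 1e-3)
  expect_equal(estimateShrinkagePrior(rnorm(10)), 1)  # too few -> default
  set.seed(55)
  est <- vapply(1:50, function(r)
    estimateShrinkagePrior(rnorm(2000, 0, 0.5)), numeric(1))
  expect_lt(abs(mean(est) - 0.25) / 0.25, 0.2)
  # sampling noise is subtracted
  est2 <- estimateShrinkagePrior(rnorm(2000, 0, sqrt(0.25 + 0.1)),
                                 samplingVar = rep(0.1, 2000))
  expect_lt(abs(est2 - 0.25) / 0.25, 0.3)
})
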