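#' Cox-Reid dispersion estimation for one exonic region
#'
#' Estimates the Gamma-Poisson dispersion of the paired counts (k0, k1) of
#' one region by maximizing the Cox-Reid adjusted profile likelihood over a
#' 1-D search on log dispersion; the means are refitted at every candidate
#' dispersion and the adjustment subtracts half the log-determinant of the
#' Fisher information. By default the mean design is the full testing model
#' (sample effects + level + level:sex + level:tissue), so that genuine
#' tissue-dependent usage is not absorbed into the dispersion; with
#' \code{tissueInDesign = FALSE} the reduced sample-plus-level design
#' log mu_jl = betaS_j + l betaE is used instead, whose arrow-structured
#' information matrix allows O(n) evaluation.
#'
#' @param k1,k0 integer count vectors over samples (level 1 = region
#'   inclusion, level 0 = denominator counts).
#' @param sizeFactors positive size factors, one per sample.
#' @param design design table; required when \code{tissueInDesign = TRUE}.
#' @param tissueInDesign include the level:tissue (and level:sex) terms in
#'   the mean model used for profiling.
#' @param floor,ceiling clip range for the estimate.
#' @return list with \code{alpha} (clipped CR-ML estimate), \code{alphaRaw}
#'   (unclipped search optimum) and \code{atFloor} logical.
#' @export
estimateDispersion <- function(k1, k0, sizeFactors, design = NULL,
                               tissueInDesign = !is.null(design),
                               floor = 1e-8, ceiling = 10) {
  stopifnot(length(k1) == length(k0), length(k1) == length(sizeFactors))
  if (all(k1 + k0 == 0))
    stop("all-zero counts: dispersion undefined for this region")
  if (tissueInDesign) {
    stopifnot(!is.null(design))
    X <- .testModelMatrices(checkDesign(design))$full
    y <- c(k0, k1)
    off <- rep(log(sizeFactors), 2L)
    zero <- rep(0, ncol(X))
    obj <- function(la) {
      al <- exp(la)
      f <- cppGPIRLS(X, y, off, al, zero, 1e-8, 100L)
      f$loglik - cppCoxReidTerm(X, drop(f$mu), al)
    }
  } else {
    obj <- function(la) .crProfile(exp(la), k1, k0, sizeFactors)$obj
  }
  opt <- optimize(obj, interval = log(c(floor, ceiling)), maximum = TRUE,
                  tol = 1e-3)
  # compare against the boundary: underdispersed data have no interior optimum
  atFloor <- FALSE
  alphaRaw <- exp(opt$maximum)
  if (obj(log(floor)) >= opt$objective - 1e-10) {
    alphaRaw <- floor
    atFloor <- TRUE
  }
  alpha <- min(max(alphaRaw, floor), ceiling)
  list(alpha = alpha, alphaRaw = alphaRaw, atFloor = atFloor)
}

# CR-adjusted profile log-likelihood at a fixed dispersion.
# Fits log mu_jl = betaS_j + l*betaE by IRLS using the arrow structure of
# X'WX (diagonal block for the n sample effects, one bordered column).
.crProfile <- function(alpha, k1, k0, s, maxit = 50L, tol = 1e-10) {
  n <- length(k1)
  off <- log(s)
  betaS <- log(pmax((k1 + k0) / 2, 0.25))
  betaE <- log((sum(k1) + 0.5) / (sum(k0) + 0.5))
  for (it in seq_len(maxit)) {
    eta0 <- betaS + off
    eta1 <- betaS + betaE + off
    mu0 <- exp(pmin(pmax(eta0, -30), 30))
    mu1 <- exp(pmin(pmax(eta1, -30), 30))
    w0 <- mu0 / (1 + alpha * mu0)
    w1 <- mu1 / (1 + alpha * mu1)
    z0 <- (eta0 - off) + (k0 - mu0) / mu0
    z1 <- (eta1 - off) + (k1 - mu1) / mu1
    d <- w0 + w1               # diagonal of X'WX (sample effects)
    b <- w1                    # border (sample x level)
    cc <- sum(w1)              # level-level entry
    r1 <- w0 * z0 + w1 * z1
    r2 <- sum(w1 * z1)
    denom <- cc - sum(b^2 / d)
    betaE_new <- (r2 - sum(b / d * r1)) / denom
    betaS_new <- (r1 - b * betaE_new) / d
    delta <- max(abs(c(betaS_new - betaS, betaE_new - betaE)))
    betaS <- betaS_new
    betaE <- betaE_new
    if (delta < tol) break
  }
  mu0 <- exp(pmin(pmax(betaS + off, -30), 30))
  mu1 <- exp(pmin(pmax(betaS + betaE + off, -30), 30))
  w0 <- mu0 / (1 + alpha * mu0)
  w1 <- mu1 / (1 + alpha * mu1)
  d <- w0 + w1
  cr <- 0.5 * (sum(log(d)) + log(sum(w1) - sum(w1^2 / d)))
  ll <- .gpLogLik(c(k0, k1), c(mu0, mu1), alpha)
  list(obj = ll - cr, mu = c(mu0, mu1), ll = ll, betaE = betaE)
}

.gpLogLik <- function(y, mu, alpha) cppGPLogLik(y, mu, alpha)

#' Fit and apply a mean-dispersion trend
#'
#' Fits the two-parameter trend alpha(mu) = a0 + a1/mu across regions by
#' iteratively trimmed least squares (coefficients clamped non-negative), and
#' shrinks per-region estimates toward the trend by a fixed-weight average in
#' log space.
#'
#' @param baseMean per-region mean of normalized counts.
#' @param alphaRaw per-region CR-ML dispersion estimates.
#' @param weight weight of the per-region estimate in the log-space average
#'   (1 disables trend shrinkage).
#' @param floor,ceiling clip range.
#' @return list with \code{alpha} (final per-region dispersions),
#'   \code{trend} = c(a0, a1) and the trend values per region.
#' @export
fitDispersionTrend <- function(baseMean, alphaRaw, weight = 0.5,
                               floor = 1e-8, ceiling = 10) {
  stopifnot(length(baseMean) == length(alphaRaw))
  use <- is.finite(baseMean) & is.finite(alphaRaw) & baseMean > 0 &
         alphaRaw > floor * 1.0001 & alphaRaw < ceiling * 0.9999
  a <- c(a0 = mean(alphaRaw[use]), a1 = 0)
  if (sum(use) >= 10) {
    x <- 1 / baseMean
    for (pass in 1:3) {
      fit <- lm(alphaRaw[use] ~ x[use])
      a <- pmax(c(unname(coef(fit))), 0)
      pred <- pmax(a[1] + a[2] * x, floor)
      resid <- log(pmax(alphaRaw, floor)) - log(pred)
      keep <- abs(resid) < 2
      if (all(keep[use])) break
      use <- use & keep
      if (sum(use) < 10) break
    }
  }
  trendVal <- pmax(a[1] + a[2] / pmax(baseMean, 1e-8), floor)
  alpha <- exp(weight * log(pmax(alphaRaw, floor)) +
               (1 - weight) * log(trendVal))
  alpha <- pmin(pmax(alpha, floor), ceiling)
  list(alpha = alpha, trend = setNames(a, c("a0", "a1")), trendVal = trendVal)
}
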