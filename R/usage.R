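#' Estimate relative exon usage / spliced-in coefficients
#'
#' \code{estimateREUCs} fits, for every exonic region passing the expression
#' filter, the penalized Gamma-Poisson GLM of inclusion counts against
#' rest-of-gene counts and returns the shrunken individual-by-tissue
#' interaction matrix (the REUCs). \code{estimateRSICs} applies the same
#' machinery with exon-skipping junction counts as the denominator (the
#' RSICs); regions whose mean (size-factor normalized) skipping count falls
#' below \code{skipFloor} are flagged unestimable. The shrinkage prior is
#' estimated from a first pass of minimum-norm MLE fits across regions
#' (see \code{\link{estimateShrinkagePrior}}); regions are fitted
#' independently, so results do not depend on processing order.
#'
#' @param object an \code{\link{ExonUsageExperiment}} with the required
#'   assays (\code{inclusion} + \code{rest} for REUCs; \code{inclusion} +
#'   \code{skipping} for RSICs).
#' @param minCount minimum total count (k1 + k0, summed over samples) for a
#'   region to be fitted.
#' @param skipFloor minimum mean normalized skipping count for RSIC
#'   estimability.
#' @param sizeFactors optional per-sample size factors; estimated by
#'   median-of-ratios from the inclusion assay when missing.
#' @param priorVariance optional fixed prior variance for the interaction
#'   coefficients (skips the empirical-Bayes estimation).
#' @param trendWeight weight of the per-region dispersion estimate in the
#'   log-space average with the fitted mean-dispersion trend.
#' @param dispersionFloor,dispersionCeiling clip range for dispersions.
#' @return a \code{\link{UsageCoefficients}} object covering all rows of
#'   \code{object}; rows not fitted carry \code{NA} coefficients and an
#'   explanatory flag.
#' @export
estimateREUCs <- function(object, minCount = 10, sizeFactors = NULL,
                          priorVariance = NULL, trendWeight = 0.5,
                          dispersionFloor = 1e-8, dispersionCeiling = 10) {
  stopifnot(is(object, "ExonUsageExperiment"))
  if (!"rest" %in% SummarizedExperiment::assayNames(object))
    stop("'rest' assay required; see buildReucPairs()")
  .estimateUsage(object,
                 k0mat = SummarizedExperiment::assay(object, "rest"),
                 scheme = "REUC", minCount = minCount,
                 sizeFactors = sizeFactors, priorVariance = priorVariance,
                 trendWeight = trendWeight,
                 dispersionFloor = dispersionFloor,
                 dispersionCeiling = dispersionCeiling)
}

#' @rdname estimateREUCs
#' @export
estimateRSICs <- function(object, minCount = 10, skipFloor = 1,
                          sizeFactors = NULL, priorVariance = NULL,
                          trendWeight = 0.5, dispersionFloor = 1e-8,
                          dispersionCeiling = 10) {
  stopifnot(is(object, "ExonUsageExperiment"))
  if (!"skipping" %in% SummarizedExperiment::assayNames(object))
    stop("'skipping' assay required for RSIC estimation")
  .estimateUsage(object,
                 k0mat = SummarizedExperiment::assay(object, "skipping"),
                 scheme = "RSIC", minCount = minCount, skipFloor = skipFloor,
                 sizeFactors = sizeFactors, priorVariance = priorVariance,
                 trendWeight = trendWeight,
                 dispersionFloor = dispersionFloor,
                 dispersionCeiling = dispersionCeiling)
}

.estimateUsage <- function(object, k0mat, scheme, minCount, skipFloor = 1,
                           sizeFactors = NULL, priorVariance = NULL,
                           trendWeight = 0.5, dispersionFloor = 1e-8,
                           dispersionCeiling = 10) {
  design <- checkDesign(designTable(object))
  k1mat <- SummarizedExperiment::assay(object, "inclusion")
  if (!identical(colnames(k1mat), design$sample_id))
    stop("count columns do not match design")
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(k1mat)
  sizeFactors <- sizeFactors[design$sample_id]
  n <- nrow(design)
  nr <- nrow(k1mat)

  flags <- rep("ok", nr)
  total <- rowSums(k1mat) + rowSums(k0mat)
  flags[total < minCount] <- "low_count"
  flags[rowSums(k1mat) == 0 | rowSums(k0mat) == 0] <- "unestimable"
  if (scheme == "RSIC") {
    meanSkip <- rowMeans(sweep(k0mat, 2L, sizeFactors, "/"))
    flags[meanSkip < skipFloor] <- "unestimable"
  }
  fit_idx <- which(flags == "ok")

  alphaRaw <- rep(NA_real_, nr)
  baseMean <- rowMeans(sweep(k1mat, 2L, sizeFactors, "/"))
  for (i in fit_idx) {
    alphaRaw[i] <- estimateDispersion(k1mat[i, ], k0mat[i, ], sizeFactors,
                                      design = design,
                                      floor = dispersionFloor,
                                      ceiling = dispersionCeiling)$alphaRaw
  }
  disp <- rep(NA_real_, nr)
  if (length(fit_idx)) {
    tr <- fitDispersionTrend(baseMean[fit_idx], alphaRaw[fit_idx],
                             weight = trendWeight, floor = dispersionFloor,
                             ceiling = dispersionCeiling)
    disp[fit_idx] <- tr$alpha
  }

  beta <- matrix(NA_real_, nr, n, dimnames = list(rownames(k1mat),
                                                  design$sample_id))
  meanUsage <- sexEffect <- rep(NA_real_, nr)

  # pass 1: minimum-norm MLE fits to learn the shrinkage prior
  pv <- priorVariance
  pvSex <- NULL
  if (is.null(pv)) {
    mleUT <- matrix(NA_real_, length(fit_idx), n)
    mleVar <- matrix(NA_real_, length(fit_idx), n)
    mleSex <- varSex <- rep(NA_real_, length(fit_idx))
    for (k in seq_along(fit_idx)) {
      i <- fit_idx[k]
      f <- fitGPGLM(k1mat[i, ], k0mat[i, ], design, sizeFactors, disp[i],
                    priorVariance = Inf)
      mleUT[k, ] <- f$betaUT
      mleVar[k, ] <- f$varUT
      mleSex[k] <- f$betaSex
      varSex[k] <- f$varSex
    }
    pv <- estimateShrinkagePrior(mleUT, mleVar)
    pvSex <- estimateShrinkagePrior(mleSex, varSex)
  }
  if (is.null(pvSex)) pvSex <- pv

  for (i in fit_idx) {
    f <- fitGPGLM(k1mat[i, ], k0mat[i, ], design, sizeFactors, disp[i],
                  priorVariance = pv, priorVarianceSex = pvSex)
    beta[i, ] <- f$betaUT
    meanUsage[i] <- f$betaE
    sexEffect[i] <- f$betaSex
    if (!f$converged) flags[i] <- "not_converged"
  }
  names(flags) <- rownames(k1mat)
  new("UsageCoefficients", scheme = scheme, beta = beta,
      meanUsage = setNames(meanUsage, rownames(k1mat)),
      sexEffect = setNames(sexEffect, rownames(k1mat)),
      dispersion = setNames(disp, rownames(k1mat)),
      priorVariance = c(interaction = pv, sex = pvSex),
      flags = flags, design = design)
}

#' Write usage coefficients to TSV
#'
#' One row per region: the mean usage, sex effect, dispersion, flag, and one
#' column per individual:tissue combination.
#'
#' @param x a \code{\link{UsageCoefficients}} object.
#' @param path output path.
#' @param meta optional named character vector written as '#'-prefixed
#'   header lines.
#' @export
writeUsageTSV <- function(x, path, meta = NULL) {
  stopifnot(is(x, "UsageCoefficients"))
  d <- x@design
  cols <- paste(d$individual, d$tissue, sep = ":")
  df <- data.frame(region_id = rownames(x@beta),
                   mean_usage = x@meanUsage, sex_effect = x@sexEffect,
                   dispersion = x@dispersion, flag = x@flags,
                   check.names = FALSE)
  betadf <- as.data.frame(x@beta)
  colnames(betadf) <- cols
  .writeTSV(cbind(df, betadf), path,
            meta = c(scheme = x@scheme, meta))
  invisible(path)
}
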