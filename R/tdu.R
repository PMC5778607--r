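#' Robust z-scores of usage coefficients
#'
#' Expresses a region's usage coefficients as the number of standard
#' deviations away from their median:
#' \deqn{Z_{ut} = (\beta_{ut} - \mathrm{median}_{u,t}\,\beta_{ut}) /
#'       \sigma_{u,t}(\beta_{ut}),}
#' with the (n-1)-denominator standard deviation over all
#' individual-by-tissue entries; when the standard deviation is zero, Z is
#' identically zero.
#'
#' @param beta numeric vector of coefficients over samples (one region), or
#'   a regions x samples matrix.
#' @param naMax fraction of missing entries above which the result is
#'   flagged (attribute \code{"incomplete"}); entries are otherwise handled
#'   pairwise-complete.
#' @return z-scores in the same shape as the input.
#' @export
tissueZScores <- function(beta, naMax = 0.2) {
  if (is.matrix(beta)) {
    z <- t(apply(beta, 1L, tissueZScores, naMax = naMax))
    dimnames(z) <- dimnames(beta)
    return(z)
  }
  if (sum(!is.na(beta)) < 2L)
    return(rep(NA_real_, length(beta)))
  s <- sd(beta, na.rm = TRUE)
  z <- if (s == 0) ifelse(is.na(beta), NA_real_, 0)
       else (beta - median(beta, na.rm = TRUE)) / s
  if (mean(is.na(beta)) > naMax) attr(z, "incomplete") <- TRUE
  z
}

#' Tissue-dependence score
#'
#' The tissue score of a region is the maximum over tissues of the absolute
#' mean, over the m individuals, of the usage z-scores:
#' \deqn{T = \max_t | \frac{1}{m} \sum_u Z_{ut} |.}
#'
#' @param z per-sample z-scores (vector for one region or regions x samples
#'   matrix; see \code{\link{tissueZScores}}).
#' @param design validated design table mapping samples to individuals and
#'   tissues.
#' @return for a vector, a list with \code{score} and \code{argmaxTissue};
#'   for a matrix, a data.frame with one row per region.
#' @export
tissueScore <- function(z, design) {
  design <- checkDesign(design)
  if (is.matrix(z)) {
    res <- apply(z, 1L, function(r) {
      s <- tissueScore(r, design)
      c(s$score, match(s$argmaxTissue, levels(design$tissue)))
    })
    return(data.frame(region_id = rownames(z), score = res[1, ],
                      argmaxTissue = levels(design$tissue)[res[2, ]],
                      stringsAsFactors = FALSE))
  }
  means <- tapply(z, design$tissue, mean)
  a <- abs(means)
  if (all(is.na(a))) return(list(score = NA_real_, argmaxTissue = NA))
  list(score = max(a, na.rm = TRUE),
       argmaxTissue = names(a)[which.max(a)])
}

#' Likelihood-ratio test for tissue-dependent usage of one region
#'
#' Compares the Gamma-Poisson GLM with sample effects, level, level:sex and
#' level:tissue terms against the reduced model lacking level:tissue; the
#' statistic 2(ll_full - ll_reduced) is referred to a chi-squared
#' distribution with (number of tissues - 1) degrees of freedom. Both
#' models are unpenalized and use the dispersion fixed from
#' \code{\link{estimateDispersion}}.
#'
#' @param k1,k0 count vectors over samples.
#' @param design validated design table (needs >= 2 tissues).
#' @param sizeFactors per-sample size factors.
#' @param alpha fixed Gamma-Poisson dispersion.
#' @param withIndividual add level:individual terms to both models.
#' @return list with \code{pvalue}, \code{stat}, \code{df}, \code{llFull},
#'   \code{llReduced} and a convergence flag.
#' @export
lrtTissueDependence <- function(k1, k0, design, sizeFactors, alpha,
                                withIndividual = FALSE) {
  design <- checkDesign(design)
  if (nlevels(design$tissue) < 2L) stop("at least two tissues required")
  mm <- .testModelMatrices(design, withIndividual)
  y <- c(k0, k1)
  off <- rep(log(sizeFactors), 2L)
  zero <- function(X) rep(0, ncol(X))
  ff <- cppGPIRLS(mm$full, y, off, alpha, zero(mm$full), 1e-8, 100L)
  fr <- cppGPIRLS(mm$reduced, y, off, alpha, zero(mm$reduced), 1e-8, 100L)
  stat <- 2 * (ff$loglik - fr$loglik)
  conv <- ff$converged && fr$converged
  if (stat < 0) {
    if (stat > -1e-6) stat <- 0
    else {
      # reduced likelihood above full beyond tolerance: refit harder
      ff <- cppGPIRLS(mm$full, y, off, alpha, zero(mm$full), 1e-12, 500L)
      fr <- cppGPIRLS(mm$reduced, y, off, alpha, zero(mm$reduced), 1e-12,
                      500L)
      stat <- max(2 * (ff$loglik - fr$loglik), 0)
      conv <- FALSE
    }
  }
  list(pvalue = pchisq(stat, df = mm$df, lower.tail = FALSE), stat = stat,
       df = mm$df, llFull = ff$loglik, llReduced = fr$loglik,
       converged = conv)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values controlling the false discovery rate.
#' Input p-values must be finite and in [0, 1].
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjustBH <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call tissue-dependent usage
#'
#' A region is called TDU when its BH-adjusted p-value is at or below the
#' FDR threshold AND its tissue score strictly exceeds the score threshold.
#'
#' @param pvalues raw LRT p-values.
#' @param scores tissue scores, aligned with \code{pvalues}.
#' @param fdr FDR threshold (default 0.1).
#' @param scoreMin tissue-score threshold; the comparison is strict
#'   (score > scoreMin).
#' @return a \code{DataFrame} with \code{pvalue}, \code{padj},
#'   \code{tissueScore} and logical \code{isTDU}; the thresholds are kept in
#'   its metadata.
#' @export
callTDU <- function(pvalues, scores, fdr = 0.1, scoreMin = 1.0) {
  if (length(pvalues) != length(scores))
    stop("pvalues and scores length mismatch")
  padj <- adjustBH(pvalues)
  res <- S4Vectors::DataFrame(pvalue = pvalues, padj = padj,
                              tissueScore = scores,
                              isTDU = !is.na(padj) & !is.na(scores) &
                                      padj <= fdr & scores > scoreMin)
  S4Vectors::metadata(res) <- list(fdr = fdr, scoreMin = scoreMin)
  res
}

#' Test every region for tissue-dependent usage
#'
#' Orchestrates the per-region likelihood-ratio tests, the tissue scores from
#' the shrunken usage coefficients, Benjamini-Hochberg adjustment across all
#' tested regions, and the TDU call. The same machinery applies to any
#' within-gene counting unit (e.g. TSS clusters grouped by gene) supplied as
#' the rows of \code{object}.
#'
#' @param object an \code{\link{ExonUsageExperiment}} with \code{inclusion}
#'   and \code{rest} assays.
#' @param coefficients a \code{\link{UsageCoefficients}} object for the same
#'   rows (source of tissue scores, dispersions and fit flags).
#' @param fdr,scoreMin TDU thresholds (see \code{\link{callTDU}}).
#' @param sizeFactors optional size factors (median-of-ratios otherwise).
#' @param withIndividual include level:individual in both tested models.
#' @return a \code{DataFrame} with one row per region: \code{region_id},
#'   \code{gene_id}, \code{baseMean}, \code{pvalue}, \code{padj},
#'   \code{tissueScore}, \code{argmaxTissue}, \code{isTDU},
#'   \code{excludedReason}.
#' @export
testTissueDependence <- function(object, coefficients, fdr = 0.1,
                                 scoreMin = 1.0, sizeFactors = NULL,
                                 withIndividual = FALSE) {
  stopifnot(is(object, "ExonUsageExperiment"),
            is(coefficients, "UsageCoefficients"))
  k1mat <- SummarizedExperiment::assay(object, "inclusion")
  k0mat <- SummarizedExperiment::assay(object, "rest")
  stopifnot(identical(rownames(k1mat), rownames(coefMatrix(coefficients))))
  design <- checkDesign(designTable(object))
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(k1mat)
  sizeFactors <- sizeFactors[design$sample_id]

  nr <- nrow(k1mat)
  flags <- coefficients@flags
  testable <- which(flags %in% c("ok", "not_converged"))
  pvals <- rep(NA_real_, nr)
  for (i in testable) {
    pvals[i] <- lrtTissueDependence(k1mat[i, ], k0mat[i, ], design,
                                    sizeFactors,
                                    coefficients@dispersion[i],
                                    withIndividual)$pvalue
  }
  z <- tissueZScores(coefMatrix(coefficients))
  sc <- tissueScore(z, design)
  call <- callTDU(pvals, sc$score, fdr = fdr, scoreMin = scoreMin)
  rd <- SummarizedExperiment::rowData(object)
  res <- S4Vectors::DataFrame(
    region_id = rd$region_id, gene_id = rd$gene_id,
    baseMean = rowMeans(sweep(k1mat, 2L, sizeFactors, "/")),
    pvalue = call$pvalue, padj = call$padj,
    tissueScore = call$tissueScore, argmaxTissue = sc$argmaxTissue,
    isTDU = call$isTDU,
    excludedReason = ifelse(flags %in% c("ok", "not_converged"),
                            NA_character_, flags),
    row.names = rownames(k1mat))
  S4Vectors::metadata(res) <- list(fdr = fdr, scoreMin = scoreMin,
                                   withIndividual = withIndividual)
  res
}
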