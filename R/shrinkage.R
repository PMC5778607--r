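#' Empirical-Bayes shrinkage prior variance from MLE coefficients
#'
#' Estimates the variance of a zero-centered normal prior for a coefficient
#' class (the individual-by-tissue interactions, or the sex effects) by
#' upper-quantile matching on the genome-wide distribution of unpenalized
#' (minimum-norm) MLE coefficients: the prior variance is the implied total
#' variance at the chosen |quantile|, minus the typical sampling variance of
#' the MLEs, floored at \code{minPrior}. With fewer than \code{minCoefs}
#' finite coefficients the default prior is returned.
#'
#' @param betas numeric vector (or matrix) of MLE coefficients pooled across
#'   regions.
#' @param samplingVar optional vector of estimated sampling variances of the
#'   coefficients; its median is subtracted from the matched total variance.
#' @param prob upper quantile used for matching.
#' @param minPrior lower bound for the returned prior variance (also the
#'   value returned for degenerate, all-zero MLEs).
#' @param default prior variance returned when too few coefficients are
#'   available.
#' @param minCoefs minimum number of finite coefficients required.
#' @return a single positive prior variance.
#' @export
estimateShrinkagePrior <- function(betas, samplingVar = NULL, prob = 0.95,
                                   minPrior = 1e-3, default = 1,
                                   minCoefs = 50L) {
  b <- as.numeric(betas)
  b <- b[is.finite(b)]
  if (length(b) < minCoefs) return(default)
  q <- quantile(abs(b), prob, names = FALSE)
  if (q <= 0) return(minPrior)
  total <- (q / qnorm((1 + prob) / 2))^2
  noise <- 0
  if (!is.null(samplingVar)) {
    sv <- as.numeric(samplingVar)
    sv <- sv[is.finite(sv)]
    if (length(sv)) noise <- median(sv)
  }
  max(total - noise, minPrior)
}
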