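#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth scaling factors: for each sample j, the median
#' over rows (restricted to rows with an all-positive geometric mean) of the
#' ratio of the count to the row geometric mean. No further rescaling is
#' applied. Methods are provided on the \code{BiocGenerics} generic for a
#' plain count matrix and for an \code{\link{ExonUsageExperiment}} (whose
#' \code{inclusion} assay is used); both return the numeric vector of
#' factors.
#'
#' @param object a regions x samples count matrix, or an
#'   \code{ExonUsageExperiment}.
#' @param ... unused.
#' @return numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(2, 4, 4, 8, 8, 16), 3, 2, byrow = TRUE)
#' estimateSizeFactors(m)
#' @importFrom BiocGenerics estimateSizeFactors
#' @aliases estimateSizeFactors
#' @export estimateSizeFactors
#' @exportMethod estimateSizeFactors
#' @rdname estimateSizeFactors
setMethod("estimateSizeFactors", "matrix", function(object, ...) {
  logc <- log(object)
  geo <- rowMeans(logc)
  use <- is.finite(geo)
  if (!any(use))
    stop("every row contains a zero; size factors are undefined. ",
         "Filter to rows with all-positive counts (e.g. well-expressed ",
         "regions) before estimating size factors.")
  s <- apply(logc[use, , drop = FALSE] - geo[use], 2L,
             function(r) exp(stats::median(r)))
  setNames(s, colnames(object))
})

#' @rdname estimateSizeFactors
setMethod("estimateSizeFactors", "SummarizedExperiment",
  function(object, ...) {
    estimateSizeFactors(SummarizedExperiment::assay(object, "inclusion"))
  })
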