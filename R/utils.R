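#' @importFrom methods new validObject is as setClass setGeneric setMethod
#'   setValidity show slot
#' @importFrom stats optimize p.adjust pchisq rnbinom
#'   rpois rlnorm rnorm runif lm qnorm setNames coef residuals model.matrix
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom GenomeInfoDb seqlevels
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Rcpp evalCpp
#' @useDynLib TDUseq, .registration = TRUE
NULL

globalKey <- function(gene_id, region_id) paste(gene_id, region_id, sep = ":")

#' Validate and normalize a design table
#'
#' Checks that a design table has the columns \code{sample_id},
#' \code{individual}, \code{tissue} and \code{sex}, and recodes sex to the
#' numeric contrast used in the GLM: -1/2 for males, +1/2 for females.
#'
#' @param design a data.frame with one row per sample.
#' @param requireCrossed if \code{TRUE}, error unless every
#'   individual-by-tissue combination occurs exactly once (required by the
#'   ANOVA variance partition and the tissue score).
#' @return the design data.frame with \code{sex} numeric in \{-1/2, +1/2\},
#'   \code{individual} and \code{tissue} as factors.
#' @export
checkDesign <- function(design, requireCrossed = FALSE) {
  design <- as.data.frame(design)
  needed <- c("sample_id", "individual", "tissue", "sex")
  missing <- setdiff(needed, colnames(design))
  if (length(missing))
    stop("design table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design table")
  if (is.character(design$sex) || is.factor(design$sex)) {
    sx <- tolower(as.character(design$sex))
    num <- ifelse(sx %in% c("male", "m"), -0.5,
           ifelse(sx %in% c("female", "f"), 0.5, NA_real_))
    if (anyNA(num))
      stop("sex must be male/female (or numeric -1/2, +1/2)")
    design$sex <- num
  }
  if (!all(design$sex %in% c(-0.5, 0.5)))
    stop("numeric sex covariate must take values -1/2 or +1/2")
  design$individual <- factor(design$individual)
  design$tissue <- factor(design$tissue)
  if (requireCrossed && !isFullyCrossed(design))
    stop("design is not fully crossed: every individual x tissue ",
         "combination must be present exactly once")
  rownames(design) <- design$sample_id
  design
}

#' Test whether a design is fully crossed
#'
#' @param design a design table (see \code{\link{checkDesign}}).
#' @return \code{TRUE} if every individual-by-tissue combination occurs
#'   exactly once.
#' @export
isFullyCrossed <- function(design) {
  tab <- table(design$individual, design$tissue)
  all(tab == 1L)
}

#' Read a design table from TSV
#'
#' Expects columns \code{sample_id}, \code{individual}, \code{tissue},
#' \code{sex} (male/female or -1/2, +1/2). Lines starting with '#' are
#' treated as comments.
#'
#' @param path path to a tab-separated file.
#' @return a validated design data.frame.
#' @export
readDesign <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  checkDesign(d)
}

# Reshape a per-sample vector into an individuals x tissues matrix.
# Requires a fully crossed design.
utMatrix <- function(values, design) {
  stopifnot(length(values) == nrow(design))
  ind <- levels(design$individual)
  tis <- levels(design$tissue)
  m <- matrix(NA_real_, length(ind), length(tis), dimnames = list(ind, tis))
  m[cbind(as.character(design$individual), as.character(design$tissue))] <-
    values
  m
}

# Inverse of utMatrix: per-sample vector in design row order.
utVector <- function(mat, design) {
  mat[cbind(as.character(design$individual), as.character(design$tissue))]
}
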