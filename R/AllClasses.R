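#' @import SummarizedExperiment
NULL

#' FlattenedGeneModel: reduced gene models of disjoint exonic regions
#'
#' Holds the non-overlapping exonic regions obtained by flattening transcript
#' annotation: per (aggregate) gene, the base-level union of all transcripts'
#' exons, partitioned at every distinct exon boundary. Regions carry a
#' \code{gene_id} and a \code{region_id} (zero-padded ordinal by ascending
#' start, e.g. \code{E001}).
#'
#' @slot regions a \code{GRanges}, sorted by gene and start, with metadata
#'   columns \code{gene_id} and \code{region_id}.
#' @slot aggregateMap named character vector mapping each original gene
#'   identifier to its (possibly aggregated) gene group identifier.
#' @export
setClass("FlattenedGeneModel",
  representation(regions = "GRanges", aggregateMap = "character"))

setValidity("FlattenedGeneModel", function(object) {
  gr <- object@regions
  msg <- NULL
  if (length(gr)) {
    mc <- S4Vectors::mcols(gr)
    if (!all(c("gene_id", "region_id") %in% colnames(mc)))
      return("regions must carry gene_id and region_id metadata columns")
    if (any(width(gr) < 1L))
      msg <- c(msg, "all regions must have width >= 1")
    bygene <- split(gr, mc$gene_id)
    ovl <- vapply(bygene, function(g)
      any(IRanges::overlapsAny(ranges(g), drop.self = TRUE)), logical(1))
    if (any(ovl))
      msg <- c(msg, "regions of the same gene must be pairwise disjoint")
    if (anyDuplicated(globalKey(mc$gene_id, mc$region_id)))
      msg <- c(msg, "duplicated gene_id:region_id keys")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn FlattenedGeneModel number of exonic regions.
#' @param x,object a \code{FlattenedGeneModel}.
#' @export
setMethod("length", "FlattenedGeneModel", function(x) length(x@regions))

#' Accessors for FlattenedGeneModel
#'
#' \code{regions} returns the exonic-region \code{GRanges};
#' \code{aggregateMap} the original-to-aggregate gene map; \code{geneIds}
#' the aggregate gene identifiers (one per gene group).
#'
#' @param x a \code{FlattenedGeneModel}.
#' @return see description.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname regions
#' @export
setMethod("regions", "FlattenedGeneModel", function(x) x@regions)

#' @rdname regions
#' @export
setGeneric("aggregateMap", function(x) standardGeneric("aggregateMap"))

#' @rdname regions
#' @export
setMethod("aggregateMap", "FlattenedGeneModel", function(x) x@aggregateMap)

#' @rdname regions
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname regions
#' @export
setMethod("geneIds", "FlattenedGeneModel",
  function(x) unique(S4Vectors::mcols(x@regions)$gene_id))

setMethod("show", "FlattenedGeneModel", function(object) {
  cat("FlattenedGeneModel with", length(object), "exonic regions in",
      length(geneIds(object)), "gene group(s)\n")
  naggr <- sum(names(object@aggregateMap) != object@aggregateMap)
  if (naggr)
    cat(" ", naggr, "original gene(s) merged into aggregates\n")
})

#' ExonUsageExperiment: counts per exonic region and sample
#'
#' A \code{RangedSummarizedExperiment} whose rows are the exonic regions of a
#' \code{\link{FlattenedGeneModel}} and whose columns are samples of a fully
#' crossed individuals-by-tissues design. Assays: \code{inclusion} (fragments
#' overlapping the region), optionally \code{rest} (fragments of the same gene
#' not touching the region) and \code{skipping} (fragments whose splice gap
#' skips the region while anchoring up- and downstream in the same gene).
#' Per-gene distinct-fragment totals, when known at fragment level, are kept
#' in \code{metadata(x)$geneTotals}.
#'
#' @export
setClass("ExonUsageExperiment", contains = "RangedSummarizedExperiment")

setValidity("ExonUsageExperiment", function(object) {
  msg <- NULL
  if (!"inclusion" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an 'inclusion' assay is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene_id", "region_id") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain gene_id and region_id")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "individual", "tissue", "sex") %in% colnames(cd)))
    msg <- c(msg, "colData must contain sample_id, individual, tissue, sex")
  for (a in SummarizedExperiment::assayNames(object)) {
    m <- SummarizedExperiment::assay(object, a)
    if (any(m < 0) || any(m != floor(m)))
      msg <- c(msg, sprintf("assay '%s' must contain non-negative integers", a))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExonUsageExperiment
#'
#' @param inclusion integer matrix of inclusion counts, regions x samples;
#'   rownames must be \code{gene:region} keys matching \code{model}.
#' @param model a \code{\link{FlattenedGeneModel}} (or \code{NULL}; then
#'   rownames of \code{inclusion} are parsed as \code{gene:region}).
#' @param design design table (see \code{\link{checkDesign}}); rows are
#'   matched to columns of the assays via \code{sample_id}.
#' @param rest,skipping optional count matrices with the same dimnames.
#' @param geneTotals optional genes x samples matrix of distinct fragments
#'   assigned per gene.
#' @return an \code{ExonUsageExperiment}.
#' @export
ExonUsageExperiment <- function(inclusion, design, model = NULL,
                                rest = NULL, skipping = NULL,
                                geneTotals = NULL) {
  design <- checkDesign(design)
  if (!setequal(colnames(inclusion), design$sample_id))
    stop("column names of counts do not match design sample_id; offending: ",
         paste(union(setdiff(colnames(inclusion), design$sample_id),
                     setdiff(design$sample_id, colnames(inclusion))),
               collapse = ", "))
  ord <- design$sample_id
  inclusion <- inclusion[, ord, drop = FALSE]
  assays <- list(inclusion = inclusion)
  for (nm in c("rest", "skipping")) {
    m <- get(nm)
    if (!is.null(m)) {
      stopifnot(identical(rownames(m), rownames(inclusion)))
      assays[[nm]] <- m[, ord, drop = FALSE]
    }
  }
  if (!is.null(model)) {
    gr <- regions(model)
    key <- globalKey(S4Vectors::mcols(gr)$gene_id,
                     S4Vectors::mcols(gr)$region_id)
    stopifnot(setequal(rownames(inclusion), key))
    gr <- gr[match(rownames(inclusion), key)]
  } else {
    parts <- strsplit(rownames(inclusion), ":", fixed = TRUE)
    gid <- vapply(parts, function(p) paste(head(p, -1), collapse = ":"),
                  character(1))
    rid <- vapply(parts, function(p) p[length(p)], character(1))
    gr <- GRanges("unknown", IRanges(seq_along(gid), width = 1L),
                  gene_id = gid, region_id = rid)
  }
  names(gr) <- rownames(inclusion)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = gr,
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
  if (!is.null(geneTotals))
    S4Vectors::metadata(se)$geneTotals <- geneTotals[, ord, drop = FALSE]
  new("ExonUsageExperiment", se)
}

#' UsageCoefficients: fitted relative usage coefficients
#'
#' Per-region shrunken individual-by-tissue interaction coefficients from the
#' Gamma-Poisson GLM fits, for one counting scheme: \code{REUC} (exon counts
#' versus rest-of-gene counts) or \code{RSIC} (exon counts versus
#' exon-skipping junction counts). Rows of \code{beta} are regions, columns
#' are samples (one per individual-tissue combination in a fully crossed
#' design); excluded regions are all-\code{NA} rows with the reason in
#' \code{flags}.
#'
#' @slot scheme \code{"REUC"} or \code{"RSIC"}.
#' @slot beta regions x samples matrix of shrunken interaction coefficients.
#' @slot meanUsage per-region average log usage ratio (the level main effect).
#' @slot sexEffect per-region sex coefficient.
#' @slot dispersion per-region Gamma-Poisson dispersion used in the fit.
#' @slot priorVariance named numeric: shrinkage prior variances for the
#'   interaction and sex coefficient classes.
#' @slot flags per-region fit status ("ok", "low_count", "unestimable",
#'   "not_converged").
#' @slot design the validated design table.
#' @export
setClass("UsageCoefficients",
  representation(scheme = "character", beta = "matrix",
                 meanUsage = "numeric", sexEffect = "numeric",
                 dispersion = "numeric", priorVariance = "numeric",
                 flags = "character", design = "data.frame"))

setValidity("UsageCoefficients", function(object) {
  msg <- NULL
  if (!object@scheme %in% c("REUC", "RSIC"))
    msg <- c(msg, "scheme must be 'REUC' or 'RSIC'")
  if (nrow(object@beta) != length(object@flags))
    msg <- c(msg, "flags length must match rows of beta")
  if (ncol(object@beta) != nrow(object@design))
    msg <- c(msg, "columns of beta must match design rows")
  bad <- object@flags == "ok" & !is.finite(rowSums(object@beta))
  if (any(bad))
    msg <- c(msg, "non-finite coefficients in regions flagged 'ok'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname regions
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname regions
#' @export
setMethod("scheme", "UsageCoefficients", function(x) x@scheme)

#' @rdname regions
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname regions
#' @export
setMethod("coefMatrix", "UsageCoefficients", function(x) x@beta)

#' @rdname regions
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname regions
#' @export
setMethod("designTable", "UsageCoefficients", function(x) x@design)

#' @rdname regions
#' @export
setMethod("designTable", "ExonUsageExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' Individuals-by-tissues coefficient matrix for one region
#'
#' @param x a \code{UsageCoefficients} object.
#' @param region a region key (rowname of \code{coefMatrix(x)}) or row index.
#' @return matrix with one row per individual and one column per tissue.
#' @export
betaMatrixUT <- function(x, region) {
  stopifnot(is(x, "UsageCoefficients"))
  utMatrix(x@beta[region, ], x@design)
}

setMethod("show", "UsageCoefficients", function(object) {
  cat("UsageCoefficients (", object@scheme, ") for ", nrow(object@beta),
      " regions x ", ncol(object@beta), " samples\n", sep = "")
  cat("  estimable regions:", sum(object@flags == "ok"), "\n")
  cat("  prior variance (interaction):",
      signif(object@priorVariance[["interaction"]], 4), "\n")
})
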