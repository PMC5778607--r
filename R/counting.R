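#' Count fragments over a flattened gene model
#'
#' Assigns uniquely mapped fragments to exonic regions under the two counting
#' schemes. A fragment increments the inclusion count of every exonic region
#' of one gene group that any of its blocks overlaps by at least one base;
#' fragments touching regions of more than one gene group are discarded as
#' ambiguous, and non-unique fragments are discarded. A fragment increments
#' the skipping count of region i when one of its splice gaps fully contains
#' region i and it has blocks overlapping regions of the same gene both
#' strictly upstream and strictly downstream of i. Per-gene totals of
#' distinct assigned fragments are recorded for the rest-of-gene counts.
#'
#' @param fragments a fragment block data.frame (see \code{\link{fragments}}).
#' @param model a \code{\link{FlattenedGeneModel}}.
#' @param samples optional character vector fixing the sample set/order of
#'   the returned matrices (defaults to the samples present).
#' @return \code{countFragments}: list with integer matrices
#'   \code{inclusion} and \code{skipping} (regions x samples),
#'   \code{geneTotals} (genes x samples), and counts of discarded fragments
#'   (\code{nNonUnique}, \code{nAmbiguous}, \code{nUnassigned},
#'   \code{nSkippedChrom}). \code{countInclusion} and \code{countSkipping}
#'   return just the corresponding matrix.
#' @export
countFragments <- function(fragments, model, samples = NULL) {
  fragments <- .validateFragments(fragments)
  gr <- regions(model)
  if (is.null(samples)) samples <- unique(fragments$sample_id)
  rkeys <- names(gr)
  genes <- unique(gr$gene_id)
  empty <- function(rn) matrix(0L, length(rn), length(samples),
                               dimnames = list(rn, samples))
  res <- list(inclusion = empty(rkeys), skipping = empty(rkeys),
              geneTotals = empty(genes), nNonUnique = 0L, nAmbiguous = 0L,
              nUnassigned = 0L, nSkippedChrom = 0L)
  if (nrow(fragments) == 0L) return(res)

  frag <- factor(fragments$fragment_id, levels = unique(fragments$fragment_id))
  nonuniq <- vapply(split(fragments$unique, frag), function(u) !all(u),
                    logical(1))
  res$nNonUnique <- sum(nonuniq)
  keep <- !nonuniq[frag]
  fragments <- fragments[keep, , drop = FALSE]
  frag <- droplevels(frag[keep])
  if (nrow(fragments) == 0L) return(res)

  onModel <- fragments$chrom %in% as.character(seqlevels(gr))
  droppedChrom <- unique(frag[!onModel])
  res$nSkippedChrom <- length(droppedChrom)
  fragments <- fragments[onModel, , drop = FALSE]
  frag <- droplevels(frag[onModel])
  if (nrow(fragments) == 0L) return(res)

  blocks <- GRanges(fragments$chrom, IRanges(fragments$start, fragments$end))
  hits <- GenomicRanges::findOverlaps(blocks, gr, ignore.strand = TRUE)
  pair <- unique(data.frame(frag = as.integer(frag)[S4Vectors::queryHits(hits)],
                            region = S4Vectors::subjectHits(hits)))
  if (nrow(pair) == 0L) {
    res$nUnassigned <- nlevels(frag)
    return(res)
  }
  pair$gene <- gr$gene_id[pair$region]
  ngene <- vapply(split(pair$gene, pair$frag), function(g)
    length(unique(g)), integer(1))
  ambig <- as.integer(names(ngene))[ngene > 1L]
  res$nAmbiguous <- length(ambig)
  res$nUnassigned <- nlevels(frag) - length(unique(pair$frag))
  pair <- pair[!pair$frag %in% ambig, , drop = FALSE]
  if (nrow(pair) == 0L) return(res)

  fragSample <- fragments$sample_id[match(levels(frag), fragments$fragment_id)]
  pair$sample <- fragSample[pair$frag]

  inc <- table(factor(pair$region, levels = seq_along(gr)),
               factor(pair$sample, levels = samples))
  res$inclusion <- matrix(as.integer(inc), nrow = length(gr),
                          dimnames = list(rkeys, samples))

  gt <- unique(pair[, c("frag", "gene", "sample")])
  gtt <- table(factor(gt$gene, levels = genes),
               factor(gt$sample, levels = samples))
  res$geneTotals <- matrix(as.integer(gtt), nrow = length(genes),
                           dimnames = list(genes, samples))

  # skipping: splice gaps fully containing a region, flanked within the gene
  multi <- tapply(seq_len(nrow(fragments)), frag, identity)
  multi <- multi[lengths(multi) >= 2L]
  if (length(multi)) {
    gapdf <- do.call(rbind, lapply(multi, function(i) {
      i <- i[order(fragments$start[i])]
      data.frame(frag = as.integer(frag)[i[1]],
                 chrom = fragments$chrom[i[1]],
                 gs = fragments$end[i[-length(i)]] + 1L,
                 ge = fragments$start[i[-1]] - 1L)
    }))
    gapdf <- gapdf[gapdf$ge >= gapdf$gs & !gapdf$frag %in% ambig, ,
                   drop = FALSE]
    if (nrow(gapdf)) {
      gaps <- GRanges(gapdf$chrom, IRanges(gapdf$gs, gapdf$ge))
      gh <- GenomicRanges::findOverlaps(gr, gaps, type = "within",
                                        ignore.strand = TRUE)
      if (length(gh)) {
        cand <- data.frame(region = S4Vectors::queryHits(gh),
                           frag = gapdf$frag[S4Vectors::subjectHits(gh)])
        cand <- unique(cand)
        cand$gene <- gr$gene_id[cand$region]
        # touched regions per fragment within the same gene
        key <- paste(cand$frag, cand$gene)
        pkey <- paste(pair$frag, pair$gene)
        touched <- split(pair$region, pkey)
        ok <- vapply(seq_len(nrow(cand)), function(k) {
          tr <- touched[[key[k]]]
          if (is.null(tr)) return(FALSE)
        any(end(gr)[tr] < start(gr)[cand$region[k]]) &&
          any(start(gr)[tr] > end(gr)[cand$region[k]])
        }, logical(1))
        cand <- cand[ok, , drop = FALSE]
        if (nrow(cand)) {
          cand$sample <- fragSample[cand$frag]
          sk <- table(factor(cand$region, levels = seq_along(gr)),
                      factor(cand$sample, levels = samples))
          res$skipping <- matrix(as.integer(sk), nrow = length(gr),
                                 dimnames = list(rkeys, samples))
        }
      }
    }
  }
  res
}

#' @rdname countFragments
#' @export
countInclusion <- function(fragments, model, samples = NULL)
  countFragments(fragments, model, samples)$inclusion

#' @rdname countFragments
#' @export
countSkipping <- function(fragments, model, samples = NULL)
  countFragments(fragments, model, samples)$skipping

#' Build inclusion/rest count pairs for the REUC scheme
#'
#' For each exonic region i and sample, the rest-of-gene count is the number
#' of the gene's fragments not overlapping region i. When per-gene
#' distinct-fragment totals are available (fragment-level counting), this is
#' \code{geneTotal - inclusion}; otherwise gene totals are taken as the sum
#' of the gene's per-region inclusion counts (exact when every fragment
#' touches a single region).
#'
#' @param inclusion regions x samples inclusion count matrix with
#'   \code{gene:region} rownames.
#' @param model a \code{\link{FlattenedGeneModel}} (or \code{NULL} to parse
#'   gene ids from rownames).
#' @param geneTotals optional genes x samples matrix of distinct fragments.
#' @return list with matrices \code{k1} (inclusion) and \code{k0} (rest).
#' @export
buildReucPairs <- function(inclusion, model = NULL, geneTotals = NULL) {
  if (!is.null(model)) {
    gr <- regions(model)
    gene <- gr$gene_id[match(rownames(inclusion), names(gr))]
  } else {
    gene <- sub(":[^:]+$", "", rownames(inclusion))
  }
  if (anyNA(gene) || any(gene == rownames(inclusion)))
    stop("region(s) without gene assignment: ",
         paste(head(rownames(inclusion)[is.na(gene) |
                                        gene == rownames(inclusion)]),
               collapse = ", "))
  if (is.null(geneTotals)) {
    geneTotals <- rowsum(inclusion, gene)
  }
  k0 <- geneTotals[gene, , drop = FALSE] - inclusion
  dimnames(k0) <- dimnames(inclusion)
  if (any(k0 < 0))
    stop("negative rest counts: gene totals inconsistent with inclusion")
  list(k1 = inclusion, k0 = k0)
}

#' Build an ExonUsageExperiment from fragments
#'
#' Runs \code{\link{countFragments}} and assembles inclusion, rest and
#' skipping assays with the design.
#'
#' @inheritParams countFragments
#' @param design design table (see \code{\link{checkDesign}}).
#' @return an \code{\link{ExonUsageExperiment}}.
#' @export
countExperiment <- function(fragments, model, design) {
  design <- checkDesign(design)
  cf <- countFragments(fragments, model, samples = design$sample_id)
  pairs <- buildReucPairs(cf$inclusion, model, cf$geneTotals)
  ExonUsageExperiment(inclusion = cf$inclusion, design = design,
                      model = model, rest = pairs$k0,
                      skipping = cf$skipping, geneTotals = cf$geneTotals)
}
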