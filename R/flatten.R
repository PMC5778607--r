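#' Flatten transcript annotation into reduced gene models
#'
#' Converts a transcript-level annotation into non-overlapping exonic regions:
#' per gene, the base-level union of its transcripts' exons is partitioned at
#' every distinct exon boundary occurring in any transcript (adjacent pieces
#' covered by identical transcript sets are kept merged, so the partition
#' equals maximal runs of constant per-base transcript coverage). Genes whose
#' exon unions overlap are merged into one aggregate gene group (identifier
#' \code{geneA+geneB}) or, optionally, dropped.
#'
#' @param annotation a GTF/GFF file path, or a \code{GRanges} of exon records
#'   with metadata columns \code{gene_id} and \code{transcript_id} (records
#'   with a \code{type} column are filtered to \code{type == "exon"}), or a
#'   data.frame with columns \code{chrom,start,end,strand,gene_id,
#'   transcript_id} (1-based inclusive coordinates).
#' @param aggregate if \code{TRUE} (default), overlapping genes are merged
#'   into aggregate groups; if \code{FALSE}, all genes involved in an overlap
#'   are dropped.
#' @param ignoreStrand if \code{TRUE}, genes on different strands (and strand
#'   \code{*}) may be merged; default is strand-specific merging, with
#'   \code{*} compatible only with itself.
#' @return a \code{\link{FlattenedGeneModel}}.
#' @examples
#' ex <- data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 250),
#'                  strand = "+", gene_id = "g1",
#'                  transcript_id = c("t1", "t2"))
#' fgm <- flattenGeneModels(ex)
#' regions(fgm)   # three regions: [100,149], [150,200], [201,250]
#' @export
flattenGeneModels <- function(annotation, aggregate = TRUE,
                              ignoreStrand = FALSE) {
  ex <- .asExonGRanges(annotation)
  if (length(ex) == 0L)
    stop("annotation contains no exon records with gene identifiers")

  # merge abutting/overlapping exons within each transcript first
  extx <- GenomicRanges::reduce(
    GenomicRanges::split(ex, paste(ex$gene_id, ex$transcript_id, sep = "\r")))
  txmeta <- do.call(rbind, strsplit(names(extx), "\r", fixed = TRUE))
  ex <- unlist(extx, use.names = FALSE)
  ex$gene_id <- rep(txmeta[, 1], lengths(extx))
  ex$transcript_id <- rep(txmeta[, 2], lengths(extx))

  # group overlapping genes via their exon unions
  genes <- sort(unique(ex$gene_id))
  un <- GenomicRanges::reduce(GenomicRanges::split(ex, ex$gene_id))[genes]
  flat <- unlist(un, use.names = FALSE)
  gof <- rep(seq_along(genes), lengths(un))
  hits <- GenomicRanges::findOverlaps(flat, flat,
                                      ignore.strand = ignoreStrand)
  hits <- hits[gof[S4Vectors::queryHits(hits)] !=
               gof[S4Vectors::subjectHits(hits)]]
  # union-find over genes
  parent <- seq_along(genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_along(hits)) {
    a <- find(gof[S4Vectors::queryHits(hits)[k]])
    b <- find(gof[S4Vectors::subjectHits(hits)[k]])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_along(genes), find, integer(1))
  aggId <- vapply(split(genes, comp), function(g)
    paste(sort(g), collapse = "+"), character(1))
  aggregateMap <- setNames(aggId[as.character(comp)], genes)

  if (!aggregate) {
    multi <- names(table(comp))[table(comp) > 1]
    keep <- !(as.character(comp) %in% multi)
    aggregateMap <- aggregateMap[keep]
    ex <- ex[ex$gene_id %in% genes[keep]]
    if (length(ex) == 0L)
      stop("all genes dropped as overlapping; rerun with aggregate = TRUE")
  }
  ex$group_id <- unname(aggregateMap[ex$gene_id])

  out <- lapply(split(seq_along(ex), ex$group_id), function(idx) {
    .flattenOneGroup(ex[idx], ex$group_id[idx[1]])
  })
  regions <- sort(unlist(GRangesList(out), use.names = FALSE),
                  ignore.strand = TRUE)
  regions <- regions[order(regions$gene_id, start(regions))]
  new("FlattenedGeneModel", regions = regions, aggregateMap = aggregateMap)
}

# Partition the pooled exons of one gene group at every transcript boundary,
# keeping abutting pieces merged when covered by identical transcript sets.
.flattenOneGroup <- function(ex, group_id) {
  if (length(unique(as.character(seqnames(ex)))) > 1L)
    stop("gene group '", group_id, "' has exons on multiple chromosomes")
  strands <- unique(as.character(strand(ex)))
  str <- if (length(strands) == 1L) strands else "*"
  dj <- GenomicRanges::disjoin(ex, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(dj, ex, ignore.strand = TRUE)
  txset <- vapply(
    split(paste(ex$gene_id, ex$transcript_id)[S4Vectors::subjectHits(ov)],
          factor(S4Vectors::queryHits(ov), levels = seq_along(dj))),
    function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  # dj from disjoin(ignore.strand = TRUE) is sorted by start already;
  # merge adjacent pieces with identical covering transcript sets
  newrun <- c(TRUE, !(start(dj)[-1] == end(dj)[-length(dj)] + 1L &
                      txset[-1] == txset[-length(txset)]))
  run <- cumsum(newrun)
  st <- tapply(start(dj), run, min)
  en <- tapply(end(dj), run, max)
  gr <- GRanges(seqnames(dj)[1], IRanges(as.integer(st), as.integer(en)),
                strand = str)
  gr$gene_id <- group_id
  gr$region_id <- sprintf("E%03d", seq_along(gr))
  names(gr) <- globalKey(gr$gene_id, gr$region_id)
  gr
}

.asExonGRanges <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- rtracklayer::import(annotation)
  }
  if (is.data.frame(annotation)) {
    needed <- c("chrom", "start", "end", "gene_id", "transcript_id")
    if (!all(needed %in% colnames(annotation)))
      stop("annotation data.frame needs columns: ",
           paste(needed, collapse = ", "))
    if (any(annotation$end < annotation$start))
      stop("malformed annotation: exon with end < start")
    strand <- if ("strand" %in% colnames(annotation))
      as.character(annotation$strand) else "*"
    if (!all(strand %in% c("+", "-", "*")))
      stop("unknown strand symbol; must be one of +, -, *")
    annotation <- GRanges(annotation$chrom,
                          IRanges(annotation$start, annotation$end),
                          strand = strand,
                          gene_id = as.character(annotation$gene_id),
                          transcript_id = as.character(annotation$transcript_id))
  }
  if (!is(annotation, "GRanges"))
    stop("annotation must be a file path, GRanges or data.frame")
  mc <- S4Vectors::mcols(annotation)
  if ("type" %in% colnames(mc))
    annotation <- annotation[mc$type == "exon"]
  mc <- S4Vectors::mcols(annotation)
  if (!"gene_id" %in% colnames(mc))
    stop("exon records must carry a gene_id attribute")
  if (!"transcript_id" %in% colnames(mc) || all(is.na(mc$transcript_id)))
    annotation$transcript_id <- annotation$gene_id
  if (any(width(annotation) < 1L))
    stop("malformed annotation: exon with end < start")
  annotation
}
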