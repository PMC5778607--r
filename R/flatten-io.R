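#' Write and read flattened gene models as GFF3
#'
#' \code{writeFlattenedGFF} serializes a \code{\link{FlattenedGeneModel}} as
#' GFF3 (1-based inclusive coordinates) with one \code{aggregate_gene}
#' feature per gene group and one \code{exonic_region} feature per region;
#' \code{readFlattenedGFF} inverts it, so that
#' \code{readFlattenedGFF(writeFlattenedGFF(m, f))} reproduces \code{m}.
#' Aggregate membership is encoded in the gene group identifier
#' (\code{geneA+geneB}).
#'
#' @param model a \code{FlattenedGeneModel}.
#' @param path output (input) file path.
#' @return \code{writeFlattenedGFF} returns \code{path} invisibly;
#'   \code{readFlattenedGFF} returns a \code{FlattenedGeneModel}.
#' @export
writeFlattenedGFF <- function(model, path) {
  stopifnot(is(model, "FlattenedGeneModel"))
  gr <- regions(model)
  lines <- "##gff-version 3"
  if (length(gr)) {
    bygene <- split(seq_along(gr), gr$gene_id)
    bygene <- bygene[order(vapply(bygene, function(i) min(start(gr)[i]), 0),
                           vapply(bygene, function(i)
                             as.character(seqnames(gr))[i[1]], ""))]
    feat <- character(0)
    for (idx in bygene) {
      g <- gr[idx]
      gid <- g$gene_id[1]
      feat <- c(feat,
        paste(as.character(seqnames(g))[1], "TDUseq", "aggregate_gene",
              min(start(g)), max(end(g)), ".", as.character(strand(g))[1],
              ".", sprintf("ID=%s;gene_id=%s", gid, gid), sep = "\t"),
        paste(as.character(seqnames(g)), "TDUseq", "exonic_region",
              start(g), end(g), ".", as.character(strand(g)), ".",
              sprintf("ID=%s:%s;gene_id=%s;region_id=%s",
                      gid, g$region_id, gid, g$region_id), sep = "\t"))
    }
    lines <- c(lines, feat)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFlattenedGFF
#' @export
readFlattenedGFF <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "exonic_region"]
  if (length(gr) == 0L) {
    empty <- GRanges()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      gene_id = character(0), region_id = character(0))
    return(new("FlattenedGeneModel", regions = empty,
               aggregateMap = setNames(character(0), character(0))))
  }
  out <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr),
                 gene_id = as.character(gr$gene_id),
                 region_id = as.character(gr$region_id))
  out <- out[order(out$gene_id, start(out))]
  names(out) <- globalKey(out$gene_id, out$region_id)
  groups <- unique(out$gene_id)
  orig <- strsplit(groups, "+", fixed = TRUE)
  aggregateMap <- setNames(rep(groups, lengths(orig)), unlist(orig))
  aggregateMap <- aggregateMap[order(names(aggregateMap))]
  new("FlattenedGeneModel", regions = out, aggregateMap = aggregateMap)
}
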