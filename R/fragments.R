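#' Fragment representation and I/O
#'
#' Sequenced fragments are represented as a data.frame with one row per
#' aligned block: columns \code{fragment_id}, \code{sample_id}, \code{chrom},
#' \code{start}, \code{end} (1-based inclusive), \code{strand} and
#' \code{unique} (logical; uniquely mapped). Gaps between consecutive blocks
#' of a fragment are splice gaps. Paired-end mates are merged into one
#' fragment before counting.
#'
#' \code{readFragmentsTSV} reads the 6-column fragment format
#' (\code{sample}, \code{chrom}, comma-separated \code{block_starts} and
#' \code{block_ends}, \code{strand}, \code{unique});
#' \code{writeFragmentsTSV} writes it. \code{readFragmentsSAM} parses a SAM
#' file (text), merging mates by read name and splitting blocks at N CIGAR
#' operations.
#'
#' @param path file path.
#' @param fragments a fragment block data.frame as described above.
#' @return a fragment block data.frame.
#' @name fragments
NULL

.validateFragments <- function(fragments) {
  needed <- c("fragment_id", "sample_id", "chrom", "start", "end",
              "strand", "unique")
  stopifnot(all(needed %in% colnames(fragments)))
  if (any(fragments$end < fragments$start))
    stop("fragment block with end < start")
  fragments
}

#' @rdname fragments
#' @export
readFragmentsTSV <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(block_starts = "character",
                                 block_ends = "character"))
  needed <- c("sample", "chrom", "block_starts", "block_ends", "strand",
              "unique")
  if (!all(needed %in% colnames(d)))
    stop("fragment TSV needs columns: ", paste(needed, collapse = ", "))
  st <- strsplit(d$block_starts, ",", fixed = TRUE)
  en <- strsplit(d$block_ends, ",", fixed = TRUE)
  if (!identical(lengths(st), lengths(en)))
    stop("block_starts and block_ends length mismatch")
  n <- lengths(st)
  out <- data.frame(
    fragment_id = rep(seq_len(nrow(d)), n),
    sample_id = rep(d$sample, n),
    chrom = rep(d$chrom, n),
    start = as.integer(unlist(st)),
    end = as.integer(unlist(en)),
    strand = rep(d$strand, n),
    unique = rep(as.logical(d$unique), n),
    stringsAsFactors = FALSE)
  .validateFragments(out)
}

#' @rdname fragments
#' @export
writeFragmentsTSV <- function(fragments, path) {
  fragments <- .validateFragments(fragments)
  o <- order(factor(fragments$fragment_id,
                    levels = unique(fragments$fragment_id)),
             fragments$start)
  fragments <- fragments[o, ]
  byfrag <- split(seq_len(nrow(fragments)), fragments$fragment_id)
  byfrag <- byfrag[order(vapply(byfrag, min, 0L))]  # keep input order
  rows <- vapply(byfrag, function(i) {
    paste(fragments$sample_id[i[1]], fragments$chrom[i[1]],
          paste(fragments$start[i], collapse = ","),
          paste(fragments$end[i], collapse = ","),
          fragments$strand[i[1]], fragments$unique[i[1]], sep = "\t")
  }, character(1))
  writeLines(c("sample\tchrom\tblock_starts\tblock_ends\tstrand\tunique",
               rows), path)
  invisible(path)
}

#' @rdname fragments
#' @param sample_id sample identifier assigned to all fragments in the file.
#' @param mapqMin if not \code{NA}, a fragment is unique when its mapping
#'   quality is at least this value; by default uniqueness is flag/NH-based
#'   (not secondary/supplementary, and NH tag equal to 1 when present).
#' @export
readFragmentsSAM <- function(path, sample_id, mapqMin = NA) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(fragment_id = character(0), sample_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      unique = logical(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  keep <- bitwAnd(flag, 0x4) == 0L & bitwAnd(flag, 0x100) == 0L &
          bitwAnd(flag, 0x800) == 0L
  f <- f[keep]; flag <- flag[keep]
  if (length(f) == 0L)
    return(data.frame(fragment_id = character(0), sample_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      unique = logical(0)))
  qname <- vapply(f, `[`, "", 1L)
  rname <- vapply(f, `[`, "", 3L)
  pos <- vapply(f, function(x) as.integer(x[4]), 0L)
  mapq <- vapply(f, function(x) as.integer(x[5]), 0L)
  cigar <- vapply(f, `[`, "", 6L)
  nh <- vapply(f, function(x) {
    tag <- grep("^NH:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NH:i:", "", tag[1])) else NA_integer_
  }, 0L)
  uniq <- if (is.na(mapqMin)) is.na(nh) | nh == 1L else mapq >= mapqMin
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(cigar, pos)
  nb <- lengths(blocks)
  bl <- unlist(blocks, use.names = FALSE)
  df <- data.frame(
    qname = rep(qname, nb), chrom = rep(rname, nb),
    start = start(bl), end = end(bl),
    strand = rep(ifelse(bitwAnd(flag, 0x10) > 0L, "-", "+"), nb),
    unique = rep(uniq, nb), stringsAsFactors = FALSE)
  # merge mates: blocks of a fragment are the reduced union over both reads
  byq <- split(seq_len(nrow(df)), factor(df$qname, levels = unique(df$qname)))
  pieces <- lapply(names(byq), function(q) {
    i <- byq[[q]]
    r <- IRanges::reduce(IRanges(df$start[i], df$end[i]))
    data.frame(fragment_id = q, sample_id = sample_id,
               chrom = df$chrom[i[1]], start = start(r), end = end(r),
               strand = "*", unique = all(df$unique[i]),
               stringsAsFactors = FALSE)
  })
  .validateFragments(do.call(rbind, pieces))
}

#' Write fragments as a minimal SAM file
#'
#' Emits one single-end SAM record per fragment with an M/N CIGAR encoding
#' its blocks and splice gaps (MAPQ 60, flag 0). Intended for feeding the
#' counting module and external tools with synthetic data.
#'
#' @param fragments a fragment block data.frame (see \code{\link{fragments}}).
#' @param path output path.
#' @param seqlengths optional named vector of chromosome lengths for the
#'   \code{@SQ} headers; inferred from the data when missing.
#' @export
writeFragmentsSAM <- function(fragments, path, seqlengths = NULL) {
  fragments <- .validateFragments(fragments)
  if (is.null(seqlengths)) {
    seqlengths <- tapply(fragments$end, fragments$chrom, max)
    seqlengths <- setNames(as.integer(seqlengths + 1000L), names(seqlengths))
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  o <- order(factor(fragments$fragment_id,
                    levels = unique(fragments$fragment_id)), fragments$start)
  fragments <- fragments[o, ]
  byfrag <- split(seq_len(nrow(fragments)), fragments$fragment_id)
  recs <- vapply(byfrag, function(i) {
    st <- fragments$start[i]; en <- fragments$end[i]
    cig <- paste0(en - st + 1L, "M")
    if (length(i) > 1L) {
      gaps <- st[-1] - en[-length(en)] - 1L
      cig <- paste0(paste0(cig[-length(cig)], gaps, "N", collapse = ""),
                    cig[length(cig)])
    }
    seq <- paste(rep("N", sum(en - st + 1L)), collapse = "")
    paste(fragments$fragment_id[i[1]], 0L, fragments$chrom[i[1]], st[1],
          60L, cig, "*", 0L, 0L, seq, "*", "NH:i:1", sep = "\t")
  }, character(1))
  recs <- recs[order(vapply(byfrag, function(i) fragments$chrom[i[1]], ""),
                     vapply(byfrag, function(i) fragments$start[i[1]], 0L))]
  writeLines(c(hdr, recs), path)
  invisible(path)
}
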