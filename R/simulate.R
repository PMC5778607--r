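#' Gamma-Poisson random deviates
#'
#' Draws counts with mean \code{mean} and variance \code{mean + dispersion *
#' mean^2} (Poisson-gamma mixture); \code{dispersion = 0} is Poisson.
#'
#' @param n number of draws.
#' @param mean mean (vector recycled to length n).
#' @param dispersion dispersion alpha >= 0.
#' @return integer vector of counts.
#' @export
rgampois <- function(n, mean, dispersion) {
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  out <- integer(n)
  mean <- rep_len(mean, n)
  dispersion <- rep_len(dispersion, n)
  pois <- dispersion < 1e-12
  out[pois] <- rpois(sum(pois), mean[pois])
  if (any(!pois))
    out[!pois] <- as.integer(rnbinom(sum(!pois), mu = mean[!pois],
                                     size = 1 / dispersion[!pois]))
  out
}

#' Simulate a fully crossed tissue-by-individual exon usage study
#'
#' Generates Gamma-Poisson counts per exonic region under the usage model,
#' with known ground truth, for a fully crossed design of
#' \code{nIndividuals} x \code{nTissues} (one sample per combination; sexes
#' alternate across individuals). Per gene, interior regions may carry
#' exon-skipping junction counts; the two planted effect mechanisms are:
#' \itemize{
#' \item \emph{splicing}: in the affected tissue the region's interior
#'   inclusion mean is multiplied by \code{exp(-effectSize)} and the removed
#'   mass is moved to its skipping mean, so gene-level fragment totals are
#'   conserved exactly (usage is not confounded with expression);
#' \item \emph{start_termination}: the inclusion mean is reduced the same
#'   way with skipping counts untouched, and all of the gene's means in the
#'   affected tissue are rescaled so the gene total is restored (the region
#'   is excluded from transcripts via an alternative start/termination site,
#'   which produces no junction reads).
#' }
#' Skipping fragments anchor in the two neighbouring regions, and those
#' anchor contributions are part of the emitted inclusion counts, exactly as
#' \code{\link{countFragments}} would count the corresponding fragments.
#' The truth table records the exact model-implied per-sample log usage
#' (inclusion versus rest-of-gene, anchors and all), its per-tissue shifts,
#' and whether a region is genuinely tissue-dependent.
#'
#' @param nIndividuals,nTissues design dimensions (>= 2 each).
#' @param nGenes number of genes.
#' @param regionsPerGene integer range (min, max) of regions per gene.
#' @param meanLog,sdLog log-normal parameters of baseline per-region
#'   inclusion means.
#' @param dispersion Gamma-Poisson dispersion: a constant, or c(a0, a1) for
#'   the trend a0 + a1/mean.
#' @param sizeFactorRange range of uniform (log-scale) true library-size
#'   factors.
#' @param sexEffectSd standard deviation of planted per-region sex effects
#'   (0 = none).
#' @param fractionAffected fraction of regions carrying a planted effect (at
#'   most one affected region per gene, interior regions only).
#' @param effectSize planted log effect size (exclusion of the region in the
#'   affected tissue).
#' @param mechanismMix fraction of planted effects that are splicing-driven
#'   (the rest are start/termination-driven).
#' @param nAffectedTissues number of affected tissues per event.
#' @param spliceBaselineFraction baseline skipping mean of splicing-affected
#'   regions, as a fraction of the inclusion mean.
#' @param skippableFraction fraction of unaffected interior regions with
#'   baseline skipping (cassette-like exons).
#' @param skippableRange skipping mean of such regions, as a uniform range
#'   of fractions of the inclusion mean.
#' @param startTermSkipMean baseline (unnormalized) skipping mean of
#'   start/termination-affected regions; 0 reflects that boundary-driven
#'   regions are typically never spliced out.
#' @param seed mandatory RNG seed (Mersenne-Twister / Inversion / Rejection).
#' @return list with \code{counts} (an \code{\link{ExonUsageExperiment}}
#'   with assays inclusion, rest, skipping), \code{truth} (a
#'   \code{DataFrame}; see Details), \code{model} (the
#'   \code{\link{FlattenedGeneModel}}) and \code{config}.
#' @export
simulateStudy <- function(nIndividuals = 10, nTissues = 6, nGenes = 100,
                          regionsPerGene = c(3, 8), meanLog = log(100),
                          sdLog = 1, dispersion = 0.05,
                          sizeFactorRange = c(0.5, 2), sexEffectSd = 0,
                          fractionAffected = 0.1, effectSize = 1.5,
                          mechanismMix = 0.5, nAffectedTissues = 1,
                          spliceBaselineFraction = 0.25,
                          skippableFraction = 0.2,
                          skippableRange = c(0.05, 0.3),
                          startTermSkipMean = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(nIndividuals >= 2, nTissues >= 2,
            nAffectedTissues <= nTissues - 1)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  individuals <- sprintf("I%02d", seq_len(nIndividuals))
  tissues <- sprintf("T%d", seq_len(nTissues))
  design <- expand.grid(individual = individuals, tissue = tissues,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample_id <- paste(design$individual, design$tissue, sep = ".")
  design$sex <- rep(rep_len(c(-0.5, 0.5), nIndividuals), nTissues)
  design <- checkDesign(design[, c("sample_id", "individual", "tissue",
                                   "sex")])
  n <- nrow(design)

  # gene model on one synthetic chromosome
  nreg <- if (regionsPerGene[1] == regionsPerGene[2])
    rep(regionsPerGene[1], nGenes)
  else sample(seq(regionsPerGene[1], regionsPerGene[2]), nGenes,
              replace = TRUE)
  geneOf <- rep(seq_len(nGenes), nreg)
  widths <- sample(50:300, sum(nreg), replace = TRUE)
  starts <- integer(sum(nreg))
  pos <- 1000L
  for (k in seq_along(widths)) {
    if (k > 1 && geneOf[k] != geneOf[k - 1]) pos <- pos + 1000L
    starts[k] <- pos
    pos <- pos + widths[k] + 100L
  }
  geneIdsV <- sprintf("G%04d", geneOf)
  ordinal <- unlist(lapply(nreg, seq_len))
  gr <- GRanges("chrS1", IRanges(starts, width = widths), strand = "+",
                gene_id = geneIdsV,
                region_id = sprintf("E%03d", ordinal))
  names(gr) <- globalKey(gr$gene_id, gr$region_id)
  model <- new("FlattenedGeneModel", regions = gr,
               aggregateMap = setNames(unique(geneIdsV), unique(geneIdsV)))
  R <- length(gr)
  interior <- ordinal > 1L & ordinal < nreg[geneOf]

  qBase <- rlnorm(R, meanLog, sdLog)
  alphaR <- if (length(dispersion) == 2L)
    pmax(dispersion[1] + dispersion[2] / qBase, 1e-8)
  else rep(dispersion, R)

  # planted effects: at most one per gene, interior regions only
  nAff <- round(fractionAffected * R)
  intIdx <- which(interior)
  # one candidate interior region per gene, chosen at random
  oneRegionPerGene <- vapply(split(intIdx, geneOf[intIdx]),
                             function(v) if (length(v) == 1L) v else
                               sample(v, 1L), 0L)
  nAff <- min(nAff, length(oneRegionPerGene))
  affected <- sample(unname(oneRegionPerGene), nAff)
  mech <- rep("start_termination", nAff)
  nspl <- round(mechanismMix * nAff)
  if (nspl > 0) mech[seq_len(nspl)] <- "splicing"
  mech <- sample(mech)
  affTissue <- lapply(seq_len(nAff), function(k)
    sample(tissues, nAffectedTissues))

  # baseline skipping means
  rhoBase <- numeric(R)
  skippable <- interior & runif(R) < skippableFraction
  rhoBase[skippable] <- qBase[skippable] *
    runif(sum(skippable), skippableRange[1], skippableRange[2])
  rhoBase[affected[mech == "splicing"]] <-
    qBase[affected[mech == "splicing"]] * spliceBaselineFraction
  rhoBase[affected[mech == "start_termination"]] <- startTermSkipMean

  betaSexTrue <- if (sexEffectSd > 0) rnorm(R, 0, sexEffectSd) else
    numeric(R)

  # per-sample mean matrices (interior inclusion and skipping pools)
  sexFac <- exp(outer(betaSexTrue, design$sex))
  IMu <- qBase * sexFac
  RhoMu <- matrix(rhoBase, R, n)
  for (k in seq_len(nAff)) {
    i <- affected[k]
    jj <- design$tissue %in% affTissue[[k]]
    removed <- IMu[i, jj] * (1 - exp(-effectSize))
    IMu[i, jj] <- IMu[i, jj] * exp(-effectSize)
    if (mech[k] == "splicing") {
      RhoMu[i, jj] <- RhoMu[i, jj] + removed
    } else {
      # restore the gene total in the affected tissue
      rows <- which(geneOf == geneOf[i])
      cur <- colSums(IMu[rows, jj, drop = FALSE]) +
             colSums(RhoMu[rows, jj, drop = FALSE])
      scl <- (cur + removed) / cur
      IMu[rows, jj] <- sweep(IMu[rows, jj, drop = FALSE], 2L, scl, "*")
      RhoMu[rows, jj] <- sweep(RhoMu[rows, jj, drop = FALSE], 2L, scl, "*")
    }
  }

  # anchor contributions: a skipping fragment of region i also overlaps
  # regions i-1 and i+1 of the same gene
  hasSkipPool <- rowSums(RhoMu) > 0
  anchorContrib <- matrix(0, R, n)
  for (i in which(hasSkipPool)) {
    anchorContrib[i - 1L, ] <- anchorContrib[i - 1L, ] + RhoMu[i, ]
    anchorContrib[i + 1L, ] <- anchorContrib[i + 1L, ] + RhoMu[i, ]
  }
  Mu1 <- IMu + anchorContrib
  geneTotMu <- rowsum(IMu + RhoMu, geneIdsV)
  Mu0 <- geneTotMu[geneIdsV, , drop = FALSE] - Mu1

  trueUsage <- log(Mu1 / Mu0)
  centered <- trueUsage - rowMeans(trueUsage)
  tisF <- factor(design$tissue, levels = tissues)
  tissueShift <- t(apply(centered, 1L, function(r) tapply(r, tisF, mean)))
  colnames(tissueShift) <- tissues
  trulyTDU <- apply(abs(tissueShift), 1L, max) > 0.01

  # draw counts
  sTrue <- exp(runif(n, log(sizeFactorRange[1]), log(sizeFactorRange[2])))
  names(sTrue) <- design$sample_id
  I <- matrix(rgampois(R * n, t(t(IMu) * sTrue), rep(alphaR, n)), R, n)
  Rho <- matrix(0L, R, n)
  pos <- RhoMu > 0
  if (any(pos))
    Rho[pos] <- rgampois(sum(pos), (t(t(RhoMu) * sTrue))[pos],
                         matrix(alphaR, R, n)[pos])
  inclusion <- I
  for (i in which(hasSkipPool)) {
    inclusion[i - 1L, ] <- inclusion[i - 1L, ] + Rho[i, ]
    inclusion[i + 1L, ] <- inclusion[i + 1L, ] + Rho[i, ]
  }
  dimnames(I) <- dimnames(Rho) <- dimnames(inclusion) <-
    list(names(gr), design$sample_id)
  geneTotals <- rowsum(I + Rho, geneIdsV)
  rest <- geneTotals[geneIdsV, , drop = FALSE] - inclusion
  dimnames(rest) <- dimnames(inclusion)

  mechV <- rep(NA_character_, R); mechV[affected] <- mech
  affT <- rep(NA_character_, R)
  affT[affected] <- vapply(affTissue, paste, "", collapse = ",")
  truth <- S4Vectors::DataFrame(
    gene_id = geneIdsV, region_id = gr$region_id,
    interior = interior, affected = seq_len(R) %in% affected,
    mechanism = mechV, affectedTissue = affT,
    effectSize = ifelse(seq_len(R) %in% affected, effectSize, 0),
    baselineMean = qBase, skipBaseline = rhoBase,
    betaSexTrue = betaSexTrue, trulyTDU = trulyTDU,
    row.names = names(gr))
  truth$trueUsage <- trueUsage
  truth$tissueShift <- tissueShift

  counts <- ExonUsageExperiment(inclusion = inclusion, design = design,
                                model = model, rest = rest, skipping = Rho,
                                geneTotals = geneTotals)
  S4Vectors::metadata(counts)$interiorCounts <- I
  S4Vectors::metadata(counts)$trueSizeFactors <- sTrue
  config <- list(nIndividuals = nIndividuals, nTissues = nTissues,
                 nGenes = nGenes, regionsPerGene = regionsPerGene,
                 meanLog = meanLog, sdLog = sdLog, dispersion = dispersion,
                 sizeFactorRange = sizeFactorRange, sexEffectSd = sexEffectSd,
                 fractionAffected = fractionAffected,
                 effectSize = effectSize, mechanismMix = mechanismMix,
                 nAffectedTissues = nAffectedTissues,
                 spliceBaselineFraction = spliceBaselineFraction,
                 skippableFraction = skippableFraction,
                 skippableRange = skippableRange,
                 startTermSkipMean = startTermSkipMean, seed = seed)
  list(counts = counts, truth = truth, model = model, config = config)
}

#' Emit the fragment stream underlying a simulated study
#'
#' Writes out, for each emitted count, a fragment whose blocks reproduce it:
#' interior inclusion counts become single-block fragments inside their
#' region, and skipping counts become two-block fragments anchored in the
#' two neighbouring regions with a splice gap fully containing the skipped
#' region. Recounting this stream with \code{\link{countFragments}}
#' reproduces the study's count tables exactly.
#'
#' @param sim result of \code{\link{simulateStudy}}.
#' @return a fragment block data.frame (see \code{\link{fragments}}).
#' @export
simulateFragments <- function(sim) {
  gr <- regions(sim$model)
  I <- S4Vectors::metadata(sim$counts)$interiorCounts
  Rho <- SummarizedExperiment::assay(sim$counts, "skipping")
  samples <- colnames(I)
  w <- width(gr)

  ii <- which(I > 0, arr.ind = TRUE)
  cntI <- I[ii]
  ri <- rep(ii[, 1], cntI)
  si <- rep(ii[, 2], cntI)
  intdf <- data.frame(
    fragment_id = sprintf("fi%07d", seq_along(ri)),
    sample_id = samples[si], chrom = "chrS1",
    start = start(gr)[ri],
    end = start(gr)[ri] + pmin(w[ri], 76L) - 1L,
    strand = "*", unique = TRUE, stringsAsFactors = FALSE)

  is_ <- which(Rho > 0, arr.ind = TRUE)
  skdf <- NULL
  if (nrow(is_)) {
    cntS <- Rho[is_]
    rs <- rep(is_[, 1], cntS)
    ss <- rep(is_[, 2], cntS)
    up <- rs - 1L
    dn <- rs + 1L
    id <- sprintf("fs%07d", seq_along(rs))
    b1 <- data.frame(
      fragment_id = id, sample_id = samples[ss], chrom = "chrS1",
      start = end(gr)[up] - pmin(w[up], 20L) + 1L, end = end(gr)[up],
      strand = "*", unique = TRUE, stringsAsFactors = FALSE)
    b2 <- data.frame(
      fragment_id = id, sample_id = samples[ss], chrom = "chrS1",
      start = start(gr)[dn], end = start(gr)[dn] + pmin(w[dn], 20L) - 1L,
      strand = "*", unique = TRUE, stringsAsFactors = FALSE)
    skdf <- rbind(b1, b2)
    skdf <- skdf[order(skdf$fragment_id, skdf$start), ]
  }
  out <- rbind(intdf, skdf)
  rownames(out) <- NULL
  out
}
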