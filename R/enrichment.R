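#' Per-gene summaries of tissue-dependent usage
#'
#' For each gene: the number and fraction of its exonic regions subject to
#' TDU, the fraction of exonic base pairs affected, the mean number of
#' sequenced fragments across samples, and a high-expression flag (mean
#' fragments >= \code{highExpr}).
#'
#' @param tdu result of \code{\link{testTissueDependence}}.
#' @param model the \code{\link{FlattenedGeneModel}} providing region widths.
#' @param object the \code{\link{ExonUsageExperiment}} (gene fragment totals
#'   are taken from \code{metadata(object)$geneTotals} when present, else
#'   from summed inclusion counts).
#' @param highExpr threshold for the high-expression flag.
#' @return a \code{DataFrame}, one row per gene.
#' @export
summarizeGeneTDU <- function(tdu, model, object, highExpr = 100) {
  gr <- regions(model)
  key <- names(gr)
  stopifnot(all(rownames(tdu) %in% key))
  gr <- gr[match(rownames(tdu), key)]
  gene <- gr$gene_id
  w <- width(gr)
  isTDU <- !is.na(tdu$isTDU) & tdu$isTDU
  gt <- S4Vectors::metadata(object)$geneTotals
  if (is.null(gt)) {
    gt <- rowsum(SummarizedExperiment::assay(object, "inclusion")[
      rownames(tdu), , drop = FALSE], gene)
  }
  byg <- split(seq_along(gene), gene)
  out <- S4Vectors::DataFrame(
    gene_id = names(byg),
    n_regions = unname(lengths(byg)),
    n_tdu_regions = unname(vapply(byg, function(i) sum(isTDU[i]), 0L)),
    total_bp = unname(vapply(byg, function(i) sum(w[i]), 0L)),
    tdu_bp = unname(vapply(byg, function(i) sum(w[i][isTDU[i]]), 0L)))
  out$frac_regions_tdu <- out$n_tdu_regions / out$n_regions
  out$frac_bp_tdu <- out$tdu_bp / out$total_bp
  out$mean_fragments <- unname(rowMeans(gt)[out$gene_id])
  out$high_expression <- out$mean_fragments >= highExpr
  rownames(out) <- out$gene_id
  out
}

#' Matched background by greedy nearest-neighbour covariate matching
#'
#' Selects, for each target unit, the closest pool unit in standardized
#' covariate space (Euclidean distance), 1:1 and without replacement, in
#' target order; ties are broken by unit-id order. Covariates are
#' standardized over targets and pool jointly. Targets present in the pool
#' are removed from it first.
#'
#' @param targets character vector of target unit ids.
#' @param pool character vector of candidate background unit ids.
#' @param covariates numeric data.frame/matrix of matching covariates with
#'   unit ids as rownames (e.g. log mean count and number of regions for
#'   genes; log mean count and width for exons).
#' @return character vector of matched background ids, aligned with
#'   \code{targets}.
#' @export
matchedBackground <- function(targets, pool, covariates) {
  pool <- setdiff(pool, targets)
  if (length(pool) < length(targets))
    stop("matching pool smaller than target set (", length(pool), " < ",
         length(targets), ")")
  covariates <- as.matrix(covariates)
  stopifnot(all(targets %in% rownames(covariates)),
            all(pool %in% rownames(covariates)))
  Z <- scale(covariates[c(targets, pool), , drop = FALSE])
  Z[, !is.finite(colSums(Z))] <- 0  # constant covariate: no contribution
  zt <- Z[targets, , drop = FALSE]
  pool <- sort(pool)
  zp <- Z[pool, , drop = FALSE]
  avail <- rep(TRUE, length(pool))
  matched <- character(length(targets))
  for (k in seq_along(targets)) {
    d2 <- colSums((t(zp) - zt[k, ])^2)
    d2[!avail] <- Inf
    j <- which.min(d2)  # ties: first in unit-id (sorted) order
    matched[k] <- pool[j]
    avail[j] <- FALSE
  }
  matched
}

#' Category enrichment between targets and matched background
#'
#' Builds the categories x \{target, background\} contingency table, tests
#' for differences with Pearson's chi-squared test (no continuity
#' correction by default) and reports per-category odds ratios of target
#' versus background membership.
#'
#' @param targets,background character vectors of unit ids.
#' @param labels named character vector mapping unit ids to category labels
#'   (e.g. the five exon categories).
#' @param correct apply continuity correction in the chi-squared test.
#' @return list with \code{table}, \code{statistic}, \code{pvalue},
#'   \code{oddsRatio} (per category).
#' @export
categoryEnrichment <- function(targets, background, labels,
                               correct = FALSE) {
  miss <- setdiff(c(targets, background), names(labels))
  if (length(miss))
    stop("unlabeled unit(s): ", paste(head(miss), collapse = ", "))
  cats <- sort(unique(labels[c(targets, background)]))
  tab <- cbind(target = table(factor(labels[targets], levels = cats)),
               background = table(factor(labels[background], levels = cats)))
  zero <- rowSums(tab) == 0
  if (any(zero)) {
    warning("dropping empty categor(ies): ",
            paste(rownames(tab)[zero], collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  orv <- vapply(rownames(tab), function(cat) {
    a <- tab[cat, "target"]; b <- sum(tab[, "target"]) - a
    c_ <- tab[cat, "background"]; d <- sum(tab[, "background"]) - c_
    (a / b) / (c_ / d)
  }, numeric(1))
  list(table = tab, statistic = unname(cs$statistic),
       pvalue = cs$p.value, oddsRatio = orv)
}
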