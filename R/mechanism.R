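#' Partial coefficient of determination for the tissue predictor
#'
#' Fits, by ordinary least squares, the two-way additive ANOVA model
#' \eqn{\beta_{ut} = \beta^0 + \beta^{Ind}_u + \beta^{Tis}_t +
#' \epsilon_{ut}} and the reduced model lacking the tissue term, on the
#' individual-by-tissue coefficient matrix of one region; the partial R2 of
#' tissue is \eqn{1 - RSS_{full} / RSS_{reduced}}. Requires a fully crossed
#' layout (every cell present once). When both residual sums of squares
#' vanish (coefficients depending only on individual, or constant), the R2
#' is defined as 0.
#'
#' @param mat numeric matrix, individuals x tissues, no missing entries.
#' @return list with \code{r2}, \code{rssFull}, \code{rssReduced} and the
#'   fitted-model objects' coefficients.
#' @export
partialR2 <- function(mat) {
  if (!is.matrix(mat) || anyNA(mat))
    stop("partialR2 requires a complete individuals x tissues matrix ",
         "(fully crossed design)")
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 individuals and 2 tissues")
  df <- data.frame(value = as.vector(mat),
                   individual = factor(rep(rownames(mat) %||%
                                           seq_len(nrow(mat)), ncol(mat))),
                   tissue = factor(rep(colnames(mat) %||%
                                       seq_len(ncol(mat)),
                                       each = nrow(mat))))
  full <- lm(value ~ individual + tissue, data = df)
  red <- lm(value ~ individual, data = df)
  rssF <- sum(residuals(full)^2)
  rssR <- sum(residuals(red)^2)
  r2 <- if (rssR <= .Machine$double.eps * sum(df$value^2 + 1))
    0 else 1 - rssF / rssR
  r2 <- min(max(r2, 0), 1)
  list(r2 = r2, rssFull = rssF, rssReduced = rssR,
       coefFull = coef(full), coefReduced = coef(red))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Skipping-evidence stratum of a region
#'
#' Classifies a region by the mean of its (by default size-factor
#' normalized) exon-skipping counts across samples: \code{none} (mean = 0),
#' \code{weak} (0 < mean <= 1), \code{moderate} (1 < mean <= 10),
#' \code{strong} (mean > 10; the comparison with 10 is strict).
#'
#' @param skipping counts vector over samples (or regions x samples matrix).
#' @param sizeFactors per-sample size factors; ignored when
#'   \code{normalized = FALSE}.
#' @param normalized divide by size factors before averaging.
#' @return list with \code{stratum} (factor with levels none < weak <
#'   moderate < strong) and \code{mean}; for matrix input both are vectors.
#' @export
skippingEvidenceClass <- function(skipping, sizeFactors = NULL,
                                  normalized = TRUE) {
  if (is.matrix(skipping)) {
    m <- if (normalized) {
      stopifnot(!is.null(sizeFactors))
      rowMeans(sweep(skipping, 2L, sizeFactors, "/"))
    } else rowMeans(skipping)
  } else {
    m <- if (normalized) {
      stopifnot(!is.null(sizeFactors))
      mean(skipping / sizeFactors)
    } else mean(skipping)
  }
  stratum <- cut(m, breaks = c(-Inf, 0, 1, 10, Inf),
                 labels = c("none", "weak", "moderate", "strong"),
                 ordered_result = TRUE)
  list(stratum = stratum, mean = m)
}

#' Pearson correlation between a region's REUCs and RSICs
#'
#' @param reuc,rsic coefficient vectors over the same samples.
#' @param minShared minimum number of shared non-missing entries.
#' @return the Pearson correlation over shared entries, or \code{NA} (with a
#'   \code{"reason"} attribute) when fewer than \code{minShared} entries are
#'   shared or either vector is constant.
#' @export
reucRsicCorrelation <- function(reuc, rsic, minShared = 3L) {
  ok <- is.finite(reuc) & is.finite(rsic)
  if (sum(ok) < minShared) {
    r <- NA_real_; attr(r, "reason") <- "insufficient_overlap"
    return(r)
  }
  if (sd(reuc[ok]) == 0 || sd(rsic[ok]) == 0) {
    r <- NA_real_; attr(r, "reason") <- "constant"
    return(r)
  }
  cor(reuc[ok], rsic[ok])
}

#' Attribute TDU regions to splicing versus transcription boundaries
#'
#' Labels each tissue-dependent region: \code{TDU-AS} (alternative splicing)
#' when the skipping-evidence stratum is \code{strong} AND the REUC-RSIC
#' Pearson correlation is at least \code{rMin} AND the RSIC tissue partial
#' R2 is at least \code{r2Min}; \code{TDU-NAS} (consistent with alternative
#' transcription start/termination) when the stratum is \code{none} or
#' \code{weak}; \code{unresolved} otherwise. Only TDU regions are labeled;
#' all three underlying signals are reported alongside the label.
#'
#' @param tdu result of \code{\link{testTissueDependence}}.
#' @param reucs,rsics \code{\link{UsageCoefficients}} objects (REUC and
#'   RSIC schemes) over the same regions.
#' @param skipping regions x samples skipping-count matrix.
#' @param sizeFactors per-sample size factors for the strata.
#' @param rMin,r2Min thresholds of the TDU-AS rule.
#' @param normalizedSkip use normalized skipping means for the strata.
#' @return a \code{DataFrame} with one row per TDU region: \code{region_id},
#'   \code{meanSkip}, \code{stratum}, \code{r2Reuc}, \code{r2Rsic},
#'   \code{pearsonR}, \code{label}; thresholds kept in metadata.
#' @export
attributeMechanism <- function(tdu, reucs, rsics, skipping, sizeFactors,
                               rMin = 0.5, r2Min = 0.3,
                               normalizedSkip = TRUE) {
  stopifnot(is(reucs, "UsageCoefficients"), scheme(reucs) == "REUC",
            is(rsics, "UsageCoefficients"), scheme(rsics) == "RSIC")
  idx <- which(!is.na(tdu$isTDU) & tdu$isTDU)
  keys <- rownames(tdu)[idx]
  design <- reucs@design
  sk <- skippingEvidenceClass(skipping[keys, , drop = FALSE],
                              sizeFactors, normalized = normalizedSkip)
  r2r <- r2s <- pr <- rep(NA_real_, length(keys))
  for (k in seq_along(keys)) {
    key <- keys[k]
    br <- coefMatrix(reucs)[key, ]
    if (all(is.finite(br)))
      r2r[k] <- partialR2(utMatrix(br, design))$r2
    bs <- coefMatrix(rsics)[key, ]
    if (all(is.finite(bs))) {
      r2s[k] <- partialR2(utMatrix(bs, rsics@design))$r2
      pr[k] <- as.numeric(reucRsicCorrelation(br, bs))
    }
  }
  label <- rep("unresolved", length(keys))
  isAS <- sk$stratum == "strong" & !is.na(pr) & pr >= rMin &
          !is.na(r2s) & r2s >= r2Min
  label[isAS] <- "TDU-AS"
  label[sk$stratum %in% c("none", "weak")] <- "TDU-NAS"
  res <- S4Vectors::DataFrame(
    region_id = tdu$region_id[idx], gene_id = tdu$gene_id[idx],
    meanSkip = sk$mean, stratum = sk$stratum,
    r2Reuc = r2r, r2Rsic = r2s, pearsonR = pr, label = label,
    row.names = keys)
  S4Vectors::metadata(res) <- list(rMin = rMin, r2Min = r2Min,
                                   skipStrong = 10,
                                   normalizedSkip = normalizedSkip)
  res
}
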