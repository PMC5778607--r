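# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (per-base scans, generic numerical optimization) and
# share no code with the implementation paths they check.

# Per-base flattening oracle: label every covered base with the set of
# transcripts covering it; regions are maximal runs of constant non-empty
# label; genes sharing a base (same chrom+strand unless ignoreStrand) are
# pooled. Only suitable for small (<= 10 kb) annotations.
oracleFlatten <- function(ex, ignoreStrand = FALSE) {
  ex$strand <- if (ignoreStrand) "*" else as.character(ex$strand)
  out <- list()
  for (cs in unique(paste(ex$chrom, ex$strand))) {
    sub <- ex[paste(ex$chrom, ex$strand) == cs, , drop = FALSE]
    lo <- min(sub$start); hi <- max(sub$end)
    cover <- vector("list", hi - lo + 1L)
    for (r in seq_len(nrow(sub))) {
      for (b in sub$start[r]:sub$end[r]) {
        i <- b - lo + 1L
        cover[[i]] <- union(cover[[i]],
                            paste(sub$gene_id[r], sub$transcript_id[r]))
      }
    }
    genesAt <- lapply(cover, function(x)
      unique(sub("\\s.*", "", x %||% character(0))))
    # pool genes sharing a base
    pools <- list()
    for (g in unique(sub$gene_id)) pools[[g]] <- g
    for (gs in genesAt) if (length(gs) > 1) {
      merged <- unique(unlist(pools[gs]))
      for (g in merged) pools[[g]] <- merged
      # propagate transitively
      repeat {
        m2 <- unique(unlist(pools[merged]))
        if (setequal(m2, merged)) break
        merged <- m2
        for (g in merged) pools[[g]] <- merged
      }
    }
    groupOf <- vapply(names(pools), function(g)
      paste(sort(pools[[g]]), collapse = "+"), "")
    for (grp in unique(groupOf)) {
      gset <- names(groupOf)[groupOf == grp]
      lab <- vapply(seq_along(cover), function(i) {
        x <- cover[[i]]
        x <- x[sub("\\s.*", "", x) %in% gset]
        if (length(x) == 0) "" else paste(sort(x), collapse = ";")
      }, "")
      runs <- rle(lab)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- runs$values != ""
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        group_id = grp, chrom = sub$chrom[1],
        start = starts[keep] + lo - 1L, end = ends[keep] + lo - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$group_id, out$start), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compare a FlattenedGeneModel against the per-base oracle on the same
# annotation; returns the number of mismatching regions.
flattenMismatches <- function(model, ex, ignoreStrand = FALSE) {
  oracle <- oracleFlatten(ex, ignoreStrand)
  gr <- regions(model)
  got <- data.frame(group_id = gr$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  got <- got[order(got$group_id, got$start), , drop = FALSE]
  rownames(got) <- rownames(oracle) <- NULL
  if (nrow(got) != nrow(oracle)) return(abs(nrow(got) - nrow(oracle)))
  sum(got$group_id != oracle$group_id | got$start != oracle$start |
      got$end != oracle$end)
}

# Random small annotation: a handful of genes with 1-3 transcripts of 1-4
# exons each, on a short chromosome, occasionally overlapping.
randomAnnotation <- function(nGenes = 3) {
  rows <- list()
  pos <- sample(1:500, 1)
  for (g in seq_len(nGenes)) {
    strand <- sample(c("+", "-"), 1)
    gstart <- pos + sample(0:300, 1) - 100  # may overlap previous gene
    ntx <- sample(1:3, 1)
    gend <- gstart
    for (t in seq_len(ntx)) {
      nex <- sample(1:4, 1)
      p <- gstart + sample(0:50, 1)
      for (e in seq_len(nex)) {
        w <- sample(10:120, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "c1", start = p, end = p + w - 1L, strand = strand,
          gene_id = paste0("g", g), transcript_id = paste0("g", g, "t", t),
          stringsAsFactors = FALSE)
        gend <- max(gend, p + w - 1L)
        p <- p + w + sample(5:100, 1)
      }
    }
    pos <- gend + 1L
  }
  do.call(rbind, rows)
}

# Generic-optimizer oracle for the penalized Gamma-Poisson usage GLM: builds
# the coefficient vector (betaS, betaE, betaSex, betaUT) and maximizes the
# ridge-penalized log-likelihood with BFGS and an analytic gradient.
oracleGPGLM <- function(k1, k0, design, s, alpha, pv, pvSex = pv) {
  n <- nrow(design)
  y <- c(k0, k1)
  l <- rep(c(0, 1), each = n)
  X <- cbind(diag(n)[rep(1:n, 2), ], l, l * rep(design$sex, 2),
             diag(n)[rep(1:n, 2), ] * l)
  lam <- c(rep(0, n), 0, 1 / pvSex, rep(1 / pv, n))
  off <- rep(log(s), 2)
  nll <- function(b) {
    mu <- exp(pmin(X %*% b + off, 30))
    ll <- if (alpha < 1e-12) sum(dpois(y, mu, log = TRUE)) else
      sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    -ll + 0.5 * sum(lam * b^2)
  }
  grad <- function(b) {
    mu <- as.vector(exp(pmin(X %*% b + off, 30)))
    sc <- if (alpha < 1e-12) y - mu else
      y - mu * (y + 1 / alpha) / (mu + 1 / alpha)
    -as.vector(t(X) %*% sc) + lam * b
  }
  b0 <- c(log(pmax((k1 + k0) / 2, 0.5)), 0, 0, rep(0, n))
  o <- optim(b0, nll, grad, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  list(betaS = o$par[1:n], betaE = o$par[n + 1], betaSex = o$par[n + 2],
       betaUT = o$par[n + 2 + 1:n], value = -o$value)
}

# Closed-form two-way balanced ANOVA oracle for the tissue partial R2:
# additive fitted values are row mean + column mean - grand mean.
oraclePartialR2 <- function(mat) {
  fitF <- outer(rowMeans(mat), rep(1, ncol(mat))) +
    outer(rep(1, nrow(mat)), colMeans(mat)) - mean(mat)
  rssF <- sum((mat - fitF)^2)
  rssR <- sum(sweep(mat, 1, rowMeans(mat))^2)
  if (rssR < 1e-12) return(list(r2 = 0, rssFull = rssF, rssReduced = rssR))
  list(r2 = 1 - rssF / rssR, rssFull = rssF, rssReduced = rssR)
}

# Small fully crossed design for GLM unit tests.
toyDesign <- function(nInd = 2, nTis = 2) {
  d <- expand.grid(individual = sprintf("I%d", 1:nInd),
                   tissue = sprintf("T%d", 1:nTis),
                   stringsAsFactors = FALSE)
  d$sample_id <- paste(d$individual, d$tissue, sep = ".")
  d$sex <- rep(rep_len(c(-0.5, 0.5), nInd), nTis)
  checkDesign(d[, c("sample_id", "individual", "tissue", "sex")])
}
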