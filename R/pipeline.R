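# TSV writing with '#'-prefixed metadata header lines (version, config
# hash, seed) so that reruns with identical inputs are byte-identical.
.writeTSV <- function(df, path, meta = NULL) {
  df <- as.data.frame(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# TDUseq %s", as.character(packageVersion("TDUseq"))),
             con)
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read precomputed count tables into an ExonUsageExperiment
#'
#' @param inclusion,rest,skipping paths to TSV count tables (first column
#'   \code{region_id} holding \code{gene:region} keys, one column per
#'   sample); \code{rest} and \code{skipping} optional (\code{rest} is
#'   derived per gene when absent).
#' @param design a design table or path to one.
#' @param model optional \code{\link{FlattenedGeneModel}} or flattened GFF
#'   path.
#' @return an \code{\link{ExonUsageExperiment}}.
#' @export
readCountTables <- function(inclusion, design, rest = NULL, skipping = NULL,
                            model = NULL) {
  readMat <- function(p) {
    d <- .readTSV(p)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    storage.mode(m) <- "integer"
    m
  }
  inc <- readMat(inclusion)
  if (is.character(design)) design <- readDesign(design)
  if (is.character(model)) model <- readFlattenedGFF(model)
  restM <- if (!is.null(rest)) readMat(rest) else
    buildReucPairs(inc, model)$k0
  skipM <- if (!is.null(skipping)) readMat(skipping) else NULL
  ExonUsageExperiment(inclusion = inc, design = design, model = model,
                      rest = restM, skipping = skipM)
}

#' Write the count tables of an experiment to TSV
#'
#' @param object an \code{\link{ExonUsageExperiment}}.
#' @param prefix output path prefix; files \code{<prefix>_inclusion.tsv}
#'   etc. are written.
#' @param meta optional metadata header fields.
#' @return invisibly, the written paths.
#' @export
writeCountTables <- function(object, prefix, meta = NULL) {
  paths <- character(0)
  for (a in SummarizedExperiment::assayNames(object)) {
    p <- paste0(prefix, "_", a, ".tsv")
    m <- SummarizedExperiment::assay(object, a)
    .writeTSV(data.frame(region_id = rownames(m), m, check.names = FALSE),
              p, meta)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run the full tissue-dependent usage pipeline
#'
#' Executes count loading (or simulation), REUC and RSIC estimation, the
#' tissue-dependence test, mechanism attribution, gene-level summaries and
#' (when category labels are provided) matched-background enrichment, and
#' writes one TSV per stage into \code{outDir}. Every output carries
#' '#'-prefixed header lines with the package version, a hash of the
#' configuration and the seed, and reruns with identical inputs are
#' byte-identical.
#'
#' @param config a named list or path to a YAML file with entries:
#'   \describe{
#'   \item{counts}{list of paths \code{inclusion}, optional \code{rest},
#'     \code{skipping}, \code{model} (flattened GFF), \code{design}; or}
#'   \item{simulate}{list of \code{\link{simulateStudy}} arguments
#'     (including \code{seed});}
#'   \item{fragments}{alternatively, list with \code{tsv} (fragment TSV) or
#'     \code{sam} + \code{sample_id}, plus \code{annotation} (GTF/GFF) and
#'     \code{design}: the flatten and count stages are run first;}
#'   \item{unitType}{"exonic_region" (default) or "tss_cluster" (rows are
#'     TSS clusters grouped by gene; the skipping/mechanism stages are
#'     skipped);}
#'   \item{thresholds}{optional list: \code{fdr} (0.1), \code{scoreMin}
#'     (1.0), \code{minCount} (10), \code{skipFloor} (1), \code{highExpr}
#'     (100), \code{rMin} (0.5), \code{r2Min} (0.3);}
#'   \item{labels}{optional path to a TSV (unit_id, category) for
#'     enrichment;}
#'   \item{outDir}{output directory.}}
#' @return invisibly, a list with the experiment, coefficient sets, the TDU
#'   table, mechanism and gene summaries, enrichment results and output
#'   paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outDir))
  th <- config$thresholds
  thr <- list(fdr = th$fdr %||% 0.1, scoreMin = th$scoreMin %||% 1.0,
              minCount = th$minCount %||% 10, skipFloor = th$skipFloor %||% 1,
              highExpr = th$highExpr %||% 100, rMin = th$rMin %||% 0.5,
              r2Min = th$r2Min %||% 0.3)
  stopifnot(all(unlist(thr) > 0))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- .configHash(config[setdiff(names(config), "outDir")])
  seed <- config$simulate$seed %||% config$seed %||% NA
  meta <- c(config_hash = cfgHash, seed = as.character(seed))
  outs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  model <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", do.call(simulateStudy, config$simulate))
    eue <- sim$counts
    model <- sim$model
    truth <- sim$truth
  } else if (!is.null(config$fragments)) {
    model <- stage("flatten", flattenGeneModels(config$fragments$annotation))
    frags <- stage("read_fragments",
      if (!is.null(config$fragments$tsv)) readFragmentsTSV(config$fragments$tsv)
      else readFragmentsSAM(config$fragments$sam,
                            config$fragments$sample_id))
    design <- readDesign(config$fragments$design)
    eue <- stage("count", countExperiment(frags, model, design))
  } else if (!is.null(config$counts)) {
    eue <- stage("load_counts", do.call(readCountTables, config$counts))
    if (is.character(config$counts$model))
      model <- readFlattenedGFF(config$counts$model)
  } else stop("config must provide 'counts', 'fragments' or 'simulate'")

  sf <- estimateSizeFactors(eue)
  tssMode <- identical(config$unitType, "tss_cluster")
  hasSkip <- !tssMode &&
    "skipping" %in% SummarizedExperiment::assayNames(eue)

  reucs <- stage("estimate_reuc",
                 estimateREUCs(eue, minCount = thr$minCount,
                               sizeFactors = sf))
  rsics <- if (hasSkip)
    stage("estimate_rsic",
          estimateRSICs(eue, minCount = thr$minCount,
                        skipFloor = thr$skipFloor, sizeFactors = sf))
  else NULL

  tdu <- stage("test", testTissueDependence(eue, reucs, fdr = thr$fdr,
                                            scoreMin = thr$scoreMin,
                                            sizeFactors = sf))
  mech <- if (hasSkip)
    stage("attribute",
          attributeMechanism(tdu, reucs, rsics,
                             SummarizedExperiment::assay(eue, "skipping"),
                             sf, rMin = thr$rMin, r2Min = thr$r2Min))
  else NULL

  genes <- if (!is.null(model))
    stage("summarize", summarizeGeneTDU(tdu, model, eue,
                                        highExpr = thr$highExpr))
  else NULL

  enr <- NULL
  if (!is.null(config$labels) && !is.null(genes)) {
    lab <- .readTSV(config$labels)
    labels <- setNames(as.character(lab[[2]]), lab[[1]])
    tduGenes <- genes$gene_id[genes$n_tdu_regions > 0]
    pool <- setdiff(genes$gene_id, tduGenes)
    covs <- data.frame(logMean = log1p(genes$mean_fragments),
                       nRegions = genes$n_regions,
                       row.names = genes$gene_id)
    enr <- stage("enrich", {
      bg <- matchedBackground(tduGenes, pool, covs)
      categoryEnrichment(tduGenes, bg, labels)
    })
  }

  op <- function(f) file.path(config$outDir, f)
  writeCountTables(eue, op("counts"), meta)
  .writeTSV(designTable(eue), op("design.tsv"), meta)
  writeUsageTSV(reucs, op("reucs.tsv"), meta)
  if (!is.null(rsics)) writeUsageTSV(rsics, op("rsics.tsv"), meta)
  .writeTSV(cbind(region = rownames(tdu), as.data.frame(tdu)),
            op("tdu.tsv"), meta)
  if (!is.null(mech))
    .writeTSV(cbind(region = rownames(mech), as.data.frame(mech)),
              op("mechanism.tsv"), meta)
  if (!is.null(genes))
    .writeTSV(as.data.frame(genes), op("gene_summary.tsv"), meta)
  if (!is.null(enr))
    .writeTSV(data.frame(category = rownames(enr$table), enr$table,
                         odds_ratio = enr$oddsRatio,
                         chi2 = enr$statistic, pvalue = enr$pvalue),
              op("enrichment.tsv"), meta)

  invisible(list(experiment = eue, model = model, truth = truth,
                 sizeFactors = sf, reucs = reucs, rsics = rsics, tdu = tdu,
                 mechanism = mech, genes = genes, enrichment = enr,
                 outDir = config$outDir, configHash = cfgHash))
}

# Deterministic hash of the configuration (md5 of its canonical deparse).
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
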