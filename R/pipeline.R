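## End-to-end orchestration of the synthetic workflow:
## simulate -> qc -> normalize -> bulk_de -> hvg -> correct -> diffusion
## -> markers.  One global seed fans out to fixed per-stage substreams;
## intermediates can be written as plain TSV with md5 digests recorded in
## the run manifest.

#' Default pipeline configuration
#'
#' Nested list mirroring every tunable of the workflow.  The `sc` and
#' `bulk` blocks configure the synthetic generators (see [scSimConfig()]
#' and [simulateBulk()]); `qc` scales the gene-detection threshold to the
#' simulated transcriptome size while keeping the published read-count and
#' mitochondrial criteria.
#'
#' @param seed global integer seed.
#' @return a config list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sc = list(nCells = 516L, nGenes = 2000L, nMarkerGenes = 5L,
              nMonotoneGenes = 200L, nBatches = 2L, cellFactorSd = 0.4,
              batchLocationSd = 0.3,
              batchScaleSd = 0.1, nbDispersion = 0.3,
              mitoFractionGenes = 0.05, nLowqCells = 47L,
              labelOverlap = 0.3, markerLog2Amp = 3, markerWidth = 0.15,
              meanLibSize = 2e5, libSizeSd = 0.25,
              lowqExpressedGenes = 600L),
    bulk = list(nReplicates = 3L, dispersion = 0.1,
                plantedMarkerLog2FC = 2, nSignatureGenes = 150L,
                signatureLog2FC = 1.5),
    qc = list(minTotalReads = 50000L, minGenesDetected = 1000L,
              maxMitoPercent = 15),
    hvg = list(minMean = 0.1, form = "loglog"),
    diffusion = list(nComponents = 10L, knn = 30L, kernel = "local_knn",
                     anchorLabel = "P1"),
    scDe = list(alpha = 0.1, fcCut = 0.8),
    bulkDe = list(alpha = 0.1, fcCut = 0, dispShrink = 0.9)
  ), class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' @param config a nested list; unknown keys raise an error naming them.
#' @return the merged config (defaults overridden by `config`).
#' @export
validatePipelineConfig <- function(config) {
  defaults <- defaultPipelineConfig()
  bad <- character()
  checkKeys <- function(given, known, prefix) {
    unknown <- setdiff(names(given), names(known))
    if (length(unknown))
      bad <<- c(bad, paste0(prefix, unknown))
    for (k in intersect(names(given), names(known)))
      if (is.list(known[[k]]) && is.list(given[[k]]))
        checkKeys(given[[k]], known[[k]], paste0(prefix, k, "."))
  }
  checkKeys(config, defaults, "")
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  merged <- defaults
  for (k in names(config)) {
    merged[[k]] <- if (is.list(defaults[[k]]) && is.list(config[[k]]))
      modifyList(defaults[[k]], config[[k]]) else config[[k]]
  }
  structure(merged, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [defaultPipelineConfig()].
#' @return validated config.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

.stageOut <- function(outdir, manifest, stage, objects, secs) {
  files <- character()
  if (!is.null(outdir)) {
    for (nm in names(objects)) {
      path <- file.path(outdir, paste0(stage, "_", nm, ".tsv"))
      obj <- objects[[nm]]
      if (is(obj, "ExpressionMatrix")) {
        writeExpressionMatrix(obj, path)
      } else if (is.data.frame(obj) || is(obj, "DataFrame")) {
        write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      } else {
        writeLines(as.character(obj), path)
      }
      files <- c(files, path)
    }
  }
  digests <- if (length(files)) unname(md5sum(files)) else character()
  rbind(manifest, data.frame(
    stage = stage, seconds = round(secs, 3),
    outputs = paste(basename(files), collapse = ";"),
    md5 = paste(digests, collapse = ";"), stringsAsFactors = FALSE))
}

#' Run the full synthetic marker-discovery workflow
#'
#' Executes the eight pipeline stages in fixed order on data from the
#' seeded generators and returns every intermediate plus a run manifest
#' (stage timings and, when `outdir` is given, md5 digests of the written
#' TSV intermediates).  Re-running with the same config and seed
#' reproduces identical outputs.
#'
#' @param config a `PipelineConfig` (or a nested list validated against
#'   the defaults).
#' @param seed overrides `config$seed` when given.
#' @param outdir optional directory for TSV intermediates.
#' @return list of class `hscmarkRun`: simulated inputs and truth, QC
#'   report, normalised matrices, bulk DE lists, noise fit and informed
#'   gene set, corrected matrix, diffusion state, single-cell DE results,
#'   common DE set, ranked marker table, and `manifest`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), seed = NULL,
                        outdir = NULL) {
  config <- validatePipelineConfig(unclass(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- config$seed
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  manifest <- data.frame(stage = character(), seconds = numeric(),
                         outputs = character(), md5 = character(),
                         stringsAsFactors = FALSE)
  run <- list(config = config, seed = seed)

  ## 1. simulate (sc substream: seed, bulk substream: seed + 1)
  secs <- system.time({
    scCfg <- do.call(scSimConfig, c(config$sc, list(seed = seed)))
    sim <- simulateSingleCell(scCfg)
    markers <- sim$truth$markerGeneIds
    set.seed(seed + 2L)
    nonStruct <- setdiff(rownames(sim$matrix),
                         c(markers, sim$truth$monotoneGeneIds))
    signature <- sample(nonStruct, config$bulk$nSignatureGenes)
    stemEff <- c(setNames(rep(config$bulk$plantedMarkerLog2FC,
                              length(markers)), markers),
                 setNames(sample(c(-1, 1), length(signature), TRUE) *
                            config$bulk$signatureLog2FC, signature))
    bulk <- simulateBulk(nReplicates = config$bulk$nReplicates,
                         plantedEffects = list(P1 = stemEff, P2 = stemEff),
                         seed = seed + 1L,
                         geneIds = rownames(sim$matrix),
                         dispersion = config$bulk$dispersion)
  })[["elapsed"]]
  run$sc <- sim$matrix; run$truth <- sim$truth; run$bulk <- bulk
  manifest <- .stageOut(outdir, manifest, "simulate",
                        list(sc_counts = sim$matrix, bulk_counts = bulk),
                        secs)

  ## 2. qc
  secs <- system.time({
    thr <- qcThresholds(minTotalReads = config$qc$minTotalReads,
                        minGenesDetected = config$qc$minGenesDetected,
                        maxMitoPercent = config$qc$maxMitoPercent)
    qc <- applyQC(run$sc, thr)
  })[["elapsed"]]
  run$qcReport <- qc$report
  manifest <- .stageOut(outdir, manifest, "qc",
                        list(report = qc$report), secs)

  ## 3. normalize
  secs <- system.time({
    logtpm <- logTransform(countsToTPM(qc$matrix))
  })[["elapsed"]]
  run$logTPM <- logtpm
  manifest <- .stageOut(outdir, manifest, "normalize",
                        list(log_tpm = logtpm), secs)

  ## 4. bulk_de (lists A, B, C)
  secs <- system.time({
    pops <- populationLabels(run$bulk)
    bulkCfg <- do.call(bulkDEConfig, config$bulkDe)
    p34 <- names(pops)[pops %in% c("P3", "P4")]
    deA <- nbWaldDE(run$bulk, names(pops)[pops == "P1"], p34, bulkCfg,
                    groupNames = c("P1", "P3+P4"))
    deB <- nbWaldDE(run$bulk, names(pops)[pops == "P2"], p34, bulkCfg,
                    groupNames = c("P2", "P3+P4"))
    lists <- candidateLists(deA, deB)
  })[["elapsed"]]
  run$bulkDE <- list(deA = deA, deB = deB)
  run$lists <- lists
  manifest <- .stageOut(outdir, manifest, "bulk_de",
                        list(listC = lists$listC), secs)

  ## 5. hvg + informed gene set
  secs <- system.time({
    fit <- fitNoiseModel(logtpm, minMean = config$hvg$minMean,
                         form = config$hvg$form)
    informed <- informedGeneSet(fit, lists$listC)
  })[["elapsed"]]
  run$noiseFit <- fit; run$informedGenes <- informed
  manifest <- .stageOut(outdir, manifest, "hvg",
                        list(informed_genes = informed), secs)

  ## 6. correct: surrogate regression, then batch adjustment
  secs <- system.time({
    sub <- logtpm[informed, ]
    sv <- estimateSurrogate(sub)
    adj <- regressOut(sub, sv)
    adj <- combatAdjust(adj)
  })[["elapsed"]]
  run$surrogate <- sv; run$corrected <- adj
  manifest <- .stageOut(outdir, manifest, "correct",
                        list(corrected = adj), secs)

  ## 7. diffusion state + terciles
  secs <- system.time({
    state <- computeDiffusionState(
      adj, anchorLabel = config$diffusion$anchorLabel,
      nComponents = config$diffusion$nComponents,
      kernel = config$diffusion$kernel, knn = config$diffusion$knn)
  })[["elapsed"]]
  run$state <- state
  manifest <- .stageOut(outdir, manifest, "diffusion",
                        list(terciles = data.frame(
                          cell = names(tercileAssignment(state)),
                          tau = state@diffusionTime,
                          tercile = as.character(tercileAssignment(state)))),
                        secs)

  ## 8. markers: tercile contrasts, common set, dual-evidence ranking
  secs <- system.time({
    terc <- tercileAssignment(state)
    sp <- split(names(terc), terc)
    de1 <- wilcoxonDE(adj, sp$SP1, sp$SP2, alpha = config$scDe$alpha,
                      fcCut = config$scDe$fcCut,
                      groupNames = c("SP1", "SP2"))
    de2 <- wilcoxonDE(adj, sp$SP3, sp$SP2, alpha = config$scDe$alpha,
                      fcCut = config$scDe$fcCut,
                      groupNames = c("SP3", "SP2"))
    common <- commonDE(de1, de2)
    markerTab <- rankMarkers(common, lists$listC, list(de1, de2),
                             list(deA, deB))
  })[["elapsed"]]
  run$scDE <- list(de1 = de1, de2 = de2)
  run$commonDE <- common
  run$markerTable <- markerTab
  manifest <- .stageOut(outdir, manifest, "markers",
                        list(marker_table = markerTab), secs)

  run$manifest <- manifest
  structure(run, class = "hscmarkRun")
}

#' @export
print.hscmarkRun <- function(x, ...) {
  cat("hscmark pipeline run (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  cells: %d simulated, %d passed QC\n",
              S4Vectors::metadata(x$qcReport)$nInput,
              S4Vectors::metadata(x$qcReport)$nPassed))
  cat(sprintf("  informed genes: %d; common single-cell DE genes: %d\n",
              length(x$informedGenes), length(x$commonDE)))
  cat(sprintf("  tercile sizes: %s\n",
              paste(tercileSizes(x$state), collapse = "/")))
  cat(sprintf("  candidate markers ranked: %d (top: %s)\n",
              nrow(x$markerTable),
              paste(head(x$markerTable$gene, 5), collapse = ", ")))
  invisible(x)
}
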