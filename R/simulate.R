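## Seeded generators of single-cell, bulk and dose-response inputs carrying
## the statistical structure the analysis assumes: a latent 1-D continuum
## with a shared central state, centre-peaked marker genes, monotone
## transition genes, negative-binomial noise whose CV^2 decays roughly
## log-linearly with the mean, batch location/scale effects, planted
## low-quality cells, and single-hit Poisson engraftment.

#' Configuration for the single-cell simulator
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: 516 sorted cells of which 47 are planted low-quality (so 469
#' survive QC), a 2000-gene transcriptome with 5 centre-peaked marker genes
#' and 200 monotone transition genes, two batches, and negative-binomial
#' counts.
#'
#' @param nCells total cells, including planted low-quality ones.
#' @param nGenes transcriptome size.
#' @param nMarkerGenes genes whose mean peaks at the centre of the latent
#'   continuum (log2 amplitude `markerLog2Amp`, Gaussian bump of width
#'   `markerWidth` in latent-time units).
#' @param nMonotoneGenes genes with a sigmoidal monotone mean profile along
#'   the continuum (random sign, log2 amplitude in \[1, 3\]).
#' @param nBatches number of batches (round-robin assignment).
#' @param cellFactorSd SD of a per-cell global technical factor (log2
#'   scale) loading on every gene — the amplification/efficiency-style
#'   confounder that one-component surrogate-variable correction is meant
#'   to remove.
#' @param batchLocationSd SD of the per-gene-per-batch location shift on the
#'   log2-mean scale.
#' @param batchScaleSd SD (log scale) of the per-gene-per-batch dispersion
#'   scale factor.
#' @param nbDispersion baseline negative-binomial dispersion (1/size).
#' @param mitoFractionGenes fraction of genes flagged mitochondrial.
#' @param nLowqCells planted low-quality cells: library below 50,000 reads,
#'   fewer than `lowqExpressedGenes` expressed genes, mitochondrial
#'   fraction above 15%.
#' @param labelOverlap in \[0, 1\]: how far the P1 and P2 latent-time
#'   sampling windows overlap around the centre (0 = disjoint halves,
#'   1 = identical full-range windows).
#' @param markerLog2Amp,markerWidth marker bump peak amplitude (log2) and
#'   width in latent-time units.  Markers are drawn from the upper half of
#'   baseline abundance.
#' @param meanLibSize expected library size of a good cell (reads).
#' @param libSizeSd log-scale SD of good-cell library sizes.
#' @param lowqExpressedGenes number of genes a low-quality cell expresses.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return a validated config list of class `SCSimConfig`.
#' @export
scSimConfig <- function(nCells = 516L, nGenes = 2000L, nMarkerGenes = 5L,
                        nMonotoneGenes = 200L, nBatches = 2L,
                        cellFactorSd = 0.4,
                        batchLocationSd = 0.3, batchScaleSd = 0.1,
                        nbDispersion = 0.3, mitoFractionGenes = 0.05,
                        nLowqCells = 47L, labelOverlap = 0.3,
                        markerLog2Amp = 3, markerWidth = 0.15,
                        meanLibSize = 2e5, libSizeSd = 0.25,
                        lowqExpressedGenes = 600L, seed = 1L) {
  cfg <- list(nCells = as.integer(nCells), nGenes = as.integer(nGenes),
              nMarkerGenes = as.integer(nMarkerGenes),
              nMonotoneGenes = as.integer(nMonotoneGenes),
              nBatches = as.integer(nBatches),
              cellFactorSd = cellFactorSd,
              batchLocationSd = batchLocationSd, batchScaleSd = batchScaleSd,
              nbDispersion = nbDispersion,
              mitoFractionGenes = mitoFractionGenes,
              nLowqCells = as.integer(nLowqCells),
              labelOverlap = labelOverlap,
              markerLog2Amp = markerLog2Amp, markerWidth = markerWidth,
              meanLibSize = meanLibSize, libSizeSd = libSizeSd,
              lowqExpressedGenes = as.integer(lowqExpressedGenes),
              seed = as.integer(seed))
  if (cfg$nMarkerGenes + cfg$nMonotoneGenes > cfg$nGenes)
    stop("nMarkerGenes + nMonotoneGenes must not exceed nGenes")
  if (cfg$nLowqCells >= cfg$nCells)
    stop("nLowqCells must be smaller than nCells")
  if (cfg$labelOverlap < 0 || cfg$labelOverlap > 1)
    stop("labelOverlap must lie in [0, 1]")
  if (cfg$mitoFractionGenes <= 0 || cfg$mitoFractionGenes >= 1)
    stop("mitoFractionGenes must lie in (0, 1)")
  if (cfg$nbDispersion < 0) stop("nbDispersion must be non-negative")
  structure(cfg, class = "SCSimConfig")
}

.rnbinomMu <- function(n, mu, dispersion) {
  if (dispersion <= 1e-10) rpois(n, mu) else rnbinom(n, mu = mu,
                                                     size = 1 / dispersion)
}

#' Simulate a single-cell count matrix along a latent continuum
#'
#' Two labelled populations (P1, P2) are sampled from opposite (possibly
#' overlapping) windows of a latent time axis in \[0, 1\].  Marker genes have
#' a Gaussian-bump mean profile peaked at latent time 0.5 (the shared
#' central state); monotone genes follow a sigmoid; all counts are
#' negative-binomial with batch location/scale effects.  Planted
#' low-quality cells have small libraries, few expressed genes and a high
#' mitochondrial fraction.
#'
#' @param config an [scSimConfig()].
#' @return a list with elements `matrix` (an [ExpressionMatrix-class] of
#'   counts with population/batch column annotation and `isMito` /
#'   `effectiveLength` row annotation) and `truth` (latent times, marker /
#'   monotone gene ids, batch assignment, low-quality cell ids).
#' @export
simulateSingleCell <- function(config) {
  stopifnot(inherits(config, "SCSimConfig"))
  set.seed(config$seed)
  nc <- config$nCells; ng <- config$nGenes
  nMito <- max(1L, round(config$mitoFractionGenes * ng))
  geneIds <- c(sprintf("G%04d", seq_len(ng - nMito)),
               sprintf("MTG%03d", seq_len(nMito)))
  isMito <- c(rep(FALSE, ng - nMito), rep(TRUE, nMito))
  cellIds <- sprintf("cell%04d", seq_len(nc))

  ## labels and latent time
  label <- rep(c("P1", "P2"), length.out = nc)[sample.int(nc)]
  ov <- config$labelOverlap / 2
  t <- ifelse(label == "P1", runif(nc, 0, 0.5 + ov), runif(nc, 0.5 - ov, 1))

  ## baseline relative abundances; mito block pinned to ~6% of a library
  abund <- rlnorm(ng, meanlog = 0, sdlog = 1.5)
  mitoShare <- 0.06
  abund[isMito] <- abund[isMito] / sum(abund[isMito]) * mitoShare
  abund[!isMito] <- abund[!isMito] / sum(abund[!isMito]) * (1 - mitoShare)

  ## structural genes drawn among non-mito genes; markers come from the
  ## upper half of baseline abundance (a usable sorting marker must be
  ## robustly expressed, and log-scale fold changes of weakly expressed
  ## genes are flattened by the pseudocount)
  nonMito <- which(!isMito)
  wellExpr <- nonMito[abund[nonMito] > median(abund[nonMito])]
  markerIdx <- sample(wellExpr, config$nMarkerGenes)
  monotoneIdx <- sample(setdiff(nonMito, markerIdx),
                        config$nMonotoneGenes)
  monoAmp <- sample(c(-1, 1), length(monotoneIdx), replace = TRUE) *
    runif(length(monotoneIdx), 1, 3)

  ## per-gene log2 fold profile as a function of latent time (genes x cells)
  bump <- exp(-(t - 0.5)^2 / (2 * config$markerWidth^2))
  sig <- plogis((t - 0.5) / 0.08) - 0.5
  logFold <- matrix(0, ng, nc)
  if (length(markerIdx))
    logFold[markerIdx, ] <- config$markerLog2Amp *
      matrix(bump, length(markerIdx), nc, byrow = TRUE)
  if (length(monotoneIdx))
    logFold[monotoneIdx, ] <- outer(monoAmp, sig)

  ## per-cell technical factor (orthogonal to labels by construction) with
  ## gene-specific loadings centred at zero: any common component would be
  ## cancelled by library-size normalisation, so what confounds the
  ## normalised data is the gene-specific part (capture/amplification
  ## efficiency interacting with gene properties)
  cellFactor <- rnorm(nc, 0, config$cellFactorSd)
  factorLoad <- rnorm(ng, 0, 1)
  logFold <- logFold + outer(factorLoad, cellFactor)

  ## batches: round-robin, per-gene location (log2 mean) and scale
  ## (dispersion factor) effects
  batch <- paste0("B", rep(seq_len(config$nBatches), length.out = nc))
  batchLoc <- matrix(rnorm(ng * config$nBatches, 0, config$batchLocationSd),
                     ng, config$nBatches)
  batchScale <- matrix(exp(rnorm(ng * config$nBatches, 0,
                                 config$batchScaleSd)),
                       ng, config$nBatches)
  bIdx <- as.integer(factor(batch, levels = paste0("B",
                                                   seq_len(config$nBatches))))

  ## library sizes and low-quality defects
  lowq <- sample.int(nc, config$nLowqCells)
  lib <- rlnorm(nc, log(config$meanLibSize), config$libSizeSd)
  lib[lowq] <- runif(length(lowq), 5000, 30000)
  dropMask <- matrix(FALSE, ng, nc)
  for (j in lowq) {
    keep <- sample(nonMito, min(config$lowqExpressedGenes, length(nonMito)))
    dropMask[setdiff(nonMito, keep), j] <- TRUE
  }

  ## expected counts, then NB draws column by column
  disp <- config$nbDispersion * exp(rnorm(ng, 0, 0.3))
  counts <- matrix(0L, ng, nc, dimnames = list(geneIds, cellIds))
  for (j in seq_len(nc)) {
    a <- abund * 2^(logFold[, j] + batchLoc[, bIdx[j]])
    if (j %in% lowq) {
      a[dropMask[, j]] <- 0
      ## boost mito share of a failing cell to ~25%
      a[isMito] <- a[isMito] / sum(a[isMito]) * 0.25 * sum(a[!isMito]) / 0.75
    }
    mu <- lib[j] * a / sum(a)
    dj <- disp * batchScale[, bIdx[j]]
    counts[, j] <- if (config$nbDispersion <= 1e-10)
      as.integer(rpois(ng, mu))
    else
      as.integer(rnbinom(ng, mu = mu, size = 1 / dj))
  }

  em <- ExpressionMatrix(counts, "counts", populationLabel = label,
                         batch = batch, isMito = isMito,
                         effectiveLength = rep(1000, ng))
  truth <- structure(list(
    latentTime = setNames(t, cellIds),
    markerGeneIds = geneIds[markerIdx],
    monotoneGeneIds = geneIds[monotoneIdx],
    batchAssignment = setNames(batch, cellIds),
    cellFactor = setNames(cellFactor, cellIds),
    lowqCellIds = cellIds[sort(lowq)]
  ), class = "SCSimTruth")
  list(matrix = em, truth = truth)
}

#' Simulate a four-population bulk RNA-seq count matrix
#'
#' Populations P1..P4 with `nReplicates` columns each; negative-binomial
#' counts around shared baseline means, with planted per-population log2
#' effects applied multiplicatively.
#'
#' @param nReplicates replicates per population (>= 2).
#' @param plantedEffects named list mapping population (`"P1"`..`"P4"`) to a
#'   named numeric vector of log2 effects per gene id, e.g.
#'   `list(P1 = c(G0001 = 2), P2 = c(G0001 = 2))`.
#' @param seed integer seed.
#' @param geneIds gene identifiers; defaults to `G0001..G2000` plus the ids
#'   in `plantedEffects`.
#' @param baseMeans optional named baseline means; defaults to log-normal
#'   draws around 100.
#' @param dispersion NB dispersion of bulk replicates.
#' @return an [ExpressionMatrix-class] of counts with `populationLabel`
#'   column annotation.
#' @export
simulateBulk <- function(nReplicates = 3L, plantedEffects = list(),
                         seed = 1L, geneIds = NULL, baseMeans = NULL,
                         dispersion = 0.1) {
  if (nReplicates < 2L) stop("nReplicates must be >= 2")
  set.seed(as.integer(seed))
  if (is.null(geneIds)) {
    geneIds <- sprintf("G%04d", seq_len(2000L))
    extra <- setdiff(unlist(lapply(plantedEffects, names)), geneIds)
    geneIds <- c(geneIds, extra)
  }
  ng <- length(geneIds)
  if (is.null(baseMeans)) {
    baseMeans <- setNames(rlnorm(ng, log(100), 1.2), geneIds)
  } else {
    baseMeans <- baseMeans[geneIds]
  }
  pops <- c("P1", "P2", "P3", "P4")
  label <- rep(pops, each = nReplicates)
  sampleIds <- paste0(label, "_r", rep(seq_len(nReplicates), times = 4))
  counts <- matrix(0L, ng, length(sampleIds),
                   dimnames = list(geneIds, sampleIds))
  for (p in seq_along(pops)) {
    mu <- baseMeans
    eff <- plantedEffects[[pops[p]]]
    if (!is.null(eff)) {
      hit <- intersect(names(eff), geneIds)
      mu[hit] <- mu[hit] * 2^eff[hit]
    }
    for (r in seq_len(nReplicates)) {
      j <- (p - 1L) * nReplicates + r
      counts[, j] <- as.integer(.rnbinomMu(ng, mu, dispersion))
    }
  }
  ExpressionMatrix(counts, "counts", populationLabel = label,
                   effectiveLength = rep(1000, ng))
}

#' Simulate a limiting-dilution dose-response table
#'
#' Each animal engrafts independently with probability
#' `1 - exp(-f * dose)` (single-hit Poisson).
#'
#' @param trueFrequency per-cell frequency f in (0, 1); `0` is allowed and
#'   yields all-negative tables.
#' @param doses vector of positive cell doses.
#' @param nPerDose animals per dose.
#' @param seed integer seed.
#' @return a validated dose-response table (`dose`, `n_tested`,
#'   `n_engrafted`).
#' @export
simulateDoseResponse <- function(trueFrequency, doses, nPerDose, seed = 1L) {
  if (trueFrequency < 0 || trueFrequency > 1)
    stop("trueFrequency must lie in [0, 1]")
  if (any(doses <= 0)) stop("doses must be positive")
  set.seed(as.integer(seed))
  p <- 1 - exp(-trueFrequency * doses)
  validateDoseTable(data.frame(
    dose = doses,
    n_tested = as.integer(nPerDose),
    n_engrafted = rbinom(length(doses), nPerDose, p)
  ))
}
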