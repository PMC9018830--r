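## Cell-level quality control and counts -> TPM -> log2 transforms.
## The three QC criteria are strict inequalities exactly as published for
## plate-based full-length scRNA-seq: total reads > 50,000, genes detected
## (>= 1 mapped read) > 2,000, mitochondrial reads < 15%.

#' Quality-control thresholds
#'
#' @param minTotalReads cells must exceed this many total reads (strict).
#' @param minGenesDetected cells must detect (at `detectionMinReads` reads
#'   or more) more than this many genes (strict).
#' @param maxMitoPercent mitochondrial read percentage must be below this
#'   (strict).
#' @param detectionMinReads reads needed to call a gene detected.
#' @return a validated threshold list of class `QCThresholds`.
#' @export
qcThresholds <- function(minTotalReads = 50000L, minGenesDetected = 2000L,
                         maxMitoPercent = 15, detectionMinReads = 1L) {
  if (minTotalReads <= 0 || minGenesDetected <= 0 || detectionMinReads <= 0)
    stop("thresholds must be positive")
  if (maxMitoPercent <= 0 || maxMitoPercent >= 100)
    stop("maxMitoPercent must lie in (0, 100)")
  structure(list(minTotalReads = as.integer(minTotalReads),
                 minGenesDetected = as.integer(minGenesDetected),
                 maxMitoPercent = maxMitoPercent,
                 detectionMinReads = as.integer(detectionMinReads)),
            class = "QCThresholds")
}

#' Filter low-quality cells from a count matrix
#'
#' A cell passes only if all three criteria hold: total reads above
#' `minTotalReads`, detected genes above `minGenesDetected`, and
#' mitochondrial percentage below `maxMitoPercent` (all strict).  The gene
#' set is unchanged; the report lists every cell with its metrics and, for
#' removed cells, which criteria failed.
#'
#' @param x an [ExpressionMatrix-class] of counts with `isMito` row
#'   annotation.
#' @param thresholds a [qcThresholds()] object.
#' @return list with `matrix` (passing cells only) and `report` (a
#'   `DataFrame` with per-cell `totalReads`, `nGenesDetected`,
#'   `mitoPercent`, `pass`, `failReads`, `failGenes`, `failMito`; metadata
#'   fields `nInput`, `nPassed`).
#' @export
applyQC <- function(x, thresholds = qcThresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  if (!identical(valueKind(x), "counts"))
    stop("applyQC needs a counts matrix")
  mito <- mitoGenes(x)
  if (is.null(mito))
    stop("no mitochondrial annotation: set the isMito gene flag ",
         "(ExpressionMatrix(..., isMito = ...)) before applyQC")
  v <- assay(x)
  totalReads <- colSums(v)
  nGenes <- colSums(v >= thresholds$detectionMinReads)
  mitoPct <- ifelse(totalReads > 0,
                    100 * colSums(v[mito, , drop = FALSE]) / totalReads, 100)
  failReads <- !(totalReads > thresholds$minTotalReads)
  failGenes <- !(nGenes > thresholds$minGenesDetected)
  failMito <- !(mitoPct < thresholds$maxMitoPercent)
  pass <- !(failReads | failGenes | failMito)
  report <- DataFrame(totalReads = totalReads, nGenesDetected = nGenes,
                      mitoPercent = mitoPct, pass = pass,
                      failReads = failReads, failGenes = failGenes,
                      failMito = failMito, row.names = colnames(v))
  metadata(report) <- list(nInput = ncol(v), nPassed = sum(pass),
                           thresholds = thresholds)
  list(matrix = x[, pass], report = report)
}

#' Convert counts to transcripts per million
#'
#' `TPM[g, s] = (count/length)[g, s] / sum_g (count/length)[g, s] * 1e6`,
#' using the per-gene effective transcript length; every column sums to
#' 1e6.
#'
#' @param x an [ExpressionMatrix-class] of counts with `effectiveLength`
#'   row annotation.
#' @return an [ExpressionMatrix-class] of TPM values.
#' @export
countsToTPM <- function(x) {
  if (!identical(valueKind(x), "counts"))
    stop("countsToTPM needs a counts matrix")
  len <- effectiveLengths(x)
  if (is.null(len) || anyNA(len))
    stop("effectiveLength must be set for every gene")
  v <- assay(x) / len
  cs <- colSums(v)
  if (any(cs == 0))
    stop("zero-count column(s): ",
         paste(colnames(x)[cs == 0], collapse = ", "),
         " (TPM undefined)")
  tpm <- sweep(v, 2, cs, "/") * 1e6
  .replaceValues(x, tpm, "tpm")
}

#' Log-transform a TPM matrix
#'
#' Elementwise `log2(x + pseudocount)`.  Base 2 so that downstream
#' fold-change thresholds are on the log2 scale.
#'
#' @param x an [ExpressionMatrix-class] of TPM values.
#' @param pseudocount added before taking logs (default 1).
#' @return an [ExpressionMatrix-class] of `log_tpm` values.
#' @export
logTransform <- function(x, pseudocount = 1) {
  if (!identical(valueKind(x), "tpm"))
    stop("logTransform needs a tpm matrix")
  .replaceValues(x, log2(assay(x) + pseudocount), "log_tpm")
}
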