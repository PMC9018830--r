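## Central S4 classes.  ExpressionMatrix rides on SummarizedExperiment so that
## the usual Bioconductor accessors (assay, rowData, colData, dim, [ ) work;
## the extra slot records what the numbers are (counts / tpm / log_tpm),
## which downstream operations check before doing anything.

.VALUE_KINDS <- c("counts", "tpm", "log_tpm")

#' ExpressionMatrix: a typed genes-by-samples expression container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `valueKind`
#' slot declaring whether the single assay holds raw counts, transcripts per
#' million, or log2(TPM + pseudocount) values.  Per-sample annotation
#' (`populationLabel`, `batch`) lives in `colData`; per-gene annotation
#' (`isMito`, `effectiveLength`) in `rowData`.
#'
#' @slot valueKind character(1), one of `"counts"`, `"tpm"`, `"log_tpm"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(valueKind = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@valueKind) != 1L || !object@valueKind %in% .VALUE_KINDS)
    msg <- c(msg, sprintf("valueKind must be one of %s",
                          paste(.VALUE_KINDS, collapse = ", ")))
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene and sample identifiers are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  if (length(assays(object)) >= 1L) {
    v <- assay(object)
    if (length(object@valueKind) == 1L &&
        object@valueKind %in% c("counts", "tpm") &&
        any(v < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("%s values must be non-negative", object@valueKind))
    if (identical(object@valueKind, "tpm") && ncol(v) > 0L) {
      cs <- colSums(v)
      if (any(abs(cs - 1e6) > 1e-6 * 1e6))
        msg <- c(msg, "tpm columns must sum to 1e6 (relative tolerance 1e-6)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric genes x samples matrix with rownames (gene ids) and
#'   colnames (sample ids), or a bare matrix accompanied by `geneIds` /
#'   `sampleIds`.
#' @param valueKind what the values are: `"counts"`, `"tpm"` or `"log_tpm"`.
#' @param geneIds,sampleIds optional identifier vectors used when `values`
#'   lacks dimnames.
#' @param populationLabel,batch optional per-sample annotation vectors.
#' @param isMito optional per-gene logical flag marking mitochondrial genes.
#' @param effectiveLength optional per-gene positive effective transcript
#'   length (needed for TPM conversion).
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- ExpressionMatrix(m, "counts")
#' valueKind(em)
#' @export
ExpressionMatrix <- function(values, valueKind = c("counts", "tpm", "log_tpm"),
                             geneIds = NULL, sampleIds = NULL,
                             populationLabel = NULL, batch = NULL,
                             isMito = NULL, effectiveLength = NULL) {
  valueKind <- match.arg(valueKind)
  values <- as.matrix(values)
  if (!is.null(geneIds)) rownames(values) <- geneIds
  if (!is.null(sampleIds)) colnames(values) <- sampleIds
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(populationLabel)) cd$populationLabel <- as.character(populationLabel)
  if (!is.null(batch)) cd$batch <- as.character(batch)
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(isMito)) rd$isMito <- as.logical(isMito)
  if (!is.null(effectiveLength)) {
    if (any(effectiveLength <= 0, na.rm = TRUE))
      stop("effectiveLength must be positive")
    rd$effectiveLength <- as.numeric(effectiveLength)
  }
  se <- SummarizedExperiment(assays = list(values = values),
                             rowData = rd, colData = cd)
  new("ExpressionMatrix", se, valueKind = valueKind)
}

## internal: rebuild with a new assay and/or kind, keeping annotation
.replaceValues <- function(x, values, valueKind = x@valueKind) {
  se <- SummarizedExperiment(assays = list(values = values),
                             rowData = rowData(x), colData = colData(x))
  new("ExpressionMatrix", se, valueKind = valueKind)
}

#' @describeIn ExpressionMatrix kind of values stored (`counts`, `tpm`,
#'   `log_tpm`).
#' @param x an `ExpressionMatrix`.
#' @export
valueKind <- function(x) x@valueKind

#' @describeIn ExpressionMatrix per-sample population labels (or NULL).
#' @export
populationLabels <- function(x) {
  if ("populationLabel" %in% colnames(colData(x)))
    setNames(colData(x)$populationLabel, colnames(x)) else NULL
}

#' @describeIn ExpressionMatrix per-sample batch labels (or NULL).
#' @export
batchLabels <- function(x) {
  if ("batch" %in% colnames(colData(x)))
    setNames(colData(x)$batch, colnames(x)) else NULL
}

#' @describeIn ExpressionMatrix logical per-gene mitochondrial flag (or NULL).
#' @export
mitoGenes <- function(x) {
  if ("isMito" %in% colnames(rowData(x)))
    setNames(rowData(x)$isMito, rownames(x)) else NULL
}

#' @describeIn ExpressionMatrix per-gene effective transcript lengths (or
#'   NULL).
#' @export
effectiveLengths <- function(x) {
  if ("effectiveLength" %in% colnames(rowData(x)))
    setNames(rowData(x)$effectiveLength, rownames(x)) else NULL
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              object@valueKind, nrow(object), ncol(object)))
  callNextMethod()
})

#' DiffusionState: diffusion-map embedding, pseudotime and terciles
#'
#' Holds the row-stochastic transition matrix and spectral components of a
#' diffusion map, and (once computed) the root cell, per-cell diffusion
#' time, and the tercile sub-population assignment SP1/SP2/SP3.
#'
#' @slot cellNames character, sample identifiers in matrix order.
#' @slot eigenvalues numeric, eigenvalues of the non-trivial components.
#' @slot components cells x k matrix of diffusion components (eigenvector
#'   scaled by eigenvalue), columns `DC1..DCk`.
#' @slot transition n x n row-stochastic transition matrix.
#' @slot kernelInfo list describing the kernel (type, knn, scales).
#' @slot root character, the root cell id (length 0 until chosen).
#' @slot diffusionTime named numeric, per-cell diffusion time (length 0
#'   until computed).
#' @slot terciles named factor with levels SP1, SP2, SP3 (length 0 until
#'   computed).
#' @slot tercileSizes integer(3), cells per tercile.
#' @export
setClass("DiffusionState", representation(
  cellNames = "character",
  eigenvalues = "numeric",
  components = "matrix",
  transition = "matrix",
  kernelInfo = "list",
  root = "character",
  diffusionTime = "numeric",
  terciles = "factor",
  tercileSizes = "integer"
))

setValidity("DiffusionState", function(object) {
  msg <- character()
  n <- length(object@cellNames)
  if (nrow(object@transition) != n || ncol(object@transition) != n)
    msg <- c(msg, "transition matrix must be n x n")
  if (n > 0L) {
    rs <- rowSums(object@transition)
    if (any(abs(rs - 1) > 1e-8))
      msg <- c(msg, "transition matrix rows must sum to 1")
  }
  if (nrow(object@components) != n)
    msg <- c(msg, "components must have one row per cell")
  if (length(object@root) > 1L)
    msg <- c(msg, "at most one root cell")
  if (length(object@diffusionTime) &&
      length(object@diffusionTime) != n)
    msg <- c(msg, "diffusionTime length must match cells")
  if (length(object@terciles) && length(object@terciles) != n)
    msg <- c(msg, "terciles length must match cells")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiffusionState", function(object) {
  cat(sprintf("DiffusionState: %d cells, %d components (%s kernel)\n",
              length(object@cellNames), ncol(object@components),
              if (length(object@kernelInfo$kernel)) object@kernelInfo$kernel
              else "?"))
  if (length(object@root))
    cat(sprintf("  root: %s\n", object@root))
  if (length(object@tercileSizes) == 3L)
    cat(sprintf("  terciles SP1/SP2/SP3: %s\n",
                paste(object@tercileSizes, collapse = "/")))
})

#' @describeIn DiffusionState diffusion components matrix (cells x k).
#' @param x a `DiffusionState`.
#' @export
diffusionComponents <- function(x) x@components

#' @describeIn DiffusionState non-trivial eigenvalues.
#' @export
diffusionEigenvalues <- function(x) x@eigenvalues

#' @describeIn DiffusionState tercile assignment factor (SP1/SP2/SP3).
#' @export
tercileAssignment <- function(x) x@terciles

#' @describeIn DiffusionState integer tercile sizes.
#' @export
tercileSizes <- function(x) x@tercileSizes

#' DEResult: per-gene differential-expression results
#'
#' @slot table `DataFrame` with one row per tested gene: `gene`, `meanA`,
#'   `meanB`, `log2FC`, `statistic`, `p`, `padj`, `direction`
#'   (`up_in_A`/`up_in_B`), `significant`.
#' @slot alpha numeric, BH-FDR threshold used for the `significant` call.
#' @slot fcCut numeric, |log2FC| threshold used for the `significant` call.
#' @slot groupA,groupB character, names of the contrasted groups.
#' @slot method character, test used.
#' @export
setClass("DEResult", representation(
  table = "DataFrame",
  alpha = "numeric",
  fcCut = "numeric",
  groupA = "character",
  groupB = "character",
  method = "character"
))

setValidity("DEResult", function(object) {
  msg <- character()
  need <- c("gene", "log2FC", "statistic", "p", "padj", "direction",
            "significant")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, paste("table must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    ok <- !is.na(object@table$p)
    if (any(object@table$padj[ok] < object@table$p[ok] - 1e-12))
      msg <- c(msg, "padj must be >= p")
    p <- object@table$p[ok]
    if (any(p < 0 | p > 1)) msg <- c(msg, "p outside [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DEResult", function(object) {
  cat(sprintf("DEResult (%s): %s vs %s, %d genes tested, %d significant\n",
              object@method, object@groupA, object@groupB,
              sum(!is.na(object@table$p)),
              sum(object@table$significant, na.rm = TRUE)))
  cat(sprintf("  thresholds: padj < %g, |log2FC| >= %g\n",
              object@alpha, object@fcCut))
})

#' @describeIn DEResult the per-gene result table as a `DataFrame`.
#' @param x a `DEResult`.
#' @export
deTable <- function(x) x@table

#' @describeIn DEResult ids of genes passing the active thresholds.
#' @export
significantGenes <- function(x) {
  x@table$gene[which(x@table$significant)]
}

#' LDAEstimate: single-hit Poisson limiting-dilution estimate
#'
#' @slot frequency estimated per-cell frequency f in (0, 1].
#' @slot oneIn 1/f, the "1 in N" form used for reporting.
#' @slot ci95 length-2 numeric, 95% confidence interval on the oneIn scale
#'   (lower bound of oneIn corresponds to the upper bound of f).
#' @slot logFSE standard error of log f.
#' @slot fitMethod character, `"cloglog_glm"` or `"boundary"`.
#' @slot nAnimals total animals in the assay.
#' @slot degenerate `"none"`, `"all_negative"` or `"all_positive"`.
#' @export
setClass("LDAEstimate", representation(
  frequency = "numeric",
  oneIn = "numeric",
  ci95 = "numeric",
  logFSE = "numeric",
  fitMethod = "character",
  nAnimals = "integer",
  degenerate = "character"
))

setValidity("LDAEstimate", function(object) {
  msg <- character()
  if (identical(object@degenerate, "none")) {
    if (!(object@frequency > 0 && object@frequency <= 1))
      msg <- c(msg, "frequency must be in (0, 1]")
    if (object@oneIn < 1) msg <- c(msg, "oneIn must be >= 1")
    if (length(object@ci95) == 2L &&
        !(object@ci95[1] <= object@oneIn + 1e-9 &&
          object@oneIn <= object@ci95[2] + 1e-9))
      msg <- c(msg, "oneIn must lie inside ci95")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LDAEstimate", function(object) {
  if (identical(object@degenerate, "none")) {
    cat(sprintf("LDAEstimate: 1 in %.4g (95%% CI 1 in %.4g - 1 in %.4g), %d animals\n",
                object@oneIn, object@ci95[1], object@ci95[2], object@nAnimals))
  } else {
    cat(sprintf("LDAEstimate: degenerate (%s), %d animals", object@degenerate,
                object@nAnimals))
    if (length(object@ci95) == 2L)
      cat(sprintf("; one-sided 95%% bound on 1-in-N: [%.4g, %.4g]",
                  object@ci95[1], object@ci95[2]))
    cat("\n")
  }
})

#' @describeIn LDAEstimate estimated per-cell frequency f.
#' @param x an `LDAEstimate`.
#' @export
srcFrequency <- function(x) x@frequency

#' @describeIn LDAEstimate the "1 in N" form of the estimate.
#' @export
oneIn <- function(x) x@oneIn

#' @describeIn LDAEstimate 95% confidence interval on the "1 in N" scale.
#' @export
ci95 <- function(x) x@ci95
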