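## Readers/writers for the external formats the workflow touches.
## Matrix TSV dialect: genes as rows, first column the gene id, header row of
## sample ids (bulk RNA-seq convention).  MatrixMarket triplets are 1-based
## and come with sidecar gene / sample name files.  Sample metadata travels
## in a sidecar TSV keyed by sample id.

.msg <- function(...) message("[hscmark] ", sprintf(...))

.sidecar <- function(path, suffix) {
  paste0(sub("\\.(tsv|mtx|txt|csv)$", "", path), suffix)
}

#' Read an expression matrix from TSV or MatrixMarket triplet
#'
#' @param path file to read.  For `format = "mtx_triplet"` this is the
#'   `.mtx` file; gene and sample names are read from `genesPath` and
#'   `samplesPath` (one identifier per line).
#' @param format `"tsv"` (genes as rows, first column gene id, header of
#'   sample ids) or `"mtx_triplet"`.
#' @param valueKind what the stored values are (default `"counts"`).
#' @param genesPath,samplesPath sidecar name files for the MTX format;
#'   default `<stem>.genes.txt` / `<stem>.samples.txt`.
#' @param metaPath optional sample-metadata TSV with columns
#'   `sample`, `populationLabel`, `batch`; default `<stem>.meta.tsv` if the
#'   file exists.
#' @return An [ExpressionMatrix-class] with row/column order as in the file.
#' @export
readExpressionMatrix <- function(path, format = c("tsv", "mtx_triplet"),
                                 valueKind = c("counts", "tpm", "log_tpm"),
                                 genesPath = NULL, samplesPath = NULL,
                                 metaPath = NULL) {
  format <- match.arg(format)
  valueKind <- match.arg(valueKind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L)
      stop("malformed header at line 1 of ", path,
           ": expected gene id column plus at least one sample column")
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    geneIds <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(values))
      stop("non-numeric values in ", path)
    rownames(values) <- geneIds
  } else {
    if (is.null(genesPath)) genesPath <- .sidecar(path, ".genes.txt")
    if (is.null(samplesPath)) samplesPath <- .sidecar(path, ".samples.txt")
    if (!file.exists(genesPath) || !file.exists(samplesPath))
      stop("mtx_triplet format needs gene and sample name files (",
           genesPath, ", ", samplesPath, ")")
    m <- as.matrix(readMM(path))
    geneIds <- readLines(genesPath)
    sampleIds <- readLines(samplesPath)
    if (nrow(m) != length(geneIds) || ncol(m) != length(sampleIds))
      stop("dimension mismatch between ", path, " and its name files")
    dimnames(m) <- list(geneIds, sampleIds)
    values <- m
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in ", path)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in ", path)
  pop <- batch <- NULL
  if (is.null(metaPath)) {
    cand <- .sidecar(path, ".meta.tsv")
    if (file.exists(cand)) metaPath <- cand
  }
  if (!is.null(metaPath) && file.exists(metaPath)) {
    meta <- read.delim(metaPath, stringsAsFactors = FALSE)
    if (!"sample" %in% colnames(meta))
      stop("metadata file must have a 'sample' column: ", metaPath)
    idx <- match(colnames(values), meta$sample)
    if (anyNA(idx))
      stop("metadata file is missing samples: ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    if ("populationLabel" %in% colnames(meta)) pop <- meta$populationLabel[idx]
    if ("batch" %in% colnames(meta)) batch <- meta$batch[idx]
  }
  ExpressionMatrix(values, valueKind, populationLabel = pop, batch = batch)
}

#' Write an expression matrix as TSV or MatrixMarket triplet
#'
#' Sample metadata (population label, batch), when present, is written to a
#' `<stem>.meta.tsv` sidecar so that a round trip through
#' [readExpressionMatrix()] restores it.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, format = c("tsv", "mtx_triplet")) {
  format <- match.arg(format)
  v <- assay(x)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(v), v, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeMM(as(Matrix::Matrix(v, sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(v), .sidecar(path, ".genes.txt"))
    writeLines(colnames(v), .sidecar(path, ".samples.txt"))
  }
  pop <- populationLabels(x); batch <- batchLabels(x)
  if (!is.null(pop) || !is.null(batch)) {
    meta <- data.frame(sample = colnames(v), stringsAsFactors = FALSE)
    if (!is.null(pop)) meta$populationLabel <- unname(pop)
    if (!is.null(batch)) meta$batch <- unname(batch)
    write.table(meta, .sidecar(path, ".meta.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Build a gene-set collection
#'
#' A gene-set collection is a named list of character vectors with a
#' `descriptions` attribute, the in-memory form of a GMT file.  Genes are
#' deduplicated preserving first occurrence; empty-after-dedup sets and
#' duplicate set names are rejected.
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector of per-set descriptions.
#' @return the validated collection.
#' @export
geneSetCollection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop("empty gene sets after deduplication: ",
         paste(names(sets)[empty], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  attr(sets, "descriptions") <- setNames(as.character(descriptions),
                                         names(sets))
  sets
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: `name TAB description TAB gene TAB gene ...`, one set per
#' line.
#'
#' @param path GMT file.
#' @return a gene-set collection (see [geneSetCollection()]).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT parse error at line ", bad[1], " of ", path,
         ": fewer than 3 tab-separated fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  geneSetCollection(sets, vapply(fields, `[[`, character(1), 2L))
}

#' Write gene sets to a GMT file
#'
#' @param sets a gene-set collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a limiting-dilution dose-response table
#'
#' @param table data.frame with columns `dose` (cells per animal,
#'   positive), `n_tested` (positive integer), `n_engrafted` (non-negative
#'   integer, at most `n_tested`).
#' @return the table, with columns coerced to numeric/integer.
#' @export
validateDoseTable <- function(table) {
  need <- c("dose", "n_tested", "n_engrafted")
  if (!all(need %in% colnames(table)))
    stop("dose table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table) < 1L) stop("dose table must have at least one row")
  table$dose <- as.numeric(table$dose)
  table$n_tested <- as.integer(table$n_tested)
  table$n_engrafted <- as.integer(table$n_engrafted)
  if (any(!is.finite(table$dose)) || any(table$dose <= 0))
    stop("doses must be positive")
  if (any(table$n_tested <= 0L))
    stop("n_tested must be positive")
  if (any(table$n_engrafted < 0L))
    stop("n_engrafted must be non-negative")
  if (any(table$n_engrafted > table$n_tested))
    stop("n_engrafted exceeds n_tested in row ",
         which(table$n_engrafted > table$n_tested)[1])
  table
}

#' Read a dose-response table from CSV
#'
#' @param path CSV with columns `dose,n_tested,n_engrafted`.
#' @return validated data.frame, row order preserved.
#' @export
readDoseTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  validateDoseTable(tab)
}

#' Write a dose-response table to CSV
#'
#' @param table a validated dose-response table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDoseTable <- function(table, path) {
  table <- validateDoseTable(table)
  write.table(table[, c("dose", "n_tested", "n_engrafted")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
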