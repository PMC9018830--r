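## Candidate-marker ranking: genes supported by both evidence streams
## (common single-cell DE set and bulk list C) ranked by a rank-sum of
## single-cell significance (ascending max padj across the two tercile
## contrasts, ties broken by descending min |log2FC|) and bulk
## significance (ascending min padj across the two bulk contrasts).

#' Rank candidate marker genes by combined single-cell and bulk evidence
#'
#' @param commonSc gene ids differentially expressed in both single-cell
#'   tercile contrasts (see [commonDE()]).
#' @param listC bulk candidate gene ids (see [candidateLists()]).
#' @param scDE list of the two single-cell [DEResult-class] objects
#'   (SP1-vs-SP2, SP3-vs-SP2).
#' @param bulkDE list of the two bulk [DEResult-class] objects (lists A
#'   and B contrasts).
#' @param restrictTo optional allowlist of gene ids (e.g. surface
#'   antigens); candidates outside it are dropped.
#' @return a `DataFrame` sorted by `combinedRank`: `gene`, `scRank`,
#'   `bulkRank`, `combinedRank`, `inCommonSc`, `inListC`, `scDirection`,
#'   `bulkDirection`.  Empty candidate set gives an empty table with a
#'   warning.
#' @export
rankMarkers <- function(commonSc, listC, scDE, bulkDE,
                        restrictTo = NULL) {
  stopifnot(length(scDE) == 2L, length(bulkDE) == 2L)
  cand <- intersect(commonSc, listC)
  if (!is.null(restrictTo)) cand <- intersect(cand, restrictTo)
  if (!length(cand)) {
    warning("no genes shared between the single-cell common DE set and ",
            "bulk list C")
    return(DataFrame(gene = character(), scRank = integer(),
                     bulkRank = integer(), combinedRank = integer(),
                     inCommonSc = logical(), inListC = logical(),
                     scDirection = character(), bulkDirection = character()))
  }
  get <- function(de, col) setNames(de@table[[col]], de@table$gene)[cand]
  scPadj <- pmax(get(scDE[[1]], "padj"), get(scDE[[2]], "padj"))
  scMinFc <- pmin(abs(get(scDE[[1]], "log2FC")),
                  abs(get(scDE[[2]], "log2FC")))
  bulkPadj <- pmin(get(bulkDE[[1]], "padj"), get(bulkDE[[2]], "padj"),
                   na.rm = TRUE)
  scOrd <- order(scPadj, -scMinFc, cand)
  scRank <- integer(length(cand)); scRank[scOrd] <- seq_along(cand)
  bulkOrd <- order(bulkPadj, cand)
  bulkRank <- integer(length(cand)); bulkRank[bulkOrd] <- seq_along(cand)
  combOrd <- order(scRank + bulkRank, cand)
  combinedRank <- integer(length(cand))
  combinedRank[combOrd] <- seq_along(cand)
  tab <- DataFrame(gene = cand, scRank = scRank, bulkRank = bulkRank,
                   combinedRank = combinedRank,
                   inCommonSc = TRUE, inListC = TRUE,
                   scDirection = get(scDE[[1]], "direction"),
                   bulkDirection = get(bulkDE[[1]], "direction"))
  tab[order(tab$combinedRank), ]
}
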