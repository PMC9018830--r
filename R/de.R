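## Differential expression.
## Single-cell contrasts use the two-sided Wilcoxon rank-sum test (exact
## null distribution when both groups have <= 8 tie-free observations,
## otherwise the tie-corrected normal approximation with continuity
## correction) with BH adjustment; fold changes are differences of group
## means on the log2(TPM + 1) scale.  Bulk contrasts use a deliberately
## simple negative-binomial Wald test: median-of-ratios size factors,
## method-of-moments dispersions shrunk towards a mean-dispersion trend,
## a two-group NB log-linear model fitted by Newton iterations, and
## log2FC / lfcSE compared to a standard normal.

.wilcoxonOne <- function(xa, xb) {
  nA <- length(xa); nB <- length(xb); N <- nA + nB
  x <- c(xa, xb)
  if (max(x) == min(x))         # constant across both groups
    return(c(stat = nA * nB / 2, p = 1, flag = 1))
  r <- rank(x)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  runs <- rle(sort.int(x))$lengths
  hasTies <- any(runs > 1L)
  if (nA <= 8L && nB <= 8L && !hasTies) {
    if (U > nA * nB / 2)
      p <- min(1, 2 * (1 - pwilcox(U - 1, nA, nB)))
    else
      p <- min(1, 2 * pwilcox(U, nA, nB))
    return(c(stat = U, p = p, flag = 0))
  }
  sigma2 <- nA * nB / 12 * ((N + 1) - sum(runs^3 - runs) / (N * (N - 1)))
  if (sigma2 <= 0) return(c(stat = U, p = 1, flag = 1))
  z <- U - nA * nB / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  c(stat = U, p = min(1, 2 * pnorm(-abs(z))), flag = 0)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values.
#' @param groupA,groupB disjoint character vectors of cell ids (each >= 3
#'   cells).
#' @param alpha BH-FDR threshold for the `significant` call (default 0.1).
#' @param fcCut |log2FC| threshold for the `significant` call (default
#'   0.8).
#' @param groupNames length-2 character used for reporting.
#' @return a [DEResult-class].  Genes with no expression in either group
#'   are dropped before BH adjustment (reported with `p = padj = NA`);
#'   genes constant across both groups get `p = 1` and are flagged in the
#'   `constant` column.
#' @export
wilcoxonDE <- function(x, groupA, groupB, alpha = 0.1, fcCut = 0.8,
                       groupNames = c("A", "B")) {
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("each group needs at least 3 cells")
  miss <- setdiff(c(groupA, groupB), colnames(x))
  if (length(miss)) stop("unknown cells: ", paste(head(miss), collapse = ", "))
  va <- assay(x)[, groupA, drop = FALSE]
  vb <- assay(x)[, groupB, drop = FALSE]
  mA <- rowMeans(va); mB <- rowMeans(vb)
  lfc <- mA - mB
  ng <- nrow(va)
  stat <- p <- rep(NA_real_, ng)
  flag <- logical(ng)
  tested <- !(rowSums(va != 0) == 0 & rowSums(vb != 0) == 0)
  for (g in which(tested)) {
    res <- .wilcoxonOne(va[g, ], vb[g, ])
    stat[g] <- res[["stat"]]; p[g] <- res[["p"]]
    flag[g] <- res[["flag"]] > 0
  }
  padj <- rep(NA_real_, ng)
  padj[tested] <- p.adjust(p[tested], method = "BH")
  sig <- !is.na(padj) & padj < alpha & abs(lfc) >= fcCut
  tab <- DataFrame(gene = rownames(va), meanA = unname(mA),
                   meanB = unname(mB), log2FC = unname(lfc),
                   statistic = stat, p = p, padj = padj,
                   direction = unname(ifelse(lfc > 0, "up_in_A", "up_in_B")),
                   significant = unname(sig), constant = flag)
  new("DEResult", table = tab, alpha = alpha, fcCut = fcCut,
      groupA = groupNames[1], groupB = groupNames[2], method = "wilcoxon")
}

#' Genes differentially expressed in both of two contrasts
#'
#' Intersection of the significant gene sets of two [DEResult-class]
#' objects sharing a gene universe.  When `requireConsistentDirection` is
#' on (the default) both contrasts must agree on the direction relative to
#' the shared reference group, which is assumed to be group B of both
#' results (as in SP1-vs-SP2 and SP3-vs-SP2).
#'
#' @param de1,de2 [DEResult-class] objects over the same gene universe.
#' @param requireConsistentDirection logical.
#' @return character vector of gene ids, in `de1` order.
#' @export
commonDE <- function(de1, de2, requireConsistentDirection = TRUE) {
  g1 <- de1@table$gene; g2 <- de2@table$gene
  if (!setequal(g1, g2))
    stop("DE results have different gene universes")
  sig1 <- significantGenes(de1)
  sig2 <- significantGenes(de2)
  common <- intersect(sig1, sig2)
  if (requireConsistentDirection && length(common)) {
    d1 <- setNames(de1@table$direction, g1)[common]
    d2 <- setNames(de2@table$direction, g2)[common]
    common <- common[d1 == d2]
  }
  common
}

.sizeFactorsMOR <- function(counts) {
  logGeo <- rowMeans(log(counts))
  ok <- is.finite(logGeo)
  if (!any(ok))
    stop("cannot compute size factors: no gene has all-positive counts")
  sf <- apply(counts, 2, function(cnt) {
    exp(median((log(cnt) - logGeo)[ok & cnt > 0]))
  })
  unname(sf)
}

#' Bulk DE configuration
#'
#' @param alpha BH-FDR threshold (default 0.1).
#' @param fcCut |log2FC| threshold (default 0: FDR alone decides).
#' @param dispShrink weight in \[0, 1\] pulling per-gene method-of-moments
#'   dispersions towards the mean-dispersion trend (default 0.9; per-gene
#'   estimates from 2-3 replicates are individually very noisy).
#' @param minDisp dispersion floor.
#' @return a config list of class `BulkDEConfig`.
#' @export
bulkDEConfig <- function(alpha = 0.1, fcCut = 0, dispShrink = 0.9,
                         minDisp = 1e-8) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (dispShrink < 0 || dispShrink > 1) stop("dispShrink must lie in [0, 1]")
  structure(list(alpha = alpha, fcCut = fcCut, dispShrink = dispShrink,
                 minDisp = minDisp), class = "BulkDEConfig")
}

## Newton fit of a one-parameter NB log-linear mean per gene within one
## group: mu_gj = sf_j * exp(beta_g), fixed dispersion.  Returns beta and
## the expected information.
.nbGroupFit <- function(Y, sf, disp, iter = 30L) {
  tot <- rowSums(Y)
  beta <- log((tot + 0.5) / sum(sf))
  for (it in seq_len(iter)) {
    Mu <- exp(beta) %o% sf
    Wt <- Mu / (1 + disp * Mu)
    U <- rowSums((Y - Mu) / (1 + disp * Mu))
    I <- rowSums(Wt)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    beta <- beta + step
    beta <- pmax(beta, log(1e-10))
    if (max(abs(step)) < 1e-10) break
  }
  Mu <- exp(beta) %o% sf
  list(beta = beta, info = rowSums(Mu / (1 + disp * Mu)))
}

#' Negative-binomial Wald differential expression for bulk counts
#'
#' @param x an [ExpressionMatrix-class] of counts.
#' @param groupA,groupB disjoint sample-id vectors (each >= 2 replicates).
#' @param config a [bulkDEConfig()].
#' @param groupNames length-2 character used for reporting.
#' @return a [DEResult-class]; genes with zero counts in all samples of
#'   both groups are excluded from testing (`p = padj = NA`).
#' @export
nbWaldDE <- function(x, groupA, groupB, config = bulkDEConfig(),
                     groupNames = c("A", "B")) {
  stopifnot(inherits(config, "BulkDEConfig"))
  if (!identical(valueKind(x), "counts"))
    stop("nbWaldDE needs a counts matrix")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 replicates")
  counts <- assay(x)[, c(groupA, groupB), drop = FALSE]
  sf <- .sizeFactorsMOR(counts)
  ia <- seq_along(groupA); ib <- length(groupA) + seq_along(groupB)
  norm <- sweep(counts, 2, sf, "/")
  tested <- rowSums(counts) > 0
  ng <- nrow(counts)

  ## dispersion: pooled within-group method of moments, shrunk to trend
  mAll <- rowMeans(norm)
  vA <- .rowVars(norm[, ia, drop = FALSE])
  vB <- .rowVars(norm[, ib, drop = FALSE])
  dfA <- length(ia) - 1L; dfB <- length(ib) - 1L
  s2w <- (vA * dfA + vB * dfB) / (dfA + dfB)
  shot <- mAll * mean(1 / sf)
  raw <- pmax((s2w - shot) / pmax(mAll, 1e-8)^2, config$minDisp)
  use <- tested & mAll > 0
  trend <- rep(config$minDisp, ng)
  if (sum(use) >= 10L) {
    ## iter = 0: the MoM dispersion distribution is right-skewed and the
    ## robust (median-like) fit would systematically under-estimate it
    lo <- lowess(log(mAll[use]), raw[use], f = 2 / 3, iter = 0)
    trend[use] <- pmax(approx(lo$x, lo$y, xout = log(mAll[use]),
                              rule = 2, ties = mean)$y, config$minDisp)
  } else trend[use] <- pmax(mean(raw[use]), config$minDisp)
  ## shrink towards the trend, but never below it ("maximum" sharing):
  ## with 2-3 replicates an under-estimated per-gene dispersion is the
  ## dominant source of false positives
  w <- config$dispShrink
  disp <- exp(w * log(trend) + (1 - w) * log(pmax(raw, trend / 10)))
  disp <- pmax(disp, trend, config$minDisp)

  lfc <- stat <- p <- rep(NA_real_, ng)
  if (any(tested)) {
    Yt <- counts[tested, , drop = FALSE]
    dt <- disp[tested]
    fa <- .nbGroupFit(Yt[, ia, drop = FALSE] + 0, sf[ia], dt)
    fb <- .nbGroupFit(Yt[, ib, drop = FALSE] + 0, sf[ib], dt)
    dBeta <- fa$beta - fb$beta
    se <- sqrt(1 / pmax(fa$info, 1e-12) + 1 / pmax(fb$info, 1e-12))
    z <- dBeta / se
    lfc[tested] <- dBeta / log(2)
    stat[tested] <- z
    p[tested] <- 2 * pnorm(-abs(z))
  }
  padj <- rep(NA_real_, ng)
  padj[tested] <- p.adjust(p[tested], method = "BH")
  sig <- !is.na(padj) & padj < config$alpha & abs(lfc) >= config$fcCut
  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  tab <- DataFrame(gene = rownames(counts), meanA = unname(mA),
                   meanB = unname(mB), log2FC = unname(lfc),
                   statistic = stat, p = p, padj = padj,
                   direction = unname(ifelse(!is.na(lfc) & lfc > 0,
                                             "up_in_A", "up_in_B")),
                   significant = unname(sig), dispersion = unname(disp))
  new("DEResult", table = tab, alpha = config$alpha, fcCut = config$fcCut,
      groupA = groupNames[1], groupB = groupNames[2], method = "nb_wald")
}

#' Bulk candidate gene lists A, B and C
#'
#' List A and list B are the significant genes of the two bulk contrasts
#' (stem-like populations each against the pooled non-stem populations);
#' list C is their union in stable order (A first, then novel B genes) and
#' is the set used to guide the single-cell analysis.
#'
#' @param deA,deB [DEResult-class] objects over the same gene universe.
#' @return list with `listA`, `listB`, `listC`.
#' @export
candidateLists <- function(deA, deB) {
  if (!setequal(deA@table$gene, deB@table$gene))
    stop("DE results have different gene universes")
  listA <- significantGenes(deA)
  listB <- significantGenes(deB)
  list(listA = listA, listB = listB,
       listC = c(listA, setdiff(listB, listA)))
}
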