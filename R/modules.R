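## Gene-module analytics: pre-ranked GSEA with a gene-sampling permutation
## null, a competitive gene-set test whose variance is inflated for
## inter-gene correlation (VIF = 1 + (m - 1) * rhobar), and per-cell
## module "expression strength" scores controlled for overall expression.

## Weighted Kolmogorov-Smirnov running-sum enrichment score for hit
## positions `pos` (sorted ascending) in a ranking of length N with
## per-position weights |r|^p at the hits.  Returns the signed extreme of
## the running sum and the index of the extreme (for the leading edge).
.gseaES <- function(pos, w, N) {
  m <- length(pos)
  if (m == N) return(list(es = 0, peak = 0L))
  NR <- sum(w)
  if (NR == 0) { w <- rep(1, m); NR <- m }
  miss <- 1 / (N - m)
  cumW <- cumsum(w) / NR
  ## running sum just after each hit, and just before each hit
  atHit <- cumW - (pos - seq_len(m)) * miss
  beforeHit <- c(0, cumW[-m]) - (pos - seq_len(m)) * miss
  hi <- max(atHit); lo <- min(beforeHit)
  if (hi >= -lo) list(es = hi, peak = which.max(atHit))
  else list(es = lo, peak = -which.min(beforeHit))
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment scores against a
#' gene-sampling null: `nPerm` random same-size gene sets define the null
#' ES distribution, the NES is the ES divided by the mean |null ES| of
#' matching sign, and the permutation p-value uses only matching-sign null
#' scores (so p-values cannot fall below roughly `1/nPerm`).  BH across
#' sets.
#'
#' @param ranking named numeric vector of per-gene ranking scores (larger
#'   = more associated with the phenotype of interest); names must be
#'   unique.
#' @param sets a gene-set collection (see [geneSetCollection()]).
#' @param nPerm permutations per set (default 10000).
#' @param weightP running-sum weight exponent (default 1, the classic
#'   weighted statistic; 0 gives the unweighted KS statistic).
#' @param minSize sets with fewer overlapping genes are skipped with a
#'   warning.
#' @param seed integer seed for the permutation draws.
#' @return a `DataFrame` per tested set: `set`, `size`, `ES`, `NES`, `p`,
#'   `padj`, `leadingEdge` (CharacterList-like list column).
#' @export
gseaPreranked <- function(ranking, sets, nPerm = 10000L, weightP = 1,
                          minSize = 5L, seed = 1L) {
  if (is.null(names(ranking)) || anyDuplicated(names(ranking)))
    stop("ranking must be a named vector with unique gene ids")
  set.seed(as.integer(seed))
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  scores <- ranking[ord]
  N <- length(genes)
  wAll <- abs(scores)^weightP
  keep <- vapply(sets, function(s) sum(genes %in% s) >= minSize, logical(1))
  if (any(!keep))
    warning("skipping ", sum(!keep), " set(s) with fewer than ", minSize,
            " genes in the ranking")
  sets <- sets[keep]
  res <- lapply(names(sets), function(nm) {
    pos <- sort(which(genes %in% sets[[nm]]))
    m <- length(pos)
    obs <- .gseaES(pos, wAll[pos], N)
    null <- vapply(seq_len(nPerm), function(i) {
      rp <- sort(sample.int(N, m))
      .gseaES(rp, wAll[rp], N)$es
    }, numeric(1))
    same <- null[sign(null) == sign(obs$es)]
    if (!length(same)) same <- abs(null)
    nes <- obs$es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    le <- if (obs$peak > 0) genes[pos[seq_len(obs$peak)]]
          else genes[pos[seq.int(-obs$peak, m)]]
    list(set = nm, size = m, ES = obs$es, NES = nes, p = p,
         leadingEdge = le)
  })
  tab <- DataFrame(set = vapply(res, `[[`, character(1), "set"),
                   size = vapply(res, `[[`, integer(1), "size"),
                   ES = vapply(res, `[[`, numeric(1), "ES"),
                   NES = vapply(res, `[[`, numeric(1), "NES"),
                   p = vapply(res, `[[`, numeric(1), "p"))
  tab$padj <- p.adjust(tab$p, method = "BH")
  tab$leadingEdge <- lapply(res, `[[`, "leadingEdge")
  metadata(tab) <- list(nPerm = nPerm, weightP = weightP,
                        minP = 1 / (nPerm + 1))
  tab
}

#' Competitive gene-set test with inter-gene-correlation adjustment
#'
#' Per-gene two-sample (pooled-variance) t statistics are mapped to normal
#' z scores; each set is tested by a two-sample z comparing the mean
#' in-set z against the mean out-of-set z, with the in-set variance term
#' inflated by `VIF = 1 + (m - 1) * rhobar`, where rhobar is the mean
#' pairwise correlation of the within-group residuals of the set genes.
#' Without the inflation a handful of correlated genes masquerades as
#' independent evidence and the test is wildly anti-conservative.
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values.
#' @param groupA,groupB disjoint sample-id vectors (each >= 2 samples).
#' @param sets a gene-set collection.
#' @param adjustCorrelation set `FALSE` to force `VIF = 1` (for comparison
#'   only).
#' @param minSize sets with fewer overlapping genes are skipped.
#' @return a `DataFrame` per tested set: `set`, `size`, `rhobar`, `vif`,
#'   `z`, `p`, `padj`.
#' @export
cameraCompetitive <- function(x, groupA, groupB, sets,
                              adjustCorrelation = TRUE, minSize = 2L) {
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 samples")
  va <- assay(x)[, groupA, drop = FALSE]
  vb <- assay(x)[, groupB, drop = FALSE]
  nA <- ncol(va); nB <- ncol(vb); df <- nA + nB - 2L
  s2 <- (.rowVars(va) * (nA - 1) + .rowVars(vb) * (nB - 1)) / df
  tstat <- (rowMeans(va) - rowMeans(vb)) /
    sqrt(pmax(s2, 1e-12) * (1 / nA + 1 / nB))
  zg <- qnorm(pt(tstat, df))
  zg[is.infinite(zg)] <- sign(zg[is.infinite(zg)]) * 8
  resid <- cbind(va - rowMeans(va), vb - rowMeans(vb))
  G <- length(zg)
  keep <- vapply(sets, function(s) sum(rownames(va) %in% s) >= minSize,
                 logical(1))
  sets <- sets[keep]
  rows <- lapply(names(sets), function(nm) {
    inSet <- rownames(va) %in% sets[[nm]]
    m <- sum(inSet)
    if (m >= 2L && adjustCorrelation) {
      cm <- cor(t(resid[inSet, , drop = FALSE]))
      rhobar <- mean(cm[upper.tri(cm)], na.rm = TRUE)
      if (!is.finite(rhobar)) rhobar <- 0
    } else rhobar <- 0
    vif <- if (adjustCorrelation) max(1 + (m - 1) * rhobar, 0.05) else 1
    delta <- mean(zg[inSet]) - mean(zg[!inSet])
    sdz <- sd(zg)
    sigma <- sdz * sqrt(vif / m + 1 / (G - m))
    z <- delta / sigma
    list(set = nm, size = m, rhobar = rhobar, vif = vif, z = z,
         p = 2 * pnorm(-abs(z)))
  })
  tab <- DataFrame(set = vapply(rows, `[[`, character(1), "set"),
                   size = vapply(rows, `[[`, integer(1), "size"),
                   rhobar = vapply(rows, `[[`, numeric(1), "rhobar"),
                   vif = vapply(rows, `[[`, numeric(1), "vif"),
                   z = vapply(rows, `[[`, numeric(1), "z"),
                   p = vapply(rows, `[[`, numeric(1), "p"))
  tab$padj <- p.adjust(tab$p, method = "BH")
  tab
}

#' Per-cell gene-module expression strength
#'
#' The raw per-cell score of a module is the mean gene-wise z-score of its
#' genes.  With `controlTotalExpression` (the default) the raw scores are
#' regressed on the per-cell mean z-score across all genes and the
#' intercept-plus-residual is reported, so a module that merely tracks a
#' cell's overall expression level scores near zero.
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values.
#' @param sets a gene-set collection; genes absent from the matrix are
#'   dropped (warning), modules with no overlap are dropped (warning).
#' @param controlTotalExpression logical (default TRUE).
#' @return list of class `ModuleStrength`: `scores` (cells x modules
#'   matrix) and `summary` (data.frame of per-module mean and SD across
#'   cells).
#' @export
moduleStrength <- function(x, sets, controlTotalExpression = TRUE) {
  v <- assay(x)
  sds <- sqrt(.rowVars(v))
  ok <- sds > 1e-12
  z <- (v[ok, , drop = FALSE] - rowMeans(v[ok, , drop = FALSE])) / sds[ok]
  universe <- rownames(z)
  overlap <- lapply(sets, intersect, x = universe)
  dropped <- lengths(overlap) == 0L
  if (any(dropped))
    warning("module(s) with no genes in the matrix dropped: ",
            paste(names(sets)[dropped], collapse = ", "))
  partial <- !dropped &
    lengths(overlap) < vapply(sets, length, integer(1))
  if (any(partial))
    warning(sum(partial), " module(s) had absent genes dropped")
  overlap <- overlap[!dropped]
  raw <- vapply(overlap, function(g) colMeans(z[g, , drop = FALSE]),
                numeric(ncol(z)))
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = ncol(z),
                                     dimnames = list(colnames(z),
                                                     names(overlap)))
  scores <- raw
  if (controlTotalExpression && ncol(z) >= 3L) {
    overall <- colMeans(z)
    oc <- overall - mean(overall)
    denom <- sum(oc^2)
    if (denom > 1e-12) {
      beta <- as.vector(crossprod(raw, oc)) / denom
      scores <- raw - outer(oc, beta)
    }
  }
  structure(list(scores = scores,
                 summary = data.frame(module = colnames(scores),
                                      mean = colMeans(scores),
                                      sd = apply(scores, 2, sd))),
            class = "ModuleStrength")
}

#' @export
print.ModuleStrength <- function(x, ...) {
  cat(sprintf("ModuleStrength: %d cells x %d modules\n", nrow(x$scores),
              ncol(x$scores)))
  print(head(x$summary, 10))
  invisible(x)
}
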