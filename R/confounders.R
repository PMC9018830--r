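## Confounder handling, applied in fixed order: a one-component surrogate
## variable (first principal component of the design-residual matrix) is
## regressed out, then remaining batch structure is removed by parametric
## empirical-Bayes batch adjustment (ComBat) with the population design
## protected.

#' Estimate a one-component surrogate variable
#'
#' First principal component of the residual matrix after removing
#' per-population gene means — the standard first iterate of surrogate
#' variable analysis when exactly one component is requested.  Scores are
#' standardised to mean 0, SD 1; the sign is fixed so that the loading of
#' the highest-variance gene is positive.
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values.
#' @param designLabels per-cell population labels; defaults to the
#'   matrix's `populationLabel` annotation.
#' @return list of class `SurrogateVariable`: `score` (named, per cell),
#'   `varianceExplained` in \[0, 1\].
#' @export
estimateSurrogate <- function(x, designLabels = populationLabels(x)) {
  if (is.null(designLabels)) stop("designLabels required")
  if (ncol(x) < 10L) stop("need at least 10 cells")
  designLabels <- as.character(designLabels)
  if (length(unique(designLabels)) < 2L)
    stop("need at least 2 design labels")
  v <- assay(x)
  resid <- v
  for (lab in unique(designLabels)) {
    j <- designLabels == lab
    resid[, j] <- v[, j, drop = FALSE] - rowMeans(v[, j, drop = FALSE])
  }
  tot <- sum(resid^2)
  if (tot < 1e-10 * length(resid))
    stop("residual matrix is (numerically) zero: no surrogate to estimate")
  sv <- svd(resid, nu = 1, nv = 1)
  score <- sv$v[, 1]
  if (sd(score) < 1e-12)
    stop("rank-deficient residual matrix")
  topGene <- which.max(.rowVars(v))
  if (sv$u[topGene, 1] < 0) { score <- -score; sv$u <- -sv$u }
  score <- (score - mean(score)) / sd(score)
  structure(list(score = setNames(score, colnames(v)),
                 varianceExplained = sv$d[1]^2 / tot),
            class = "SurrogateVariable")
}

#' Regress a surrogate variable out of an expression matrix
#'
#' Per-gene ordinary least squares of expression on the surrogate score;
#' the returned values are the gene intercepts plus residuals, so each
#' gene's mean is preserved and every gene is orthogonal to the score.
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values.
#' @param sv a `SurrogateVariable` (or a numeric score vector of length
#'   `ncol(x)`).
#' @return the adjusted [ExpressionMatrix-class].
#' @export
regressOut <- function(x, sv) {
  score <- if (inherits(sv, "SurrogateVariable")) sv$score else sv
  if (length(score) != ncol(x))
    stop("surrogate score length must equal the number of cells")
  v <- assay(x)
  s <- score - mean(score)
  beta <- as.vector(v %*% s) / sum(s^2)
  .replaceValues(x, v - outer(beta, s))
}

#' Empirical-Bayes batch adjustment preserving the population design
#'
#' Parametric ComBat (normal prior on batch locations, inverse-gamma prior
#' on batch scales, moment-matched) with the population label protected as
#' a design covariate, via \pkg{sva}.  With a single batch the adjustment
#' is the identity.  Genes that are constant across all cells are passed
#' through unchanged.
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values.
#' @param batch per-cell batch labels; defaults to the `batch` annotation.
#' @param designLabels per-cell population labels; defaults to the
#'   `populationLabel` annotation.
#' @return the adjusted [ExpressionMatrix-class].
#' @export
combatAdjust <- function(x, batch = batchLabels(x),
                         designLabels = populationLabels(x)) {
  if (is.null(batch)) stop("batch labels required")
  batch <- as.character(batch)
  if (length(batch) != ncol(x))
    stop("batch length must equal the number of cells")
  if (length(unique(batch)) == 1L) return(x)
  tooSmall <- names(which(table(batch) < 2L))
  if (length(tooSmall))
    stop("every batch needs at least 2 cells; offending batch(es): ",
         paste(tooSmall, collapse = ", "))
  mod <- NULL
  if (!is.null(designLabels) && length(unique(designLabels)) > 1L) {
    designLabels <- as.character(designLabels)
    ## a batch whose cells carry a single label that occurs nowhere else is
    ## indistinguishable from that label's effect
    conf <- vapply(unique(batch), function(b) {
      labs <- unique(designLabels[batch == b])
      length(labs) == 1L && all(batch[designLabels == labs[1]] == b)
    }, logical(1))
    if (any(conf))
      stop("batch confounded with the design: ",
           paste(unique(batch)[conf], collapse = ", "))
    mod <- model.matrix(~designLabels)
  }
  v <- assay(x)
  keep <- .rowVars(v) > 1e-12
  adj <- v
  if (any(keep)) {
    adj[keep, ] <- suppressMessages(
      sva::ComBat(dat = v[keep, , drop = FALSE], batch = batch, mod = mod,
                  par.prior = TRUE, prior.plots = FALSE)
    )
  }
  .replaceValues(x, adj)
}

#' Batch-mixing diagnostic on principal components
#'
#' Mean silhouette width of the batch labels on the first two principal
#' components of the adjusted matrix; values near zero (below
#' `threshold`) indicate good mixing.
#'
#' @param x an [ExpressionMatrix-class].
#' @param batch per-cell batch labels; defaults to the `batch` annotation.
#' @param threshold silhouette width below which mixing is called good.
#' @return list with `silhouette` (mean width) and `goodMixing` (logical).
#' @export
batchMixingCheck <- function(x, batch = batchLabels(x), threshold = 0.1) {
  if (is.null(batch)) stop("batch labels required")
  batch <- as.character(batch)
  pc <- prcomp(t(assay(x)), rank. = 2, center = TRUE, scale. = FALSE)$x
  d <- as.matrix(dist(pc))
  sil <- vapply(seq_len(nrow(pc)), function(i) {
    own <- batch == batch[i]; own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(batch), batch[i]), function(bt) {
      mean(d[i, batch == bt])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  list(silhouette = mean(sil), goodMixing = mean(sil) < threshold)
}
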