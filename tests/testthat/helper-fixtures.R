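# Fixture builders and independent oracles shared across test files.

toyEM <- function(values, kind = "counts", ...) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  ExpressionMatrix(values, kind, ...)
}

randomLogTPM <- function(ng, nc, seed = 1) {
  set.seed(seed)
  toyEM(matrix(rnorm(ng * nc, 5, 2), ng, nc), "log_tpm")
}

# Exhaustive-enumeration oracle for the two-sided rank-sum test: computes
# the Mann-Whitney U for every assignment of nA observations to group A
# and the two-sided tail probability under that permutation distribution.
wilcoxEnumOracle <- function(xa, xb) {
  nA <- length(xa)
  x <- c(xa, xb)
  r <- rank(x)
  u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  splits <- combn(length(x), nA)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - nA * (nA + 1) / 2)
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# Step-up BH oracle: for a fine grid of candidate FDR levels, apply the raw
# step-up rejection rule; the oracle-adjusted p of a hypothesis is the
# smallest level at which it is rejected.
bhGridOracle <- function(p, grid = seq(0.0005, 1, by = 0.0005)) {
  m <- length(p)
  padj <- rep(1, m)
  for (alpha in rev(grid)) {
    ord <- order(p)
    k <- max(c(0, which(p[ord] <= alpha * seq_len(m) / m)))
    rejected <- if (k > 0) ord[seq_len(k)] else integer(0)
    padj[rejected] <- alpha
  }
  padj
}

# Hand-stepped weighted Kolmogorov-Smirnov running sum over an explicit
# gene-by-gene loop (independent of the package's closed-form hit/miss
# bookkeeping).
gseaStepOracle <- function(ranking, set, p = 1) {
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  scores <- abs(ranking[ord])^p
  hit <- genes %in% set
  NR <- sum(scores[hit])
  miss <- 1 / (length(genes) - sum(hit))
  run <- 0; best <- 0
  for (i in seq_along(genes)) {
    run <- if (hit[i]) run + scores[i] / NR else run - miss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Two-stage grid-search likelihood oracle for the single-hit Poisson model.
ldaGridOracle <- function(tab) {
  ll <- function(lf) {
    p <- 1 - exp(-exp(lf) * tab$dose)
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    sum(tab$n_engrafted * log(p) +
        (tab$n_tested - tab$n_engrafted) * log(1 - p))
  }
  lf <- seq(log(1e-5), log(2), length.out = 3000)
  pk <- lf[which.max(vapply(lf, ll, numeric(1)))]
  lf2 <- seq(pk - 0.01, pk + 0.01, length.out = 2001)
  exp(lf2[which.max(vapply(lf2, ll, numeric(1)))])
}
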