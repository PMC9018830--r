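test_that("the exact rank-sum path matches closed-form and enumeration", {
  # complete separation of 5 vs 5 distinct values: p = 2/252
  va <- matrix(c(1:5, 6:10), 1, 10,
               dimnames = list("g1", sprintf("c%02d", 1:10)))
  em <- toyEM(va, "log_tpm")
  de <- wilcoxonDE(em, sprintf("c%02d", 1:5), sprintf("c%02d", 6:10))
  expect_equal(deTable(de)$p, 2 / 252)

  set.seed(51)
  for (i in 1:25) {
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    xa <- rnorm(nA); xb <- rnorm(nB)          # continuous: no ties
    em <- toyEM(matrix(c(xa, xb), 1, nA + nB), "log_tpm")
    de <- wilcoxonDE(em, colnames(em)[1:nA], colnames(em)[nA + 1:nB])
    expect_equal(deTable(de)$p, wilcoxEnumOracle(xa, xb), tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks enumeration at moderate p", {
  # the approximation is built for non-extreme tail probabilities; deep
  # tails (p << 0.01) are served by the exact small-sample path instead
  set.seed(53)
  done <- 0
  for (i in 1:30) {
    nA <- sample(8:10, 1); nB <- sample(8:10, 1)
    xa <- rnorm(nA); xb <- rnorm(nB)          # null, continuous: no ties
    exact <- wilcoxEnumOracle(xa, xb)
    if (exact < 0.05 || exact == 1) next
    em <- toyEM(matrix(c(xa, xb), 1, nA + nB), "log_tpm")
    de <- wilcoxonDE(em, colnames(em)[1:nA], colnames(em)[nA + 1:nB])
    expect_lt(abs(deTable(de)$p - exact) / exact, 0.10)
    done <- done + 1
  }
  expect_gt(done, 10)
  # with heavy ties the tie-corrected approximation stays in the ballpark
  for (i in 1:8) {
    xa <- sample(0:4, 10, replace = TRUE)
    xb <- sample(1:5, 10, replace = TRUE)
    exact <- wilcoxEnumOracle(xa, xb)
    if (exact < 0.05 || exact == 1) next
    em <- toyEM(matrix(c(xa, xb), 1, 20), "log_tpm")
    de <- wilcoxonDE(em, colnames(em)[1:10], colnames(em)[11:20])
    expect_lt(abs(deTable(de)$p - exact) / exact, 0.35)
  }
})

test_that("identical groups and constant genes behave by convention", {
  v <- rbind(gSame = rep(c(1, 2, 3), 4), gConst = rep(5, 12),
             gZero = rep(0, 12))
  em <- toyEM(v, "log_tpm")
  de <- wilcoxonDE(em, colnames(em)[c(1, 3, 5, 7, 9, 11)],
                   colnames(em)[c(2, 4, 6, 8, 10, 12)])
  tab <- deTable(de)
  expect_equal(tab[tab$gene == "gSame", "p"], 1)
  expect_equal(tab[tab$gene == "gSame", "log2FC"], 0)
  expect_equal(tab[tab$gene == "gConst", "p"], 1)
  expect_true(tab[tab$gene == "gConst", "constant"])
  expect_true(is.na(tab[tab$gene == "gZero", "p"]))   # dropped before BH
})

test_that("BH adjustment agrees with the step-up grid oracle", {
  set.seed(57)
  for (i in 1:20) {
    p <- runif(sample(3:10, 1))^sample(1:3, 1)
    expect_true(all(abs(p.adjust(p, "BH") - bhGridOracle(p)) < 6e-4))
  }
})

test_that("planted 2-fold centre-peaked genes are recalled at the stated
           thresholds", {
  set.seed(61)
  ng <- 500; nA <- 250; nB <- 250
  planted <- sprintf("g%03d", 1:50)
  X <- matrix(rnorm(ng * (nA + nB), 5, 1), ng, nA + nB)
  X[1:50, 1:nA] <- X[1:50, 1:nA] + 1        # exp(log2) = 2-fold in group A
  em <- toyEM(X, "log_tpm")
  de <- wilcoxonDE(em, colnames(em)[1:nA], colnames(em)[nA + 1:nB])
  recall <- mean(planted %in% significantGenes(de))
  expect_gte(recall, 0.9)
  fp <- setdiff(significantGenes(de), planted)
  expect_lt(length(fp), 10)
})

test_that("median-of-ratios size factors recover exact scalar multiples", {
  set.seed(63)
  ref <- rpois(100, 50) + 1
  cnt <- cbind(ref, ref * 2, ref * 4, ref)
  dimnames(cnt) <- list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4))
  em <- ExpressionMatrix(cnt, "counts")
  de <- nbWaldDE(em, c("s1", "s2"), c("s3", "s4"))
  sf <- hscmark:::.sizeFactorsMOR(cnt)
  expect_equal(sf / sf[1], c(1, 2, 4, 1))
})

test_that("the NB Wald test is calibrated on null bulk data", {
  rates <- vapply(1:10, function(s) {
    set.seed(700 + s)
    cnt <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), 2000, 6,
                  dimnames = list(sprintf("g%04d", 1:2000),
                                  sprintf("s%d", 1:6)))
    de <- nbWaldDE(ExpressionMatrix(cnt, "counts"),
                   paste0("s", 1:3), paste0("s", 4:6))
    mean(deTable(de)$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})

test_that("planted 4-fold bulk effects are powered at n = 3", {
  pw <- vapply(1:5, function(s) {
    set.seed(800 + s)
    mu <- rlnorm(2000, log(100), 1)
    up <- c(rep(4, 100), rep(1, 1900))
    cnt <- cbind(matrix(rnbinom(2000 * 3, mu = mu * up, size = 10), 2000, 3),
                 matrix(rnbinom(2000 * 3, mu = mu, size = 10), 2000, 3))
    dimnames(cnt) <- list(sprintf("g%04d", 1:2000), sprintf("s%d", 1:6))
    de <- nbWaldDE(ExpressionMatrix(cnt, "counts"),
                   paste0("s", 1:3), paste0("s", 4:6))
    mean(sprintf("g%04d", 1:100) %in% significantGenes(de))
  }, numeric(1))
  expect_gt(mean(pw), 0.8)
})

test_that("the simplified NB Wald test agrees with DESeq2 on planted data", {
  set.seed(67)
  mu <- rlnorm(1000, log(100), 1)
  up <- c(rep(4, 50), rep(1, 950))
  cnt <- cbind(matrix(rnbinom(1000 * 3, mu = mu * up, size = 10), 1000, 3),
               matrix(rnbinom(1000 * 3, mu = mu, size = 10), 1000, 3))
  dimnames(cnt) <- list(sprintf("g%04d", 1:1000), sprintf("s%d", 1:6))
  mine <- significantGenes(nbWaldDE(ExpressionMatrix(cnt, "counts"),
                                    paste0("s", 1:3), paste0("s", 4:6)))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, data.frame(group = factor(rep(c("A", "B"), each = 3),
                                     levels = c("B", "A"))), ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, alpha = 0.1)
  })
  ref <- rownames(res)[!is.na(res$padj) & res$padj < 0.1]
  planted <- sprintf("g%04d", 1:50)
  expect_gt(mean(planted %in% mine), 0.9)
  expect_gt(mean(planted %in% ref), 0.9)
  jac <- length(intersect(mine, ref)) / length(union(mine, ref))
  expect_gt(jac, 0.5)
})

test_that("common DE respects direction consistency relative to the shared
           group", {
  mkDE <- function(genes, sig, dirs) {
    tab <- S4Vectors::DataFrame(
      gene = genes, meanA = 0, meanB = 0,
      log2FC = ifelse(dirs == "up_in_A", 1, -1),
      statistic = 0, p = ifelse(sig, 0.001, 0.9),
      padj = ifelse(sig, 0.01, 0.95),
      direction = dirs, significant = sig & TRUE)
    new("DEResult", table = tab, alpha = 0.1, fcCut = 0.8,
        groupA = "X", groupB = "SP2", method = "wilcoxon")
  }
  genes <- c("A", "B", "C", "D")
  de1 <- mkDE(genes, c(TRUE, TRUE, TRUE, FALSE),
              c("up_in_A", "up_in_B", "up_in_A", "up_in_A"))
  de2 <- mkDE(genes, c(FALSE, TRUE, TRUE, TRUE),
              c("up_in_A", "up_in_B", "up_in_B", "up_in_A"))
  expect_identical(commonDE(de1, de2), "B")             # C flips direction
  expect_setequal(commonDE(de1, de2, requireConsistentDirection = FALSE),
                  c("B", "C"))
  de3 <- mkDE(c("A", "B"), c(TRUE, TRUE), c("up_in_A", "up_in_A"))
  expect_error(commonDE(de1, de3), "universe")
})

test_that("candidate lists obey inclusion-exclusion", {
  mk <- function(sig) {
    tab <- S4Vectors::DataFrame(gene = sprintf("g%02d", 1:20),
                                meanA = 0, meanB = 0, log2FC = 1,
                                statistic = 0, p = 0.5, padj = 0.5,
                                direction = "up_in_A",
                                significant = sprintf("g%02d", 1:20) %in% sig)
    new("DEResult", table = tab, alpha = 0.1, fcCut = 0, groupA = "A",
        groupB = "B", method = "nb_wald")
  }
  set.seed(71)
  for (i in 1:10) {
    a <- sample(sprintf("g%02d", 1:20), sample(0:10, 1))
    b <- sample(sprintf("g%02d", 1:20), sample(0:10, 1))
    l <- candidateLists(mk(a), mk(b))
    expect_setequal(l$listC, union(a, b))
    expect_length(l$listC, length(a) + length(b) - length(intersect(a, b)))
  }
})
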