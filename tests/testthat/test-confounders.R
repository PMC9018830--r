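test_that("a planted global factor orthogonal to labels is recovered", {
  set.seed(17)
  ng <- 400; nc <- 500
  labels <- rep(c("P1", "P2"), length.out = nc)
  planted <- rnorm(nc)
  X <- outer(rnorm(ng, 0, 1), ifelse(labels == "P1", 1, 0)) +   # label means
    outer(rnorm(ng), planted) +                                 # confounder
    matrix(rnorm(ng * nc, 0, 0.5), ng, nc)
  sv <- estimateSurrogate(toyEM(X, "log_tpm"), labels)
  expect_gt(abs(cor(sv$score, planted)), 0.95)
  expect_equal(mean(sv$score), 0, tolerance = 1e-12)
  expect_equal(sd(sv$score), 1, tolerance = 1e-12)
  expect_true(sv$varianceExplained > 0 && sv$varianceExplained <= 1)
})

test_that("data exactly equal to label means has no surrogate", {
  labels <- rep(c("P1", "P2"), each = 10)
  X <- outer(1:30, ifelse(labels == "P1", 2, 5))
  expect_error(estimateSurrogate(toyEM(X + 0, "log_tpm"), labels), "zero")
})

test_that("regressing out the surrogate orthogonalises every gene", {
  set.seed(23)
  em <- randomLogTPM(150, 80, seed = 23)
  labels <- rep(c("P1", "P2"), 40)
  sv <- estimateSurrogate(em, labels)
  adj <- regressOut(em, sv)
  cors <- apply(assay(adj), 1, cor, y = sv$score)
  expect_true(all(abs(cors) < 1e-8))
  expect_equal(rowMeans(assay(adj)), rowMeans(assay(em)))  # means preserved

  # a gene exactly linear in the score becomes constant
  v <- assay(em)
  v["g001", ] <- 3 + 2 * sv$score
  # and a gene orthogonal to the score is untouched
  orth <- rnorm(80)
  orth <- orth - mean(orth)
  orth <- orth - sv$score * sum(orth * sv$score) / sum(sv$score^2)
  v["g002", ] <- orth
  adj2 <- regressOut(toyEM(v, "log_tpm"), sv)
  expect_lt(var(assay(adj2)["g001", ]), 1e-20)
  expect_equal(assay(adj2)["g002", ], v["g002", ], tolerance = 1e-12)
})

test_that("batch adjustment is the identity for a single batch", {
  em <- randomLogTPM(60, 20, seed = 2)
  adj <- combatAdjust(em, batch = rep("B1", 20),
                      designLabels = rep(c("P1", "P2"), 10))
  expect_equal(assay(adj), assay(em), tolerance = 1e-10)
})

test_that("planted batch shifts are removed while the design survives", {
  set.seed(29)
  ng <- 400; nc <- 200
  labels <- rep(c("P1", "P2"), length.out = nc)
  batch <- rep(c("B1", "B2"), each = nc / 2)[sample(nc)]
  shift <- c(rnorm(ng * 0.2, 0, 0) + 1, rep(0, ng * 0.8))  # 1.0 log2 units
  X <- outer(rnorm(ng, 5, 1), rep(1, nc)) +
    outer(c(rep(1, 40), rep(0, ng - 40)), ifelse(labels == "P1", 1, 0)) +
    outer(shift, ifelse(batch == "B2", 1, 0)) +
    matrix(rnorm(ng * nc, 0, 0.7), ng, nc)
  em <- toyEM(X, "log_tpm", populationLabel = labels, batch = batch)
  adj <- combatAdjust(em)
  betweenBatchVar <- function(M, genes) {
    mean(vapply(genes, function(g) {
      var(tapply(M[g, ], batch, mean))
    }, numeric(1)))
  }
  shifted <- rownames(em)[seq_len(ng * 0.2)]
  expect_lt(betweenBatchVar(assay(adj), shifted) /
              betweenBatchVar(assay(em), shifted), 0.05)
  # the planted population effect is still detectable afterwards
  de <- wilcoxonDE(adj, colnames(em)[labels == "P1"],
                   colnames(em)[labels == "P2"], fcCut = 0.5)
  expect_gt(mean(rownames(em)[1:40] %in% significantGenes(de)), 0.9)
})

test_that("EB shrinkage perturbs identically distributed batches less than
           the unshrunken location-scale adjustment", {
  set.seed(37)
  ng <- 200; nc <- 80
  X <- matrix(rnorm(ng * nc, 5, 1), ng, nc)
  batch <- rep(c("B1", "B2"), each = 40)
  labels <- rep(c("P1", "P2"), 40)
  em <- toyEM(X, "log_tpm", populationLabel = labels, batch = batch)
  adj <- combatAdjust(em)
  # unshrunken oracle: per gene, standardise each batch to the pooled
  # location/scale
  oracle <- X
  for (b in unique(batch)) {
    j <- batch == b
    mb <- rowMeans(X[, j]); sb <- apply(X[, j], 1, sd)
    oracle[, j] <- (X[, j] - mb) / sb * apply(X, 1, sd) + rowMeans(X)
  }
  dAdj <- mean(abs(assay(adj) - X))
  dOracle <- mean(abs(oracle - X))
  expect_lt(dAdj, dOracle)          # shrinkage corrects less aggressively
  expect_lt(dAdj, 0.2)              # and stays close to the input
})

test_that("confounded batch/design structure is refused with the batch named", {
  em <- randomLogTPM(30, 12, seed = 5)
  labels <- rep(c("P1", "P2"), each = 6)
  batch <- rep(c("BX", "BY"), each = 6)
  expect_error(combatAdjust(em, batch, labels), "BX")
  expect_error(combatAdjust(em, batch = c(rep("B1", 11), "B2"),
                            designLabels = labels), "at least 2 cells")
})
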