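makeLineEM <- function(n = 60, ng = 50, noise = 0, seed = 1) {
  set.seed(seed)
  pos <- seq(0, 1, length.out = n)
  X <- outer(rnorm(ng, 0, 1), pos) + matrix(rnorm(ng), ng, n) +
    matrix(rnorm(ng * n, 0, noise), ng, n)
  list(em = toyEM(X, "log_tpm"), pos = pos)
}

test_that("DC1 recovers position along a noiseless 1-D manifold", {
  line <- makeLineEM()
  st <- diffusionMap(line$em, knn = 10)
  expect_gt(abs(cor(diffusionComponents(st)[, 1], line$pos,
                    method = "spearman")), 0.99)
  expect_true(all(abs(rowSums(st@transition) - 1) < 1e-10))
})

test_that("duplicated cells get identical diffusion coordinates", {
  line <- makeLineEM(n = 40)
  v <- assay(line$em)
  v <- cbind(v, dupcell = v[, 17])
  st <- diffusionMap(toyEM(v, "log_tpm"), knn = 8)
  cc <- diffusionComponents(st)
  expect_equal(cc[17, ], cc[41, ], tolerance = 1e-6)
})

test_that("diffusion time is monotone along the manifold with tau(root) = 0", {
  line <- makeLineEM()
  st <- diffusionMap(line$em, knn = 10)
  root <- colnames(line$em)[1]
  tau <- diffusionTime(st, root)
  expect_identical(unname(tau[root]), 0)
  expect_true(all(is.finite(tau)))
  expect_gt(abs(cor(tau, line$pos, method = "spearman")), 0.99)
})

test_that("diffusion time matches a hand-computed 3x3 accumulation", {
  Tm <- rbind(c(0.6, 0.4, 0.0),
              c(0.3, 0.4, 0.3),
              c(0.0, 0.4, 0.6))
  dimnames(Tm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  state <- new("DiffusionState", cellNames = c("a", "b", "c"),
               eigenvalues = numeric(0),
               components = matrix(0, 3, 1), transition = Tm,
               kernelInfo = list(), root = character(0),
               diffusionTime = numeric(0),
               terciles = factor(character(0),
                                 levels = c("SP1", "SP2", "SP3")),
               tercileSizes = integer(0))
  # oracle: birth-death stationary distribution and explicit 3x3 inverse
  pi1 <- 1; pi2 <- pi1 * 0.4 / 0.3; pi3 <- pi2 * 0.3 / 0.4
  pi <- c(pi1, pi2, pi3) / (pi1 + pi2 + pi3)
  A <- diag(3) - (Tm - rbind(pi, pi, pi))
  det3 <- function(M) {
    M[1,1]*(M[2,2]*M[3,3] - M[2,3]*M[3,2]) -
    M[1,2]*(M[2,1]*M[3,3] - M[2,3]*M[3,1]) +
    M[1,3]*(M[2,1]*M[3,2] - M[2,2]*M[3,1])
  }
  cof <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    minor <- A[-i, -j, drop = FALSE]
    cof[i, j] <- (-1)^(i + j) * (minor[1,1]*minor[2,2] -
                                 minor[1,2]*minor[2,1])
  }
  Ainv <- t(cof) / det3(A)
  M <- Ainv - diag(3)
  oracle <- sqrt(rowSums((M - matrix(M[1, ], 3, 3, byrow = TRUE))^2))
  tau <- diffusionTime(state, "a")
  expect_equal(unname(tau), oracle, tolerance = 1e-10)
})

test_that("the root anchors to the population-enriched extreme", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 80
    t <- runif(n)
    labels <- ifelse(t < 0.5, "P1", "P2")
    # mislabel a few cells so enrichment, not identity, drives the choice
    flip <- sample(n, 8)
    labels[flip] <- ifelse(labels[flip] == "P1", "P2", "P1")
    X <- outer(rnorm(60), t) + matrix(rnorm(60), 60, n) +
      matrix(rnorm(60 * n, 0, 0.3), 60, n)
    em <- toyEM(X, "log_tpm")
    st <- diffusionMap(em, knn = 10)
    root <- selectRoot(st, labels, "P1")
    t[match(root, colnames(em))] <= quantile(t, 0.1)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("root selection breaks exact ties lexicographically and flips with
           the anchor", {
  n <- 20
  ids <- c("zzz", "aaa", sprintf("m%02d", 1:(n - 2)))
  dc1 <- c(-1, -1, seq(-0.8, 1, length.out = n - 2))  # exact tie at the low end
  comps <- matrix(dc1, n, 1, dimnames = list(ids, "DC1"))
  state <- new("DiffusionState", cellNames = ids, eigenvalues = 0.9,
               components = comps, transition = diag(n),
               kernelInfo = list(), root = character(0),
               diffusionTime = numeric(0),
               terciles = factor(character(0),
                                 levels = c("SP1", "SP2", "SP3")),
               tercileSizes = integer(0))
  labels <- c("P1", "P1", rep(c("P1", "P2"), length.out = n - 2))
  labels[(n - 3):n] <- "P2"
  expect_identical(selectRoot(state, labels, "P1"), "aaa")
  expect_identical(selectRoot(state, labels, "P2"),
                   ids[which.max(dc1)])   # anchoring to P2 flips ends
  expect_error(selectRoot(state, labels, "P9"), "not present")
})

test_that("tercile partition reproduces the published 157/156/156 split", {
  set.seed(3)
  tau <- setNames(runif(469), sprintf("c%04d", 1:469))
  part <- tercilePartition(tau)
  expect_equal(unname(part$sizes), c(157L, 156L, 156L))
  expect_equal(sum(part$sizes), 469L)
})

test_that("tercile remainder goes to the earlier terciles", {
  expect_equal(unname(tercilePartition(setNames(1:6 / 7, letters[1:6]))$sizes),
               c(2L, 2L, 2L))
  expect_equal(unname(tercilePartition(setNames(1:7 / 8, letters[1:7]))$sizes),
               c(3L, 2L, 2L))
  expect_equal(unname(tercilePartition(setNames(1:8 / 9, letters[1:8]))$sizes),
               c(3L, 3L, 2L))
})

test_that("the partition is invariant under monotone transforms of tau", {
  set.seed(5)
  tau <- setNames(rexp(100), sprintf("c%03d", 1:100))
  a <- tercilePartition(tau)
  b <- tercilePartition(tau^3 + 2)
  expect_identical(a$assignment, b$assignment)
  # SP1 holds the smallest diffusion times
  expect_true(max(tau[a$assignment == "SP1"]) <=
              min(tau[a$assignment == "SP3"]))
})

test_that("tercile medians of true latent time are ordered on a continuum", {
  cfg <- scSimConfig(nCells = 150L, nGenes = 400L, nMarkerGenes = 3L,
                     nMonotoneGenes = 60L, nBatches = 1L, cellFactorSd = 0,
                     batchLocationSd = 0, nLowqCells = 0L, seed = 41L)
  sim <- simulateSingleCell(cfg)
  lt <- logTransform(countsToTPM(sim$matrix))
  st <- computeDiffusionState(lt, knn = 15)
  med <- tapply(sim$truth$latentTime[names(tercileAssignment(st))],
                tercileAssignment(st), median)
  expect_true(med[["SP1"]] < med[["SP2"]] && med[["SP2"]] < med[["SP3"]])
})
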