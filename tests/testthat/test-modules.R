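test_that("the enrichment score matches a hand-stepped running sum", {
  ranking <- setNames(seq(10, 1), paste0("g", 1:10))
  sets <- geneSetCollection(list(top2 = c("g1", "g2")))
  # unweighted (classic KS): two hits at the very top reach ES = 1
  res0 <- gseaPreranked(ranking, sets, nPerm = 200, weightP = 0,
                        minSize = 2, seed = 1)
  expect_equal(res0$ES, gseaStepOracle(ranking, c("g1", "g2"), p = 0))
  expect_equal(res0$ES, 1)
  # weighted: oracle loop again
  res1 <- gseaPreranked(ranking, sets, nPerm = 200, weightP = 1,
                        minSize = 2, seed = 1)
  expect_equal(res1$ES, gseaStepOracle(ranking, c("g1", "g2"), p = 1))
  # a set in the middle, mixed signs
  sets2 <- geneSetCollection(list(mid = c("g2", "g5", "g9")))
  res2 <- gseaPreranked(ranking, sets2, nPerm = 200, weightP = 1,
                        minSize = 2, seed = 1)
  expect_equal(res2$ES, gseaStepOracle(ranking, c("g2", "g5", "g9"), p = 1))
})

test_that("degenerate sets and monotone re-scalings behave as expected", {
  ranking <- setNames(rnorm(30), paste0("g", 1:30))
  whole <- geneSetCollection(list(all = names(ranking)))
  expect_equal(gseaPreranked(ranking, whole, nPerm = 50, seed = 2)$ES, 0)
  # classic KS statistic only uses ranks
  set.seed(3)
  sets <- geneSetCollection(list(S = sample(names(ranking), 8)))
  a <- gseaPreranked(ranking, sets, nPerm = 100, weightP = 0, seed = 5)
  b <- gseaPreranked(rank(ranking) * 7 + 2, sets, nPerm = 100, weightP = 0,
                     seed = 5)
  expect_equal(a$ES, b$ES)
  small <- geneSetCollection(list(tiny = c("g1", "g2")))
  expect_warning(out <- gseaPreranked(ranking, small, nPerm = 50,
                                      minSize = 5, seed = 1), "skipping")
  expect_equal(nrow(out), 0L)
})

test_that("enrichment scores agree with the fgsea reference statistic", {
  set.seed(7)
  ranking <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  ord <- order(ranking, decreasing = TRUE)
  for (i in 1:5) {
    genes <- sample(names(ranking), 15)
    mine <- gseaPreranked(ranking, geneSetCollection(list(S = genes)),
                          nPerm = 10, weightP = 1, seed = i)$ES
    ref <- fgsea::calcGseaStat(ranking[ord],
                               which(names(ranking)[ord] %in% genes),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation p-values are null-calibrated", {
  ps <- vapply(1:60, function(s) {
    set.seed(s)
    r <- setNames(rnorm(300), sprintf("g%03d", 1:300))
    sets <- geneSetCollection(list(S = sample(names(r), 20)))
    gseaPreranked(r, sets, nPerm = 200, seed = s + 11)$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the competitive test reduces to a plain two-sample z without
           correlation", {
  set.seed(9)
  X <- matrix(rnorm(200 * 8, 5, 1), 200, 8)
  em <- toyEM(X, "log_tpm")
  gA <- colnames(em)[1:4]; gB <- colnames(em)[5:8]
  genes <- rownames(em)[11:40]
  res <- cameraCompetitive(em, gA, gB, geneSetCollection(list(S = genes)),
                           adjustCorrelation = FALSE)
  # hand-computed z from the per-gene moderated-free statistics
  va <- X[, 1:4]; vb <- X[, 5:8]
  s2 <- (apply(va, 1, var) * 3 + apply(vb, 1, var) * 3) / 6
  tg <- (rowMeans(va) - rowMeans(vb)) / sqrt(s2 * (1 / 4 + 1 / 4))
  zg <- qnorm(pt(tg, 6))
  inSet <- rownames(em) %in% genes
  delta <- mean(zg[inSet]) - mean(zg[!inSet])
  zz <- delta / (sd(zg) * sqrt(1 / 30 + 1 / 170))
  expect_equal(res$z, zz, tolerance = 1e-10)
  expect_equal(res$vif, 1)
})

test_that("competitive p-values fall monotonically with the planted shift", {
  ps <- vapply(c(0, 0.4, 0.8, 1.2), function(eff) {
    set.seed(13)
    X <- matrix(rnorm(400 * 10, 5, 1), 400, 10)
    X[1:40, 1:5] <- X[1:40, 1:5] + eff
    em <- toyEM(X, "log_tpm")
    cameraCompetitive(em, colnames(em)[1:5], colnames(em)[6:10],
                      geneSetCollection(list(S = rownames(em)[1:40])))$p[1]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("module strength self-controls and separates a planted module", {
  # the module is kept small relative to the transcriptome so that the
  # total-expression control covariate is not itself driven by the module
  set.seed(15)
  X <- matrix(rnorm(2000 * 200, 5, 1), 2000, 200)
  up <- c(rep(1, 100), rep(0, 100))           # half the cells upregulated
  X[1:30, ] <- X[1:30, ] + outer(rep(1, 30), up)
  em <- toyEM(X, "log_tpm")
  sets <- geneSetCollection(list(
    planted = rownames(em)[1:30],
    everything = rownames(em)
  ))
  ms <- moduleStrength(em, sets)
  expect_true(all(abs(ms$scores[, "everything"]) < 1e-8))   # self-control
  sc <- ms$scores[, "planted"]
  auc <- mean(outer(sc[up == 1], sc[up == 0], ">"))
  expect_gt(auc, 0.95)
  raw <- moduleStrength(em, sets, controlTotalExpression = FALSE)
  scr <- raw$scores[, "planted"]
  expect_gt(mean(outer(scr[up == 1], scr[up == 0], ">")), 0.95)
})

test_that("module strength is idempotent for duplicated modules and drops
           unknown genes with a warning", {
  em <- randomLogTPM(50, 30, seed = 17)
  sets <- geneSetCollection(list(a = rownames(em)[1:10],
                                 aCopy = rownames(em)[1:10]))
  ms <- moduleStrength(em, sets)
  expect_equal(ms$scores[, "a"], ms$scores[, "aCopy"])
  mixed <- geneSetCollection(list(m = c(rownames(em)[1:5], "ghost"),
                                  gone = c("ghost1", "ghost2")))
  expect_warning(expect_warning(ms2 <- moduleStrength(em, mixed), "dropped"),
                 "absent")
  expect_identical(colnames(ms2$scores), "m")
})
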