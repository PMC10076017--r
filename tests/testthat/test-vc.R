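## A small two-class panel reused across the estimator tests.
vcPanel <- function(n = 300, p = 500, seed = 3) {
  set.seed(seed)
  af <- runif(p, 0.05, 0.45)
  D <- matrix(rbinom(n * p, 2, rep(af, each = n)), nrow = n)
  NimPanel(t(D), data.frame(chrom = "1", pos = seq_len(p) * 1000,
                            id = paste0("v", seq_len(p)),
                            ancestry = rep(c("NIM", "MH"), each = p / 2)))
}

test_that("exact moment solution equals the dense-GRM oracle", {
  panel <- vcPanel()
  n <- ncol(panel); p <- nrow(panel)
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  truth <- simulatePhenotype(panel, rownames(panel)[seq(1, p, 5)],
                             h2 = 0.5, seed = 2)
  est <- estimateComponents(truth@y, panel, prt, mode = "exact",
                            nBlocks = 20)

  ## oracle: explicit dense GRMs and the full trace system
  X <- t(dosages(panel)); storage.mode(X) <- "double"
  pf <- colMeans(X) / 2
  W <- sweep(sweep(X, 2, 2 * pf), 2, sqrt(2 * pf * (1 - pf)), "/")
  W <- sweep(W, 2, colMeans(W))
  yr <- truth@y - mean(truth@y)
  asg <- binAssignment(prt)
  K <- nrow(binLabels(prt))
  binIdx <- lapply(seq_len(K), function(k)
    match(names(asg)[asg == k], rownames(panel)))
  Ks <- lapply(binIdx, function(ii) tcrossprod(W[, ii]) / length(ii))
  T <- matrix(0, K + 1, K + 1); b <- numeric(K + 1)
  for (k in seq_len(K)) {
    for (l in seq_len(K)) T[k, l] <- sum(Ks[[k]] * Ks[[l]])
    T[k, K + 1] <- T[K + 1, k] <- sum(diag(Ks[[k]]))
    b[k] <- drop(yr %*% Ks[[k]] %*% yr)
  }
  T[K + 1, K + 1] <- n - 1
  b[K + 1] <- sum(yr^2)
  sigOracle <- solve(T, b)
  expect_equal(unname(est@sigma2), sigOracle, tolerance = 1e-10)

  ## h2 normalization and aggregate identities
  expect_equal(unname(est@h2PerBin),
               sigOracle[1:K] / (sum(yr^2) / (n - 1)), tolerance = 1e-10)
  nimRows <- which(binLabels(prt)$ancestry == "NIM")
  expect_identical(est@h2Nim, sum(est@h2PerBin[nimRows]))
  expect_identical(est@deltaH2, est@h2Nim - est@h2MhMatched)
})

test_that("randomized trace mode converges to exact mode", {
  panel <- vcPanel(n = 500, p = 2000, seed = 5)
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  truth <- simulatePhenotype(panel, rownames(panel)[seq(1, 2000, 4)],
                             h2 = 0.4, seed = 3)
  mE <- vcModel(panel, prt, mode = "exact", nBlocks = 20)
  mR <- vcModel(panel, prt, mode = "randomized", probes = 100, nBlocks = 20,
                seed = 4)
  ## trace aggregates agree to ~1% relative error at B = 100
  expect_lt(max(abs(mR$S2 - mE$S2) / mE$S2), 0.01)
  eE <- estimateComponents(truth@y, model = mE)
  eR <- estimateComponents(truth@y, model = mR)
  expect_lt(max(abs(eR@h2PerBin - eE@h2PerBin)), 0.02)
})

test_that("null phenotypes give per-bin heritability within 3 SE of zero", {
  panel <- vcPanel(n = 250, p = 400, seed = 7)
  prt <- buildPartition(panel, schemes = c(maf = 2), minSnps = 5)
  model <- vcModel(panel, prt, mode = "exact", nBlocks = 50)
  set.seed(11)
  worst <- 0
  for (r in 1:20) {
    est <- estimateComponents(rnorm(250), model = model)
    se <- sqrt(diag(est@jackknifeCov))
    worst <- max(worst, max(abs(est@h2PerBin) / se))
  }
  expect_lt(worst, 3)
})

test_that("moderate-scale simulation recovers h2 within 3 SE", {
  panel <- vcPanel(n = 400, p = 800, seed = 9)
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  model <- vcModel(panel, prt, mode = "exact", nBlocks = 50)
  bad <- 0
  for (r in 1:10) {
    tr <- simulatePhenotype(panel, rownames(panel)[seq(1, 800, 3)],
                            h2 = 0.5, seed = 20 + r)
    est <- estimateComponents(tr@y, model = model)
    if (abs(est@h2Total - 0.5) > 3 * est@se["h2Total"]) bad <- bad + 1
  }
  expect_lte(bad, 1)
})

test_that("jackknife SE tracks the sampling SD on a one-bin toy", {
  set.seed(1)
  n <- 500; p <- 1000
  D <- matrix(rbinom(n * p, 2, rep(runif(p, .05, .45), each = n)), nrow = n)
  panel <- NimPanel(t(D), data.frame(chrom = "1", pos = 1:p * 500,
                                     id = paste0("v", 1:p), ancestry = "NIM"))
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  model <- vcModel(panel, prt, mode = "exact", nBlocks = 100)
  h2s <- ses <- c()
  for (r in 1:50) {
    tr <- simulatePhenotype(panel, rownames(panel)[seq(1, p, 4)], h2 = 0.3,
                            seed = 100 + r)
    est <- estimateComponents(tr@y, model = model)
    h2s <- c(h2s, est@h2Total)
    ses <- c(ses, est@se["h2Total"])
  }
  expect_lt(abs(mean(ses) / sd(h2s) - 1), 0.25)
})

test_that("estimates are scale-free in y and invariant to variant order", {
  panel <- vcPanel(n = 200, p = 300, seed = 13)
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  tr <- simulatePhenotype(panel, rownames(panel)[1:60], h2 = 0.5, seed = 4)
  e1 <- estimateComponents(tr@y, panel, prt, mode = "exact", nBlocks = 20)
  e2 <- estimateComponents(5 + 3 * tr@y, panel, prt, mode = "exact",
                           nBlocks = 20)
  expect_equal(e1@h2PerBin, e2@h2PerBin, tolerance = 1e-10)
  expect_equal(unname(e1@se), unname(e2@se), tolerance = 1e-8)

  set.seed(5)
  perm <- sample(nrow(panel))
  vt <- variantTable(panel)[perm, c("chrom", "pos", "id", "ancestry")]
  pp <- NimPanel(dosages(panel)[perm, ], vt)
  prtP <- buildPartition(pp, schemes = c(), minSnps = 5)
  eP <- estimateComponents(tr@y, pp, prtP, mode = "exact", nBlocks = 20)
  expect_equal(e1@h2PerBin[binLabels(prt)$bin],
               eP@h2PerBin[binLabels(prtP)$bin], tolerance = 1e-10)
})

test_that("aggregation and the matched background follow their formulas", {
  ## hand-evaluated matched-background example: two bin pairs with
  ## M_NIM = (10, 20), M_MH = (100, 50), h2_MH bins = (0.1, 0.05) and
  ## h2_NIM = 0.02 gives h2_MH matched = 0.01 + 0.02 = 0.03, delta = -0.01
  labels <- data.frame(bin = c("NIM.1", "NIM.2", "MH.1", "MH.2"),
                       ancestry = c("NIM", "NIM", "MH", "MH"),
                       maf_q = c(1L, 2L, 1L, 2L))
  pairs <- nimher:::.matchedPairs(labels)
  h2k <- c(0.005, 0.015, 0.1, 0.05)
  M <- c(10, 20, 100, 50)
  st <- nimher:::.derivedStats(h2k, M, labels, pairs)
  expect_equal(unname(st["h2MhMatched"]), 0.03)
  expect_equal(unname(st["deltaH2"]), 0.02 - 0.03)
  ## doubling h2_NIM with the background fixed raises delta by h2_NIM
  st2 <- nimher:::.derivedStats(c(0.01, 0.03, 0.1, 0.05), M, labels, pairs)
  expect_equal(unname(st2["deltaH2"] - st["deltaH2"]), 0.02)

  ## on a fitted object: aggregate equals the NIM-bin sum; single NIM bin
  ## aggregates to its own h2; truth centring zeroes the Z
  panel <- vcPanel(n = 200, p = 300, seed = 15)
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  tr <- simulatePhenotype(panel, rownames(panel)[1:50], h2 = 0.4, seed = 6)
  est <- estimateComponents(tr@y, panel, prt, mode = "exact", nBlocks = 20)
  agg <- aggregateH2Nim(est, truth = est@h2Nim)
  nimRow <- which(binLabels(prt)$ancestry == "NIM")
  expect_identical(agg$h2Nim, unname(est@h2PerBin[nimRow]))
  expect_equal(agg$zVsTruth, 0)
  expect_equal(agg$se, unname(est@se["h2Nim"]))
  ds <- deltaH2Stats(est)
  expect_identical(ds$delta, est@h2Nim - est@h2MhMatched)

  ## matched null: per-SNP h2 identical in every pair gives delta = 0
  stNull <- nimher:::.derivedStats(c(0.01, 0.02, 0.1, 0.05),
                                   c(10, 20, 100, 50), labels, pairs)
  ## here per-SNP equality means h2_NIM,i = (M_NIM,i / M_MH,i) h2_MH,i
  expect_equal(unname(stNull["deltaH2"]), 0)
})

test_that("orphaned NIM bins make delta-h2 unavailable but not the fit", {
  set.seed(2)
  n <- 150; p <- 100
  D <- matrix(rbinom(n * p, 2, 0.3), nrow = n)
  panel <- NimPanel(t(D), data.frame(chrom = "1", pos = 1:p * 100,
                                     id = paste0("v", 1:p), ancestry = "NIM"))
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  est <- estimateComponents(rnorm(n), panel, prt, mode = "exact",
                            nBlocks = 10)
  expect_true(is.na(est@deltaH2))
  expect_error(deltaH2Stats(est), "unmatched")
  expect_equal(aggregateH2Nim(est)$h2Nim, unname(est@h2PerBin[1]))
})

test_that("no retained NIM bins is an aggregation error", {
  panel <- toyPanel(n = 80, p = 40, nimFrac = 0, seed = 3)
  prt <- buildPartition(panel, schemes = c(), minSnps = 5)
  est <- estimateComponents(rnorm(80), panel, prt, mode = "exact",
                            nBlocks = 10)
  expect_error(aggregateH2Nim(est), "no NIM bins")
})
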