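test_that("a configuration without segments yields a pure modern-human panel", {
  cfg <- panelConfig(nIndividuals = 50, nMhSnps = 120, nSegments = 0,
                     genomeLengthBp = 1e7, seed = 3)
  p <- simulateGenotypes(cfg)
  expect_true(all(ancestry(p) == "MH"))
  expect_equal(nrow(p), 120)
})

test_that("zero block decay gives perfect within-segment LD", {
  cfg <- panelConfig(nIndividuals = 120, nMhSnps = 30, nSegments = 2,
                     nimsPerSegment = 8, nimsDispersion = 0,
                     blockDecay = 0, erodedFraction = 0.5,
                     anchorsPerSegment = 0, genomeLengthBp = 2e7, seed = 5)
  p <- simulateGenotypes(cfg)
  seg <- mcols(SummarizedExperiment::rowRanges(p))$segment
  for (s in unique(na.omit(seg))) {
    idx <- which(seg == s & ancestry(p) == "NIM")
    D <- dosages(p)[idx, , drop = FALSE]
    poly <- apply(D, 1L, sd) > 0
    if (sum(poly) < 2) next
    r2 <- cor(t(D[poly, , drop = FALSE]))^2
    expect_equal(unname(r2), matrix(1, sum(poly), sum(poly)))
  }
})

test_that("generation is reproducible and haplotypes sum to dosages", {
  cfg <- panelConfig(nIndividuals = 40, nMhSnps = 60, nSegments = 2,
                     nimsPerSegment = 6, genomeLengthBp = 1e7, seed = 11)
  p1 <- simulateGenotypes(cfg, keepHaplotypes = TRUE)
  p2 <- simulateGenotypes(cfg, keepHaplotypes = TRUE)
  expect_identical(dosages(p1), dosages(p2))
  expect_identical(variantTable(p1), variantTable(p2))
  H <- haplotypes(p1)
  expect_identical(H[, seq(1, ncol(H), 2)] + H[, seq(2, ncol(H), 2)],
                   unname(dosages(p1)) + 0L)
  ## positions strictly increasing, dosages in range
  expect_true(!is.unsorted(variantTable(p1)$pos, strictly = TRUE))
  expect_true(all(dosages(p1) %in% 0:2))
})

test_that("overflowing segment placement is rejected", {
  expect_error(panelConfig(nIndividuals = 20, nMhSnps = 10, nSegments = 10,
                           segmentLengthBp = 1e6, genomeLengthBp = 5e6,
                           seed = 1),
               "genome too short")
})

test_that("causal selection honours architecture quotas", {
  p <- toyPanel(n = 60, p = 200, seed = 2, mafRange = c(0.01, 0.45))
  vt <- variantTable(p)

  ## BASELINE with all variants causal is exhaustive
  specAll <- architectureSpec("BASELINE", nCausal = 200, h2 = 0.5)
  expect_setequal(selectCausalVariants(p, specAll, seed = 1), vt$id)

  ## RARE: 90% of causal variants have MAF <= 0.05
  nRare <- sum(vt$maf <= 0.05)
  spec <- architectureSpec("RARE", nCausal = min(20, nRare), h2 = 0.5)
  ids <- selectCausalVariants(p, spec, seed = 4)
  frac <- mean(vt$maf[match(ids, vt$id)] <= 0.05)
  expect_equal(frac, floor(0.9 * spec@nCausal + 0.5) / spec@nCausal)

  ## HIGH: quota sizes match round-half-up arithmetic
  p2 <- toyPanel(n = 60, p = 100, seed = 3)
  SummarizedExperiment::rowRanges(p2)$ldScore <- c(rep(20, 37), rep(2, 63))
  for (nc in c(7, 10, 15)) {
    specH <- architectureSpec("HIGH", nCausal = nc, h2 = 0.3)
    ids <- selectCausalVariants(p2, specH, seed = 9)
    ld <- ldScores(p2)[match(ids, rownames(p2))]
    expect_equal(sum(ld > 10), floor(0.9 * nc + 0.5))
    expect_equal(sum(ld <= 10), nc - floor(0.9 * nc + 0.5))
  }

  ## ULTRA_RARE: 90% of causal variants below 1% MAF (selection on a
  ## supplied variant table)
  vtU <- data.frame(id = paste0("u", 1:200), chrom = "1", pos = 1:200,
                    maf = c(runif(80, 0.001, 0.009), runif(120, 0.02, 0.5)),
                    ldScore = 1, qcPass = TRUE,
                    ancestry = "MH")
  idsU <- selectCausalVariants(vtU, architectureSpec("ULTRA_RARE", 20, 0.5),
                               seed = 2)
  expect_equal(sum(vtU$maf[match(idsU, vtU$id)] < 0.01), 18)

  ## deficient class errors by name
  p3 <- toyPanel(n = 60, p = 50, seed = 4, mafRange = c(0.2, 0.45))
  expect_error(
    selectCausalVariants(p3, architectureSpec("RARE", 40, 0.5), seed = 1),
    "RARE")

  ## deterministic given seed
  expect_identical(selectCausalVariants(p, spec, seed = 7),
                   selectCausalVariants(p, spec, seed = 7))
})

test_that("phenotype model matches the standardized-dosage formula", {
  ## 3 individuals, one causal SNP, dosages (0, 1, 2), no noise:
  ## p = 0.5 so w = (x - 1) / sqrt(0.5) and y = beta * (-1, 0, 1) / sqrt(0.5)
  D <- matrix(c(0L, 1L, 2L), nrow = 1)
  vt <- data.frame(chrom = "1", pos = 100, id = "v1", ancestry = "NIM")
  panel <- NimPanel(D, vt)
  truth <- simulatePhenotype(panel, "v1", h2 = 1, seed = 1)
  expect_equal(truth@y, truth@beta[1] * c(-1, 0, 1) / sqrt(0.5))

  ## h2 = 1 means zero residual for any panel
  p <- toyPanel(n = 50, p = 10, seed = 5)
  t1 <- simulatePhenotype(p, rownames(p)[1:5], h2 = 1, seed = 2)
  X <- t(dosages(p)[1:5, ]); storage.mode(X) <- "double"
  pf <- colMeans(X) / 2
  W <- sweep(sweep(X, 2, 2 * pf), 2, sqrt(2 * pf * (1 - pf)), "/")
  expect_equal(t1@y, unname(drop(W %*% t1@beta)))

  ## residual scaling hits the target heritability in-sample
  p2 <- toyPanel(n = 4000, p = 30, seed = 6)
  t2 <- simulatePhenotype(p2, rownames(p2)[1:20], h2 = 0.4, seed = 3)
  X2 <- t(dosages(p2)[1:20, ]); storage.mode(X2) <- "double"
  pf2 <- colMeans(X2) / 2
  W2 <- sweep(sweep(X2, 2, 2 * pf2), 2, sqrt(2 * pf2 * (1 - pf2)), "/")
  g <- drop(W2 %*% t2@beta)
  expect_lt(abs(var(g) / var(t2@y) - 0.4), 0.03)

  ## error cases
  expect_error(simulatePhenotype(p, rownames(p)[1], h2 = 0, seed = 1), "h2")
  Dm <- matrix(c(0L, 0L, 0L, 1L, 2L, 0L), nrow = 2, byrow = TRUE)
  pm <- NimPanel(Dm, data.frame(chrom = "1", pos = c(1, 2), id = c("a", "b"),
                                ancestry = "MH"))
  expect_error(simulatePhenotype(pm, "a", h2 = 0.5, seed = 1), "monomorphic")
})

test_that("true NIM heritability is the NIM effect-sum over Var(y)", {
  p <- toyPanel(n = 200, p = 20, nimFrac = 0.5, seed = 8)
  causal <- rownames(p)[c(1, 2, 15)]          # two NIM, one MH
  truth <- simulatePhenotype(p, causal, h2 = 0.6, seed = 4)
  expect_equal(trueNimH2(truth, p),
               sum(truth@beta[1:2]^2) / var(truth@y))
  expect_equal(truth@trueH2Nim, trueNimH2(truth, p))

  ## no causal NIMs -> zero
  tMh <- simulatePhenotype(p, rownames(p)[15:18], h2 = 0.5, seed = 5)
  expect_equal(trueNimH2(tMh, p), 0)

  ## all-causal-NIM limit: truth approaches the target up to the
  ## finite-sample gap between realized and target variance ratio
  pN <- toyPanel(n = 3000, p = 12, nimFrac = 1, seed = 9)
  tN <- simulatePhenotype(pN, rownames(pN), h2 = 0.5, seed = 6)
  expect_lt(abs(tN@trueH2Nim - 0.5), 0.05)
})

test_that("generator moments reproduce the introgression contrasts", {
  ## reduced panels, several seeds: NIM MAF below MH MAF, NIM LD score
  ## above MH LD score
  mafN <- mafM <- ldN <- ldM <- c()
  for (sd in 1:2) {
    cfg <- panelConfig(nIndividuals = 400, nMhSnps = 2500, nSegments = 8,
                       nimsPerSegment = 60, anchorsPerSegment = 15,
                       mhBlockSize = 40, genomeLengthBp = 6e7, seed = sd)
    p <- computeLdScores(applyQc(simulateGenotypes(cfg)))
    vt <- variantTable(p); vt <- vt[vt$qcPass, ]
    mafN <- c(mafN, mean(vt$maf[vt$ancestry == "NIM"]))
    mafM <- c(mafM, mean(vt$maf[vt$ancestry == "MH"]))
    ldN <- c(ldN, mean(vt$ldScore[vt$ancestry == "NIM"]))
    ldM <- c(ldM, mean(vt$ldScore[vt$ancestry == "MH"]))
  }
  expect_true(all(mafN < mafM))
  expect_true(all(ldN > ldM))

  ## the share of common NIMs rises with the introgression-frequency
  ## location parameter
  share1 <- share5 <- c()
  for (loc in c(10, 10 / 2, 10 / 4)) {  # Beta(0.9, b): smaller b = higher freq
    cfg <- panelConfig(nIndividuals = 300, nMhSnps = 200, nSegments = 10,
                       nimsPerSegment = 40, introFreqShape = c(0.9, loc),
                       genomeLengthBp = 6e7, seed = 31)
    p <- simulateGenotypes(cfg)
    vt <- variantTable(p)
    nim <- vt[vt$ancestry == "NIM", ]
    share1 <- c(share1, mean(nim$maf > 0.01))
    share5 <- c(share5, mean(nim$maf > 0.05))
  }
  expect_true(!is.unsorted(share1))
  expect_true(!is.unsorted(share5))
})
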