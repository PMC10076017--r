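test_that("NIM principal components match a dense SVD", {
  set.seed(1)
  n <- 60; p <- 120
  panel <- toyPanel(n = n, p = p, nimFrac = 1, seed = 2)
  scores <- computeNimPcs(panel, k = 4)
  X <- t(dosages(panel)); storage.mode(X) <- "double"
  X <- scale(X)
  sv <- svd(X)
  want <- sv$u[, 1:4] %*% diag(sv$d[1:4])
  for (j in 1:4) {
    expect_equal(abs(cor(scores[, j], want[, j])), 1, tolerance = 1e-6)
    expect_equal(sd(scores[, j]), sd(want[, j]), tolerance = 1e-6)
  }
  ## columns orthogonal
  cp <- crossprod(scores)
  expect_equal(unname(cp - diag(diag(cp))), matrix(0, 4, 4), tolerance = 1e-6)

  ## k = 0 is an empty covariate block and leaves association unchanged
  expect_equal(ncol(computeNimPcs(panel, k = 0)), 0)

  ## rank-1 matrix: PC1 carries all the variance
  base <- rbinom(n, 2, 0.5)
  D1 <- rbind(base, base, base, 2L - base)
  p1 <- NimPanel(D1, data.frame(chrom = "1", pos = 1:4 * 100,
                                id = paste0("v", 1:4), ancestry = "NIM"))
  expect_error(computeNimPcs(p1, k = 2), "rank")
  s1 <- computeNimPcs(p1, k = 1)
  expect_equal(abs(cor(s1[, 1], base)), 1, tolerance = 1e-9)
})

test_that("association scan equals per-variant least squares", {
  ## printed single-variant toy, no covariates: compare with lm()
  D <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), nrow = 1)
  y <- c(1.2, 2.1, 2.9, 0.8, 2.2, 3.3)
  panel <- NimPanel(D, data.frame(chrom = "1", pos = 50, id = "v1",
                                  ancestry = "NIM"))
  res <- gwasLinear(y, panel, threshold = 0.05)
  ref <- summary(lm(y ~ I(scale(c(0, 1, 2, 0, 1, 2))[, 1])))
  expect_equal(res@table$beta, ref$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(res@table$se, ref$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(res@table$p, ref$coefficients[2, 4], tolerance = 1e-10)

  ## with covariates: t statistics match the full OLS fit
  set.seed(3)
  n <- 80
  panel2 <- toyPanel(n = n, p = 10, seed = 4)
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y2 <- rnorm(n) + 0.5 * C[, 1]
  res2 <- gwasLinear(y2, panel2, testIds = rownames(panel2),
                     covariates = C, threshold = 1e-3)
  for (i in c(1, 5, 10)) {
    x <- as.numeric(dosages(panel2)[i, ])
    ref2 <- summary(lm(y2 ~ x + C))$coefficients["x", ]
    expect_equal(res2@table$p[i], unname(ref2[4]), tolerance = 1e-9)
    expect_equal(res2@table$beta[i] / res2@table$se[i], unname(ref2[3]),
                 tolerance = 1e-9)
  }

  ## constant variant flagged untested
  Dc <- rbind(dosages(panel2), konst = rep(1L, n))
  vtc <- rbind(variantTable(panel2)[, c("chrom", "pos", "id", "ancestry")],
               data.frame(chrom = "1", pos = 2e6, id = "konst",
                          ancestry = "NIM"))
  pc <- NimPanel(Dc, vtc)
  resc <- gwasLinear(y2, pc, testIds = "konst", threshold = 0.05)
  expect_false(resc@table$tested)
  expect_true(is.na(resc@table$p))
})

test_that("p-values are uniform under the null", {
  set.seed(5)
  n <- 150; p <- 1200
  panel <- toyPanel(n = n, p = p, seed = 6)
  y <- rnorm(n)
  res <- gwasLinear(y, panel, testIds = rownames(panel), threshold = 1e-10)
  ks <- ks.test(res@table$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("clumping follows the window and LD rules", {
  set.seed(7)
  n <- 200
  a <- rbinom(n, 2, 0.4)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- 2 - x[i]; x }
  b <- flip(a, 25)                     # correlated with a (r2 ~ 0.6)
  c2 <- rbinom(n, 2, 0.4)              # independent
  D <- rbind(a, b, c2)
  panel <- NimPanel(D, data.frame(chrom = "1",
                                  pos = c(1e5, 2e5, 4.5e5),
                                  id = c("a", "b", "c"), ancestry = "NIM"))
  y <- a + b + c2 + rnorm(n, 0, 0.8)
  res <- gwasLinear(y, panel, testIds = c("a", "b", "c"), threshold = 1)
  res@significant <- c("a", "b", "c")
  cl <- clumpAssociations(res, panel, windowBp = 2.5e5, r2 = 0.5, pIndex = 1)
  ## a and b share a clump (100 kb apart, r2 > 0.5); c is 250+ kb from b
  ## and independent, so it indexes its own clump
  expect_equal(length(unique(cl@clumps$index)), 2)
  expect_setequal(cl@clumps$member[cl@clumps$index != "c"], c("a", "b"))
  ## every significant variant in exactly one clump
  expect_setequal(cl@clumps$member, c("a", "b", "c"))
  expect_false(any(duplicated(cl@clumps$member)))

  ## two significant variants beyond the window stay separate clumps even
  ## at perfect LD
  p2 <- NimPanel(rbind(a, a), data.frame(chrom = "1", pos = c(1e5, 4e5),
                                         id = c("x", "z"), ancestry = "NIM"))
  r2 <- gwasLinear(y, p2, testIds = c("x", "z"), threshold = 1)
  r2@significant <- c("x", "z")
  cl2 <- clumpAssociations(r2, p2, windowBp = 2.5e5, r2 = 0.5, pIndex = 1)
  expect_equal(length(unique(cl2@clumps$index)), 2)

  ## single significant variant is its own index
  r3 <- gwasLinear(y, panel, testIds = c("a"), threshold = 1)
  r3@significant <- "a"
  cl3 <- clumpAssociations(r3, panel, pIndex = 1)
  expect_identical(unique(cl3@clumps$index), "a")
})

test_that("LD pruning keeps a certified set", {
  set.seed(8)
  n <- 150
  base <- rbinom(n, 2, 0.3)
  D <- rbind(base, base, rbinom(n, 2, 0.3))   # duplicate + independent
  panel <- NimPanel(D, data.frame(chrom = "1", pos = c(1e4, 2e4, 3e4),
                                  id = c("d1", "d2", "ind"), ancestry = "NIM"))
  kept <- ldPrune(c("d1", "d2", "ind"), panel, windowBp = 1e5, r2 = 0.99)
  expect_identical(kept, c("d1", "ind"))       # later duplicate dropped

  ## no pair above the bound: input unchanged
  p2 <- toyPanel(n = 120, p = 15, seed = 9)
  kept2 <- ldPrune(rownames(p2), p2, windowBp = 1e6, r2 = 0.99)
  expect_identical(kept2, rownames(p2))

  ## 30-variant toy with induced duplicates: exhaustive certificate
  set.seed(10)
  cols <- lapply(1:10, function(i) rbinom(100, 2, runif(1, 0.2, 0.4)))
  D3 <- do.call(rbind, cols[c(rep(1:10, 3))])
  pos <- sort(sample(2e5, 30))
  p3 <- NimPanel(D3, data.frame(chrom = "1", pos = pos,
                                id = paste0("s", 1:30), ancestry = "NIM"))
  kept3 <- ldPrune(rownames(p3), p3, windowBp = 5e4, r2 = 0.99)
  ki <- match(kept3, rownames(p3))
  r2m <- cor(t(dosages(p3)[ki, ]))^2
  posk <- pos[ki]
  for (i in seq_along(ki)) for (j in seq_along(ki)) {
    if (i < j && abs(posk[i] - posk[j]) <= 5e4)
      expect_lte(r2m[i, j], 0.99)
  }
})

test_that("association FDP labels clumped indices against causal NIMs", {
  panel <- smallBlockPanel(seed = 21)
  panel <- applyQc(panel)
  nims <- rownames(panel)[ancestry(panel) == "NIM" & qcPass(panel)]
  truth <- simulatePhenotype(panel, nims[1], h2 = 0.8, seed = 2)
  res <- gwasLinear(truth@y, panel)
  res <- clumpAssociations(res, panel)
  fdp <- associationFdp(res, panel, truth)
  if (length(unique(res@clumps$index))) {
    ## the causal NIM sits in a segment; its clump index must be within
    ## 100 kb of it, so every discovery here is a true positive
    expect_equal(fdp$fdp, 0)
  } else {
    expect_true(is.na(fdp$fdp))
  }
})
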