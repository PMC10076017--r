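## Shared fixtures, built in code.

## Independent-site panel with a NIM/MH split but no LD structure.
toyPanel <- function(n = 100, p = 40, nimFrac = 0.5, seed = 1,
                     mafRange = c(0.1, 0.4)) {
  set.seed(seed)
  af <- runif(p, mafRange[1], mafRange[2])
  D <- sapply(af, function(a) rbinom(n, 2, a))
  vt <- data.frame(chrom = "1", pos = sort(sample(1e6, p)),
                   id = paste0("v", seq_len(p)),
                   ancestry = rep(c("NIM", "MH"),
                                  c(round(p * nimFrac), p - round(p * nimFrac))))
  NimPanel(t(D), vt)
}

## Small introgression-structured panel via the generator itself.
smallBlockPanel <- function(seed = 7, n = 150, segments = 3, nims = 12,
                            mh = 150) {
  cfg <- panelConfig(nIndividuals = n, nMhSnps = mh, nSegments = segments,
                     nimsPerSegment = nims, nimsDispersion = 0,
                     anchorsPerSegment = 5, mhBlockSize = 10,
                     mhBlockSpanBp = 2e4, genomeLengthBp = 3e7, seed = seed)
  simulateGenotypes(cfg)
}

## Quadratic-time windowed LD-score oracle.
bruteLdScores <- function(D, pos, windowBp) {
  p <- nrow(D)
  r2 <- suppressWarnings(cor(t(D)))^2
  sapply(seq_len(p), function(i) {
    j <- which(abs(pos - pos[i]) <= windowBp)
    sum(r2[i, j])
  })
}

## Exhaustive HWE exact-test oracle: enumerate heterozygote counts directly
## from the conditional multinomial probabilities.
bruteHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nMin <- min(nA, 2 * n - nA)
  hs <- seq(nMin %% 2, nMin, by = 2)
  pr <- sapply(hs, function(h) {
    hmin <- (nMin - h) / 2
    hmaj <- n - h - hmin
    exp(lfactorial(n) - lfactorial(hmin) - lfactorial(h) - lfactorial(hmaj) +
          h * log(2) + lfactorial(nMin) + lfactorial(2 * n - nMin) -
          lfactorial(2 * n))
  })
  pObs <- pr[match(nAa, hs)]
  sum(pr[pr <= pObs + 1e-12])
}

## Per-step brute-force greedy oracle.
bruteGreedy <- function(r2, freqs, costs, chr, pos, untagged, budget = Inf) {
  selected <- integer(0); scores <- numeric(0); used <- 0
  while (any(untagged)) {
    sc <- sapply(seq_along(freqs), function(j) {
      if (!untagged[j]) return(-Inf)
      sum(freqs[untagged][r2[j, untagged] > 0.8]) / costs[j]
    })
    best <- which(sc == max(sc))
    best <- best[order(chr[best], pos[best])][1]
    if (!is.finite(sc[best]) || used + costs[best] > budget) break
    selected <- c(selected, best); scores <- c(scores, sc[best])
    used <- used + costs[best]
    untagged <- untagged & !(r2[, best] > 0.8)
  }
  list(selected = selected, scores = scores)
}

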