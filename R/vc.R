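## Multi-component method-of-moments heritability partitioning.
##
## Model: y = sum_k W_k beta_k + e with per-bin GRMs K_k = W_k W_k' / M_k
## over standardized, covariate-residualized genotypes. The estimator
## solves the moment equations
##   E[y' K_k y] = sum_l sigma2_l tr(K_k K_l) + sigma2_e tr(K_k)
##   E[y' y]     = sum_l sigma2_l tr(K_l)     + sigma2_e (n - q)
## jointly by least squares. Uncertainty comes from a delete-one-block
## jackknife over contiguous SNP blocks; every derived statistic (h2_NIM,
## matched-background h2_MH, delta-h2) is recomputed in full within each
## replicate so covariances between annotation aggregates are propagated.
##
## All trace quantities decompose over SNP blocks, so the model object
## stores, per bin pair (k, l) and block b, the aggregates
##   S2[k,l]    = tr(S_k S_l)            (S_k = W_k W_k', unnormalized)
##   FA[(k,b),l] = tr(S_kb S_l)          (block b part of bin k vs all of l)
##   BB[k,l,b]  = tr(S_kb S_lb)
## from which every delete-one-block trace follows exactly. In exact mode
## these are computed from the squared Gram matrix in column chunks; in
## randomized mode they are Hutchinson estimates sharing one set of probe
## vectors, which converge to the exact aggregates as the probe count
## grows.

#' Precompute a variance-components model
#'
#' Builds the trace aggregates for [estimateComponents()] once per
#' (panel, partition, covariates) so that many phenotypes can be estimated
#' against the same genotypes cheaply.
#'
#' @param panel a \linkS4class{NimPanel} (QC-passing variants are used).
#' @param partition an \linkS4class{AnnotationPartition}.
#' @param covariates optional numeric matrix/data.frame of covariates (an
#'   intercept is always added).
#' @param mode \code{"exact"} (chunked squared-Gram aggregation) or
#'   \code{"randomized"} (Hutchinson probe vectors).
#' @param probes number of random probe vectors in randomized mode.
#' @param nBlocks number of contiguous SNP jackknife blocks (default 100).
#' @param chunkSize columns per chunk in exact mode.
#' @param seed seed for the probe vectors.
#' @return An opaque model object (class \code{VcModel}).
#' @export
vcModel <- function(panel, partition, covariates = NULL,
                    mode = c("exact", "randomized"), probes = 100L,
                    nBlocks = 100L, chunkSize = 1024L, seed = 1L) {
  mode <- match.arg(mode)
  .vcModelMulti(panel, list(model = partition), covariates, mode, probes,
                nBlocks, chunkSize, seed)[[1L]]
}

## Build models for several partitions of the same panel with one pass over
## the (shared) squared Gram matrix.
.vcModelMulti <- function(panel, partitions, covariates = NULL,
                          mode = "exact", probes = 100L, nBlocks = 100L,
                          chunkSize = 1024L, seed = 1L) {
  stopifnot(is(panel, "NimPanel"))
  qc <- which(qcPass(panel))
  ids <- rownames(panel)[qc]
  n <- ncol(panel)
  C <- .covariateMatrix(covariates, n)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariate matrix is rank deficient")

  X <- t(dosages(panel)[qc, , drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idxNA <- which(is.na(X), arr.ind = TRUE)
    X[idxNA] <- mu[idxNA[, 2L]]
  }
  W <- .standardizeDosage(X)
  W <- W - C %*% qr.coef(qrC, W)
  rm(X)

  p <- ncol(W)
  J <- max(1L, min(as.integer(nBlocks), p))
  block <- .blockIds(p, J)

  binList <- lapply(partitions, function(prt) {
    b <- integer(p)
    m <- match(names(binAssignment(prt)), ids)
    if (anyNA(m)) stop("partition refers to variants absent from the QC set")
    b[m] <- binAssignment(prt)
    b
  })
  Ks <- vapply(partitions, function(prt) nrow(binLabels(prt)), 0L)

  aggs <- if (mode == "exact")
    .traceAggExact(W, binList, Ks, block, J, chunkSize)
  else
    .traceAggRandomized(W, binList, Ks, block, J, probes, seed)

  colSq <- colSums(W * W)
  shared <- new.env(parent = emptyenv())
  shared$W <- W

  out <- vector("list", length(partitions))
  names(out) <- names(partitions)
  for (i in seq_along(partitions)) {
    bin <- binList[[i]]; K <- Ks[i]
    M <- tabulate(bin[bin > 0L], nbins = K)
    mKB <- matrix(0L, K, J)
    tKB <- matrix(0, K, J)
    sel <- bin > 0L
    if (any(sel)) {
      tb <- table(factor(bin[sel], levels = seq_len(K)),
                  factor(block[sel], levels = seq_len(J)))
      mKB <- matrix(as.integer(tb), K, J)
      tKB <- .rowsumKB(colSq, bin, block, K, J)
    }
    trS <- rowSums(tKB)
    out[[i]] <- structure(list(
      mode = mode, n = n, qC = ncol(C), C = C, qrC = qrC,
      shared = shared, ids = ids, bin = bin, block = block, K = K, J = J,
      M = M, mKB = mKB, trS = trS, trSKB = tKB,
      S2 = aggs[[i]]$S2, FA = aggs[[i]]$FA, BB = aggs[[i]]$BB,
      partition = partitions[[i]]), class = "VcModel")
  }
  out
}

## sum `values` over (bin, block) cells -> K x J matrix.
.rowsumKB <- function(values, bin, block, K, J) {
  sel <- bin > 0L
  g <- (bin[sel] - 1L) * J + block[sel]
  s <- rowsum(values[sel], g)
  gId <- as.integer(rownames(s))
  out <- matrix(0, K, J)
  out[cbind((gId - 1L) %/% J + 1L, (gId - 1L) %% J + 1L)] <- s
  out
}

## Exact trace aggregates from the squared Gram matrix, in column chunks.
.traceAggExact <- function(W, binList, Ks, block, J, chunkSize) {
  p <- ncol(W)
  nS <- length(binList)
  ## group id per scheme: (bin-1)*J + block, 0 for excluded columns
  gList <- lapply(seq_len(nS), function(i) {
    ifelse(binList[[i]] > 0L, (binList[[i]] - 1L) * J + block, 0L)
  })
  Fm <- lapply(seq_len(nS), function(i) matrix(0, Ks[i] * J, Ks[i] * J))
  for (lo in seq(1L, p, by = chunkSize)) {
    hi <- min(lo + chunkSize - 1L, p)
    Gc <- crossprod(W, W[, lo:hi, drop = FALSE])
    Gc <- Gc * Gc
    for (i in seq_len(nS)) {
      g <- gList[[i]]
      rs <- rowsum(Gc, g)                     # (#groups incl 0) x m
      gc <- g[lo:hi]
      cs <- t(rowsum(t(rs), gc))              # rows: groups, cols: chunk groups
      rg <- as.integer(rownames(rs)); cg <- as.integer(colnames(cs))
      keepR <- rg > 0L; keepC <- cg > 0L
      if (any(keepR) && any(keepC))
        Fm[[i]][rg[keepR], cg[keepC]] <-
          Fm[[i]][rg[keepR], cg[keepC]] + cs[keepR, keepC, drop = FALSE]
    }
  }
  lapply(seq_len(nS), function(i) .foldF(Fm[[i]], Ks[i], J))
}

## Reduce the fine (bin x block) x (bin x block) matrix F to the aggregates
## used by the jackknife.
.foldF <- function(Fm, K, J) {
  if (K == 0L) return(list(S2 = matrix(0, 0, 0), FA = matrix(0, 0, 0),
                           BB = array(0, c(0, 0, 0))))
  ## FA[(k,b), l] = sum_{b'} F[(k,b), (l,b')]
  colBin <- rep(seq_len(K), each = J)
  FA <- t(rowsum(t(Fm), colBin))              # (K*J) x K
  S2 <- rowsum(FA, rep(seq_len(K), each = J)) # K x K
  BB <- array(0, c(K, K, J))
  for (b in seq_len(J)) {
    idx <- (seq_len(K) - 1L) * J + b
    BB[, , b] <- Fm[idx, idx, drop = FALSE]
  }
  list(S2 = S2, FA = FA, BB = BB)
}

## Hutchinson estimates of the same aggregates with shared probe vectors.
.traceAggRandomized <- function(W, binList, Ks, block, J, probes, seed) {
  n <- nrow(W); p <- ncol(W)
  nS <- length(binList)
  Z <- .withSeed(seed, matrix(stats::rnorm(n * probes), n, probes))
  P <- crossprod(W, Z)                        # p x B
  out <- vector("list", nS)
  for (i in seq_len(nS)) {
    bin <- binList[[i]]; K <- Ks[i]
    V <- vector("list", K)                    # V_k = S_k Z  (n x B)
    for (k in seq_len(K)) {
      ck <- which(bin == k)
      V[[k]] <- W[, ck, drop = FALSE] %*% P[ck, , drop = FALSE]
    }
    S2 <- matrix(0, K, K)
    for (k in seq_len(K)) for (l in k:K) {
      S2[k, l] <- S2[l, k] <- sum(V[[k]] * V[[l]]) / probes
    }
    FA <- matrix(0, K * J, K)
    BB <- array(0, c(K, K, J))
    for (b in seq_len(J)) {
      inB <- which(block == b & bin > 0L)
      if (!length(inB)) next
      binsHere <- sort(unique(bin[inB]))
      U <- vector("list", K)
      for (k in binsHere) {
        ck <- inB[bin[inB] == k]
        U[[k]] <- W[, ck, drop = FALSE] %*% P[ck, , drop = FALSE]
      }
      for (k in binsHere) {
        for (l in seq_len(K))
          FA[(k - 1L) * J + b, l] <- sum(U[[k]] * V[[l]]) / probes
        for (l in binsHere)
          BB[k, l, b] <- BB[l, k, b] <- sum(U[[k]] * U[[l]]) / probes
      }
    }
    out[[i]] <- list(S2 = S2, FA = FA, BB = BB)
  }
  out
}

## Solve one moment system. Returns sigma2 (length K + 1, noise last).
.solveMoments <- function(S2, trS, M, n, b, binNames) {
  K <- length(M)
  T <- matrix(0, K + 1L, K + 1L)
  T[seq_len(K), seq_len(K)] <- S2 / outer(M, M)
  T[seq_len(K), K + 1L] <- trS / M
  T[K + 1L, seq_len(K)] <- trS / M
  T[K + 1L, K + 1L] <- n
  qrT <- qr(T)
  if (qrT$rank < K + 1L) {
    bad <- qrT$pivot[seq(qrT$rank + 1L, K + 1L)]
    stop("singular moment matrix; collinear bins: ",
         paste(c(binNames, "noise")[bad], collapse = ", "))
  }
  drop(qr.coef(qrT, b))
}

## Matched-pair index: for each NIM bin row, the row of the MH bin with
## identical quantile labels (NA when absent).
.matchedPairs <- function(labels) {
  nimRows <- which(labels$ancestry == "NIM")
  qcols <- setdiff(colnames(labels), c("bin", "ancestry"))
  mhRows <- which(labels$ancestry == "MH")
  partner <- rep(NA_integer_, length(nimRows))
  if (!length(qcols)) {
    if (length(mhRows) == 1L) partner[] <- mhRows
  } else {
    keyN <- do.call(paste, c(labels[nimRows, qcols, drop = FALSE], sep = "|"))
    keyM <- do.call(paste, c(labels[mhRows, qcols, drop = FALSE], sep = "|"))
    partner <- mhRows[match(keyN, keyM)]
  }
  data.frame(nim = nimRows, mh = partner)
}

## Derived statistics from per-bin h2 and bin sizes.
.derivedStats <- function(h2k, M, labels, pairs) {
  nimRows <- which(labels$ancestry == "NIM")
  h2Nim <- if (length(nimRows)) sum(h2k[nimRows]) else NA_real_
  h2Mh <- NA_real_
  if (nrow(pairs) && !anyNA(pairs$mh)) {
    h2Mh <- sum(M[pairs$nim] / M[pairs$mh] * h2k[pairs$mh])
  }
  c(h2Total = sum(h2k), h2Nim = h2Nim, h2MhMatched = h2Mh,
    deltaH2 = h2Nim - h2Mh)
}

#' Estimate variance components for a phenotype
#'
#' Multi-component method-of-moments estimation of per-bin heritabilities
#' with delete-one-block jackknife standard errors, aggregate NIM
#' heritability, matched modern-human background heritability and their
#' difference delta-h2 (negative values indicate NIM depletion).
#'
#' @param y numeric phenotype vector.
#' @param panel,partition,covariates,mode,probes,nBlocks see [vcModel()];
#'   ignored when \code{model} is supplied.
#' @param model optional precomputed [vcModel()] result.
#' @param trueH2Nim optional simulation truth for the truth-centred Z-score.
#' @return A \linkS4class{ComponentEstimates}.
#' @export
estimateComponents <- function(y, panel = NULL, partition = NULL,
                               covariates = NULL,
                               mode = c("exact", "randomized"),
                               probes = 100L, nBlocks = 100L, model = NULL,
                               trueH2Nim = NA_real_) {
  if (is.null(model)) {
    mode <- match.arg(mode)
    model <- vcModel(panel, partition, covariates, mode = mode,
                     probes = probes, nBlocks = nBlocks)
  }
  m <- model
  stopifnot(length(y) == m$n, !anyNA(y))
  labels <- binLabels(m$partition)
  binNames <- labels$bin
  K <- m$K; J <- m$J

  yr <- y - m$C %*% qr.coef(m$qrC, y)
  yy <- sum(yr^2)
  nEff <- m$n - m$qC
  varY <- yy / nEff
  r <- drop(crossprod(m$shared$W, yr))
  cKB <- .rowsumKB(r^2, m$bin, m$block, K, J)
  cK <- rowSums(cKB)

  theta <- .solveMoments(m$S2, m$trS, m$M, nEff, c(cK / m$M, yy), binNames)
  sigma2 <- theta
  names(sigma2) <- c(binNames, "noise")
  h2k <- theta[seq_len(K)] / varY
  names(h2k) <- binNames

  ## NIM bins without a surviving matched MH bin leave the matched
  ## statistics NA; deltaH2Stats() reports the orphans
  pairs <- .matchedPairs(labels)
  stats <- .derivedStats(h2k, m$M, labels, pairs)

  ## delete-one-block jackknife; every statistic recomputed per replicate
  jkH2 <- matrix(NA_real_, J, K, dimnames = list(NULL, binNames))
  jkStats <- matrix(NA_real_, J, 4L,
                    dimnames = list(NULL, names(stats)))
  for (b in seq_len(J)) {
    Mb <- m$M - m$mKB[, b]
    alive <- which(Mb > 0L)
    idxFA <- (seq_len(K) - 1L) * J + b
    S2b <- m$S2 - m$FA[idxFA, , drop = FALSE] -
      t(m$FA[idxFA, , drop = FALSE]) + m$BB[, , b]
    trSb <- m$trS - m$trSKB[, b]
    cKb <- cK - cKB[, b]
    h2b <- h2k   # emptied bins keep the full-data value (zero jackknife weight)
    if (length(alive)) {
      th <- .solveMoments(S2b[alive, alive, drop = FALSE], trSb[alive],
                          Mb[alive], nEff, c(cKb[alive] / Mb[alive], yy),
                          binNames[alive])
      h2b[alive] <- th[seq_along(alive)] / varY
    }
    jkH2[b, ] <- h2b
    Mb2 <- ifelse(Mb > 0L, Mb, m$M)   # emptied bins fall back to full size
    jkStats[b, ] <- .derivedStats(h2b, Mb2, labels, pairs)
  }
  dev <- sweep(jkH2, 2L, colMeans(jkH2), "-")
  jkCov <- (J - 1) / J * crossprod(dev)
  devS <- sweep(jkStats, 2L, colMeans(jkStats), "-")
  se <- sqrt((J - 1) / J * colSums(devS^2))

  zNim0 <- unname(stats["h2Nim"] / se["h2Nim"])
  zNimT <- unname((stats["h2Nim"] - trueH2Nim) / se["h2Nim"])
  zDelta <- unname(stats["deltaH2"] / se["deltaH2"])
  z <- c(h2NimVsZero = zNim0, h2NimVsTruth = zNimT, deltaVsZero = zDelta)
  p <- c(h2NimGtZero = stats::pnorm(zNim0, lower.tail = FALSE),
         deltaVsZero = 2 * stats::pnorm(-abs(zDelta)))

  new("ComponentEstimates", sigma2 = sigma2, h2PerBin = h2k,
      h2Total = unname(stats["h2Total"]), h2Nim = unname(stats["h2Nim"]),
      h2MhMatched = unname(stats["h2MhMatched"]),
      deltaH2 = unname(stats["deltaH2"]), se = se, z = z, p = p,
      jackknifeCov = jkCov, jackknife = jkH2, varY = varY,
      partition = m$partition, trueH2Nim = trueH2Nim)
}

#' Aggregate NIM heritability
#'
#' Sums per-bin heritabilities over NIM-ancestry bins with the jackknife
#' standard error of the sum (propagated through the stored replicates),
#' and Z-scores against zero and, optionally, a supplied truth.
#'
#' @param est a \linkS4class{ComponentEstimates}.
#' @param truth optional true NIM heritability.
#' @return List with \code{h2Nim}, \code{se}, \code{zVsZero}, \code{zVsTruth}.
#' @export
aggregateH2Nim <- function(est, truth = NULL) {
  stopifnot(is(est, "ComponentEstimates"))
  labels <- binLabels(est@partition)
  nimRows <- which(labels$ancestry == "NIM")
  if (!length(nimRows)) stop("no NIM bins retained in the partition")
  reps <- rowSums(est@jackknife[, nimRows, drop = FALSE])
  J <- length(reps)
  se <- sqrt((J - 1) / J * sum((reps - mean(reps))^2))
  h2nim <- sum(est@h2PerBin[nimRows])
  list(h2Nim = h2nim, se = se, zVsZero = h2nim / se,
       zVsTruth = if (is.null(truth)) NA_real_ else (h2nim - truth) / se)
}

#' Matched-background delta-h2
#'
#' The contrast between aggregate NIM heritability and the heritability of
#' the modern-human background matched for the MAF/LD profile of the NIMs:
#' h2_MH = sum_i (M_NIM,i / M_MH,i) h2_MH,i over matched bin pairs, and
#' delta = h2_NIM - h2_MH. Negative values indicate NIM depletion. The
#' standard error comes from the jackknife replicates of the full linear
#' combination.
#'
#' @param est a \linkS4class{ComponentEstimates}.
#' @return List with \code{delta}, \code{se}, \code{z}, \code{p} (two-sided).
#' @export
deltaH2Stats <- function(est) {
  stopifnot(is(est, "ComponentEstimates"))
  if (is.na(est@deltaH2)) {
    labels <- binLabels(est@partition)
    pairs <- .matchedPairs(labels)
    orphans <- labels$bin[pairs$nim[is.na(pairs$mh)]]
    stop("delta-h2 undefined; unmatched NIM bins (matched MH bin absent): ",
         paste(orphans, collapse = ", "))
  }
  se <- unname(est@se["deltaH2"])
  z <- est@deltaH2 / se
  list(delta = est@deltaH2, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
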