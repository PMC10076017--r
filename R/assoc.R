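#' Principal components of the NIM genotypes
#'
#' Top-k left singular scores of the column-standardized NIM dosage matrix,
#' computed through the eigendecomposition of the individual-by-individual
#' Gram matrix (exact for any k up to the rank). Used as covariates to
#' absorb stratification specific to introgressed variation.
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param k number of components (default 5); \code{k = 0} returns an empty
#'   covariate block.
#' @param useQc restrict to QC-passing NIMs (default TRUE).
#' @return n x k matrix of PC scores (columns orthogonal, ordered by
#'   decreasing variance explained; sign is arbitrary).
#' @export
computeNimPcs <- function(panel, k = 5L, useQc = TRUE) {
  stopifnot(is(panel, "NimPanel"))
  k <- as.integer(k)
  n <- ncol(panel)
  if (k == 0L) return(matrix(0, n, 0))
  sel <- which(ancestry(panel) == "NIM" & (!useQc | qcPass(panel)))
  X <- t(dosages(panel)[sel, , drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    ii <- which(is.na(X), arr.ind = TRUE)
    X[ii] <- mu[ii[, 2L]]
  }
  X <- .scaleCols(X)                      # constant columns become NA
  X <- X[, colSums(is.na(X)) == 0L, drop = FALSE]
  if (ncol(X) < k) stop("need at least k = ", k, " polymorphic NIMs")
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  if (sum(eg$values > max(eg$values) * 1e-9) < k)
    stop("k = ", k, " exceeds the rank of the NIM matrix")
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k, k)
  colnames(scores) <- paste0("nimPC", seq_len(k))
  scores
}

#' Per-variant linear association scan
#'
#' Fits, for each test variant, the least-squares model
#' y ~ dosage + covariates and reports the dosage effect per standardized
#' allele, its standard error and a two-sided t-test p-value. Computed via
#' Frisch-Waugh projection: y and each dosage column are residualized on
#' the covariates (with intercept), after which the per-variant fit is an
#' exact simple regression with n - q - 1 residual degrees of freedom.
#' Variants collinear with the covariates (or constant) are flagged
#' untested.
#'
#' @param y numeric phenotype.
#' @param panel a \linkS4class{NimPanel}.
#' @param testIds character ids of variants to test (default: QC-passing
#'   NIMs).
#' @param covariates optional covariate matrix (age, sex, genotypic PCs,
#'   NIM PCs, ...); an intercept is always included.
#' @param threshold significance threshold; the default
#'   \code{0.05 / number of tested variants} preserves the multiple-testing
#'   logic of a genome-wide scan at any panel size. Pass e.g. \code{1e-10}
#'   for a biobank-scale scan.
#' @return An \linkS4class{AssocResult}.
#' @export
gwasLinear <- function(y, panel, testIds = NULL, covariates = NULL,
                       threshold = NULL) {
  stopifnot(is(panel, "NimPanel"))
  n <- ncol(panel)
  stopifnot(length(y) == n)
  if (is.null(testIds))
    testIds <- rownames(panel)[qcPass(panel) & ancestry(panel) == "NIM"]
  idx <- match(testIds, rownames(panel))
  if (anyNA(idx)) stop("unknown test ids")
  C <- .covariateMatrix(covariates, n)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariate matrix is rank deficient")
  yr <- y - C %*% qr.coef(qrC, y)
  X <- t(dosages(panel)[idx, , drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    ii <- which(is.na(X), arr.ind = TRUE)
    X[ii] <- mu[ii[, 2L]]
  }
  sdX <- sqrt(colSums(sweep(X, 2L, colMeans(X))^2) / (n - 1L))
  tested <- sdX > 0
  X[, tested] <- sweep(X[, tested, drop = FALSE], 2L, sdX[tested], "/")
  Xr <- X - C %*% qr.coef(qrC, X)
  xx <- colSums(Xr^2)
  df <- n - ncol(C) - 1L
  tested <- tested & xx > n * 1e-10
  xy <- drop(crossprod(Xr, yr))
  beta <- ifelse(tested, xy / xx, NA_real_)
  rss <- sum(yr^2) - beta^2 * xx
  se <- sqrt(pmax(rss, 0) / df / xx)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval[!tested] <- NA_real_
  gr <- rowRanges(panel)[idx]
  tab <- data.frame(id = testIds, chrom = as.character(seqnames(gr)),
                    pos = start(gr), beta = beta, se = se, p = pval,
                    tested = tested, row.names = NULL)
  if (is.null(threshold)) threshold <- 0.05 / sum(tested)
  sig <- tab$id[tested & !is.na(pval) & pval < threshold]
  new("AssocResult", table = tab, significant = sig, threshold = threshold,
      clumps = data.frame(index = character(), member = character()))
}

#' Greedy LD clumping of significant variants
#'
#' Repeatedly takes the smallest-p unassigned significant variant as a clump
#' index; significant variants within \code{windowBp} of it and with
#' in-sample r2 at least \code{r2} join its clump. Every significant
#' variant ends up in exactly one clump.
#'
#' @param assoc an \linkS4class{AssocResult}.
#' @param panel the panel the scan was run on.
#' @param windowBp clumping window (default 250 kb).
#' @param r2 LD threshold (default 0.5).
#' @param pIndex maximum index p-value (defaults to the scan threshold).
#' @return The \linkS4class{AssocResult} with the \code{clumps} slot filled.
#' @export
clumpAssociations <- function(assoc, panel, windowBp = 2.5e5, r2 = 0.5,
                              pIndex = NULL) {
  stopifnot(is(assoc, "AssocResult"), is(panel, "NimPanel"))
  if (is.null(pIndex)) pIndex <- assoc@threshold
  tab <- assoc@table
  sig <- tab[tab$id %in% assoc@significant & tab$p < pIndex, , drop = FALSE]
  if (!nrow(sig)) {
    assoc@clumps <- data.frame(index = character(), member = character())
    return(assoc)
  }
  sig <- sig[order(sig$p), , drop = FALSE]
  idx <- match(sig$id, rownames(panel))
  R <- .rowCorMatrix(dosages(panel)[idx, , drop = FALSE])
  assigned <- rep(FALSE, nrow(sig))
  out <- list()
  while (any(!assigned)) {
    i <- which(!assigned)[1L]
    near <- !assigned & sig$chrom == sig$chrom[i] &
      abs(sig$pos - sig$pos[i]) <= windowBp
    r2v <- drop(R[near, , drop = FALSE] %*% R[i, ])^2
    member <- which(near)[r2v >= r2]
    member <- union(i, member)
    assigned[member] <- TRUE
    out[[length(out) + 1L]] <- data.frame(index = sig$id[i],
                                          member = sig$id[member])
  }
  assoc@clumps <- do.call(rbind, out)
  assoc
}

#' Sliding-window LD pruning
#'
#' Advances a window of \code{windowBp} one variant at a time; within each
#' window any pair with r2 above the bound loses its later-position member,
#' so the kept set certifiably contains no within-window pair exceeding the
#' bound.
#'
#' @param ids character variant ids (sorted positions).
#' @param panel a \linkS4class{NimPanel}.
#' @param windowBp window size (default 100 kb).
#' @param r2 exclusive r2 bound (default 0.99).
#' @return Character ids kept.
#' @export
ldPrune <- function(ids, panel, windowBp = 1e5, r2 = 0.99) {
  stopifnot(is(panel, "NimPanel"))
  idx <- match(ids, rownames(panel))
  if (anyNA(idx)) stop("unknown ids")
  gr <- rowRanges(panel)[idx]
  ord <- order(as.character(seqnames(gr)), start(gr))
  idx <- idx[ord]
  pos <- start(gr)[ord]; chr <- as.character(seqnames(gr))[ord]
  m <- length(idx)
  if (m <= 1L) return(rownames(panel)[idx])
  R <- .rowCorMatrix(dosages(panel)[idx, , drop = FALSE])
  keep <- rep(TRUE, m)
  for (i in seq_len(m - 1L)) {
    if (!keep[i]) next
    j <- i + 1L
    while (j <= m && chr[j] == chr[i] && pos[j] - pos[i] <= windowBp) {
      if (keep[j]) {
        r <- sum(R[i, ] * R[j, ])
        if (r * r > r2) keep[j] <- FALSE   # drop the later-position variant
      }
      j <- j + 1L
    }
  }
  rownames(panel)[idx[keep]]
}

#' Label clumped associations against simulation truth
#'
#' A clump-index NIM is a true positive when any causal NIM lies within the
#' window of \code{regionBp} surrounding it (the index +/- regionBp/2).
#'
#' @param assoc a clumped \linkS4class{AssocResult}.
#' @param panel the panel.
#' @param truth a \linkS4class{PhenotypeTruth}.
#' @param regionBp surrounding-region size (default 200 kb).
#' @return List with \code{labels} (data.frame id, tp), \code{tp},
#'   \code{fp} and \code{fdp} (NA when there are no discoveries).
#' @export
associationFdp <- function(assoc, panel, truth, regionBp = 2e5) {
  stopifnot(is(assoc, "AssocResult"), is(truth, "PhenotypeTruth"))
  indices <- unique(assoc@clumps$index)
  if (!length(indices))
    return(list(labels = data.frame(id = character(), tp = logical()),
                tp = 0L, fp = 0L, fdp = NA_real_))
  anc <- ancestry(panel)
  causalNim <- truth@causalIds[anc[match(truth@causalIds, rownames(panel))] == "NIM"]
  cIdx <- match(causalNim, rownames(panel))
  cPos <- start(rowRanges(panel))[cIdx]
  cChr <- as.character(seqnames(rowRanges(panel)))[cIdx]
  iIdx <- match(indices, rownames(panel))
  iPos <- start(rowRanges(panel))[iIdx]
  iChr <- as.character(seqnames(rowRanges(panel)))[iIdx]
  tp <- vapply(seq_along(indices), function(i) {
    any(cChr == iChr[i] & abs(cPos - iPos[i]) <= regionBp / 2)
  }, logical(1))
  list(labels = data.frame(id = indices, tp = tp),
       tp = sum(tp), fp = sum(!tp), fdp = mean(!tp))
}
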