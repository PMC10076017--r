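#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: conditional on the minor-allele count, the p-value
#' is the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param nAA,nAa,naa integer vectors of genotype counts (homozygous
#'   reference, heterozygous, homozygous alternate).
#' @return Numeric vector of exact p-values.
#' @examples
#' hweExactTest(5, 0, 5)   # strong heterozygote deficit
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(length(nAA) == length(nAa), length(nAa) == length(naa))
  mapply(function(a, h, b) {
    n <- a + h + b
    if (n == 0L) return(1)
    nMinor <- 2L * min(a, b) + h
    ## all heterozygote counts compatible with the allele counts
    hs <- seq(nMinor %% 2L, min(nMinor, 2L * n - nMinor), by = 2L)
    homMin <- (nMinor - hs) %/% 2L
    homMaj <- n - hs - homMin
    logp <- lgamma(n + 1) - lgamma(homMin + 1) - lgamma(hs + 1) -
      lgamma(homMaj + 1) + hs * log(2) +
      lgamma(nMinor + 1) + lgamma(2 * n - nMinor + 1) - lgamma(2 * n + 1)
    pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
    pObs <- pr[match(h, hs)]
    sum(pr[pr <= pObs * (1 + 1e-12)])
  }, as.integer(nAA), as.integer(nAa), as.integer(naa))
}

#' Quality-control mask for a panel
#'
#' A variant passes QC when its MAF exceeds \code{mafMin}, the
#' Hardy-Weinberg exact p-value exceeds \code{hwePMin}, its non-missing
#' fraction is at least \code{callRateMin}, and it lies outside every
#' exclusion region.
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param mafMin minimum minor allele frequency (exclusive bound).
#' @param hwePMin minimum HWE exact p-value (exclusive bound).
#' @param callRateMin minimum non-missing genotype fraction.
#' @param excludeRegions optional exclusion intervals: a
#'   \link[GenomicRanges]{GRanges}, or a data.frame in BED convention
#'   (columns chrom, start, end; 0-based half-open).
#' @return Logical mask over variants.
#' @seealso [applyQc()]
#' @export
qcFilter <- function(panel, mafMin = 0.001, hwePMin = 1e-7,
                     callRateMin = 0.99, excludeRegions = NULL) {
  stopifnot(is(panel, "NimPanel"))
  D <- dosages(panel)
  nObs <- rowSums(!is.na(D))
  callRate <- nObs / ncol(D)
  af <- rowMeans(D, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  nAa <- rowSums(D == 1L, na.rm = TRUE)
  naa <- rowSums(D == 0L, na.rm = TRUE)
  nAA <- nObs - nAa - naa
  hwe <- rep(1, nrow(D))
  poly <- maf > 0 & !is.nan(maf)
  hwe[poly] <- hweExactTest(nAA[poly], nAa[poly], naa[poly])
  mask <- !is.nan(maf) & maf > mafMin & hwe > hwePMin & callRate >= callRateMin
  if (!is.null(excludeRegions)) {
    if (is.data.frame(excludeRegions))
      excludeRegions <- GRanges(as.character(excludeRegions[[1]]),
                                IRanges(start = excludeRegions[[2]] + 1L,
                                        end = excludeRegions[[3]]))
    hit <- IRanges::overlapsAny(rowRanges(panel), excludeRegions,
                                ignore.strand = TRUE)
    mask <- mask & !hit
  }
  unname(mask)
}

#' Apply a QC mask to a panel
#'
#' Records the mask in the \code{qcPass} variant column and refreshes allele
#' frequencies; downstream estimation uses only QC-passing variants.
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param mask logical mask as returned by [qcFilter()]; computed with
#'   default settings when missing.
#' @param ... passed to [qcFilter()] when \code{mask} is missing.
#' @return The updated panel.
#' @export
applyQc <- function(panel, mask = NULL, ...) {
  if (is.null(mask)) mask <- qcFilter(panel, ...)
  stopifnot(length(mask) == nrow(panel))
  mcols(rowRanges(panel))$qcPass <- mask
  panel
}

## Row-standardized (unit-norm, centered) dosage matrix for correlation
## computations; missing entries are mean-imputed per variant.
.rowCorMatrix <- function(D) {
  D <- as.matrix(D); storage.mode(D) <- "double"
  if (anyNA(D)) {
    mu <- rowMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 1L]]
  }
  D <- D - rowMeans(D)
  nrm <- sqrt(rowSums(D * D))
  if (any(nrm == 0))
    stop("zero-variance variant encountered; run QC first (rows ",
         paste(utils::head(which(nrm == 0), 5L), collapse = ", "), ")")
  D / nrm
}

#' Windowed LD scores
#'
#' The LD score of variant i is the sum of squared Pearson correlations
#' r2(i, j) over all variants j on the same chromosome within
#' \code{windowBp} of i, including the self term (so every score is >= 1).
#' Scores are computed over QC-passing variants and stored in the
#' \code{ldScore} variant column; non-QC variants keep NA.
#'
#' @param panel a \linkS4class{NimPanel} with sorted positions.
#' @param windowBp physical window (default 10 Mb).
#' @param chunkSize variants per block in the blocked correlation product.
#' @return The panel with \code{ldScore} filled in.
#' @export
computeLdScores <- function(panel, windowBp = 1e7, chunkSize = 512L) {
  stopifnot(is(panel, "NimPanel"))
  keep <- which(qcPass(panel))
  ld <- rep(NA_real_, nrow(panel))
  gr <- rowRanges(panel)
  for (ch in unique(as.character(seqnames(gr)[keep]))) {
    sel <- keep[as.character(seqnames(gr)[keep]) == ch]
    pos <- start(gr)[sel]
    if (is.unsorted(pos)) stop("positions must be sorted within chromosome")
    R <- .rowCorMatrix(dosages(panel)[sel, , drop = FALSE])
    m <- length(sel)
    out <- numeric(m)
    for (lo in seq(1L, m, by = chunkSize)) {
      hi <- min(lo + chunkSize - 1L, m)
      wLo <- findInterval(pos[lo] - windowBp, pos) + 1L
      wHi <- findInterval(pos[hi] + windowBp, pos)
      r <- tcrossprod(R[lo:hi, , drop = FALSE], R[wLo:wHi, , drop = FALSE])
      r2 <- r * r
      ## zero out pairs outside each row's own window
      wpos <- pos[wLo:wHi]
      for (i in seq_len(hi - lo + 1L)) {
        ok <- abs(wpos - pos[lo + i - 1L]) <= windowBp
        out[lo + i - 1L] <- sum(r2[i, ok])
      }
    }
    ld[sel] <- out
  }
  mcols(rowRanges(panel))$ldScore <- ld
  panel
}

#' Expand a confident NIM set through tight LD
#'
#' A QC-passing variant joins the expanded NIM set when it lies within
#' \code{windowBp} of a confident NIM on the same chromosome and has
#' squared correlation at least \code{r2Min} with it. Confident NIMs are
#' always included.
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param confident character ids of confident NIMs (subset of QC variants).
#' @param r2Min squared-correlation threshold (default 0.99).
#' @param windowBp physical window (default 200 kb).
#' @return Character ids of the expanded NIM set.
#' @seealso [setNimAncestry()] to relabel the panel accordingly.
#' @export
expandNims <- function(panel, confident, r2Min = 0.99, windowBp = 2e5) {
  stopifnot(is(panel, "NimPanel"))
  ids <- rownames(panel)
  cIdx <- match(confident, ids)
  if (anyNA(cIdx)) stop("confident ids missing from panel")
  keep <- which(qcPass(panel))
  gr <- rowRanges(panel)
  extra <- integer(0)
  for (ch in unique(as.character(seqnames(gr)[cIdx]))) {
    conf <- cIdx[as.character(seqnames(gr)[cIdx]) == ch]
    cand <- setdiff(keep[as.character(seqnames(gr)[keep]) == ch], conf)
    if (!length(cand)) next
    near <- abs(outer(start(gr)[cand], start(gr)[conf], "-")) <= windowBp
    test <- which(rowSums(near) > 0)
    if (!length(test)) next
    Rc <- .rowCorMatrix(dosages(panel)[conf, , drop = FALSE])
    Rt <- .rowCorMatrix(dosages(panel)[cand[test], , drop = FALSE])
    r2 <- tcrossprod(Rt, Rc)^2
    hit <- rowSums(r2 >= r2Min & near[test, , drop = FALSE]) > 0
    extra <- c(extra, cand[test][hit])
  }
  ids[sort(unique(c(cIdx, extra)))]
}

#' Relabel panel ancestry from an NIM id set
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param nimIds character ids to label NIM; all others become MH.
#' @return The updated panel.
#' @export
setNimAncestry <- function(panel, nimIds) {
  anc <- ifelse(rownames(panel) %in% nimIds, "NIM", "MH")
  mcols(rowRanges(panel))$ancestry <- factor(anc, levels = c("NIM", "MH"))
  panel
}

## Equal-sized quantile bins with deterministic (value, chrom, pos)
## tie-breaking.
.quantileBins <- function(value, chrom, pos, nBins) {
  if (length(unique(value)) < nBins)
    stop("cannot form ", nBins, " quantile bins from ",
         length(unique(value)), " distinct values")
  r <- order(order(value, chrom, pos))
  as.integer(ceiling(r * nBins / length(value)))
}

#' Build an annotation partition
#'
#' Intersects the ancestry annotation (NIM vs MH) with quantile bins of
#' per-variant annotations. Quantile boundaries are computed jointly over
#' all QC-passing variants (not per ancestry class); the intersected bins
#' are then formed and any bin with fewer than \code{minSnps} variants is
#' dropped in its entirety, its variants excluded from downstream
#' estimation.
#'
#' @param panel a \linkS4class{NimPanel} (or the data.frame from
#'   [variantTable()], which must then contain any extra annotation
#'   columns).
#' @param schemes named integer vector of annotations to bin, e.g.
#'   \code{c(maf = 5, ld = 5)}. Supported names: \code{maf}, \code{ld}, or
#'   any numeric column of the variant table (e.g. a B-value column).
#'   An empty vector gives the ancestry-only partition.
#' @param minSnps minimum bin size (default 30).
#' @param dropUnmatched also drop NIM bins whose matched MH bin (same
#'   quantile labels) did not survive the size filter, so that the
#'   matched-background contrast is always computable (default FALSE).
#' @return An \linkS4class{AnnotationPartition}.
#' @export
buildPartition <- function(panel, schemes = c(maf = 5, ld = 5),
                           minSnps = 30L, dropUnmatched = FALSE) {
  vt <- if (is(panel, "NimPanel")) variantTable(panel) else panel
  vt <- vt[vt$qcPass, , drop = FALSE]
  if (!nrow(vt)) stop("no QC-passing variants")
  cols <- list(ancestry = vt$ancestry)
  if (length(schemes)) {
    if (is.null(names(schemes)) || any(names(schemes) == ""))
      stop("schemes must be a named vector, e.g. c(maf = 5, ld = 5)")
    for (nm in names(schemes)) {
      val <- switch(nm, maf = vt$maf, ld = vt$ldScore, vt[[nm]])
      if (is.null(val)) stop("unknown annotation '", nm, "'")
      if (anyNA(val)) stop("annotation '", nm, "' has missing values; ",
                           if (nm == "ld") "run computeLdScores() first" else "")
      cols[[nm]] <- .quantileBins(val, vt$chrom, vt$pos, as.integer(schemes[nm]))
    }
  }
  key <- interaction(cols, drop = TRUE, sep = ".", lex.order = TRUE)
  sizes <- table(key)
  dropNames <- names(sizes)[sizes < minSnps]
  if (dropUnmatched && length(schemes)) {
    ## a NIM bin is orphaned when its quantile-matched MH bin is dropped
    survive <- setdiff(names(sizes), dropNames)
    quant <- sub("^(NIM|MH)\\.", "", survive)
    ancCls <- sub("\\..*$", "", survive)
    orphan <- survive[ancCls == "NIM" & !(quant %in% quant[ancCls == "MH"])]
    dropNames <- c(dropNames, orphan)
  }
  dropped <- data.frame(label = dropNames,
                        size = as.integer(sizes[dropNames]),
                        row.names = NULL)
  keepMask <- !(as.character(key) %in% dropNames)
  keyKept <- droplevels(key[keepMask])
  labs <- levels(keyKept)
  parts <- strsplit(labs, ".", fixed = TRUE)
  labels <- data.frame(bin = labs,
                       ancestry = vapply(parts, `[`, "", 1L),
                       row.names = NULL)
  if (length(schemes))
    for (i in seq_along(schemes))
      labels[[paste0(names(schemes)[i], "_q")]] <-
        as.integer(vapply(parts, `[`, "", i + 1L))
  assignment <- as.integer(keyKept)
  names(assignment) <- vt$id[keepMask]
  new("AnnotationPartition", assignment = assignment, labels = labels,
      sizes = as.integer(table(keyKept)), dropped = dropped,
      minSnps = as.integer(minSnps),
      schemes = if (length(schemes)) names(schemes) else character(0))
}
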