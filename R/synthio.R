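#' Create a synthetic panel configuration
#'
#' Returns a \linkS4class{PanelConfig}. Called with no arguments it yields
#' the package's default calibration configuration: 2,000 diploid
#' individuals and roughly 20,000 variants on a 250 Mb chromosome, with 30
#' introgressed segments whose NIM clusters reproduce the low-MAF /
#' high-LD-score profile characteristic of Neanderthal-introgressed
#' variation (mean NIM MAF near 0.039 and mean NIM LD score near 170, vs
#' roughly 0.099 and 65 for the modern-human background).
#'
#' @param nIndividuals,nMhSnps,nSegments,segmentLengthBp,nimsPerSegment,nimsDispersion,introFreqShape,mhMafShape,blockDecay,erodedFraction,anchorsPerSegment,anchorExtraShape,mhBlockFraction,mhBlockSize,mhBlockSizeDispersion,mhBlockDecay,mhBlockSpanBp,genomeLengthBp,seed
#'   see \linkS4class{PanelConfig}.
#' @return A validated \linkS4class{PanelConfig}.
#' @examples
#' cfg <- panelConfig(nIndividuals = 100, nMhSnps = 200, nSegments = 2,
#'                    nimsPerSegment = 10, seed = 1)
#' @export
panelConfig <- function(nIndividuals = 2000L,
                        nMhSnps = 14800L,
                        nSegments = 30L,
                        segmentLengthBp = 5e4,
                        nimsPerSegment = 159,
                        nimsDispersion = 0.2,
                        introFreqShape = c(0.9, 22.1),
                        mhMafShape = c(1.35, 11.8),
                        blockDecay = 0.05,
                        erodedFraction = 0.35,
                        anchorsPerSegment = 40,
                        anchorExtraShape = c(1.5, 9),
                        mhBlockFraction = 0.85,
                        mhBlockSize = 78,
                        mhBlockSizeDispersion = 0.5,
                        mhBlockDecay = 0.12,
                        mhBlockSpanBp = 6e4,
                        genomeLengthBp = 2.5e8,
                        seed = 1L) {
  new("PanelConfig",
      nIndividuals = as.integer(nIndividuals), nMhSnps = as.integer(nMhSnps),
      nSegments = as.integer(nSegments), segmentLengthBp = segmentLengthBp,
      nimsPerSegment = nimsPerSegment, nimsDispersion = nimsDispersion,
      introFreqShape = introFreqShape, mhMafShape = mhMafShape,
      blockDecay = blockDecay, erodedFraction = erodedFraction,
      anchorsPerSegment = anchorsPerSegment,
      anchorExtraShape = anchorExtraShape,
      mhBlockFraction = mhBlockFraction, mhBlockSize = mhBlockSize,
      mhBlockSizeDispersion = mhBlockSizeDispersion,
      mhBlockDecay = mhBlockDecay, mhBlockSpanBp = mhBlockSpanBp,
      genomeLengthBp = genomeLengthBp, seed = as.integer(seed))
}

## Dosage vector (length n) from a set of carrier haplotype indices among
## 1..2n; haplotypes (2i-1, 2i) belong to individual i.
.dosageFromHapSet <- function(hapIdx, n) {
  tabulate((hapIdx + 1L) %/% 2L, nbins = n)
}

## Draw a carrier haplotype subset: each of 1..nH independently w.p. f.
.drawCarriers <- function(nH, f) which(stats::runif(nH) < f)

## Permuted stratified uniforms: one draw per stratum of (0,1), jittered
## around the stratum midpoint. The bounded jitter keeps the extreme
## strata away from the distribution tails, where a heavy-tailed Beta
## would otherwise reintroduce large Monte-Carlo error.
.stratUnif <- function(k) {
  (sample(k) - 0.5 + 0.5 * (stats::runif(k) - 0.5)) / k
}

#' Simulate a genotype panel with introgressed-block structure
#'
#' Generates diploid genotypes on a single synthetic chromosome. Each
#' introgressed segment draws a carrier haplotype set at a low frequency;
#' NIMs inside the segment are carried by a (noise-perturbed) subset of the
#' carriers, producing the strong within-segment LD typical of introgressed
#' haplotypes. Haplotype-anchored MH SNPs near segments contain the carrier
#' set plus extra haplotypes, giving moderate NIM-MH LD (an introgressed
#' haplotype nested within an older modern-human allele background). The
#' remaining modern-human background is organised into LD blocks plus
#' independent sites so that the MH class, too, has a realistic LD-score
#' distribution.
#'
#' @param config a \linkS4class{PanelConfig}.
#' @param keepHaplotypes retain the phased haplotype matrix (memory: 2n x
#'   variants integers).
#' @return A \linkS4class{NimPanel}; the configuration is stored in
#'   \code{metadata()$config}.
#' @examples
#' p <- simulateGenotypes(panelConfig(nIndividuals = 50, nMhSnps = 100,
#'                                    nSegments = 2, nimsPerSegment = 8,
#'                                    seed = 7))
#' table(ancestry(p))
#' @export
simulateGenotypes <- function(config, keepHaplotypes = FALSE) {
  stopifnot(is(config, "PanelConfig"))
  validObject(config)
  .withSeed(config@seed, .simulateGenotypesImpl(config, keepHaplotypes))
}

.simulateGenotypesImpl <- function(config, keepHaplotypes) {
  n <- config@nIndividuals
  nH <- 2L * n
  G <- config@genomeLengthBp

  segs <- list()
  if (config@nSegments > 0) {
    sdl <- 0.4
    len <- round(config@segmentLengthBp *
                   stats::rlnorm(config@nSegments, -sdl^2 / 2, sdl))
    len <- pmax(len, 1000)
    if (sum(len) >= G)
      stop("segment placement overflows genome length; reject config")
    gaps <- stats::runif(config@nSegments + 1L)
    gaps <- gaps / sum(gaps) * (G - sum(len))
    starts <- round(cumsum(gaps[seq_len(config@nSegments)]) +
                      cumsum(c(0, len[-config@nSegments])))
    starts <- pmax(starts, 1)
    ## stratified draws of per-segment frequency and NIM count: inverse-CDF
    ## at permuted stratified uniforms keeps the marginal distributions but
    ## shrinks the Monte-Carlo error of panel-level moments
    S <- config@nSegments
    fAll <- pmin(0.5, stats::qbeta(.stratUnif(S), config@introFreqShape[1],
                                   config@introFreqShape[2]))
    mAll <- if (config@nimsDispersion > 0)
      pmax(1L, round(stats::qlnorm(.stratUnif(S),
        log(config@nimsPerSegment) - config@nimsDispersion^2 / 2,
        config@nimsDispersion)))
    else rep(max(1L, round(config@nimsPerSegment)), S)
    for (s in seq_len(config@nSegments)) {
      f <- fAll[s]
      carriers <- .drawCarriers(nH, f)
      m <- mAll[s]
      segEnd <- starts[s] + len[s] - 1
      posN <- sort(round(stats::runif(m, starts[s], segEnd)))
      core <- stats::runif(m) >= config@erodedFraction
      q <- ifelse(core | config@blockDecay == 0, 1,
                  1 - stats::runif(m, 0, 2 * config@blockDecay))
      nimHaps <- lapply(seq_len(m), function(i) {
        if (q[i] >= 1 || length(carriers) == 0L) carriers
        else carriers[stats::runif(length(carriers)) < q[i]]
      })
      nAnch <- stats::rpois(1, config@anchorsPerSegment)
      anchHaps <- list(); posA <- integer(0)
      if (nAnch > 0) {
        posA <- sort(round(stats::runif(nAnch,
          max(1, starts[s] - len[s]), min(G, segEnd + len[s]))))
        nonCarriers <- setdiff(seq_len(nH), carriers)
        anchHaps <- lapply(seq_len(nAnch), function(i) {
          g <- stats::rbeta(1, config@anchorExtraShape[1], config@anchorExtraShape[2])
          c(carriers, nonCarriers[stats::runif(length(nonCarriers)) < g])
        })
      }
      segs[[s]] <- list(pos = c(posN, posA),
                        haps = c(nimHaps, anchHaps),
                        anc = c(rep("NIM", m), rep("MH", nAnch)),
                        cls = c(rep("nim", m), rep("anchor", nAnch)),
                        segment = s)
    }
  }
  nAnchTotal <- sum(vapply(segs, function(s) sum(s$cls == "anchor"), 0L))
  nBg <- max(0L, config@nMhSnps - nAnchTotal)

  bg <- list()
  nBlockSnps <- round(config@mhBlockFraction * nBg)
  sizes <- integer(0); placed <- 0L
  while (placed < nBlockSnps) {
    size <- max(2L, round(stats::rlnorm(1,
      log(config@mhBlockSize) - config@mhBlockSizeDispersion^2 / 2,
      config@mhBlockSizeDispersion)))
    size <- min(size, nBlockSnps - placed + 1L)
    sizes <- c(sizes, size)
    placed <- placed + size
  }
  nBlocks <- length(sizes)
  if (nBlocks > 0) {
    ## stratified block frequencies (see segment draws above)
    Fb <- stats::qbeta(.stratUnif(nBlocks), config@mhMafShape[1],
                       config@mhMafShape[2])
    for (b in seq_len(nBlocks)) {
      size <- sizes[b]
      span <- max(5e3, stats::rexp(1, 1 / config@mhBlockSpanBp))
      st <- round(stats::runif(1, 1, max(1, G - span)))
      carriers <- .drawCarriers(nH, Fb[b])
      q <- 1 - stats::runif(size, 0, 2 * config@mhBlockDecay)
      haps <- lapply(seq_len(size), function(i) {
        if (q[i] >= 1 || length(carriers) == 0L) carriers
        else carriers[stats::runif(length(carriers)) < q[i]]
      })
      bg[[b]] <- list(pos = sort(round(stats::runif(size, st, st + span))),
                      haps = haps, anc = rep("MH", size),
                      cls = rep("mh_block", size), segment = NA_integer_)
    }
  }
  nSingle <- nBg - placed
  if (nSingle > 0) {
    posS <- round(stats::runif(nSingle, 1, G))
    Fs <- stats::qbeta(.stratUnif(nSingle), config@mhMafShape[1],
                       config@mhMafShape[2])
    hapsS <- lapply(seq_len(nSingle), function(i) .drawCarriers(nH, Fs[i]))
    bg[[length(bg) + 1L]] <- list(pos = posS, haps = hapsS,
                                  anc = rep("MH", nSingle),
                                  cls = rep("mh_single", nSingle),
                                  segment = NA_integer_)
  }

  all <- c(segs, bg)
  pos <- unlist(lapply(all, `[[`, "pos"), use.names = FALSE)
  anc <- unlist(lapply(all, `[[`, "anc"), use.names = FALSE)
  cls <- unlist(lapply(all, `[[`, "cls"), use.names = FALSE)
  segid <- unlist(lapply(all, function(x) rep(x$segment, length(x$pos))),
                  use.names = FALSE)
  haps <- do.call(c, lapply(all, `[[`, "haps"))
  p <- length(pos)
  if (p == 0L) stop("configuration produced no variants")

  ord <- order(pos)
  pos <- pos[ord]; anc <- anc[ord]; cls <- cls[ord]; segid <- segid[ord]
  haps <- haps[ord]
  ## enforce strictly increasing 1-based positions
  for (i in which(diff(pos) <= 0)) pos[i + 1L] <- pos[i] + 1L
  if (is.unsorted(pos, strictly = TRUE)) {   # rare long runs of ties
    while (any(d <- diff(pos) <= 0)) pos[which(d) + 1L] <- pos[which(d)] + 1L
  }

  D <- matrix(0L, nrow = p, ncol = n)
  for (i in seq_len(p)) D[i, ] <- .dosageFromHapSet(haps[[i]], n)

  H <- NULL
  if (keepHaplotypes) {
    H <- matrix(0L, nrow = p, ncol = nH)
    for (i in seq_len(p)) H[i, haps[[i]]] <- 1L
  }

  ids <- paste0(ifelse(anc == "NIM", "nim", ifelse(cls == "anchor", "anc", "mh")),
                "_", seq_len(p))
  vt <- data.frame(chrom = "1", pos = pos, id = ids, ancestry = anc)
  panel <- NimPanel(D, vt, haplotypes = H)
  mcols(rowRanges(panel))$segment <- segid
  mcols(rowRanges(panel))$class <- cls
  metadata(panel)$config <- config
  panel
}

#' Construct an architecture specification
#'
#' @param name one of BASELINE, COMMON, RARE, LOW, HIGH, ULTRA_RARE.
#' @param nCausal number of causal variants.
#' @param h2 target heritability.
#' @param enrichedFraction fraction of causal variants drawn from the
#'   enriched class (default 0.9; forced to 0 for BASELINE).
#' @return An \linkS4class{ArchitectureSpec}.
#' @export
architectureSpec <- function(name, nCausal, h2, enrichedFraction = 0.9) {
  name <- match.arg(name, c("BASELINE", "COMMON", "RARE", "LOW", "HIGH",
                            "ULTRA_RARE"))
  if (name == "BASELINE") enrichedFraction <- 0
  new("ArchitectureSpec", name = name, enrichedFraction = enrichedFraction,
      nCausal = as.integer(nCausal), h2 = h2)
}

## Enriched-class membership predicate per architecture.
.enrichedClass <- function(name, maf, ldScore) {
  switch(name,
    COMMON = maf > 0.05,
    RARE = maf <= 0.05,
    ULTRA_RARE = maf < 0.01,
    LOW = ldScore <= 10,
    HIGH = ldScore > 10,
    stop("BASELINE has no enriched class"))
}

#' Select causal variants under a genetic architecture
#'
#' BASELINE draws a uniform random subset of QC-passing variants. Coupled
#' architectures draw round(enrichedFraction * nCausal) variants (round half
#' up) uniformly from the enriched class and the remainder from its
#' complement.
#'
#' @param variants a \linkS4class{NimPanel} or a data.frame with columns
#'   \code{id}, \code{maf}, \code{ldScore}, \code{qcPass}.
#' @param spec an \linkS4class{ArchitectureSpec}.
#' @param seed integer seed (selection is deterministic given the seed).
#' @return Character vector of causal variant ids.
#' @export
selectCausalVariants <- function(variants, spec, seed = 1L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  vt <- if (is(variants, "NimPanel")) variantTable(variants) else variants
  vt <- vt[vt$qcPass, , drop = FALSE]
  if (spec@nCausal > nrow(vt))
    stop("nCausal (", spec@nCausal, ") exceeds QC-passing variants (",
         nrow(vt), ")")
  .withSeed(seed, {
    if (spec@name == "BASELINE") {
      sample(vt$id, spec@nCausal)
    } else {
      if (spec@name %in% c("LOW", "HIGH") && anyNA(vt$ldScore))
        stop("LD scores required for ", spec@name,
             " architecture; run computeLdScores() first")
      inClass <- .enrichedClass(spec@name, vt$maf, vt$ldScore)
      nEnr <- floor(spec@enrichedFraction * spec@nCausal + 0.5)
      nOth <- spec@nCausal - nEnr
      if (sum(inClass) < nEnr)
        stop("enriched class '", spec@name, "' has only ", sum(inClass),
             " variants; ", nEnr, " required")
      if (sum(!inClass) < nOth)
        stop("complement of class '", spec@name, "' has only ",
             sum(!inClass), " variants; ", nOth, " required")
      c(sample(vt$id[inClass], nEnr), sample(vt$id[!inClass], nOth))
    }
  })
}

#' Simulate a phenotype under the additive model
#'
#' Draws i.i.d. standard-normal allelic effects for the causal variants,
#' forms genetic values g_j = sum_i w_ij beta_i on the standardized dosage
#' scale w_ij = (x_ij - 2 p_i) / sqrt(2 p_i (1 - p_i)), and adds residual
#' noise with variance Var(g) (1/h2 - 1) so that the in-sample
#' genetic-variance fraction equals the target h2. With h2 = 1 the residual
#' is identically zero.
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param causal character ids of causal variants (must be polymorphic).
#' @param h2 target heritability in (0, 1].
#' @param seed integer seed.
#' @return A \linkS4class{PhenotypeTruth}.
#' @export
simulatePhenotype <- function(panel, causal, h2, seed = 1L) {
  stopifnot(is(panel, "NimPanel"))
  if (h2 <= 0 || h2 > 1)
    stop("h2 must lie in (0, 1]; the residual-variance formula is undefined at h2 = 0")
  idx <- match(causal, rownames(panel))
  if (anyNA(idx)) stop("unknown causal ids: ", paste(utils::head(causal[is.na(idx)], 3), collapse = ", "))
  X <- t(dosages(panel)[idx, , drop = FALSE])
  storage.mode(X) <- "double"
  W <- .standardizeDosage(X)   # errors on monomorphic causal variants
  anc <- ancestry(panel)[idx]
  .withSeed(seed, {
    beta <- stats::rnorm(length(idx))
    g <- drop(W %*% beta)
    if (h2 < 1) {
      vg <- stats::var(g)
      eps <- stats::rnorm(length(g), 0, sqrt(vg * (1 / h2 - 1)))
    } else eps <- numeric(length(g))
    y <- unname(g + eps)
    h2nim <- sum(beta[anc == "NIM"]^2) / stats::var(y)
    new("PhenotypeTruth", y = y, causalIds = causal, beta = beta,
        trueH2 = h2, trueH2Nim = h2nim, seed = as.integer(seed))
  })
}

#' True NIM heritability of a simulated phenotype
#'
#' Sum of squared allelic effects over causal variants labelled NIM, divided
#' by the empirical phenotypic variance. Note that under strong LD among
#' causal variants the sum of squared standardized effects is the
#' variance-component estimand, which can differ from the realized genetic
#' variance.
#'
#' @param truth a \linkS4class{PhenotypeTruth}.
#' @param variants a \linkS4class{NimPanel} or variant data.frame with
#'   \code{id} and \code{ancestry}.
#' @return Proportion of phenotypic variance.
#' @export
trueNimH2 <- function(truth, variants) {
  stopifnot(is(truth, "PhenotypeTruth"))
  vt <- if (is(variants, "NimPanel")) variantTable(variants) else variants
  anc <- vt$ancestry[match(truth@causalIds, vt$id)]
  if (anyNA(anc)) stop("causal ids missing from the variant table")
  sum(truth@beta[anc == "NIM"]^2) / stats::var(truth@y)
}
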