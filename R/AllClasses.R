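#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges rowRanges<- colData
NULL

#' Synthetic panel configuration
#'
#' Parameters of the synthetic genotype generator that emulates the
#' haplotype-block structure of Neanderthal-introgressed variation. A panel
#' consists of introgressed segments carrying clusters of NIMs (Neanderthal
#' informative mutations) on a shared low-frequency carrier haplotype,
#' haplotype-anchored modern-human (MH) SNPs in moderate LD with those
#' segments, and a modern-human background organised into LD blocks plus
#' independent sites.
#'
#' The default configuration is the package's calibration target: it is tuned
#' once so that the generated NIM class approaches the empirically observed
#' contrasts between introgressed and modern-human variation (mean NIM MAF
#' near 3.9% vs 9.9% for MH SNPs; mean NIM LD score near 170 vs 65 for MH
#' SNPs, 10 Mb windows).
#'
#' @slot nIndividuals number of diploid individuals.
#' @slot nMhSnps number of modern-human (non-NIM) variants, including
#'   haplotype-anchored MH SNPs near introgressed segments.
#' @slot nSegments number of introgressed segments.
#' @slot segmentLengthBp mean segment length in base pairs.
#' @slot nimsPerSegment mean number of NIMs per segment.
#' @slot nimsDispersion log-scale SD of the per-segment NIM count
#'   (log-normal dispersion; 0 gives a fixed count).
#' @slot introFreqShape numeric(2); Beta shape parameters of the introgressed
#'   carrier-haplotype frequency distribution (concentrated below 0.1).
#' @slot mhMafShape numeric(2); Beta shape parameters of the modern-human
#'   base allele-frequency distribution (neutral-SFS-like).
#' @slot blockDecay per-NIM expected carrier-loss probability among eroded
#'   NIMs (LD-attenuation noise); 0 gives perfect within-segment LD.
#' @slot erodedFraction fraction of NIMs subject to carrier loss; the
#'   complement is carried by every carrier haplotype.
#' @slot anchorsPerSegment mean number of haplotype-anchored MH SNPs per
#'   segment (MH alleles that contain the carrier set, creating moderate
#'   NIM-MH LD as for an introgressed haplotype nested in an older
#'   modern-human background).
#' @slot anchorExtraShape numeric(2); Beta shapes of the extra
#'   (non-carrier) allele frequency of anchored MH SNPs.
#' @slot mhBlockFraction fraction of background MH SNPs organised into LD
#'   blocks (the rest are independent sites).
#' @slot mhBlockSize mean number of SNPs per MH LD block.
#' @slot mhBlockSizeDispersion log-scale SD of MH block sizes.
#' @slot mhBlockDecay mean per-SNP carrier-loss probability within MH blocks
#'   (controls within-block r2).
#' @slot mhBlockSpanBp mean physical span of an MH LD block.
#' @slot genomeLengthBp total simulated genome length (single chromosome).
#' @slot seed integer seed; all generator output is reproducible given the
#'   configuration.
#' @seealso [panelConfig()], [simulateGenotypes()]
#' @export
setClass("PanelConfig",
  representation(
    nIndividuals = "integer", nMhSnps = "integer", nSegments = "integer",
    segmentLengthBp = "numeric", nimsPerSegment = "numeric",
    nimsDispersion = "numeric", introFreqShape = "numeric",
    mhMafShape = "numeric", blockDecay = "numeric",
    erodedFraction = "numeric", anchorsPerSegment = "numeric",
    anchorExtraShape = "numeric", mhBlockFraction = "numeric",
    mhBlockSize = "numeric", mhBlockSizeDispersion = "numeric",
    mhBlockDecay = "numeric", mhBlockSpanBp = "numeric",
    genomeLengthBp = "numeric", seed = "integer"
  )
)

setValidity("PanelConfig", function(object) {
  msgs <- character()
  pos <- c(nIndividuals = object@nIndividuals, nMhSnps = object@nMhSnps,
           segmentLengthBp = object@segmentLengthBp,
           genomeLengthBp = object@genomeLengthBp)
  if (any(pos <= 0))
    msgs <- c(msgs, paste0("fields must be positive: ",
                           paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@nSegments < 0) msgs <- c(msgs, "nSegments must be >= 0")
  if (object@nSegments > 0 && object@nimsPerSegment <= 0)
    msgs <- c(msgs, "nimsPerSegment must be positive")
  for (nm in c("introFreqShape", "mhMafShape", "anchorExtraShape")) {
    v <- slot(object, nm)
    if (length(v) != 2 || any(v <= 0))
      msgs <- c(msgs, paste0(nm, " must be two positive Beta shapes"))
  }
  for (nm in c("blockDecay", "mhBlockDecay")) {
    v <- slot(object, nm)
    if (v < 0 || v > 0.5) msgs <- c(msgs, paste0(nm, " must lie in [0, 0.5]"))
  }
  for (nm in c("erodedFraction", "mhBlockFraction")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msgs <- c(msgs, paste0(nm, " must lie in [0, 1]"))
  }
  ## mean Beta frequencies must fall in (0, 0.5]
  mIntro <- object@introFreqShape[1] / sum(object@introFreqShape)
  if (mIntro > 0.5)
    msgs <- c(msgs, "mean introgression frequency must be <= 0.5")
  if (object@nSegments * object@segmentLengthBp * 5 > object@genomeLengthBp)
    msgs <- c(msgs, "genome too short for the requested segments")
  if (length(msgs)) msgs else TRUE
})

#' Genotype panel with introgression annotation
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a dosage matrix
#' (variants x individuals, values 0/1/2) in the \code{"dosage"} assay, with
#' per-variant metadata in \code{rowRanges()}: \code{ancestry} (factor,
#' \code{NIM}/\code{MH}), \code{af} (counted-allele frequency), \code{maf},
#' \code{ldScore} (NA until computed), \code{qcPass}, plus generator
#' book-keeping (\code{segment}). Phased haplotypes, when retained, live in
#' \code{metadata()$haplotypes} (variants x 2n, 0/1) and satisfy
#' dosage = hap1 + hap2.
#'
#' @seealso [simulateGenotypes()], [variantTable()], [dosages()]
#' @export
setClass("NimPanel", contains = "RangedSummarizedExperiment")

setValidity("NimPanel", function(object) {
  msgs <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  need <- c("ancestry", "af", "maf")
  miss <- setdiff(need, colnames(mcols(rowRanges(object))))
  if (length(miss))
    msgs <- c(msgs, paste0("rowRanges mcols missing: ", paste(miss, collapse = ", ")))
  rng <- range(d, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    msgs <- c(msgs, "dosages must lie in {0, 1, 2}")
  if ("maf" %in% colnames(mcols(rowRanges(object)))) {
    maf <- mcols(rowRanges(object))$maf
    if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
      msgs <- c(msgs, "maf must lie in [0, 0.5]")
  }
  hap <- metadata(object)$haplotypes
  if (!is.null(hap)) {
    if (ncol(hap) != 2L * ncol(d) || nrow(hap) != nrow(d))
      msgs <- c(msgs, "haplotypes must be variants x 2n")
    else {
      idx <- seq_len(min(nrow(d), 50L))
      dd <- hap[idx, seq(1, 2 * ncol(d), 2), drop = FALSE] +
        hap[idx, seq(2, 2 * ncol(d), 2), drop = FALSE]
      if (!isTRUE(all.equal(unname(dd), unname(d[idx, , drop = FALSE]))))
        msgs <- c(msgs, "dosage must equal the sum of the two haplotypes")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulated phenotype with ground truth
#'
#' Result of the additive phenotype model y_j = sum_i w_ij beta_i + eps_j
#' with w_ij = (x_ij - 2 p_i) / sqrt(2 p_i (1 - p_i)). Records the causal
#' variants, their allelic effects, the target heritability and the true
#' NIM heritability sum(beta_NIM^2) / Var(y).
#'
#' @slot y numeric phenotype vector (unstandardized).
#' @slot causalIds character ids of causal variants.
#' @slot beta numeric per-causal effects on the standardized scale.
#' @slot trueH2 target heritability used to scale the residual variance.
#' @slot trueH2Nim realized NIM heritability.
#' @slot seed integer seed used.
#' @export
setClass("PhenotypeTruth",
  representation(y = "numeric", causalIds = "character", beta = "numeric",
                 trueH2 = "numeric", trueH2Nim = "numeric", seed = "integer"))

setValidity("PhenotypeTruth", function(object) {
  msgs <- character()
  if (length(object@causalIds) != length(object@beta))
    msgs <- c(msgs, "causalIds and beta must have equal length")
  ## Under strong LD among causal variants the sum of squared standardized
  ## effects (the variance-component estimand) can exceed the realized
  ## genetic variance, so the comparison against the target h2 is loose.
  if (object@trueH2Nim < 0)
    msgs <- c(msgs, "trueH2Nim must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Genetic architecture specification
#'
#' Defines how causal variants are drawn: BASELINE selects uniformly at
#' random; the MAF/LD-coupled architectures place 90% of causal variants in
#' an enriched class (COMMON: MAF > 0.05; RARE: MAF <= 0.05; LOW: LD score
#' <= 10; HIGH: LD score > 10; ULTRA_RARE: MAF < 0.01) and the remaining 10%
#' in its complement.
#'
#' @slot name architecture name.
#' @slot enrichedFraction proportion of causal variants in the enriched
#'   class (0.9 for non-BASELINE architectures).
#' @slot nCausal number of causal variants.
#' @slot h2 target heritability in [0, 1).
#' @seealso [architectureSpec()], [selectCausalVariants()]
#' @export
setClass("ArchitectureSpec",
  representation(name = "character", enrichedFraction = "numeric",
                 nCausal = "integer", h2 = "numeric"))

setValidity("ArchitectureSpec", function(object) {
  msgs <- character()
  if (!object@name %in% c("BASELINE", "COMMON", "RARE", "LOW", "HIGH", "ULTRA_RARE"))
    msgs <- c(msgs, "unknown architecture name")
  if (object@enrichedFraction < 0 || object@enrichedFraction > 1)
    msgs <- c(msgs, "enrichedFraction must lie in [0, 1]")
  if (object@nCausal < 1) msgs <- c(msgs, "nCausal must be >= 1")
  if (object@h2 < 0 || object@h2 >= 1) msgs <- c(msgs, "h2 must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Annotation partition of QC-passing variants
#'
#' Assignment of retained variants to disjoint annotation bins formed by
#' intersecting ancestry (NIM/MH) with quantile bins of MAF, LD score and
#' optional extra annotations. Quantile boundaries are computed jointly over
#' all QC-passing variants; intersected bins smaller than \code{minSnps} are
#' dropped in their entirety and their variants excluded from estimation.
#'
#' @slot assignment named integer vector mapping retained variant ids to bin
#'   indices (rows of \code{labels}).
#' @slot labels data.frame with one row per retained bin: \code{bin},
#'   \code{ancestry} and one quantile column per scheme annotation.
#' @slot sizes integer bin sizes (same order as \code{labels}).
#' @slot dropped data.frame of dropped bins (label string, size).
#' @slot minSnps minimum bin size.
#' @slot schemes character annotations used (e.g. \code{c("maf","ld")}).
#' @export
setClass("AnnotationPartition",
  representation(assignment = "integer", labels = "data.frame",
                 sizes = "integer", dropped = "data.frame",
                 minSnps = "integer", schemes = "character"))

setValidity("AnnotationPartition", function(object) {
  msgs <- character()
  if (nrow(object@labels) != length(object@sizes))
    msgs <- c(msgs, "labels and sizes disagree")
  if (length(object@assignment) &&
      !all(object@assignment %in% seq_len(nrow(object@labels))))
    msgs <- c(msgs, "assignment refers to unknown bins")
  tab <- tabulate(object@assignment, nbins = nrow(object@labels))
  if (length(object@sizes) && !all(tab == object@sizes))
    msgs <- c(msgs, "bin sizes do not match assignment counts")
  if (length(object@sizes) && any(object@sizes < object@minSnps))
    msgs <- c(msgs, "retained bin below minSnps")
  if (length(msgs)) msgs else TRUE
})

#' Variance-component estimates with jackknife uncertainty
#'
#' Output of the multi-component method-of-moments estimator: per-bin
#' variance components and heritabilities, the NIM aggregate h2_NIM, the
#' bin-size-weighted matched modern-human background h2_MH, their difference
#' delta-h2, and a delete-one-block jackknife covariance over per-bin
#' heritabilities with replicate statistics for derived quantities.
#'
#' @slot sigma2 named numeric; per-bin variance components plus "noise".
#' @slot h2PerBin per-bin heritabilities sigma2_k / Var(y).
#' @slot h2Total total genetic heritability estimate.
#' @slot h2Nim aggregate NIM heritability (sum over NIM bins).
#' @slot h2MhMatched matched MH background heritability.
#' @slot deltaH2 h2Nim - h2MhMatched.
#' @slot se named numeric standard errors (h2Total, h2Nim, h2MhMatched,
#'   deltaH2).
#' @slot z named numeric Z-scores (h2NimVsZero, h2NimVsTruth, deltaVsZero).
#' @slot p named numeric p-values (one-sided for h2Nim > 0, two-sided for
#'   delta-h2 = 0).
#' @slot jackknifeCov covariance matrix of per-bin heritabilities.
#' @slot jackknife matrix of per-replicate per-bin heritabilities
#'   (blocks x bins), from which derived statistics are re-propagated.
#' @slot varY phenotypic variance used for normalization.
#' @slot partition the \linkS4class{AnnotationPartition} used.
#' @slot trueH2Nim optional truth used for the truth-centred Z.
#' @export
setClass("ComponentEstimates",
  representation(sigma2 = "numeric", h2PerBin = "numeric", h2Total = "numeric",
                 h2Nim = "numeric", h2MhMatched = "numeric", deltaH2 = "numeric",
                 se = "numeric", z = "numeric", p = "numeric",
                 jackknifeCov = "matrix", jackknife = "matrix",
                 varY = "numeric", partition = "AnnotationPartition",
                 trueH2Nim = "numeric"))

#' Random-effects meta-analysis result
#'
#' DerSimonian-Laird pooling of per-phenotype estimates.
#'
#' @slot mean pooled estimate.
#' @slot tau2 between-phenotype variance (>= 0).
#' @slot se standard error of the pooled mean.
#' @slot z mean / se.
#' @slot k number of phenotypes pooled.
#' @export
setClass("MetaResult",
  representation(mean = "numeric", tau2 = "numeric", se = "numeric",
                 z = "numeric", k = "integer"))

setValidity("MetaResult", function(object) {
  msgs <- character()
  if (object@tau2 < 0) msgs <- c(msgs, "tau2 must be >= 0")
  if (object@k < 1) msgs <- c(msgs, "k must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Per-variant association scan result
#'
#' @slot table data.frame with columns id, chrom, pos, beta, se, p, tested
#'   (FALSE for variants collinear with the covariates).
#' @slot significant character ids passing the significance threshold.
#' @slot threshold the p-value threshold applied.
#' @slot clumps data.frame (index, member) once [clumpAssociations()] has run;
#'   empty before.
#' @export
setClass("AssocResult",
  representation(table = "data.frame", significant = "character",
                 threshold = "numeric", clumps = "data.frame"))

#' Greedy tag-SNP selection result
#'
#' @slot selected character ids in selection order.
#' @slot score numeric per-step score of each selected SNP.
#' @slot featuresUsed cumulative feature cost after each step.
#' @slot untagged character ids left untagged when the budget ran out.
#' @export
setClass("TagSelection",
  representation(selected = "character", score = "numeric",
                 featuresUsed = "numeric", untagged = "character"))
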