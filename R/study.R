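#' Generate and annotate a study panel
#'
#' Convenience wrapper: simulate genotypes, apply QC, compute LD scores.
#'
#' @param config a \linkS4class{PanelConfig}.
#' @param ... passed to [qcFilter()].
#' @return An annotated, QC-ed \linkS4class{NimPanel}.
#' @export
preparePanel <- function(config = panelConfig(), ...) {
  panel <- simulateGenotypes(config)
  panel <- applyQc(panel, ...)
  computeLdScores(panel)
}

#' Configuration of the simulation studies
#'
#' Defines the grid of simulated phenotypes: each architecture group runs
#' heritability in \code{h2} crossed with low/high polygenicity and
#' \code{replicates} replicates (the default grid gives 12 simulations per
#' architecture, 60 in total over the five architectures). Causal-variant
#' counts are scaled proportionally to the panel's QC-passing SNP count
#' from the biobank-scale reference counts of 10,000 (low polygenicity) and
#' 100,000 (high) out of 7,774,235 SNPs, with a floor of 10.
#'
#' @param architectures architecture names.
#' @param h2 heritability values.
#' @param polygenicity levels ("low", "high").
#' @param replicates replicates per cell.
#' @param seed master seed; per-simulation seeds derive deterministically.
#' @return A list with class \code{"StudyConfig"}.
#' @export
studyConfig <- function(architectures = c("BASELINE", "COMMON", "RARE",
                                          "LOW", "HIGH"),
                        h2 = c(0.2, 0.5),
                        polygenicity = c("low", "high"),
                        replicates = 3L, seed = 1L) {
  grid <- expand.grid(replicate = seq_len(replicates), h2 = h2,
                      polygenicity = polygenicity,
                      architecture = architectures,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("architecture", "h2", "polygenicity", "replicate")]
  grid$sim <- seq_len(nrow(grid))
  structure(list(grid = grid, seed = as.integer(seed)),
            class = "StudyConfig")
}

## Reference causal counts: 10k / 100k causal of 7,774,235 SNPs, scaled to
## the panel's QC-passing count with a floor of 10.
.scaledCausalCount <- function(pQc, polygenicity) {
  ref <- if (polygenicity == "low") 1e4 else 1e5
  max(10L, as.integer(round(pQc * ref / 7774235)))
}

## Simulate the phenotype for row i of the study grid (shared between the
## calibration and FDP suites so both see identical phenotypes).
.studyPhenotype <- function(panel, cfg, i) {
  row <- cfg$grid[i, ]
  pQc <- sum(qcPass(panel))
  nCausal <- .scaledCausalCount(pQc, row$polygenicity)
  spec <- architectureSpec(row$architecture, nCausal, row$h2)
  sCausal <- .childSeed(cfg$seed, 2L * i)
  sPheno <- .childSeed(cfg$seed, 2L * i + 1L)
  causal <- selectCausalVariants(panel, spec, seed = sCausal)
  truth <- simulatePhenotype(panel, causal, row$h2, seed = sPheno)
  truth
}

#' Run the heritability-calibration study
#'
#' For every simulated phenotype of the study grid, estimates variance
#' components under each annotation scheme and reports the Z-score against
#' the true NIM heritability, the matched-difference Z (delta-h2 = 0) and
#' its two-sided p-value. Causal selection is ancestry-blind, so the
#' matched difference is null by construction and the rejection rate at
#' p < 0.05 measures calibration.
#'
#' @param panel a prepared panel (see [preparePanel()]).
#' @param cfg a [studyConfig()].
#' @param schemes named list of annotation schemes (name -> vector for
#'   [buildPartition()]); the default compares ancestry-only, ancestry+MAF,
#'   ancestry+LD and ancestry+MAF+LD.
#' @param mode,probes,nBlocks passed to the variance-component model.
#' @param minSnps minimum bin size (default 30).
#' @param verbose print progress.
#' @return data.frame with one row per (simulation, scheme).
#' @export
runCalibrationStudy <- function(panel, cfg = studyConfig(),
                                schemes = list(
                                  ancestry = c(),
                                  ancestry_maf = c(maf = 5),
                                  ancestry_ld = c(ld = 5),
                                  ancestry_maf_ld = c(maf = 5, ld = 5)),
                                mode = "exact", probes = 100L,
                                nBlocks = 100L, minSnps = 30L,
                                verbose = FALSE) {
  stopifnot(inherits(cfg, "StudyConfig"))
  partitions <- lapply(schemes, function(s)
    buildPartition(panel, s, minSnps = minSnps, dropUnmatched = TRUE))
  .msg(verbose, "building ", length(partitions), " trace models (mode: ",
       mode, ")")
  models <- .vcModelMulti(panel, partitions, covariates = NULL, mode = mode,
                          probes = probes, nBlocks = nBlocks,
                          seed = .childSeed(cfg$seed, 0L))
  vt <- variantTable(panel)
  out <- list()
  for (i in seq_len(nrow(cfg$grid))) {
    row <- cfg$grid[i, ]
    truth <- .studyPhenotype(panel, cfg, i)
    .msg(verbose, "sim ", i, "/", nrow(cfg$grid), ": ", row$architecture,
         " h2=", row$h2, " poly=", row$polygenicity)
    for (s in names(models)) {
      ## truth restricted to the variants retained by this scheme
      retained <- names(binAssignment(partitions[[s]]))
      keep <- truth@causalIds %in% retained
      anc <- vt$ancestry[match(truth@causalIds, vt$id)]
      h2NimTrue <- sum(truth@beta[keep & anc == "NIM"]^2) / stats::var(truth@y)
      est <- estimateComponents(truth@y, model = models[[s]],
                                trueH2Nim = h2NimTrue)
      out[[length(out) + 1L]] <- data.frame(
        sim = row$sim, architecture = row$architecture, h2 = row$h2,
        polygenicity = row$polygenicity, replicate = row$replicate,
        scheme = s, h2Hat = est@h2Total, h2Nim = est@h2Nim,
        seNim = unname(est@se["h2Nim"]), trueH2Nim = h2NimTrue,
        zNimTruth = unname(est@z["h2NimVsTruth"]),
        zNimZero = unname(est@z["h2NimVsZero"]),
        delta = est@deltaH2, seDelta = unname(est@se["deltaH2"]),
        zDelta = unname(est@z["deltaVsZero"]),
        pDelta = unname(est@p["deltaVsZero"]))
    }
  }
  do.call(rbind, out)
}

#' Summarize calibration-study rejection rates
#'
#' @param tbl output of [runCalibrationStudy()].
#' @param alpha rejection level (default 0.05).
#' @return data.frame per scheme: number of simulations, rejection rate of
#'   the delta-h2 = 0 test, and the fraction of truth-centred |Z| <= 2.
#' @export
calibrationSummary <- function(tbl, alpha = 0.05) {
  do.call(rbind, lapply(split(tbl, tbl$scheme), function(d) {
    data.frame(scheme = d$scheme[1L], n = nrow(d),
               rejectionRate = mean(d$pDelta < alpha),
               fracZTruthWithin2 = mean(abs(d$zNimTruth) <= 2),
               fracZDeltaWithin2 = mean(abs(d$zDelta) <= 2))
  }))
}

#' Run the association / fine-mapping FDP study
#'
#' For every simulated phenotype: per-NIM association scan at the scaled
#' genome-wide threshold (0.05 / number of tested NIMs), LD clumping, and
#' true/false labelling of clump indices by the presence of a causal NIM in
#' the surrounding 200 kb region; then the credible-NIM pipeline
#' ([fineMapRegions()]) and its region-level FDP.
#'
#' @param panel a prepared panel.
#' @param cfg a [studyConfig()].
#' @param covariates optional covariates for the scan and fine-mapping.
#' @param threshold association threshold (default 0.05 / tested NIMs).
#' @param regionBp surrounding-region size for TP labelling (200 kb).
#' @param L,coverage,minPurity fine-mapper settings.
#' @param verbose print progress.
#' @return data.frame with one row per simulation.
#' @export
runFdpStudy <- function(panel, cfg = studyConfig(), covariates = NULL,
                        threshold = NULL, regionBp = 2e5, L = 10L,
                        coverage = 0.95, minPurity = 0.5, verbose = FALSE) {
  stopifnot(inherits(cfg, "StudyConfig"))
  out <- list()
  for (i in seq_len(nrow(cfg$grid))) {
    row <- cfg$grid[i, ]
    truth <- .studyPhenotype(panel, cfg, i)
    assoc <- gwasLinear(truth@y, panel, covariates = covariates,
                        threshold = threshold)
    assoc <- clumpAssociations(assoc, panel)
    af <- associationFdp(assoc, panel, truth, regionBp = regionBp)
    fm <- fineMapRegions(truth@y, panel, assoc, covariates = covariates,
                         windowBp = regionBp, L = L, coverage = coverage,
                         minPurity = minPurity)
    ef <- evaluateFdp(fm$regions, truth, panel)
    .msg(verbose, "sim ", i, "/", nrow(cfg$grid), ": ", row$architecture,
         " h2=", row$h2, " poly=", row$polygenicity, " | sig=",
         length(assoc@significant), " clumps=", af$tp + af$fp,
         " assocFDP=", signif(af$fdp, 3), " regions=", length(fm$regions),
         " fmFDP=", signif(ef$fdp, 3))
    out[[length(out) + 1L]] <- data.frame(
      sim = row$sim, architecture = row$architecture, h2 = row$h2,
      polygenicity = row$polygenicity, replicate = row$replicate,
      nSignificant = length(assoc@significant),
      nClumps = af$tp + af$fp, assocFdp = af$fdp,
      nRegions = length(fm$regions), finemapFdp = ef$fdp,
      nCredibleNims = sum(mcols(fm$regions)$nCredibleNims),
      nTestedNims = length(fm$testedNims))
  }
  do.call(rbind, out)
}

#' Summarize the FDP study
#'
#' Mean FDPs across simulations with at least one discovery, per
#' architecture and overall.
#'
#' @param tbl output of [runFdpStudy()].
#' @return data.frame with rows per architecture plus "ALL".
#' @export
fdpSummary <- function(tbl) {
  summarise <- function(d, label) {
    data.frame(architecture = label,
               nSims = nrow(d),
               nWithAssoc = sum(!is.na(d$assocFdp)),
               assocFdp = mean(d$assocFdp, na.rm = TRUE),
               nWithRegions = sum(!is.na(d$finemapFdp)),
               finemapFdp = mean(d$finemapFdp, na.rm = TRUE))
  }
  rbind(do.call(rbind, lapply(split(tbl, tbl$architecture), function(d)
    summarise(d, d$architecture[1L]))),
    summarise(tbl, "ALL"))
}
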