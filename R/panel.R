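#' Construct a NimPanel
#'
#' Assemble a \linkS4class{NimPanel} from a dosage matrix and a variant
#' table. Rows are variants, columns are individuals, matching the
#' Bioconductor convention for genotype containers.
#'
#' @param dosage integer matrix (variants x individuals) with values 0/1/2
#'   (NA for missing).
#' @param variants a \link[GenomicRanges]{GRanges} (one range per variant,
#'   width 1) or a data.frame with columns \code{chrom}, \code{pos},
#'   \code{id}, \code{ancestry}; allele frequency and MAF are computed from
#'   the dosages when absent.
#' @param haplotypes optional phased 0/1 matrix (variants x 2n), columns
#'   ordered as (ind1 hapA, ind1 hapB, ind2 hapA, ...).
#' @param sampleIds optional character sample identifiers.
#' @return A \linkS4class{NimPanel}.
#' @examples
#' d <- matrix(rbinom(20, 2, 0.3), nrow = 4)
#' v <- data.frame(chrom = "1", pos = 1:4 * 1000, id = paste0("v", 1:4),
#'                 ancestry = c("NIM", "NIM", "MH", "MH"))
#' NimPanel(d, v)
#' @export
NimPanel <- function(dosage, variants, haplotypes = NULL, sampleIds = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.data.frame(variants)) {
    gr <- GRanges(as.character(variants$chrom),
                  IRanges(start = variants$pos, width = 1L))
    names(gr) <- as.character(variants$id)
    keep <- setdiff(colnames(variants), c("chrom", "pos", "id"))
    for (k in keep) mcols(gr)[[k]] <- variants[[k]]
  } else {
    gr <- variants
    if (is.null(names(gr))) names(gr) <- paste0("v", seq_along(gr))
  }
  if (length(gr) != nrow(dosage))
    stop("variant table has ", length(gr), " rows; dosage has ", nrow(dosage))
  m <- mcols(gr)
  if (is.null(m$ancestry)) m$ancestry <- factor(rep("MH", length(gr)), c("NIM", "MH"))
  m$ancestry <- factor(as.character(m$ancestry), levels = c("NIM", "MH"))
  if (is.null(m$af)) m$af <- rowMeans(dosage, na.rm = TRUE) / 2
  if (is.null(m$maf)) m$maf <- pmin(m$af, 1 - m$af)
  if (is.null(m$ldScore)) m$ldScore <- rep(NA_real_, length(gr))
  if (is.null(m$qcPass)) m$qcPass <- rep(TRUE, length(gr))
  mcols(gr) <- m
  if (is.null(sampleIds)) sampleIds <- paste0("ind", seq_len(ncol(dosage)))
  colnames(dosage) <- sampleIds
  rownames(dosage) <- names(gr)
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowRanges = gr)
  panel <- new("NimPanel", se)
  if (!is.null(haplotypes)) {
    storage.mode(haplotypes) <- "integer"
    metadata(panel)$haplotypes <- haplotypes
  }
  validObject(panel)
  panel
}

#' Variant metadata table
#'
#' @param x a \linkS4class{NimPanel}.
#' @param ... unused.
#' @return data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ancestry}, \code{af}, \code{maf}, \code{ldScore}, \code{qcPass}.
#' @export
#' @rdname variantTable
setMethod("variantTable", "NimPanel", function(x, ...) {
  gr <- rowRanges(x)
  out <- data.frame(id = names(gr), chrom = as.character(seqnames(gr)),
                    pos = start(gr), ancestry = as.character(mcols(gr)$ancestry),
                    af = mcols(gr)$af, maf = mcols(gr)$maf,
                    ldScore = mcols(gr)$ldScore, qcPass = mcols(gr)$qcPass,
                    row.names = NULL)
  ## carry along any extra per-variant annotations (segment labels,
  ## B-values, ...)
  extra <- setdiff(colnames(mcols(gr)),
                   c("ancestry", "af", "maf", "ldScore", "qcPass"))
  for (e in extra) out[[e]] <- mcols(gr)[[e]]
  out
})

#' Dosage and haplotype matrices
#'
#' \code{dosages()} returns the variants x individuals dosage matrix;
#' \code{haplotypes()} the phased variants x 2n matrix (or NULL when the
#' panel was built without phase).
#'
#' @param x a \linkS4class{NimPanel}.
#' @param ... unused.
#' @export
#' @rdname dosages
setMethod("dosages", "NimPanel", function(x, ...) assay(x, "dosage"))

#' @export
#' @rdname dosages
setMethod("haplotypes", "NimPanel", function(x, ...) metadata(x)$haplotypes)

#' Panel and partition accessors
#'
#' Small accessors for per-variant annotations and partition slots:
#' \code{ancestry()}, \code{ldScores()}, \code{qcPass()} on a panel;
#' \code{binAssignment()}, \code{binLabels()}, \code{binSizes()},
#' \code{droppedBins()} on an \linkS4class{AnnotationPartition};
#' \code{h2PerBin()}, \code{h2Nim()}, \code{deltaH2()} on
#' \linkS4class{ComponentEstimates}.
#'
#' @param x the object.
#' @param ... unused.
#' @name accessors
NULL

#' @export
#' @rdname accessors
setMethod("ancestry", "NimPanel", function(x, ...)
  as.character(mcols(rowRanges(x))$ancestry))

#' @export
#' @rdname accessors
setMethod("ldScores", "NimPanel", function(x, ...) mcols(rowRanges(x))$ldScore)

#' @export
#' @rdname accessors
setMethod("qcPass", "NimPanel", function(x, ...) mcols(rowRanges(x))$qcPass)

setMethod("show", "NimPanel", function(object) {
  anc <- ancestry(object)
  cat("NimPanel: ", nrow(object), " variants x ", ncol(object),
      " individuals\n", sep = "")
  cat("  NIM: ", sum(anc == "NIM"), "  MH: ", sum(anc == "MH"),
      "  QC-pass: ", sum(qcPass(object)), "\n", sep = "")
  if (!all(is.na(ldScores(object))))
    cat("  mean LD score (NIM / MH): ",
        round(mean(ldScores(object)[anc == "NIM"], na.rm = TRUE), 1), " / ",
        round(mean(ldScores(object)[anc == "MH"], na.rm = TRUE), 1), "\n",
        sep = "")
  cat("  haplotypes: ", if (is.null(haplotypes(object))) "absent" else "present",
      "\n", sep = "")
})

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig: ", object@nIndividuals, " individuals, ",
      object@nSegments, " introgressed segments (~",
      round(object@nimsPerSegment), " NIMs each), ",
      object@nMhSnps, " MH SNPs, genome ",
      object@genomeLengthBp / 1e6, " Mb, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "PhenotypeTruth", function(object) {
  cat("PhenotypeTruth: n = ", length(object@y), ", ",
      length(object@causalIds), " causal variants, true h2 = ",
      signif(object@trueH2, 3), ", true h2_NIM = ",
      signif(object@trueH2Nim, 3), "\n", sep = "")
})

setMethod("show", "AnnotationPartition", function(object) {
  cat("AnnotationPartition: ", nrow(object@labels), " bins over ",
      length(object@assignment), " variants (schemes: ",
      paste(c("ancestry", object@schemes), collapse = " + "), ")\n", sep = "")
  if (nrow(object@dropped))
    cat("  dropped ", nrow(object@dropped), " bins (< ", object@minSnps,
        " SNPs) covering ", sum(object@dropped$size), " variants\n", sep = "")
})

setMethod("show", "ComponentEstimates", function(object) {
  cat("ComponentEstimates (", length(object@h2PerBin), " bins)\n", sep = "")
  cat(sprintf("  h2 total      %.4f (se %.4f)\n", object@h2Total, object@se["h2Total"]))
  cat(sprintf("  h2 NIM        %.4f (se %.4f)  Z(=0) %.2f\n", object@h2Nim,
              object@se["h2Nim"], object@z["h2NimVsZero"]))
  cat(sprintf("  h2 MH matched %.4f (se %.4f)\n", object@h2MhMatched,
              object@se["h2MhMatched"]))
  cat(sprintf("  delta h2      %+.4f (se %.4f)  Z(=0) %.2f, p %.3g\n",
              object@deltaH2, object@se["deltaH2"], object@z["deltaVsZero"],
              object@p["deltaVsZero"]))
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult: mean %.4g (se %.3g), tau2 %.3g, Z %.2f, k %d\n",
              object@mean, object@se, object@tau2, object@z, object@k))
})

setMethod("show", "AssocResult", function(object) {
  cat("AssocResult: ", sum(object@table$tested), " variants tested, ",
      length(object@significant), " significant at p < ",
      signif(object@threshold, 3), "\n", sep = "")
  if (nrow(object@clumps))
    cat("  ", length(unique(object@clumps$index)), " clumps\n", sep = "")
})

setMethod("show", "TagSelection", function(object) {
  cat("TagSelection: ", length(object@selected), " tag SNPs, ",
      utils::tail(c(0, object@featuresUsed), 1), " features used, ",
      length(object@untagged), " candidates left untagged\n", sep = "")
})

#' @export
#' @rdname accessors
setMethod("binAssignment", "AnnotationPartition", function(x, ...) x@assignment)

#' @export
#' @rdname accessors
setMethod("binLabels", "AnnotationPartition", function(x, ...) x@labels)

#' @export
#' @rdname accessors
setMethod("binSizes", "AnnotationPartition", function(x, ...) {
  s <- x@sizes
  names(s) <- x@labels$bin
  s
})

#' @export
#' @rdname accessors
setMethod("droppedBins", "AnnotationPartition", function(x, ...) x@dropped)

#' @export
#' @rdname accessors
setMethod("h2PerBin", "ComponentEstimates", function(x, ...) x@h2PerBin)

#' @export
#' @rdname accessors
setMethod("h2Nim", "ComponentEstimates", function(x, ...) x@h2Nim)

#' @export
#' @rdname accessors
setMethod("deltaH2", "ComponentEstimates", function(x, ...) x@deltaH2)
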