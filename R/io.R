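## PLINK1 binary (bed/bim/fam) input/output.
##
## No installed package reads PLINK1 binaries, so the 2-bit codec is
## implemented here. bed is SNP-major: magic bytes 0x6c 0x1b 0x01, then
## ceil(n/4) bytes per variant, two bits per individual, low bits first:
## 00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.
## Dosages count the A1 allele (bim column 5).

.bedMagic <- as.raw(c(0x6c, 0x1b, 0x01))

## byte -> 4 dosages lookup (256 x 4), NA for the missing code
.bedLookup <- local({
  codeToDose <- c(2L, NA_integer_, 1L, 0L)   # 00, 01, 10, 11
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    lut[b + 1L, ] <- codeToDose[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  }
  lut
})

#' Read genotypes from a PLINK1 fileset
#'
#' @param prefix path prefix; \code{<prefix>.bed/.bim/.fam} must exist. A
#'   \code{<prefix>.variants.tsv} annotation table (columns \code{id},
#'   \code{ancestry}, optionally \code{ldScore}, \code{qcPass}) is merged
#'   when present or when given via \code{variantsTsv}.
#' @param variantsTsv optional explicit path to the annotation table.
#' @return A \linkS4class{NimPanel}.
#' @export
readPlink <- function(prefix, variantsTsv = NULL) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimTab <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character"))
  famTab <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famTab); p <- nrow(bimTab)
  bpv <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = 3L + p * bpv)
  if (length(raw) < 3L || !identical(raw[1:3], .bedMagic))
    stop("not a SNP-major PLINK1 bed file (bad magic bytes)")
  if (length(raw) != 3L + p * bpv)
    stop("truncated bed file: expected ", 3 + p * bpv, " bytes, got ",
         length(raw))
  body <- as.integer(raw[-(1:3)])
  ## decode all bytes at once: dose[b, j] is the j-th genotype of byte b;
  ## bytes run variant-major, bpv bytes (4 slots each) per variant
  dose <- .bedLookup[body + 1L, , drop = FALSE]
  slots <- matrix(as.vector(t(dose)), nrow = 4L * bpv)  # slots x variants
  D <- t(slots[seq_len(n), , drop = FALSE])
  storage.mode(D) <- "integer"
  vt <- data.frame(chrom = bimTab$chrom, pos = bimTab$pos, id = bimTab$id,
                   ancestry = "MH")
  if (is.null(variantsTsv)) {
    cand <- paste0(prefix, ".variants.tsv")
    if (file.exists(cand)) variantsTsv <- cand
  }
  panel <- NimPanel(D, vt, sampleIds = as.character(famTab[[2L]]))
  if (!is.null(variantsTsv)) {
    ann <- utils::read.table(variantsTsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    m <- match(rownames(panel), ann$id)
    if ("ancestry" %in% colnames(ann))
      mcols(rowRanges(panel))$ancestry <-
        factor(ann$ancestry[m], levels = c("NIM", "MH"))
    if ("ldScore" %in% colnames(ann))
      mcols(rowRanges(panel))$ldScore <- ann$ldScore[m]
    if ("qcPass" %in% colnames(ann))
      mcols(rowRanges(panel))$qcPass <- ann$qcPass[m]
  }
  panel
}

#' Write genotypes to a PLINK1 fileset
#'
#' Writes \code{<prefix>.bed/.bim/.fam} plus a \code{<prefix>.variants.tsv}
#' annotation table (id, ancestry, af, maf, ldScore, qcPass). Round-trips
#' dosages, missing genotypes and variant metadata through [readPlink()].
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param prefix output path prefix.
#' @param variantsTsv also write the annotation table (default TRUE).
#' @return Invisibly, the paths written.
#' @export
writePlink <- function(panel, prefix, variantsTsv = TRUE) {
  stopifnot(is(panel, "NimPanel"))
  D <- dosages(panel)
  p <- nrow(D); n <- ncol(D)
  gr <- rowRanges(panel)
  bim <- data.frame(chrom = as.character(seqnames(gr)), id = names(gr),
                    cm = 0, pos = start(gr), a1 = "A", a2 = "G")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = colnames(D), iid = colnames(D), pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ## dosage -> 2-bit code: 2->00, NA->01, 1->10, 0->11
  code <- matrix(3L, nrow = p, ncol = n)
  code[D == 2L] <- 0L; code[D == 1L] <- 2L; code[is.na(D)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4L - n
  if (pad > 0) code <- cbind(code, matrix(0L, p, pad))
  shifts <- c(0L, 2L, 4L, 6L)
  bytes <- matrix(0L, nrow = p, ncol = bpv)
  for (j in seq_len(4L)) {
    bytes <- bytes + bitwShiftL(code[, seq(j, by = 4L, length.out = bpv),
                                     drop = FALSE], shifts[j])
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(.bedMagic, con)
  writeBin(as.raw(t(bytes)), con)
  close(con)
  if (variantsTsv) {
    vt <- variantTable(panel)
    utils::write.table(vt, paste0(prefix, ".variants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paste0(prefix, c(".bed", ".bim", ".fam",
                             if (variantsTsv) ".variants.tsv")))
}

#' Write a simulated phenotype and its truth
#'
#' The phenotype goes to a two-column TSV (sample, y); the ground truth
#' (causal ids, effects, true h2, true NIM h2, seed) to JSON.
#'
#' @param truth a \linkS4class{PhenotypeTruth}.
#' @param prefix output prefix (writes \code{<prefix>.phenotype.tsv} and
#'   \code{<prefix>.truth.json}).
#' @param sampleIds optional sample identifiers.
#' @return Invisibly, the paths written.
#' @export
writePhenotype <- function(truth, prefix, sampleIds = NULL) {
  stopifnot(is(truth, "PhenotypeTruth"))
  if (is.null(sampleIds)) sampleIds <- paste0("ind", seq_along(truth@y))
  utils::write.table(data.frame(sample = sampleIds, y = truth@y),
                     paste0(prefix, ".phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(causalIds = truth@causalIds, beta = truth@beta,
         trueH2 = truth@trueH2, trueH2Nim = truth@trueH2Nim,
         seed = truth@seed),
    paste0(prefix, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, c(".phenotype.tsv", ".truth.json")))
}
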