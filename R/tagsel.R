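#' Greedy tag-SNP selection for array design
#'
#' Selects tag SNPs that capture a candidate set (e.g. Neanderthal-derived
#' SNPs) under a feature budget. Candidates already tagged at r2 >
#' \code{r2Tag} by SNPs on an existing array are removed first. Then,
#' iteratively, each remaining candidate j is scored as
#' \deqn{Score_j = \sum_i \delta(r^2(i,j) > 0.80) \cdot freq_i / cost_j}
#' over currently untagged candidates i (including j itself), where freq is
#' the derived allele frequency and cost the number of array features
#' required to genotype j. The highest-scoring SNP is selected (ties broken
#' by lowest chromosome then position), every candidate it tags leaves the
#' pool, and its cost is charged against the budget. Selection stops when
#' all candidates are tagged or the budget cannot cover the next pick.
#'
#' @param panel a \linkS4class{NimPanel}.
#' @param candidates character ids of SNPs to tag (default: QC-passing
#'   NIMs).
#' @param freqs derived-allele frequency per candidate (default: the
#'   panel's counted-allele frequency).
#' @param costs feature cost per candidate (>= 1; default 1).
#' @param existingTags character ids of SNPs already on the array.
#' @param r2Tag tagging threshold; strictly greater-than (default 0.8).
#' @param budget total feature budget (default unlimited).
#' @return A \linkS4class{TagSelection}.
#' @export
greedyTagSelection <- function(panel, candidates = NULL, freqs = NULL,
                               costs = NULL, existingTags = character(0),
                               r2Tag = 0.8, budget = Inf) {
  stopifnot(is(panel, "NimPanel"), budget >= 0)
  if (is.null(candidates))
    candidates <- rownames(panel)[qcPass(panel) & ancestry(panel) == "NIM"]
  idx <- match(candidates, rownames(panel))
  if (anyNA(idx)) stop("unknown candidate ids")
  m <- length(idx)
  if (is.null(freqs)) freqs <- mcols(rowRanges(panel))$af[idx]
  if (is.null(costs)) costs <- rep(1, m)
  stopifnot(length(freqs) == m, length(costs) == m, all(costs >= 1))
  gr <- rowRanges(panel)[idx]
  chr <- as.character(seqnames(gr)); pos <- start(gr)

  R <- .rowCorMatrix(dosages(panel)[idx, , drop = FALSE])
  r2 <- tcrossprod(R)^2
  untagged <- rep(TRUE, m)
  if (length(existingTags)) {
    eIdx <- match(existingTags, rownames(panel))
    if (anyNA(eIdx)) stop("unknown existing tag ids")
    Re <- .rowCorMatrix(dosages(panel)[eIdx, , drop = FALSE])
    r2e <- tcrossprod(R, Re)^2
    untagged <- rowSums(r2e > r2Tag) == 0L
  }

  selected <- character(0); stepScore <- numeric(0); featUsed <- numeric(0)
  used <- 0
  while (any(untagged)) {
    ## only untagged candidates remain selectable; a selected SNP tags
    ## itself (r2 = 1) and so leaves the pool automatically
    score <- (r2[, untagged, drop = FALSE] > r2Tag) %*% freqs[untagged]
    score <- drop(score) / costs
    score[!untagged] <- -Inf
    best <- which(score == max(score))
    if (length(best) > 1L) best <- best[order(chr[best], pos[best])][1L]
    if (!is.finite(score[best])) break
    if (used + costs[best] > budget) break
    selected <- c(selected, candidates[best])
    stepScore <- c(stepScore, unname(score[best]))
    used <- used + costs[best]
    featUsed <- c(featUsed, used)
    untagged <- untagged & !(r2[, best] > r2Tag)
  }
  new("TagSelection", selected = selected, score = stepScore,
      featuresUsed = featUsed, untagged = candidates[untagged])
}
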