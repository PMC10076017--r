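#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Pools per-phenotype estimates assuming they are drawn from a common
#' distribution whose mean and between-phenotype variance are estimated by
#' the DerSimonian-Laird moment method: with fixed-effect weights
#' w_i = 1/se_i^2 and Cochran's Q, tau2 = max(0, (Q - (k-1)) /
#' (sum(w) - sum(w^2)/sum(w))); the pooled mean uses weights
#' 1/(se_i^2 + tau2).
#'
#' @param estimates numeric per-phenotype estimates.
#' @param ses positive standard errors.
#' @return A \linkS4class{MetaResult}.
#' @examples
#' randomEffectsMeta(c(0.1, 0.2, 0.6), c(0.05, 0.05, 0.05))
#' @export
randomEffectsMeta <- function(estimates, ses) {
  k <- length(estimates)
  if (k == 0L) stop("no estimates to meta-analyze")
  stopifnot(length(ses) == k, all(ses > 0), !anyNA(estimates))
  w <- 1 / ses^2
  muF <- sum(w * estimates) / sum(w)
  if (k == 1L) {
    tau2 <- 0
  } else {
    Q <- sum(w * (estimates - muF)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  wStar <- 1 / (ses^2 + tau2)
  mu <- sum(wStar * estimates) / sum(wStar)
  se <- sqrt(1 / sum(wStar))
  new("MetaResult", mean = mu, tau2 = tau2, se = se, z = mu / se,
      k = as.integer(k))
}

#' Greedy low-correlation phenotype subset
#'
#' Walks phenotypes in input order and keeps one whenever its squared
#' Pearson correlation with every already-kept phenotype is at most
#' \code{r2Max}; the kept set therefore certifiably satisfies the pairwise
#' bound. The selection is order dependent (earlier phenotypes win ties).
#'
#' @param phenoMatrix numeric matrix, one column per phenotype.
#' @param r2Max squared-correlation bound (default 0.25).
#' @return Character (or integer, if unnamed) ids of kept phenotypes.
#' @export
selectLowCorrelationSubset <- function(phenoMatrix, r2Max = 0.25) {
  phenoMatrix <- as.matrix(phenoMatrix)
  k <- ncol(phenoMatrix)
  if (k == 0L) return(integer(0))
  r2 <- stats::cor(phenoMatrix, use = "pairwise.complete.obs")^2
  kept <- integer(0)
  for (j in seq_len(k)) {
    if (all(r2[j, kept] <= r2Max)) kept <- c(kept, j)
  }
  if (!is.null(colnames(phenoMatrix))) colnames(phenoMatrix)[kept] else kept
}

#' Meta-analyze phenotype categories
#'
#' Runs [randomEffectsMeta()] within each category containing at least
#' \code{minPhenotypes} phenotypes.
#'
#' @param estimates,ses numeric vectors, one entry per phenotype.
#' @param categories character category label per phenotype.
#' @param minPhenotypes minimum category size (default 4).
#' @return data.frame with one row per analyzed category (category, k,
#'   mean, tau2, se, z).
#' @export
metaByCategory <- function(estimates, ses, categories, minPhenotypes = 4L) {
  stopifnot(length(estimates) == length(ses),
            length(categories) == length(estimates))
  keep <- names(which(table(categories) >= minPhenotypes))
  rows <- lapply(keep, function(cat) {
    i <- which(categories == cat)
    m <- randomEffectsMeta(estimates[i], ses[i])
    data.frame(category = cat, k = m@k, mean = m@mean, tau2 = m@tau2,
               se = m@se, z = m@z)
  })
  if (!length(rows))
    return(data.frame(category = character(), k = integer(), mean = numeric(),
                      tau2 = numeric(), se = numeric(), z = numeric()))
  do.call(rbind, rows)
}
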