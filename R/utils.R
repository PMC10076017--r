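## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' operations do not perturb the caller's random stream.
#' @noRd
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a reproducible child seed from a master seed; kept < 2^31.
.childSeed <- function(seed, index) {
  (as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483629
}

## Split 1..m into nBlocks contiguous blocks (sizes differing by at most 1).
## Returns an integer block id per element.
.blockIds <- function(m, nBlocks) {
  nBlocks <- max(1L, min(as.integer(nBlocks), m))
  as.integer(ceiling(seq_len(m) * nBlocks / m))
}

## Column standardization used throughout: w = (x - 2p) / sqrt(2p(1-p)) with
## p the in-sample allele frequency of the counted allele. `X` is an
## individuals x variants dosage matrix. Monomorphic columns are an error:
## they must be removed by QC before any analysis step.
.standardizeDosage <- function(X) {
  p <- colMeans(X) / 2
  bad <- which(p <= 0 | p >= 1)
  if (length(bad))
    stop("monomorphic variant(s) cannot be standardized: column(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  sweep(sweep(X, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
}

## Center and scale columns to unit sample variance (for correlations).
.scaleCols <- function(X) {
  X <- sweep(X, 2L, colMeans(X), "-")
  s <- sqrt(colSums(X^2) / (nrow(X) - 1L))
  s[s == 0] <- NA_real_
  sweep(X, 2L, s, "/")
}

## Squared Pearson correlation matrix between columns of A and columns of B
## (dosage matrices over the same individuals). Missing entries must have
## been imputed already.
.r2Matrix <- function(A, B = NULL) {
  if (is.null(B)) {
    r <- stats::cor(A)
  } else {
    r <- stats::cor(A, B)
  }
  r * r
}

## Residualize the columns of M on covariates C (a full-rank matrix that
## already contains an intercept column). Returns the residual matrix.
.residualizeOn <- function(M, C) {
  qrC <- qr(C)
  if (qrC$rank < ncol(C))
    stop("covariate matrix is rank deficient (rank ", qrC$rank,
         " < ", ncol(C), " columns)")
  M - C %*% qr.coef(qrC, M)
}

## Build a covariate matrix with a leading intercept from a possibly-NULL
## covariate input (vector, matrix or data.frame).
.covariateMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  C <- as.matrix(covariates)
  if (nrow(C) != n) stop("covariates have ", nrow(C), " rows; expected ", n)
  if (anyNA(C)) stop("covariates contain missing values")
  cbind(intercept = 1, C)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
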