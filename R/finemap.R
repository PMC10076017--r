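#' Residualize a phenotype on covariates
#'
#' Least-squares residual of y on the covariates plus an intercept; the
#' result is orthogonal to every covariate column. Used to feed
#' covariate-adjusted phenotypes to the fine-mapper.
#'
#' @param y numeric phenotype.
#' @param covariates optional covariate matrix/data.frame.
#' @return Numeric residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  C <- .covariateMatrix(covariates, length(y))
  drop(.residualizeOn(matrix(y, ncol = 1L), C))
}

#' Sum-of-single-effects fine-mapping
#'
#' Iterative Bayesian stepwise selection with L additive single effects.
#' Each effect places one causal variant with uniform prior; its prior
#' effect variance is estimated per effect by empirical-Bayes maximization
#' (bounded below at \code{priorVarLower} times Var(y)). The residual
#' variance is updated by maximizing the variational objective, which is
#' non-decreasing across iterations; convergence is declared when its
#' change falls below \code{tol}. Each reported credible set is the
#' smallest posterior-inclusion-ranked set reaching cumulative posterior
#' \code{coverage} for its effect; sets whose minimum absolute pairwise
#' dosage correlation falls below \code{minPurity} are discarded.
#'
#' @param X numeric matrix of genotypes (individuals x variants); columns
#'   are standardized internally.
#' @param y numeric (residualized) phenotype.
#' @param L maximum number of effects (default 10).
#' @param coverage credible-set coverage (default 0.95).
#' @param minPurity minimum absolute pairwise correlation within a set
#'   (default 0.5).
#' @param priorVariance fixed prior effect variance; NULL (default)
#'   estimates it per effect.
#' @param priorVarLower lower bound for the estimated prior variance, as a
#'   fraction of Var(y).
#' @param maxIter,tol iteration cap and objective tolerance.
#' @return List: \code{sets} (list of integer credible sets, deduplicated,
#'   purity-filtered), \code{pip}, \code{alpha} (L x p), \code{mu} (L x p
#'   posterior means), \code{elbo} (trace), \code{converged}, \code{sigma2}.
#' @export
susieFit <- function(X, y, L = 10L, coverage = 0.95, minPurity = 0.5,
                     priorVariance = NULL, priorVarLower = 1e-6,
                     maxIter = 200L, tol = 1e-4) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, p >= 1L)
  y <- y - mean(y)
  Xs <- .scaleCols(X)
  ok <- colSums(is.na(Xs)) == 0L
  Xs[, !ok] <- 0
  d <- colSums(Xs^2)
  d[d == 0] <- Inf                       # constant columns never selected
  varY <- stats::var(y)
  vLower <- priorVarLower * varY
  L <- min(as.integer(L), p)

  alpha <- matrix(1 / p, L, p)
  mu1 <- matrix(0, L, p)                 # posterior mean given inclusion
  mu2 <- matrix(0, L, p)                 # posterior second moment
  V <- rep(varY * 0.2, L)
  sigma2 <- varY
  Xb <- rep(0, n)                        # total fitted value
  XbL <- matrix(0, n, L)                 # per-effect fitted values
  elbo <- numeric(0)
  converged <- FALSE

  for (it in seq_len(maxIter)) {
    for (l in seq_len(L)) {
      rl <- y - Xb + XbL[, l]
      xtr <- drop(crossprod(Xs, rl))
      bhat <- xtr / d
      s2 <- sigma2 / d
      if (is.null(priorVariance)) {
        loglikV <- function(lv) {
          v <- exp(lv)
          lbf <- 0.5 * log(s2 / (s2 + v)) + 0.5 * bhat^2 / s2 * v / (s2 + v)
          m <- max(lbf)
          m + log(mean(exp(lbf - m)))
        }
        opt <- stats::optimize(loglikV, c(log(vLower), log(varY * 100)),
                               maximum = TRUE)
        V[l] <- if (loglikV(log(vLower)) >= opt$objective) vLower else exp(opt$maximum)
      } else V[l] <- priorVariance
      lbf <- 0.5 * log(s2 / (s2 + V[l])) + 0.5 * bhat^2 / s2 * V[l] / (s2 + V[l])
      lbf[!is.finite(lbf)] <- -Inf
      w <- exp(lbf - max(lbf))
      alpha[l, ] <- w / sum(w)
      tau2 <- 1 / (1 / V[l] + d / sigma2)       # posterior variance
      mu1[l, ] <- tau2 * xtr / sigma2
      mu2[l, ] <- tau2 + mu1[l, ]^2
      bl <- alpha[l, ] * mu1[l, ]
      XbLnew <- drop(Xs %*% bl)
      Xb <- Xb - XbL[, l] + XbLnew
      XbL[, l] <- XbLnew
    }
    ## variational objective
    erss <- sum((y - Xb)^2) +
      sum(vapply(seq_len(L), function(l) {
        sum(d * alpha[l, ] * mu2[l, ]) - sum(XbL[, l]^2)
      }, 0))
    sigma2new <- erss / n
    kl <- 0
    for (l in seq_len(L)) {
      tau2 <- pmax(mu2[l, ] - mu1[l, ]^2, 1e-300)
      a <- alpha[l, ]
      nz <- a > 1e-12
      kl <- kl + sum(a[nz] * (log(a[nz] * p) +
        0.5 * (log(V[l] / tau2[nz]) + (mu2[l, nz]) / V[l] - 1)))
    }
    obj <- -n / 2 * log(2 * pi * sigma2new) - erss / (2 * sigma2new) - kl
    elbo <- c(elbo, obj)
    sigma2 <- sigma2new
    if (it > 1L && abs(elbo[it] - elbo[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("susieFit did not converge in ", maxIter,
            " iterations; returning current credible sets")

  pip <- 1 - apply(1 - alpha, 2L, prod)
  sets <- list()
  for (l in seq_len(L)) {
    o <- order(alpha[l, ], decreasing = TRUE)
    cs <- o[seq_len(which(cumsum(alpha[l, o]) >= coverage)[1L])]
    if (length(cs) >= p) next
    ## purity: minimum absolute pairwise correlation among members
    ## (computed from the standardized columns; at most 200 members are
    ## checked, sampled deterministically, as the conventional shortcut)
    if (length(cs) > 1L) {
      sub <- if (length(cs) > 200L)
        cs[round(seq(1L, length(cs), length.out = 200L))] else cs
      cc <- abs(crossprod(Xs[, sub, drop = FALSE]) / (n - 1L))
      if (min(cc, na.rm = TRUE) < minPurity) next
    }
    sets[[length(sets) + 1L]] <- sort(cs)
  }
  sets <- unique(sets)
  list(sets = sets, pip = pip, alpha = alpha, mu = mu1, elbo = elbo,
       converged = converged, sigma2 = sigma2)
}

#' Post-process per-window credible sets into credible NIM regions
#'
#' Per window the credible sets are unioned; unions with 50% or more MH
#' members are dropped; the retained windows whose member spans overlap are
#' merged transitively. Credible NIMs are the NIM-labelled members of each
#' merged union, and the region span is the shortest interval containing
#' all credible NIMs.
#'
#' @param windowSets list, one entry per window, each a character vector of
#'   member variant ids (the union of that window's credible sets).
#' @param panel a \linkS4class{NimPanel} supplying ancestry and positions.
#' @return \link[GenomicRanges]{GRanges} of credible NIM regions with
#'   metadata columns \code{credibleNims}, \code{credibleAll} (character,
#'   comma-separated), \code{nCredibleNims}, \code{sourceWindows}.
#' @export
credibleNimPostprocess <- function(windowSets, panel) {
  stopifnot(is(panel, "NimPanel"))
  anc <- ancestry(panel)
  gr <- rowRanges(panel)
  keepW <- list()
  for (w in seq_along(windowSets)) {
    mem <- windowSets[[w]]
    if (!length(mem)) next
    idx <- match(mem, rownames(panel))
    if (anyNA(idx)) stop("window ", w, " refers to unknown variants")
    mhFrac <- mean(anc[idx] == "MH")
    if (mhFrac >= 0.5) next                      # majority-MH union dropped
    keepW[[length(keepW) + 1L]] <- list(
      window = w, members = mem, idx = idx,
      chrom = as.character(seqnames(gr))[idx[1L]],
      lo = min(start(gr)[idx]), hi = max(start(gr)[idx]))
  }
  if (!length(keepW)) return(GRanges())
  ## transitively merge windows whose member spans overlap
  nW <- length(keepW)
  parent <- seq_len(nW)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nW - 1L)) for (j in (i + 1L):nW) {
    a <- keepW[[i]]; b <- keepW[[j]]
    if (a$chrom == b$chrom && a$lo <= b$hi && b$lo <= a$hi) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(nW), find, 0L)
  out <- lapply(unique(roots), function(r) {
    grp <- keepW[roots == r]
    members <- sort(unique(unlist(lapply(grp, `[[`, "members"))))
    idx <- match(members, rownames(panel))
    nims <- members[anc[idx] == "NIM"]
    nIdx <- match(nims, rownames(panel))
    list(chrom = grp[[1L]]$chrom,
         start = min(start(gr)[nIdx]), end = max(start(gr)[nIdx]),
         nims = nims, all = members,
         windows = sort(unlist(lapply(grp, `[[`, "window"))))
  })
  out <- out[vapply(out, function(o) length(o$nims) > 0L, TRUE)]
  if (!length(out)) return(GRanges())
  res <- GRanges(vapply(out, `[[`, "", "chrom"),
                 IRanges(start = vapply(out, `[[`, 0, "start"),
                         end = vapply(out, `[[`, 0, "end")))
  mcols(res)$credibleNims <- vapply(out, function(o) paste(o$nims, collapse = ","), "")
  mcols(res)$credibleAll <- vapply(out, function(o) paste(o$all, collapse = ","), "")
  mcols(res)$nCredibleNims <- vapply(out, function(o) length(o$nims), 0L)
  mcols(res)$sourceWindows <- vapply(out, function(o) paste(o$windows, collapse = ","), "")
  res
}

#' Fine-map significant NIM signals
#'
#' The full credible-NIM pipeline for one phenotype: LD-prune the
#' significant NIMs (100 kb window, r2 0.99), build the 200 kb window
#' around each pruned focal NIM containing every QC-passing variant (NIM
#' and MH), run [susieFit()] on the covariate-residualized phenotype in
#' each window, union each window's credible sets, then apply
#' [credibleNimPostprocess()].
#'
#' @param y numeric phenotype.
#' @param panel a \linkS4class{NimPanel}.
#' @param assoc an \linkS4class{AssocResult} for this phenotype.
#' @param covariates optional covariates (residualized out of y).
#' @param windowBp total window size around each focal NIM (default 200 kb).
#' @param pruneWindowBp,pruneR2 LD-pruning parameters.
#' @param L,coverage,minPurity passed to [susieFit()].
#' @param verbose print per-stage counts.
#' @return List: \code{regions} (GRanges of credible NIM regions),
#'   \code{testedNims} (union of NIMs over all fine-mapped windows),
#'   \code{windows} (list of per-window member unions), \code{focal}
#'   (pruned focal NIMs).
#' @export
fineMapRegions <- function(y, panel, assoc, covariates = NULL,
                           windowBp = 2e5, pruneWindowBp = 1e5,
                           pruneR2 = 0.99, L = 10L, coverage = 0.95,
                           minPurity = 0.5, verbose = FALSE) {
  stopifnot(is(panel, "NimPanel"), is(assoc, "AssocResult"))
  empty <- list(regions = GRanges(), testedNims = character(0),
                windows = list(), focal = character(0))
  if (!length(assoc@significant)) return(empty)
  focal <- ldPrune(assoc@significant, panel, windowBp = pruneWindowBp,
                   r2 = pruneR2)
  .msg(verbose, length(assoc@significant), " significant NIMs -> ",
       length(focal), " after pruning")
  yr <- residualize(y, covariates)
  gr <- rowRanges(panel)
  qcIdx <- which(qcPass(panel))
  pos <- start(gr); chr <- as.character(seqnames(gr))
  anc <- ancestry(panel)
  windows <- vector("list", length(focal))
  tested <- character(0)
  half <- windowBp / 2
  ## neighbouring focal NIMs often define the identical variant window;
  ## identical inputs are fit once
  cache <- new.env(parent = emptyenv())
  for (w in seq_along(focal)) {
    fi <- match(focal[w], rownames(panel))
    sel <- qcIdx[chr[qcIdx] == chr[fi] & abs(pos[qcIdx] - pos[fi]) <= half]
    tested <- union(tested, rownames(panel)[sel[anc[sel] == "NIM"]])
    key <- paste(sel, collapse = ".")
    if (is.null(cache[[key]])) {
      X <- t(dosages(panel)[sel, , drop = FALSE])
      storage.mode(X) <- "double"
      fit <- susieFit(X, yr, L = L, coverage = coverage,
                      minPurity = minPurity)
      cache[[key]] <- sort(unique(unlist(fit$sets)))
    }
    windows[[w]] <- rownames(panel)[sel[cache[[key]]]]
  }
  regions <- credibleNimPostprocess(windows, panel)
  .msg(verbose, sum(lengths(windows) > 0), " windows with credible sets -> ",
       length(regions), " credible NIM regions")
  list(regions = regions, testedNims = tested, windows = windows,
       focal = focal)
}

#' False discovery proportion of credible NIM regions
#'
#' A region is a true positive when its credible NIMs include at least one
#' causal NIM of the simulation truth; FDP = FP / (TP + FP), reported as NA
#' when there are no regions.
#'
#' @param regions GRanges from [fineMapRegions()]/[credibleNimPostprocess()].
#' @param truth a \linkS4class{PhenotypeTruth}.
#' @param panel the panel (for ancestry labels).
#' @return List with \code{fdp}, \code{tp}, \code{fp}, \code{labels}.
#' @export
evaluateFdp <- function(regions, truth, panel) {
  stopifnot(is(truth, "PhenotypeTruth"))
  if (!length(regions))
    return(list(fdp = NA_real_, tp = 0L, fp = 0L, labels = character(0)))
  anc <- ancestry(panel)
  causalNim <- truth@causalIds[anc[match(truth@causalIds, rownames(panel))] == "NIM"]
  tp <- vapply(seq_along(regions), function(i) {
    nims <- strsplit(mcols(regions)$credibleNims[i], ",", fixed = TRUE)[[1L]]
    length(intersect(nims, causalNim)) > 0L
  }, logical(1))
  list(fdp = mean(!tp), tp = sum(tp), fp = sum(!tp),
       labels = ifelse(tp, "TP", "FP"))
}
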