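#' @include ica.R hungarian.R
NULL

#' Sign-invariant correlation cost between two source matrices
#'
#' For each pair of components computes the Pearson correlation rho and
#' the costs r- = (1 - rho)/2, r+ = (1 + rho)/2 and C = min(r+, r-).
#' C is 0 for perfectly (anti)correlated pairs and 0.5 for uncorrelated
#' ones, so minimizing C matches components regardless of sign.
#'
#' @param S0,Sk source matrices of identical dimensions (genes x n),
#'   columns non-constant.  [ICASolution-class] objects are accepted.
#' @return A list with matrices \code{rho}, \code{rPlus}, \code{rMinus},
#'   \code{cost}.
#' @export
correlationCost <- function(S0, Sk) {
    S0 <- if (is(S0, "ICASolution")) sources(S0) else as.matrix(S0)
    Sk <- if (is(Sk, "ICASolution")) sources(Sk) else as.matrix(Sk)
    if (!all(dim(S0) == dim(Sk))) stop("S0 and Sk must have equal dimensions")
    if (any(apply(S0, 2, stats::sd) == 0) || any(apply(Sk, 2, stats::sd) == 0))
        stop("constant component column")
    rho <- stats::cor(S0, Sk)
    rPlus <- (1 + rho) / 2
    rMinus <- (1 - rho) / 2
    list(rho = rho, rPlus = rPlus, rMinus = rMinus,
         cost = pmin(rPlus, rMinus))
}

#' Match the components of one ICA run to a reference solution
#'
#' Minimizes the total sign-invariant cost C = min(r+, r-) over perfect
#' matchings with the exact Hungarian algorithm, then orients each
#' matched pair: sign +1 where r- < r+ (positive correlation) and -1
#' where r- >= r+.  The resulting signed permutation P satisfies
#' \code{cor(S0[, i], (Sk \%*\% P)[, i]) = alignedCor[i] >= 0}.
#'
#' @inheritParams correlationCost
#' @return A [MatchResult-class].
#' @export
matchComponents <- function(S0, Sk) {
    S0 <- if (is(S0, "ICASolution")) sources(S0) else as.matrix(S0)
    Sk <- if (is(Sk, "ICASolution")) sources(Sk) else as.matrix(Sk)
    cc <- correlationCost(S0, Sk)
    n <- ncol(S0)
    assign <- solveAssignment(cc$cost)
    B <- matrix(0, n, n)
    B[cbind(seq_len(n), assign)] <- 1
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
        j <- assign[i]
        s <- if (cc$rMinus[i, j] < cc$rPlus[i, j]) 1 else -1
        P[j, i] <- s
    }
    aligned <- Sk %*% P
    cvec <- vapply(seq_len(n), function(i)
        stats::cor(S0[, i], aligned[, i]), numeric(1))
    new("MatchResult", rho = cc$rho, rPlus = cc$rPlus, rMinus = cc$rMinus,
        cost = cc$cost, B = B, P = P, alignedCor = cvec)
}

#' Per-component stability across ICA runs
#'
#' Matches every run in \code{others} to the best solution and summarizes
#' the aligned correlations per FC index: mean, standard error of the
#' mean, and maximum.
#'
#' @param best reference [ICASolution-class] (canonicalized).
#' @param others nonempty list of [ICASolution-class] objects on the same
#'   dimension.
#' @return A data.frame with columns \code{fc}, \code{mean}, \code{sem},
#'   \code{max} and one row per component.
#' @export
stabilitySummary <- function(best, others) {
    if (!length(others)) stop("no comparison solutions supplied")
    cmat <- vapply(others, function(o) alignedCor(matchComponents(best, o)),
                   numeric(nComponents(best)))
    cmat <- matrix(cmat, nrow = nComponents(best))
    data.frame(
        fc = paste0("FC", seq_len(nrow(cmat))),
        mean = rowMeans(cmat),
        sem = apply(cmat, 1, function(x)
            if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0),
        max = apply(cmat, 1, max))
}

#' Component stability under compendium subsampling
#'
#' Resamples the columns of \code{full} without replacement
#' \code{nResamples} times; each resampled pseudo-compendium is whitened
#' with the fixed component count of the reference, ICA is run
#' \code{runsEach} times, the highest-negentropy solution is kept and
#' matched to \code{reference}.  Aligned correlations are aggregated per
#' FC as in [stabilitySummary()].
#'
#' @param full [ExpressionMatrix-class], the full (preprocessed) data.
#' @param reference the best [ICASolution-class] from the full data.
#' @param size number of columns per resample (defaults to all columns,
#'   i.e. "similar-sized" pseudo-compendia).
#' @param nResamples number of resamples (reference pipeline: 50).
#' @param runsEach ICA repeats per resample (reference pipeline: 10).
#' @param seed base seed; resample r uses seed + r for sampling and
#'   (seed + r) * 100 as the ICA batch base seed.
#' @param backend,tol,maxIter,gridPoints passed to [runICA()].
#' @return A per-FC stability data.frame as in [stabilitySummary()].
#' @export
subsampleStability <- function(full, reference, size = NULL,
                               nResamples = 50, runsEach = 10, seed = 1,
                               backend = "logcosh", tol = 1e-6,
                               maxIter = 8000, gridPoints = 2000) {
    full <- .as_em(full)
    m <- nSamples(full)
    if (is.null(size)) size <- m
    if (size > m) stop("resample size exceeds the number of samples")
    n <- nComponents(reference)
    cmat <- vapply(seq_len(nResamples), function(r) {
        cols <- withr::with_seed(seed + r, sample.int(m, size))
        sub <- ExpressionMatrix(exprValues(full)[, cols, drop = FALSE])
        wd <- svdWhiten(sub, nComponents = n)
        batch <- runICABatch(wd, runs = runsEach, backend = backend,
                             tol = tol, maxIter = maxIter,
                             gridPoints = gridPoints,
                             baseSeed = (seed + r) * 100)
        alignedCor(matchComponents(reference, batch$best))
    }, numeric(n))
    cmat <- matrix(cmat, nrow = n)
    data.frame(
        fc = paste0("FC", seq_len(n)),
        mean = rowMeans(cmat),
        sem = apply(cmat, 1, function(x)
            if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0),
        max = apply(cmat, 1, max))
}
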