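#' @include whiten.R
NULL

# E[log cosh Z] for standard normal Z; baseline for the logcosh
# negentropy approximation J = (E G(s) - E G(Z))^2
.EG_LOGCOSH <- 0.3745672968160636

.extract_Y <- function(Y) {
    if (is(Y, "WhitenedData")) whitenedMatrix(Y)
    else if (is(Y, "ExpressionMatrix")) exprValues(Y)
    else as.matrix(Y)
}

# random orthogonal n x n matrix from the current RNG stream
.random_orthogonal <- function(n) {
    qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

.sym_orth <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
}

# tilted-Gaussian log-density estimate for one source on a grid:
# log f(s) = log phi(s) + ghat(s), ghat fitted by a Poisson smooth on
# binned counts with a log phi offset.  Returns the score psi = ghat'(s)
# - s and its derivative, interpolated at the sample points, plus the
# mean fitted tilt (the negentropy estimate for this component).
.proden_score <- function(s, gridPoints) {
    g <- length(s)
    ext <- max(abs(s)) * 1.05 + 0.1
    breaks <- seq(-ext, ext, length.out = gridPoints + 1)
    mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
    binw <- diff(breaks)[1]
    counts <- tabulate(findInterval(s, breaks, all.inside = TRUE), gridPoints)
    off <- log(g * binw * stats::dnorm(mid) + 1e-300)
    fit <- mgcv::gam(counts ~ s(mid, k = 10), family = stats::poisson(),
                     offset = off, method = "REML")
    ghat <- as.numeric(stats::predict(fit, newdata = data.frame(mid = mid)))
    # numerical derivatives of the tilt on the grid
    dg <- c(diff(ghat) / binw, NA)
    dg[length(dg)] <- dg[length(dg) - 1]
    d2g <- c(diff(dg) / binw, NA)
    d2g[length(d2g)] <- d2g[length(d2g) - 1]
    gh_s <- stats::approx(mid, ghat, xout = s, rule = 2)$y
    dg_s <- stats::approx(mid, dg, xout = s, rule = 2)$y
    d2g_s <- stats::approx(mid, d2g, xout = s, rule = 2)$y
    list(psi = dg_s - s,          # d/ds log f = ghat'(s) - s
         dpsi = d2g_s - 1,
         negentropy = mean(gh_s))
}

#' Run one ICA unmixing of a whitened matrix
#'
#' Fits the model Y = S A on a whitened matrix (columns orthogonal with
#' equal norm, as produced by [svdWhiten()]), by symmetric fixed-point
#' iteration with orthogonal unmixing.  Backend \code{"logcosh"}
#' maximizes the classical logcosh negentropy approximation; backend
#' \code{"proden"} re-estimates each source's log-density every iteration
#' as a tilted Gaussian on a grid of \code{gridPoints} points (Poisson
#' smooth of binned counts) and uses the estimated score function in the
#' update, maximizing the resulting nonparametric negentropy estimate.
#'
#' @param Y a [WhitenedData-class], or a genes x n matrix whose columns
#'   are orthogonal with squared norm (g - 1).
#' @param backend "logcosh" (default) or "proden".
#' @param tol convergence threshold on the maximum change in unmixing
#'   directions (default 1e-6).
#' @param maxIter maximum fixed-point iterations (default 8000).
#' @param gridPoints density-estimation grid size for the proden backend
#'   (default 2000).
#' @param seed integer seed for the random orthogonal initialization.
#' @param order opaque backend robustness option, recorded in the
#'   solution's parameter list (default 11).
#' @return An [ICASolution-class].  Non-convergence at \code{maxIter}
#'   returns the current solution with \code{converged = FALSE} and a
#'   warning.
#' @examples
#' mix <- genMixture(500, 3, seed = 2)
#' wd <- svdWhiten(preprocessExpression(mix$X), nComponents = 3)
#' sol <- runICA(wd, seed = 1)
#' sol
#' @export
runICA <- function(Y, backend = c("logcosh", "proden"), tol = 1e-6,
                   maxIter = 8000, gridPoints = 2000, seed = 1,
                   order = 11) {
    backend <- match.arg(backend)
    Ym <- .extract_Y(Y)
    g <- nrow(Ym)
    n <- ncol(Ym)
    if (n < 1) stop("Y must have at least one column")
    if (n > g) stop("more components than observations")

    sds <- NULL
    if (n == 1) {
        sds <- stats::sd(Ym[, 1])
        S <- matrix(Ym[, 1] / sds, ncol = 1)
        W <- matrix(1, 1, 1)
        iter <- 0L; converged <- TRUE
    } else {
        W <- withr::with_seed(seed, .random_orthogonal(n))
        converged <- FALSE
        iter <- 0L
        while (iter < maxIter) {
            iter <- iter + 1L
            S <- Ym %*% W
            if (backend == "logcosh") {
                G1 <- tanh(S)
                meanG2 <- colMeans(1 - G1^2)
            } else {
                G1 <- matrix(0, g, n)
                meanG2 <- numeric(n)
                for (j in seq_len(n)) {
                    sc <- .proden_score(S[, j] / stats::sd(S[, j]), gridPoints)
                    G1[, j] <- sc$psi
                    meanG2[j] <- mean(sc$dpsi)
                }
            }
            W1 <- crossprod(Ym, G1) / g - sweep(W, 2, meanG2, "*")
            Wnew <- .sym_orth(W1)
            delta <- max(abs(abs(colSums(Wnew * W)) - 1))
            W <- Wnew
            if (delta < tol) { converged <- TRUE; break }
        }
        if (!converged)
            warning("ICA did not converge in ", maxIter, " iterations")
        S <- Ym %*% W
        sds <- apply(S, 2, stats::sd)
        S <- sweep(S, 2, sds, "/")
    }
    # W orthogonal: Y = (S diag(sds)) W^T, so A = diag(sds) W^T keeps
    # Y = S A exact while S columns carry unit sample SD
    A <- sds * t(W)
    colnames(S) <- paste0("FC", seq_len(ncol(S)))
    rownames(S) <- rownames(Ym)
    ne <- .negentropy(S, backend, gridPoints)
    new("ICASolution", S = S, A = A,
        negentropy = ne, totalNegentropy = sum(ne),
        iterations = iter, converged = converged,
        seed = as.integer(seed), backend = backend,
        params = list(tol = tol, maxIter = maxIter,
                      gridPoints = gridPoints, order = order))
}

.negentropy <- function(S, backend, gridPoints = 2000) {
    if (backend == "logcosh") {
        apply(S, 2, function(s) (mean(log(cosh(s))) - .EG_LOGCOSH)^2)
    } else {
        apply(S, 2, function(s)
            max(0, .proden_score(s, gridPoints)$negentropy))
    }
}

.sample_skewness <- function(x) {
    x <- x - mean(x)
    m2 <- mean(x^2)
    if (m2 == 0) return(0)
    mean(x^3) / m2^1.5
}

#' Canonicalize an ICA solution
#'
#' Sign-flips each component so its sample skewness is nonnegative
#' (flipping the corresponding row of A), then orders components by
#' decreasing skewness (ties by original index).  Y = S A is preserved
#' exactly, and canonical solutions from different runs are directly
#' comparable.
#'
#' @param sol an [ICASolution-class].
#' @return The canonicalized [ICASolution-class].
#' @export
canonicalize <- function(sol) {
    S <- sol@S; A <- sol@A
    sk <- apply(S, 2, .sample_skewness)
    flip <- sk < 0
    S[, flip] <- -S[, flip, drop = FALSE]
    A[flip, ] <- -A[flip, , drop = FALSE]
    sk[flip] <- -sk[flip]
    ord <- order(-sk, seq_along(sk))
    S <- S[, ord, drop = FALSE]
    A <- A[ord, , drop = FALSE]
    ne <- sol@negentropy[ord]
    colnames(S) <- paste0("FC", seq_len(ncol(S)))
    methods::initialize(sol, S = S, A = A, negentropy = ne)
}

#' Select the best ICA solution by total negentropy
#'
#' @param solutions a nonempty list of [ICASolution-class] objects from
#'   the same whitened matrix and backend.
#' @return The solution with maximal total negentropy; ties broken by the
#'   lowest seed.
#' @export
selectBest <- function(solutions) {
    if (!length(solutions)) stop("no solutions supplied")
    backends <- vapply(solutions, function(s) s@backend, character(1))
    if (length(unique(backends)) > 1)
        stop("negentropy scores are not comparable across backends")
    scores <- vapply(solutions, function(s) s@totalNegentropy, numeric(1))
    seeds <- vapply(solutions, function(s) s@seed, integer(1))
    top <- which(scores == max(scores))
    solutions[[top[which.min(seeds[top])]]]
}

#' Run a batch of independent ICA repeats and pick the best solution
#'
#' Runs [runICA()] \code{runs} times with seeds \code{baseSeed + 1} ..
#' \code{baseSeed + runs}, canonicalizes every solution, and selects the
#' highest-negentropy one as the "best solution".
#'
#' @inheritParams runICA
#' @param runs number of independent repeats (the reference pipeline
#'   uses 100).
#' @param baseSeed base seed; run i uses \code{baseSeed + i}.
#' @return A list with \code{solutions} (all canonicalized runs) and
#'   \code{best}.
#' @export
runICABatch <- function(Y, runs = 100, backend = "logcosh", tol = 1e-6,
                        maxIter = 8000, gridPoints = 2000, baseSeed = 0,
                        order = 11) {
    sols <- lapply(seq_len(runs), function(i)
        canonicalize(runICA(Y, backend = backend, tol = tol,
                            maxIter = maxIter, gridPoints = gridPoints,
                            seed = baseSeed + i, order = order)))
    list(solutions = sols, best = selectBest(sols))
}
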