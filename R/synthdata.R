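#' @include AllClasses.R
NULL

# super-Gaussian samplers; each returns a length-m draw, later standardized
.draw_source <- function(m, family) {
    switch(family,
        laplace = {                      # excess kurtosis 3
            u <- stats::runif(m, -0.5, 0.5)
            -sign(u) * log(1 - 2 * abs(u))
        },
        exponential = stats::rexp(m),    # skewed, excess kurtosis 6
        gaussian_mixture = {             # scale mixture, heavy tails
            big <- stats::runif(m) < 0.2
            stats::rnorm(m, sd = ifelse(big, 3, 1))
        },
        gaussian = stats::rnorm(m),
        stop("unknown source family: ", family))
}

.standardize_cols <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    sweep(M, 2, apply(M, 2, stats::sd), "/")
}

#' Generate a synthetic super-Gaussian source mixture
#'
#' Draws n mutually independent standardized sources over g genes from the
#' requested family, mixes them with an orthogonal or unconstrained random
#' n x n matrix, and adds optional i.i.d. Gaussian noise:
#' X = S_true \%*\% A_true + noise.  This emulates the generative premise
#' of the FC model, that expression data are linear mixtures of
#' super-Gaussian (sparse, heavy-tailed) latent modules, and provides the
#' known ground truth used by the recovery tests.
#'
#' @param g number of genes (rows); g >= n.
#' @param n number of sources.
#' @param sourceFamily "laplace" (default), "exponential",
#'   "gaussian_mixture", or "gaussian" (the unidentifiable control case).
#' @param mixing "orthogonal" (QR of a random Gaussian matrix) or
#'   "random" (plain Gaussian matrix).
#' @param noiseSd standard deviation of the additive noise (0 = none).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list with \code{X} ([ExpressionMatrix-class]), \code{S} (the
#'   true standardized sources), \code{A} (the mixing matrix),
#'   \code{conditionNumber} of A, and the generator parameters.
#' @export
genMixture <- function(g, n, sourceFamily = "laplace",
                       mixing = c("orthogonal", "random"),
                       noiseSd = 0, seed = 1) {
    mixing <- match.arg(mixing)
    if (g < n) stop("g must be at least n")
    withr::with_seed(seed, {
        S <- vapply(seq_len(n), function(j) .draw_source(g, sourceFamily),
                    numeric(g))
        S <- .standardize_cols(S)
        A <- matrix(stats::rnorm(n * n), n, n)
        if (mixing == "orthogonal") A <- qr.Q(qr(A))
        X <- S %*% A
        if (noiseSd > 0)
            X <- X + matrix(stats::rnorm(g * ncol(X), sd = noiseSd), g)
        rownames(S) <- rownames(X) <- paste0("g", seq_len(g))
        colnames(S) <- paste0("src", seq_len(n))
        colnames(X) <- paste0("s", seq_len(n))
        list(X = ExpressionMatrix(X), S = S, A = A,
             conditionNumber = kappa(A, exact = TRUE),
             sourceFamily = sourceFamily, mixing = mixing,
             noiseSd = noiseSd, seed = seed)
    })
}

#' Generate a labelled two-class synthetic expression study
#'
#' Builds a study of 2 * \code{nPerGroup} samples whose expression is a
#' linear combination of \code{nFcs} planted standardized super-Gaussian
#' components: per-sample coefficients are N(0, 1), and the second group's
#' coefficients on \code{shiftedFcs} are shifted by \code{effectSize}
#' coefficient standard deviations.  Optional per-batch gene-level
#' intercepts emulate multi-center batch structure.
#'
#' @param nGenes,nPerGroup,nFcs dimensions of the study.
#' @param shiftedFcs integer indices (subset of 1..nFcs) carrying the
#'   group effect.
#' @param effectSize mean shift, in units of the coefficient SD.
#' @param batch "none" or "shift" (two batches crossing the groups, each
#'   with its own gene-level intercept).
#' @param batchSd SD of the per-batch gene intercepts; the default 3
#'   makes the batch the dominant source of gene-space variance, as in
#'   strong multi-center studies.
#' @param noiseSd SD of i.i.d. measurement noise added to the expression.
#' @param seed integer seed.
#' @return A list with \code{expr} ([ExpressionMatrix-class]),
#'   \code{labels} (named character vector, "A"/"B"), \code{S} (planted
#'   loadings), \code{W} (true coefficients, FCs x samples),
#'   \code{shiftedFcs}, and \code{batch} assignments (or NULL).
#' @export
genTwoClassStudy <- function(nGenes, nPerGroup, nFcs, shiftedFcs,
                             effectSize, batch = c("none", "shift"),
                             batchSd = 3, noiseSd = 1, seed = 1) {
    batch <- match.arg(batch)
    if (length(shiftedFcs) && !all(shiftedFcs %in% seq_len(nFcs)))
        stop("shiftedFcs must be a subset of 1..nFcs")
    withr::with_seed(seed, {
        m <- 2 * nPerGroup
        S <- vapply(seq_len(nFcs), function(j) .draw_source(nGenes, "laplace"),
                    numeric(nGenes))
        S <- .standardize_cols(S)
        W <- matrix(stats::rnorm(nFcs * m), nFcs, m)
        labels <- rep(c("A", "B"), each = nPerGroup)
        W[shiftedFcs, labels == "B"] <- W[shiftedFcs, labels == "B"] + effectSize
        X <- S %*% W + matrix(stats::rnorm(nGenes * m, sd = noiseSd), nGenes)
        batches <- NULL
        if (batch == "shift") {
            batches <- rep_len(c("b1", "b2"), m)   # alternating: crosses groups
            off <- matrix(stats::rnorm(nGenes * 2, sd = batchSd), nGenes, 2,
                          dimnames = list(NULL, c("b1", "b2")))
            X <- X + off[, batches]
        }
        ids <- sprintf("s%02d", seq_len(m))
        rownames(X) <- rownames(S) <- paste0("g", seq_len(nGenes))
        colnames(X) <- ids
        colnames(S) <- paste0("FC", seq_len(nFcs))
        names(labels) <- ids
        colnames(W) <- ids
        rownames(W) <- colnames(S)
        if (!is.null(batches)) names(batches) <- ids
        list(expr = ExpressionMatrix(X), labels = labels, S = S, W = W,
             shiftedFcs = shiftedFcs, batch = batches, seed = seed)
    })
}

#' Amari error of an estimated unmixing matrix
#'
#' The normalized Amari index of G = W \%*\% A: zero exactly when G is a
#' scaled signed permutation (perfect source recovery up to order, sign
#' and scale), approaching 1 for unrelated matrices.
#'
#' @param W estimated unmixing matrix (n x n).
#' @param A true mixing matrix (n x n, invertible).
#' @return Nonnegative scalar in [0, 1].
#' @examples
#' A <- qr.Q(qr(matrix(rnorm(9), 3)))
#' amariError(solve(A), A)  # 0
#' @export
amariError <- function(W, A) {
    W <- as.matrix(W); A <- as.matrix(A)
    if (!all(dim(W) == dim(A)) || nrow(W) != ncol(W))
        stop("W and A must be square matrices of the same size")
    if (abs(det(A)) < .Machine$double.eps^0.75 || !all(is.finite(solve(A))))
        stop("A must be invertible")
    G <- abs(W %*% A)
    n <- nrow(G)
    rows <- sum(rowSums(G) / apply(G, 1, max) - 1)
    cols <- sum(colSums(G) / apply(G, 2, max) - 1)
    (rows + cols) / (2 * n * (n - 1))
}

#' Source-recovery Amari error for a synthetic mixture
#'
#' Convenience oracle wiring: recovers the effective unmixing matrix M
#' (least squares solution of S_est = X \%*\% M) and evaluates
#' [amariError()] against the generating mixing matrix.  Since
#' [genMixture()] builds X = S_true \%*\% A, a per-gene observation
#' vector is mixed by t(A), so the product checked is t(M) \%*\% t(A).
#'
#' @param mixture output of [genMixture()].
#' @param sol an [ICASolution-class] (or source matrix) estimated from
#'   the mixture.
#' @return The Amari error in [0, 1]; near 0 means the sources were
#'   recovered up to order, sign and scale.
#' @export
recoveryError <- function(mixture, sol) {
    S <- if (is(sol, "ICASolution")) sources(sol) else as.matrix(sol)
    M <- qr.solve(exprValues(mixture$X), S)
    amariError(t(M), t(mixture$A))
}
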