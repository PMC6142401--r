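#' @include AllClasses.R
NULL

#' SVD whitening of a preprocessed expression matrix
#'
#' Decomposes X = U D V^T and forms the whitened matrix
#' Y = sqrt(g - 1) * U (leading \code{nComponents} columns), where g is
#' the gene count.  The covariance eigenvalues are recovered from the
#' singular values as e_i = d_i^2 / (g - 1); the (g - 1) divisor keeps
#' them consistent with the unbiased variance estimate, so crossprod(Y)
#' equals (g - 1) * I.
#'
#' @param X an [ExpressionMatrix-class] (or matrix), genes x samples,
#'   already preprocessed (columns centered and scaled).  The tall
#'   orientation (genes >= samples) is expected.
#' @param nComponents how many leading components to keep in Y; defaults
#'   to the full rank (all singular values).
#' @return A [WhitenedData-class] object.
#' @seealso [parallelAnalysis()] to choose \code{nComponents},
#'   [runICA()] which consumes the whitened matrix.
#' @export
svdWhiten <- function(X, nComponents = NULL) {
    X <- .as_em(X)
    v <- exprValues(X)
    if (!length(v)) stop("empty matrix")
    g <- nrow(v)
    sv <- svd(v)
    e <- sv$d^2 / (g - 1)
    if (is.null(nComponents)) nComponents <- length(sv$d)
    nComponents <- as.integer(nComponents)
    if (nComponents < 1 || nComponents > length(sv$d))
        stop("nComponents out of range")
    Y <- sqrt(g - 1) * sv$u[, seq_len(nComponents), drop = FALSE]
    rownames(Y) <- geneIds(X)
    colnames(Y) <- paste0("C", seq_len(nComponents))
    new("WhitenedData", u = sv$u, d = sv$d, v = sv$v,
        eigenvalues = e, whitened = Y,
        nComponents = nComponents, nGenes = as.integer(g),
        geneIds = geneIds(X), sampleIds = sampleIds(X))
}

# eigenvalues of t(X) %*% X / (g - 1) for an i.i.d. N(0,1) matrix of the
# given shape, via the small-side crossproduct (equivalent to SVD of X)
.sim_noise_eigenvalues <- function(g, s) {
    Z <- matrix(stats::rnorm(g * s), g, s)
    sort(eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE) / (g - 1)
}

#' Parallel analysis for the number of components to retain
#'
#' Simulates \code{nSim} i.i.d. standard-normal matrices of the same
#' dimensions as \code{X}, collects for each component index the chosen
#' quantile of the simulated covariance eigenvalues (median: Horn's
#' method; 0.95: Glorfeld's method) as the bias, and retains the
#' components whose bias-corrected eigenvalues e_i - bias_i exceed 1.
#' Simulated eigenvalues use the same (g - 1) divisor as the observed
#' ones so the two scales are commensurable.
#'
#' @param X [ExpressionMatrix-class] or matrix; alternatively a
#'   [WhitenedData-class] whose eigenvalues and dimensions are reused.
#' @param nSim number of simulated matrices (default 5000).
#' @param quantile 0.50 for Horn's method or 0.95 for Glorfeld's.
#' @param seed integer seed for the simulations.
#' @param rule "gt1" retains components with e_i - bias_i > 1 (the
#'   default); "conventional" retains components with e_i > bias_i.
#' @return Integer count of retained components, with attributes
#'   \code{table} (data.frame: index, eigenvalue, bias, corrected) for
#'   scree reporting.
#' @export
parallelAnalysis <- function(X, nSim = 5000, quantile = 0.50, seed = 1,
                             rule = c("gt1", "conventional")) {
    rule <- match.arg(rule)
    if (nSim < 1) stop("nSim must be at least 1")
    if (is(X, "WhitenedData")) {
        e <- X@eigenvalues
        g <- X@nGenes
        s <- length(X@sampleIds)
    } else {
        X <- .as_em(X)
        v <- exprValues(X)
        g <- nrow(v)
        s <- ncol(v)
        e <- svd(v, nu = 0, nv = 0)$d^2 / (g - 1)
    }
    sims <- withr::with_seed(seed, {
        vapply(seq_len(nSim), function(i) .sim_noise_eigenvalues(g, s),
               numeric(min(g, s)))
    })
    sims <- matrix(sims, nrow = min(g, s))
    bias <- apply(sims, 1, stats::quantile, probs = quantile, names = FALSE)
    m <- min(length(e), length(bias))
    e <- e[seq_len(m)]; bias <- bias[seq_len(m)]
    corrected <- e - bias
    n <- if (rule == "gt1") sum(corrected > 1) else sum(corrected > 0)
    structure(as.integer(n),
              table = data.frame(index = seq_len(m), eigenvalue = e,
                                 bias = bias, corrected = corrected))
}

#' Fraction of variance explained by the leading components
#'
#' @param e nonnegative eigenvalues (non-increasing).
#' @param n number of leading components.
#' @return sum(e[1:n]) / sum(e), a fraction in [0, 1].
#' @examples
#' varianceExplained(c(4, 3, 2, 1), 2)  # 0.7
#' @export
varianceExplained <- function(e, n) {
    if (is(e, "WhitenedData")) e <- e@eigenvalues
    if (any(e < 0)) stop("eigenvalues must be nonnegative")
    tot <- sum(e)
    if (tot == 0) stop("all eigenvalues are zero")
    if (n < 0 || n > length(e)) stop("n out of range")
    if (n == 0) return(0)
    sum(e[seq_len(n)]) / tot
}
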