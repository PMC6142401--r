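#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ExpressionMatrix: a labelled genes-by-samples expression matrix
#'
#' Thin S4 container for a real-valued expression matrix with unique,
#' ordered gene and sample identifiers.  Rows are genes, columns are
#' samples (arrays).  All preprocessing and projection functions in the
#' package consume and return this class.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#'   Dimnames mirror \code{geneIds}/\code{sampleIds}.
#'
#' @seealso [ExpressionMatrix()] for construction,
#'   [quantileNormalize()], [centerGenes()], [scaleCenterArrays()]
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "values must be a numeric matrix")
    if (anyNA(v))
        msg <- c(msg, "values must not contain missing values")
    if ((is.null(rownames(v)) && nrow(v) > 0) ||
        (is.null(colnames(v)) && ncol(v) > 0))
        msg <- c(msg, "values must carry gene (row) and sample (column) names")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicated gene identifiers")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "duplicated sample identifiers")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x samples).
#' @param geneIds optional character vector of row identifiers; defaults to
#'   existing rownames, or \code{g1..gN} when absent.
#' @param sampleIds optional character vector of column identifiers;
#'   defaults to existing colnames, or \code{s1..sN}.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' em <- ExpressionMatrix(matrix(rnorm(12), 4, 3))
#' nGenes(em)
#' @export
ExpressionMatrix <- function(values, geneIds = NULL, sampleIds = NULL) {
    values <- as.matrix(values)
    if (!is.null(geneIds)) rownames(values) <- geneIds
    if (!is.null(sampleIds)) colnames(values) <- sampleIds
    if (is.null(rownames(values)) && nrow(values))
        rownames(values) <- paste0("g", seq_len(nrow(values)))
    if (is.null(colnames(values)) && ncol(values))
        colnames(values) <- paste0("s", seq_len(ncol(values)))
    new("ExpressionMatrix", values = values)
}

#' WhitenedData: SVD whitening of an expression matrix
#'
#' Holds the singular value decomposition X = U D V^T of a preprocessed
#' compendium, the covariance eigenvalues e_i = d_ii^2 / (g - 1), and the
#' whitened matrix Y = sqrt(g - 1) * U restricted to the leading
#' \code{nComponents} columns, so that crossprod(Y) = (g - 1) * I.
#'
#' @slot u orthonormal-column matrix (genes x r).
#' @slot d singular values (length r, non-increasing).
#' @slot v right singular vectors (samples x r).
#' @slot eigenvalues e_i = d_i^2/(g-1), non-increasing and nonnegative.
#' @slot whitened Y = sqrt(g-1) * U[, 1:nComponents].
#' @slot nComponents retained component count.
#' @slot nGenes number of genes g.
#' @slot geneIds,sampleIds identifiers carried over from the input.
#' @export
setClass("WhitenedData", representation(
    u = "matrix", d = "numeric", v = "matrix",
    eigenvalues = "numeric", whitened = "matrix",
    nComponents = "integer", nGenes = "integer",
    geneIds = "character", sampleIds = "character"))

setValidity("WhitenedData", function(object) {
    msg <- character()
    e <- object@eigenvalues
    if (any(e < -1e-12)) msg <- c(msg, "eigenvalues must be nonnegative")
    if (is.unsorted(rev(e), strictly = FALSE) && any(diff(e) > 1e-8))
        msg <- c(msg, "eigenvalues must be non-increasing")
    if (object@nComponents > ncol(object@u))
        msg <- c(msg, "nComponents exceeds the available rank")
    if (ncol(object@whitened) != object@nComponents)
        msg <- c(msg, "whitened matrix has wrong column count")
    if (length(msg)) msg else TRUE
})

#' ICASolution: one converged (or not) ICA unmixing of a whitened matrix
#'
#' The model is Y = S A with S (genes x n) the source matrix whose columns
#' are the functional components, and A (n x n) the mixing matrix.  Each
#' column of S has zero mean and unit sample standard deviation.
#'
#' @slot S source/loading matrix, genes x n; columns named FC1..FCn.
#' @slot A mixing matrix, n x n.
#' @slot negentropy per-component negentropy estimates (length n).
#' @slot totalNegentropy sum of per-component negentropies; comparable only
#'   within a backend.
#' @slot iterations fixed-point iterations used.
#' @slot converged logical convergence flag.
#' @slot seed integer seed the run was initialized with.
#' @slot backend "logcosh" or "proden".
#' @slot params list of backend options recorded for provenance.
#' @export
setClass("ICASolution", representation(
    S = "matrix", A = "matrix",
    negentropy = "numeric", totalNegentropy = "numeric",
    iterations = "integer", converged = "logical",
    seed = "integer", backend = "character", params = "list"))

setValidity("ICASolution", function(object) {
    msg <- character()
    n <- ncol(object@S)
    if (!all(dim(object@A) == c(n, n)))
        msg <- c(msg, "A must be n x n with n = ncol(S)")
    if (length(object@negentropy) != n)
        msg <- c(msg, "negentropy must have one entry per component")
    if (length(msg)) msg else TRUE
})

#' MatchResult: alignment of one ICA solution to a reference solution
#'
#' Components of a run k are matched to the reference ("best") solution by
#' minimizing the sign-invariant cost C = min(r+, r-) with
#' r+ = (1 + rho)/2 and r- = (1 - rho)/2 over perfect matchings (exact
#' Hungarian assignment).  The signed permutation P reorders and reorients
#' the run's columns so that cor(S0[, i], (Sk %*% P)[, i]) is maximized
#' and nonnegative.
#'
#' @slot rho Pearson correlation matrix between columns of S0 (rows) and
#'   Sk (columns).
#' @slot rPlus,rMinus (1 + rho)/2 and (1 - rho)/2.
#' @slot cost elementwise min(rPlus, rMinus), entries in [0, 0.5].
#' @slot B 0/1 assignment matrix; B[i, j] = 1 when component i of the
#'   reference was assigned to component j of the run.
#' @slot P signed permutation with entries in -1/0/1, nonzero exactly on
#'   the transpose of B's support, so that Sk %*% P aligns to S0.
#' @slot alignedCor c_i = cor(S0[, i], (Sk %*% P)[, i]); all >= 0.
#' @export
setClass("MatchResult", representation(
    rho = "matrix", rPlus = "matrix", rMinus = "matrix", cost = "matrix",
    B = "matrix", P = "matrix", alignedCor = "numeric"))

setValidity("MatchResult", function(object) {
    msg <- character()
    if (max(abs(object@rPlus + object@rMinus - 1)) > 1e-8)
        msg <- c(msg, "rPlus + rMinus must equal 1 elementwise")
    if (any(object@cost < -1e-12) || any(object@cost > 0.5 + 1e-12))
        msg <- c(msg, "cost entries must lie in [0, 0.5]")
    if (any(rowSums(object@B) != 1) || any(colSums(object@B) != 1))
        msg <- c(msg, "B must be a permutation matrix")
    if (!all((t(object@B) != 0) == (object@P != 0)))
        msg <- c(msg, "P must be nonzero exactly on t(B)'s support")
    if (any(object@alignedCor < -1e-8))
        msg <- c(msg, "aligned correlations must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' FCProjection: expression samples projected into FC space
#'
#' Scores are Q_FC = S^T Q_gene computed over the gene intersection of the
#' loading matrix and the query study; entry (f, i) is the coefficient w_f
#' of sample i in the linear model g = sum_f w_f F_f + eps.
#'
#' @slot scores numeric matrix, FCs x samples.
#' @slot fcIds,sampleIds dimension identifiers.
#' @slot unitNorm whether loadings were scaled to unit Euclidean norm
#'   before projection.
#' @slot coverage fraction of loading-matrix genes found in the query.
#' @export
setClass("FCProjection", representation(
    scores = "matrix", fcIds = "character", sampleIds = "character",
    unitNorm = "logical", coverage = "numeric"))

setValidity("FCProjection", function(object) {
    msg <- character()
    if (nrow(object@scores) != length(object@fcIds))
        msg <- c(msg, "fcIds must match score rows")
    if (ncol(object@scores) != length(object@sampleIds))
        msg <- c(msg, "sampleIds must match score columns")
    if (length(msg)) msg else TRUE
})
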