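#' @include AllClasses.R
NULL

.as_em <- function(M) {
    if (is(M, "ExpressionMatrix")) M else ExpressionMatrix(M)
}

#' Quantile-normalize an expression matrix between arrays
#'
#' Replaces every column's values by the mean order statistics across
#' columns, so all columns share one empirical distribution while each
#' column's rank order is preserved.  Ties within a column receive the
#' average of the tied reference values.
#'
#' @param M an [ExpressionMatrix-class] or plain numeric matrix
#'   (genes x samples), no missing values.
#' @return An [ExpressionMatrix-class] of the same shape and labels.
#' @examples
#' m <- ExpressionMatrix(cbind(a = c(1, 3, 5), b = c(2, 4, 8)))
#' exprValues(quantileNormalize(m))   # both columns become 1.5, 3.5, 6.5
#' @export
quantileNormalize <- function(M) {
    M <- .as_em(M)
    v <- exprValues(M)
    if (anyNA(v)) stop("missing values are not allowed")
    out <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(out) <- dimnames(v)
    ExpressionMatrix(out)
}

#' Center each gene (row) at zero mean
#'
#' @inheritParams quantileNormalize
#' @return An [ExpressionMatrix-class] with all row means 0.
#' @export
centerGenes <- function(M) {
    M <- .as_em(M)
    v <- exprValues(M)
    ExpressionMatrix(v - rowMeans(v))
}

#' Scale and center each array (column)
#'
#' Columns end with mean 0 and sample standard deviation 1 (n - 1
#' denominator).  Zero-variance columns are an error.
#'
#' @inheritParams quantileNormalize
#' @return An [ExpressionMatrix-class] with standardized columns.
#' @export
scaleCenterArrays <- function(M) {
    M <- .as_em(M)
    v <- exprValues(M)
    sds <- apply(v, 2, stats::sd)
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad))
        stop("zero-variance column(s): ",
             paste(colnames(v)[bad], collapse = ", "))
    out <- scale(v, center = TRUE, scale = sds)
    attr(out, "scaled:center") <- NULL
    attr(out, "scaled:scale") <- NULL
    ExpressionMatrix(out)
}

#' Standard preprocessing: quantile normalize, gene-center, array-standardize
#'
#' Applies the three preprocessing steps in the fixed order used
#' throughout the package: between-array quantile normalization, then
#' gene (row) centering, then per-array scaling and centering.
#'
#' @inheritParams quantileNormalize
#' @return A preprocessed [ExpressionMatrix-class].
#' @export
preprocessExpression <- function(M) {
    scaleCenterArrays(centerGenes(quantileNormalize(M)))
}

#' Correlation distance between samples
#'
#' D[i, j] = 1 - cor(column i, column j) with Pearson or Spearman
#' correlation (average ranks for ties).  Entries lie in [0, 2] with a
#' zero diagonal.
#'
#' @inheritParams quantileNormalize
#' @param metric "spearman" or "pearson".
#' @return Symmetric numeric matrix (samples x samples) with attribute
#'   \code{metric}.
#' @examples
#' m <- ExpressionMatrix(cbind(x = c(1, 2, 3), y = c(1, 3, 2)))
#' correlationDistance(m, "spearman")["x", "y"]   # 0.5
#' @export
correlationDistance <- function(M, metric = c("spearman", "pearson")) {
    metric <- match.arg(metric)
    M <- .as_em(M)
    v <- exprValues(M)
    if (nrow(v) < 2) stop("need at least 2 rows per column comparison")
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
        stop("constant column(s): ",
             paste(colnames(v)[sds == 0], collapse = ", "))
    D <- 1 - stats::cor(v, method = metric)
    diag(D) <- 0
    attr(D, "metric") <- metric
    D
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells numeric.
#'
#' @param path file path.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    v <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(v) <- "double"
    rownames(v) <- genes
    ExpressionMatrix(v)
}

#' Write an expression matrix as tab-separated text
#'
#' Layout matches [readExpressionMatrix()] so a write/read cycle
#' round-trips the labels and values.
#'
#' @inheritParams quantileNormalize
#' @param path output file path.
#' @param idColumn name for the gene-identifier column header.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(M, path, idColumn = "gene_id") {
    M <- .as_em(M)
    v <- exprValues(M)
    df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                     setNames(list(rownames(v)), idColumn), v)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
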