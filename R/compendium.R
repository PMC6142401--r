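#' @include core-matrix.R
NULL

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' @param D symmetric distance matrix (e.g. from [correlationDistance()]).
#' @return An \code{hclust} tree (UPGMA agglomeration).
#' @export
averageLinkageTree <- function(D) {
    D <- as.matrix(D)
    if (nrow(D) < 2) stop("need at least 2 samples to cluster")
    stats::hclust(stats::as.dist(D), method = "average")
}

#' Knee of the k-nearest-neighbor distance curve
#'
#' Computes every sample's distance to its k-th nearest neighbor, sorts
#' the values ascending, and returns the curve value at the point of
#' maximum perpendicular distance from the chord joining the curve's two
#' endpoints.  Used to pick the tree-cut height for compendium
#' construction; callers may always override the height manually.
#'
#' @param D symmetric distance matrix.
#' @param k neighbor rank (k < number of samples).
#' @param tol minimum chord deviation below which the curve is considered
#'   featureless and an error is raised.
#' @return The knee height (a single distance value).
#' @export
knnKneeHeight <- function(D, k, tol = 1e-9) {
    D <- as.matrix(D)
    m <- nrow(D)
    if (k >= m) stop("k must be smaller than the number of samples")
    kd <- vapply(seq_len(m), function(i) sort(D[i, -i])[k], numeric(1))
    y <- sort(kd)
    x <- seq_along(y)
    # perpendicular distance of each point from the endpoint chord
    x1 <- x[1]; y1 <- y[1]; x2 <- x[m]; y2 <- y[m]
    denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    dist <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / denom
    if (max(dist) < tol)
        stop("no knee detected: curve is near-linear; pass a height manually")
    y[which.max(dist)]
}

#' Cut a cluster tree, filter small clusters, and pick medoids
#'
#' Clusters are the groups obtained by cutting \code{tree} at
#' \code{height}; clusters with fewer than \code{minSize} members are
#' dropped; each retained cluster is represented by its medoid, the member
#' minimizing the summed distance to all other members (ties broken by
#' smallest sample index).
#'
#' @param tree an \code{hclust} tree over the same samples as \code{D}.
#' @param D the distance matrix the tree was built from.
#' @param height cut height (maximum intra-cluster merge height).
#' @param minSize minimum retained cluster size (default 5).
#' @return A list with elements \code{height}, \code{assignments} (named
#'   integer vector), \code{retained} (retained cluster ids), and
#'   \code{medoids} (named character vector, cluster id -> sample id).
#' @export
cutFilterMedoids <- function(tree, D, height, minSize = 5) {
    if (height < 0) stop("height must be nonnegative")
    D <- as.matrix(D)
    cl <- stats::cutree(tree, h = height)
    # relabel clusters by first-occurring sample index
    cl <- match(cl, unique(cl))
    names(cl) <- tree$labels
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= minSize])
    if (!length(keep)) {
        warning("no cluster of size >= ", minSize, " at height ", height)
        return(list(height = height, assignments = cl,
                    retained = integer(0), medoids = character(0)))
    }
    medoids <- vapply(keep, function(k) {
        idx <- which(cl == k)
        tot <- rowSums(D[idx, idx, drop = FALSE])
        names(idx)[which.min(tot)]   # which.min takes the first (lowest index)
    }, character(1))
    names(medoids) <- as.character(keep)
    list(height = height, assignments = cl, retained = keep,
         medoids = medoids)
}

#' Build a representative compendium from an expression matrix
#'
#' One-call wrapper: Spearman (or Pearson) correlation distances between
#' arrays, average-linkage clustering, tree cut at a knee-detected or
#' user-supplied height, removal of clusters with fewer than
#' \code{minSize} members, and medoid selection.  The medoids form the
#' representative compendium used for whitening and ICA.
#'
#' @inheritParams quantileNormalize
#' @param metric correlation metric for distances.
#' @param k neighbor rank for automatic knee detection.
#' @param height optional manual cut height; when \code{NULL} the knee of
#'   the k-NN curve is used.
#' @param minSize minimum cluster size retained.
#' @return A list with the [cutFilterMedoids()] report plus
#'   \code{compendium}, the [ExpressionMatrix-class] restricted to the
#'   medoid samples.
#' @export
buildCompendium <- function(M, metric = c("spearman", "pearson"),
                            k = 4, height = NULL, minSize = 5) {
    M <- .as_em(M)
    D <- correlationDistance(M, match.arg(metric))
    tree <- averageLinkageTree(D)
    if (is.null(height)) height <- knnKneeHeight(D, k)
    rep <- cutFilterMedoids(tree, D, height, minSize)
    rep$compendium <- ExpressionMatrix(
        exprValues(M)[, rep$medoids, drop = FALSE])
    rep
}
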