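#' @include AllClasses.R
NULL

#' Project an expression study into FC space
#'
#' Computes Q_FC = S^T Q_gene over the intersection of the loading
#' matrix's and the query's gene universes (rows aligned by gene id;
#' genes missing from the query are dropped from S, not imputed).  With
#' \code{unitNorm = TRUE} each loading column is first scaled to unit
#' Euclidean norm ("unitary vector space").
#'
#' @param Q an [ExpressionMatrix-class] (or matrix), the query study.
#' @param S loading matrix (genes x FCs) with gene rownames, or an
#'   [ICASolution-class].
#' @param unitNorm scale loadings to unit norm before projecting
#'   (default FALSE: raw gene loadings).
#' @param minCoverage minimum fraction of S's genes that must be present
#'   in Q (default 0.9); below this the projection errors.
#' @return An [FCProjection-class]; its \code{coverage} slot records the
#'   realized gene coverage.
#' @export
projectToFC <- function(Q, S, unitNorm = FALSE, minCoverage = 0.9) {
    Q <- .as_em(Q)
    S <- if (is(S, "ICASolution")) sources(S) else as.matrix(S)
    if (is.null(rownames(S))) stop("loading matrix must carry gene rownames")
    common <- intersect(rownames(S), geneIds(Q))
    if (!length(common)) stop("no genes shared between loadings and query")
    coverage <- length(common) / nrow(S)
    if (coverage < minCoverage)
        stop(sprintf("gene coverage %.1f%% below the %.0f%% floor",
                     100 * coverage, 100 * minCoverage))
    Ssub <- S[common, , drop = FALSE]
    if (unitNorm)
        Ssub <- sweep(Ssub, 2, sqrt(colSums(Ssub^2)), "/")
    scores <- crossprod(Ssub, exprValues(Q)[common, , drop = FALSE])
    fcIds <- colnames(S)
    if (is.null(fcIds)) fcIds <- paste0("FC", seq_len(ncol(S)))
    rownames(scores) <- fcIds
    new("FCProjection", scores = scores, fcIds = fcIds,
        sampleIds = sampleIds(Q), unitNorm = unitNorm,
        coverage = coverage)
}

#' Find reference neighbors of a sample group in FC space
#'
#' For every group member, neighbors are the reference samples whose
#' Pearson correlation with it (over FC scores) exceeds \code{minCor}.
#' The union over members is filtered: a neighbor is retained only when
#' it neighbors at least \code{ceiling(minFrac * group size)} members.
#'
#' @param group [FCProjection-class] of the query group (>= 1 sample).
#' @param reference [FCProjection-class] of the reference collection, on
#'   the same FC basis.
#' @param minCor correlation threshold (default 0.95, strict >).
#' @param minFrac minimum fraction of group members a retained neighbor
#'   must serve (default 0.5).
#' @return data.frame with columns \code{sample}, \code{freq} (number of
#'   group members it neighbors) and \code{minCor} (minimum correlation
#'   to those members), sorted by decreasing \code{freq}.
#' @export
findNeighbors <- function(group, reference, minCor = 0.95, minFrac = 0.5) {
    gs <- fcScores(group)
    rs <- fcScores(reference)
    if (!ncol(gs)) stop("empty group")
    if (nrow(gs) != nrow(rs)) stop("group and reference FC bases differ")
    cc <- stats::cor(gs, rs)                 # members x reference
    hits <- cc > minCor
    freq <- colSums(hits)
    thr <- ceiling(minFrac * ncol(gs))
    keep <- which(freq >= pmax(thr, 1))
    minc <- vapply(keep, function(j) min(cc[hits[, j], j]), numeric(1))
    out <- data.frame(sample = colnames(rs)[keep],
                      freq = as.integer(freq[keep]),
                      minCor = minc, row.names = NULL)
    out[order(-out$freq, out$sample), , drop = FALSE]
}

#' Samples neighboring one group but not another
#'
#' Convenience set-difference of two [findNeighbors()] tables.
#'
#' @param neighborsA,neighborsB data.frames from [findNeighbors()].
#' @return The rows of \code{neighborsA} whose samples are absent from
#'   \code{neighborsB}.
#' @export
uniqueNeighbors <- function(neighborsA, neighborsB) {
    neighborsA[!(neighborsA$sample %in% neighborsB$sample), , drop = FALSE]
}

#' Build a tissue fingerprint library in FC space
#'
#' For every label selects the medoid sample (minimum summed 1 - Pearson
#' distance to same-label samples in FC space) and stores all labelled
#' score vectors for query annotation.
#'
#' @param reference [FCProjection-class] of the labelled reference
#'   samples.
#' @param labels named character vector (sample id -> tissue label) or a
#'   vector parallel to the reference samples.
#' @return A list of class \code{"fcFingerprint"} with \code{scores},
#'   \code{labels}, and \code{medoids} (label -> sample id).
#' @export
buildFingerprint <- function(reference, labels) {
    sc <- fcScores(reference)
    if (!is.null(names(labels))) labels <- labels[colnames(sc)]
    if (length(labels) != ncol(sc) || anyNA(labels))
        stop("labels must cover every reference sample")
    labels <- as.character(labels)
    medoids <- vapply(unique(labels), function(lab) {
        idx <- which(labels == lab)
        if (length(idx) == 1) return(colnames(sc)[idx])
        D <- 1 - stats::cor(sc[, idx, drop = FALSE])
        colnames(sc)[idx][which.min(rowSums(D))]
    }, character(1))
    structure(list(scores = sc, labels = stats::setNames(labels, colnames(sc)),
                   medoids = medoids),
              class = "fcFingerprint")
}

#' Annotate query samples with their most similar tissue
#'
#' Each query sample is correlated (Pearson, in FC space) against every
#' reference sample; the annotation is the label with the highest median
#' correlation, and the single best-correlated reference sample is also
#' reported.
#'
#' @param fingerprint an \code{fcFingerprint} from [buildFingerprint()].
#' @param query [FCProjection-class] on the same FC basis.
#' @return data.frame with one row per query sample: \code{sample},
#'   \code{label} (best median-correlation label), \code{medianCor},
#'   \code{bestSample}, \code{bestCor}.
#' @export
queryFingerprint <- function(fingerprint, query) {
    qs <- fcScores(query)
    rs <- fingerprint$scores
    if (nrow(qs) != nrow(rs)) stop("query and fingerprint FC bases differ")
    cc <- stats::cor(rs, qs)                 # reference x query
    labs <- fingerprint$labels
    do.call(rbind, lapply(seq_len(ncol(qs)), function(i) {
        med <- tapply(cc[, i], labs, stats::median)
        best <- which.max(cc[, i])
        data.frame(sample = colnames(qs)[i],
                   label = names(med)[which.max(med)],
                   medianCor = max(med),
                   bestSample = rownames(cc)[best],
                   bestCor = cc[best, i], row.names = NULL)
    }))
}

#' Cross-study tissue correlation summary
#'
#' For every pair of labels (e.g. "study/tissue" identifiers) reports the
#' median and SD of all cross-sample Pearson correlations in FC space, as
#' used to compare tissue fingerprints between two atlases.
#'
#' @param projection [FCProjection-class] holding both studies' samples.
#' @param labels named character vector of "study/tissue" labels.
#' @return A list with matrices \code{median} and \code{sd} (labels x
#'   labels).
#' @export
tissueCorrelationSummary <- function(projection, labels) {
    sc <- fcScores(projection)
    if (!is.null(names(labels))) labels <- labels[colnames(sc)]
    labels <- as.character(labels)
    ulab <- unique(labels)
    cc <- stats::cor(sc)
    med <- sdm <- matrix(NA_real_, length(ulab), length(ulab),
                         dimnames = list(ulab, ulab))
    for (a in seq_along(ulab)) for (b in seq_along(ulab)) {
        ia <- which(labels == ulab[a]); ib <- which(labels == ulab[b])
        vals <- cc[ia, ib]
        if (a == b) vals <- vals[upper.tri(vals)]
        if (!length(vals)) vals <- cc[ia, ib]
        med[a, b] <- stats::median(vals)
        sdm[a, b] <- if (length(vals) > 1) stats::sd(vals) else 0
    }
    list(median = med, sd = sdm)
}
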