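#' @include AllClasses.R
NULL

#' Active-gene module of a functional component
#'
#' Genes whose loading lies strictly more than \code{z} standard
#' deviations above the column mean form the up module; strictly below,
#' the down module.  Mean and SD are computed from the component's own
#' loading column.  The union of both is the component's active-gene set.
#'
#' @param loadings numeric loading vector (one column of S), or an
#'   [ICASolution-class] together with \code{fc} selecting a component.
#' @param geneIds gene identifiers parallel to \code{loadings}; defaults
#'   to the vector's names.
#' @param z threshold in SD units (default 3).
#' @param fc component index or name when \code{loadings} is a solution.
#' @return A list with \code{fc}, \code{up}, \code{down}, \code{active}
#'   (character vectors of gene ids) and \code{z}.
#' @export
activeGenes <- function(loadings, geneIds = NULL, z = 3, fc = NULL) {
    id <- if (is.null(fc)) NA_character_ else as.character(fc)
    if (is(loadings, "ICASolution")) {
        S <- sources(loadings)
        if (is.null(fc)) stop("supply fc to select a component")
        loadings <- S[, fc]
        if (is.null(geneIds)) geneIds <- rownames(S)
    }
    if (is.null(geneIds)) geneIds <- names(loadings)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_along(loadings))
    mu <- mean(loadings)
    sdv <- stats::sd(loadings)
    if (sdv == 0) stop("constant loading column")
    up <- geneIds[loadings > mu + z * sdv]
    down <- geneIds[loadings < mu - z * sdv]
    list(fc = id, up = up, down = down, active = union(up, down), z = z)
}

#' Overlap of an active-gene module with a gene signature
#'
#' @param module a module from [activeGenes()], or a character vector of
#'   active genes.
#' @param signature nonempty character vector of signature genes.
#' @return A list with \code{count} (shared genes) and \code{pct}
#'   (100 * count / signature size).
#' @examples
#' overlapPct(letters[1:10], letters[6:9])  # 4 shared, 100%
#' @export
overlapPct <- function(module, signature) {
    if (is.list(module)) module <- module$active
    if (!length(signature)) stop("empty signature")
    count <- length(intersect(module, signature))
    list(count = count, pct = 100 * count / length(signature))
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= overlap) for X hypergeometric with
#' \code{nSignature} successes in a universe of \code{nUniverse} genes
#' and \code{nActive} draws.
#'
#' @param overlap observed intersection size.
#' @param nActive active-gene set size (draws).
#' @param nSignature signature size (successes in the universe).
#' @param nUniverse gene universe size.
#' @return The upper-tail p-value.
#' @examples
#' hypergeomEnrich(3, 5, 4, 20)  # 496/15504
#' @export
hypergeomEnrich <- function(overlap, nActive, nSignature, nUniverse) {
    if (overlap > min(nActive, nSignature) || overlap < 0 ||
        nActive > nUniverse || nSignature > nUniverse)
        stop("inconsistent counts")
    stats::phyper(overlap - 1, nSignature, nUniverse - nSignature,
                  nActive, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment with an explicit family size
#'
#' Step-up BH where the family size N may exceed the number of supplied
#' p-values (e.g. N = total number of FCs or genes tested, with only a
#' subset of p-values passed in).  With N equal to the input length this
#' reproduces \code{p.adjust(..., "BH")}.
#'
#' @param p p-values in [0, 1].
#' @param N family size, at least \code{length(p)}.
#' @return Adjusted p-values in input order, capped at 1.
#' @export
bhAdjust <- function(p, N = length(p)) {
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    if (N < length(p)) stop("N must be at least length(p)")
    m <- length(p)
    if (!m) return(numeric(0))
    ord <- order(p)
    adj <- p[ord] * N / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[ord] <- adj
    out
}

#' Enrichment of all FC modules against a gene-set collection
#'
#' Extracts the active-gene module of every component, computes the
#' overlap with every gene set, a hypergeometric upper-tail p-value, and
#' a BH adjustment over all component-set pairs; pairs below \code{alpha}
#' are flagged as significant.
#'
#' @param sol an [ICASolution-class] (or loading matrix with rownames).
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param z active-gene threshold in SD units.
#' @param universe gene universe size; defaults to the number of genes in
#'   the loading matrix.
#' @param alpha BH significance threshold (default 0.01).
#' @return data.frame with columns \code{fc}, \code{set}, \code{count},
#'   \code{pct}, \code{p}, \code{pAdj}, \code{significant}.
#' @export
enrichModules <- function(sol, geneSets, z = 3, universe = NULL,
                          alpha = 0.01) {
    S <- if (is(sol, "ICASolution")) sources(sol) else as.matrix(sol)
    if (is.null(rownames(S))) rownames(S) <- paste0("g", seq_len(nrow(S)))
    if (is.null(universe)) universe <- nrow(S)
    rows <- list()
    for (j in seq_len(ncol(S))) {
        mod <- activeGenes(S[, j], rownames(S), z = z, fc = colnames(S)[j])
        for (setName in names(geneSets)) {
            sig <- intersect(geneSets[[setName]], rownames(S))
            if (!length(sig)) next
            ov <- overlapPct(mod, sig)
            p <- hypergeomEnrich(ov$count, length(mod$active), length(sig),
                                 universe)
            rows[[length(rows) + 1L]] <- data.frame(
                fc = mod$fc, set = setName, count = ov$count,
                pct = ov$pct, p = p)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(data.frame())
    out$pAdj <- bhAdjust(out$p)
    out$significant <- out$pAdj < alpha
    out
}

#' Gene promiscuity across FC modules
#'
#' Counts, for every gene active in at least one module, the number of
#' modules in which it is active.
#'
#' @param modules list of modules from [activeGenes()].
#' @return Named integer vector (gene -> count), sorted decreasing.
#' @export
promiscuity <- function(modules) {
    genes <- unlist(lapply(modules, function(m) m$active))
    if (!length(genes)) return(integer(0))
    sort(table(genes), decreasing = TRUE) |>
        (\(t) stats::setNames(as.integer(t), names(t)))()
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, member
#'   genes).
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
    fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#'
#' @param geneSets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to
#'   the set names).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(geneSets, path, descriptions = names(geneSets)) {
    lines <- vapply(seq_along(geneSets), function(i)
        paste(c(names(geneSets)[i], descriptions[i], geneSets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
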