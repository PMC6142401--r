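#' @include AllClasses.R
NULL

#' Accessors for fcmodules classes
#'
#' Small accessor family: \code{exprValues} returns the raw numeric matrix
#' of an [ExpressionMatrix-class]; \code{geneIds}/\code{sampleIds} its
#' labels; \code{nGenes}/\code{nSamples} its dimensions; \code{sources} and
#' \code{mixing} the S and A matrices of an [ICASolution-class];
#' \code{whitenedMatrix} and \code{covEigenvalues} the Y matrix and
#' eigenvalues of a [WhitenedData-class]; \code{fcScores} the score matrix
#' of an [FCProjection-class]; \code{alignedCor} the per-component aligned
#' correlations of a [MatchResult-class].
#'
#' @param object an fcmodules S4 object.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("sources", function(object) standardGeneric("sources"))
#' @rdname accessors
#' @export
setGeneric("mixing", function(object) standardGeneric("mixing"))
#' @rdname accessors
#' @export
setGeneric("totalNegentropy", function(object) standardGeneric("totalNegentropy"))
#' @rdname accessors
#' @export
setGeneric("whitenedMatrix", function(object) standardGeneric("whitenedMatrix"))
#' @rdname accessors
#' @export
setGeneric("covEigenvalues", function(object) standardGeneric("covEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("fcScores", function(object) standardGeneric("fcScores"))
#' @rdname accessors
#' @export
setGeneric("alignedCor", function(object) standardGeneric("alignedCor"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)
#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(object) rownames(object@values))
#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(object) colnames(object@values))
#' @rdname accessors
setMethod("nGenes", "ExpressionMatrix", function(object) nrow(object@values))
#' @rdname accessors
setMethod("nSamples", "ExpressionMatrix", function(object) ncol(object@values))

#' @rdname accessors
setMethod("geneIds", "WhitenedData", function(object) object@geneIds)
#' @rdname accessors
setMethod("sampleIds", "WhitenedData", function(object) object@sampleIds)
#' @rdname accessors
setMethod("nGenes", "WhitenedData", function(object) object@nGenes)
#' @rdname accessors
setMethod("whitenedMatrix", "WhitenedData", function(object) object@whitened)
#' @rdname accessors
setMethod("covEigenvalues", "WhitenedData", function(object) object@eigenvalues)
#' @rdname accessors
setMethod("nComponents", "WhitenedData", function(object) object@nComponents)

#' @rdname accessors
setMethod("sources", "ICASolution", function(object) object@S)
#' @rdname accessors
setMethod("mixing", "ICASolution", function(object) object@A)
#' @rdname accessors
setMethod("totalNegentropy", "ICASolution", function(object) object@totalNegentropy)
#' @rdname accessors
setMethod("nComponents", "ICASolution", function(object) ncol(object@S))

#' @rdname accessors
setMethod("fcScores", "FCProjection", function(object) object@scores)
#' @rdname accessors
setMethod("sampleIds", "FCProjection", function(object) object@sampleIds)
#' @rdname accessors
setMethod("nComponents", "FCProjection", function(object) nrow(object@scores))

#' @rdname accessors
setMethod("alignedCor", "MatchResult", function(object) object@alignedCor)

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object@values), "genes x",
        ncol(object@values), "samples\n")
})

setMethod("show", "WhitenedData", function(object) {
    cat("WhitenedData:", object@nGenes, "genes,",
        length(object@sampleIds), "samples;",
        object@nComponents, "retained components\n")
})

setMethod("show", "ICASolution", function(object) {
    cat(sprintf(
        "ICASolution (%s): %d genes x %d components; negentropy %.4f; %s in %d iterations (seed %d)\n",
        object@backend, nrow(object@S), ncol(object@S),
        object@totalNegentropy,
        if (object@converged) "converged" else "NOT converged",
        object@iterations, object@seed))
})

setMethod("show", "MatchResult", function(object) {
    cat(sprintf(
        "MatchResult: %d components; aligned correlations %.3f-%.3f (mean %.3f)\n",
        nrow(object@rho), min(object@alignedCor), max(object@alignedCor),
        mean(object@alignedCor)))
})

setMethod("show", "FCProjection", function(object) {
    cat(sprintf(
        "FCProjection: %d FCs x %d samples (%s loadings, coverage %.1f%%)\n",
        nrow(object@scores), ncol(object@scores),
        if (object@unitNorm) "unit-norm" else "raw",
        100 * object@coverage))
})
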