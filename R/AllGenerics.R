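#' @include AllClasses.R
NULL

#' Accessors for treecure classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{treeId} and \code{phyloTree} return a [GeneTree-class]'s identifier
#' and underlying \code{ape::phylo}; \code{tipInfo} its parsed tip identity
#' table; \code{catalogTable} and \code{planTable} the data frames inside a
#' [TranscriptCatalog-class] and [ReassignmentPlan-class]; \code{nodeTimes},
#' \code{nodeEvents} and \code{originTime} the calibrated times, event labels
#' and origin age of a [Chronogram-class].
#'
#' @param x the object.
#' @return the slot content (see Description).
#' @name accessors
#' @aliases treeId phyloTree tipInfo catalogTable planTable nodeTimes
#'   nodeEvents originTime
NULL

#' @rdname accessors
#' @export
setGeneric("treeId", function(x) standardGeneric("treeId"))
#' @rdname accessors
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))
#' @rdname accessors
#' @export
setGeneric("tipInfo", function(x) standardGeneric("tipInfo"))
#' @rdname accessors
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))
#' @rdname accessors
#' @export
setGeneric("planTable", function(x) standardGeneric("planTable"))
#' @rdname accessors
#' @export
setGeneric("nodeTimes", function(x) standardGeneric("nodeTimes"))
#' @rdname accessors
#' @export
setGeneric("nodeEvents", function(x) standardGeneric("nodeEvents"))
#' @rdname accessors
#' @export
setGeneric("originTime", function(x) standardGeneric("originTime"))

#' @rdname accessors
setMethod("treeId", "GeneTree", function(x) x@id)
#' @rdname accessors
setMethod("phyloTree", "GeneTree", function(x) x@tree)
#' @rdname accessors
setMethod("tipInfo", "GeneTree", function(x) x@tipInfo)
#' @rdname accessors
setMethod("catalogTable", "TranscriptCatalog", function(x) x@table)
#' @rdname accessors
setMethod("planTable", "ReassignmentPlan", function(x) x@table)
#' @rdname accessors
setMethod("treeId", "Chronogram", function(x) x@geneTree@id)
#' @rdname accessors
setMethod("phyloTree", "Chronogram", function(x) x@geneTree@tree)
#' @rdname accessors
setMethod("tipInfo", "Chronogram", function(x) x@geneTree@tipInfo)
#' @rdname accessors
setMethod("nodeTimes", "Chronogram", function(x) x@times)
#' @rdname accessors
setMethod("nodeEvents", "Chronogram", function(x) x@events)
#' @rdname accessors
setMethod("originTime", "Chronogram", function(x) x@tor)

setMethod("show", "GeneTree", function(object) {
    cat(sprintf("GeneTree '%s': %d tips, %d species\n", object@id,
                nrow(object@tipInfo), length(unique(object@tipInfo$species))))
})

setMethod("show", "TranscriptCatalog", function(object) {
    tb <- object@table
    cat(sprintf("TranscriptCatalog: %d transcripts, %d genes, %d species\n",
                nrow(tb), length(unique(tb$gene)), length(unique(tb$species))))
})

setMethod("show", "ReassignmentPlan", function(object) {
    tb <- object@table
    cat(sprintf("ReassignmentPlan (threshold %g): %d merge groups over %d genes\n",
                object@threshold, length(unique(tb$groupId)), nrow(tb)))
})

setMethod("show", "Chronogram", function(object) {
    cat(sprintf("Chronogram '%s': %d tips, t_or = %.4g, %d duplication node(s)\n",
                object@geneTree@id, nrow(object@geneTree@tipInfo), object@tor,
                sum(object@events == "duplication")))
})

setMethod("show", "MixtureParams", function(object) {
    cat(sprintf(paste0("MixtureParams: gamma(shape %.4g, rate %.4g), ",
                       "birth-death(lambda %.4g, mu %.4g), pi1 %.4g / pi2 %.4g\n"),
                object@alpha, object@beta, object@lam, object@mu,
                object@pi1, object@pi2))
})

setMethod("show", "PosteriorSamples", function(object) {
    cat(sprintf("PosteriorSamples: %d retained draws, %d chain(s)\n",
                nrow(object@draws), length(unique(object@chain))))
    print(object@summary, row.names = FALSE, digits = 5)
    if (any(object@rhat > 1.01, na.rm = TRUE))
        cat("note: split-Rhat > 1.01 for:",
            paste(names(object@rhat)[object@rhat > 1.01], collapse = ", "), "\n")
})

setMethod("show", "DecisionRule", function(object) {
    cat(sprintf(paste0("DecisionRule: errRate %.3g (loss ratio %.4g), ",
                       "t* = %.6g, length threshold = %s\n"),
                object@errRate, object@lossRatio, object@tStar,
                ifelse(is.na(object@lengthThreshold), "<not back-calibrated>",
                       format(object@lengthThreshold, digits = 6))))
})
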