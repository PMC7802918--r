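#' @import methods
NULL

#' GeneTree: a gene phylogeny with parsed tip identities
#'
#' A rooted phylogeny (an \code{ape::phylo} with branch lengths) in which each
#' tip is a single exemplar transcript standing in for a gene of one species.
#' The parsed identity of every tip is kept alongside the tree in
#' \code{tipInfo}, a data frame with columns \code{label}, \code{species},
#' \code{gene} and \code{transcript}, one row per tip in tip-number order.
#'
#' Validity requires a rooted tree, non-negative branch lengths on every edge,
#' one \code{tipInfo} row per tip, and uniqueness of (species, gene) pairs:
#' one exemplar per gene.
#'
#' @slot id single character, identifier of the gene family.
#' @slot tree an \code{ape::phylo}, rooted, with \code{edge.length}.
#' @slot tipInfo data.frame with columns label, species, gene, transcript.
#'
#' @seealso [readGeneTrees()], [subtreeLengths()], [annotateEvents()]
#' @export
setClass("GeneTree",
    representation(id = "character", tree = "ANY", tipInfo = "data.frame"))

setValidity("GeneTree", function(object) {
    tr <- object@tree
    if (!inherits(tr, "phylo"))
        return("'tree' must be an ape 'phylo' object")
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        return("'id' must be a single non-empty string")
    if (is.null(tr$edge.length))
        return("tree has no branch lengths; subtree lengths are undefined")
    if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
        return("branch lengths must all be present and >= 0")
    if (!ape::is.rooted(tr))
        return("tree must be rooted")
    ti <- object@tipInfo
    need <- c("label", "species", "gene", "transcript")
    if (!all(need %in% names(ti)))
        return(sprintf("tipInfo must have columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(ti) != length(tr$tip.label))
        return("tipInfo must have exactly one row per tip")
    if (!identical(ti$label, tr$tip.label))
        return("tipInfo$label must match tree tip labels in tip order")
    key <- paste(ti$species, ti$gene, sep = "\r")
    if (anyDuplicated(key))
        return("(species, gene) pairs must be unique within a GeneTree")
    TRUE
})

#' TranscriptCatalog: the transcript -> gene -> species assignment table
#'
#' The object that the method revises: an assembler's assignment of
#' transcripts to genes, one row per transcript, with the species each gene
#' belongs to and (optionally) the transcript length in nucleotides used for
#' exemplar reselection.
#'
#' Validity: transcript ids are unique across the catalog and every gene maps
#' to exactly one species.
#'
#' @slot table data.frame with columns transcript, gene, species and numeric
#'   length (NA when unknown).
#'
#' @seealso [readCatalog()], [applyPlan()], [selectExemplar()]
#' @export
setClass("TranscriptCatalog", representation(table = "data.frame"))

setValidity("TranscriptCatalog", function(object) {
    tb <- object@table
    need <- c("transcript", "gene", "species", "length")
    if (!all(need %in% names(tb)))
        return(sprintf("catalog table must have columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(tb$transcript))
        return(sprintf("duplicated transcript id(s): %s",
            paste(utils::head(unique(tb$transcript[duplicated(tb$transcript)]), 3L),
                  collapse = ", ")))
    sp <- tapply(tb$species, tb$gene, function(s) length(unique(s)))
    if (length(sp) && any(sp > 1L))
        return(sprintf("gene(s) mapped to more than one species: %s",
                       paste(utils::head(names(sp)[sp > 1L], 3L), collapse = ", ")))
    if (!is.numeric(tb$length))
        return("'length' column must be numeric (NA allowed)")
    TRUE
})

#' ReassignmentPlan: gene sets flagged for merging
#'
#' Disjoint groups of genes, each group within a single species, whose
#' transcripts are to be reassigned to one gene. Each row of the plan table
#' names one member gene; \code{triggerTree} and \code{triggerLength} record
#' the flagged subtree (the provenance) with the smallest total length that
#' placed the gene in its group.
#'
#' @slot table data.frame with columns groupId, species, gene, triggerTree,
#'   triggerLength.
#' @slot threshold the subtree-length threshold the plan was built with.
#'
#' @seealso [flagCandidates()], [applyPlan()]
#' @export
setClass("ReassignmentPlan",
    representation(table = "data.frame", threshold = "numeric"))

setValidity("ReassignmentPlan", function(object) {
    tb <- object@table
    need <- c("groupId", "species", "gene", "triggerTree", "triggerLength")
    if (!all(need %in% names(tb)))
        return(sprintf("plan table must have columns %s",
                       paste(need, collapse = ", ")))
    if (length(object@threshold) != 1L || object@threshold <= 0)
        return("'threshold' must be a single positive number")
    if (nrow(tb)) {
        if (anyDuplicated(paste(tb$species, tb$gene, sep = "\r")))
            return("a gene may belong to at most one merge group")
        sz <- table(tb$groupId)
        if (any(sz < 2L))
            return("every merge group must contain >= 2 genes")
        nsp <- tapply(tb$species, tb$groupId, function(s) length(unique(s)))
        if (any(nsp > 1L))
            return("a merge group must not span species")
    }
    TRUE
})

#' Chronogram: a time-calibrated gene phylogeny with node events
#'
#' Node times run from 0 at the tips toward the origin; the calibration
#' anchors the deepest speciation node at time 1, so the root age
#' (\code{tor}) equals 1 unless duplications predate the first speciation,
#' in which case \code{tor > 1} and the tree is meant to be dropped by
#' [filterOrigin()]. Internal nodes carry a \code{"duplication"} or
#' \code{"speciation"} label from the species-overlap annotation.
#'
#' @slot geneTree the source [GeneTree-class].
#' @slot times numeric vector of node times, indexed by ape node number
#'   (tips first); tips are exactly 0.
#' @slot events character vector of internal-node event labels, indexed by
#'   internal node number minus the number of tips.
#' @slot tor single numeric, the time of origin (root age).
#'
#' @seealso [ultrametricize()], [extractDuplicationTimes()], [filterOrigin()]
#' @export
setClass("Chronogram",
    representation(geneTree = "GeneTree", times = "numeric",
                   events = "character", tor = "numeric"))

setValidity("Chronogram", function(object) {
    tr <- object@geneTree@tree
    ntip <- length(tr$tip.label)
    nn <- ntip + tr$Nnode
    if (length(object@times) != nn)
        return("'times' must have one entry per node (tips + internal)")
    if (length(object@events) != tr$Nnode)
        return("'events' must have one entry per internal node")
    if (!all(object@events %in% c("duplication", "speciation")))
        return("events must be 'duplication' or 'speciation'")
    if (length(object@tor) != 1L || !is.finite(object@tor) || object@tor < 0)
        return("'tor' must be a single non-negative number")
    tol <- 1e-8 * max(object@tor, 1)
    if (any(abs(object@times[seq_len(ntip)]) > tol))
        return("tip times must be 0")
    if (any(object@times < -tol) || any(object@times > object@tor + tol))
        return("node times must lie in [0, tor]")
    parent <- tr$edge[, 1L]; child <- tr$edge[, 2L]
    if (any(object@times[parent] < object@times[child] - tol))
        return("ultrametric consistency violated: a parent is younger than its child")
    TRUE
})

#' MixtureParams: parameters of the duplication-time mixture
#'
#' Component 1 (spurious duplications from transcript misassignment) is
#' gamma with shape \code{alpha} and rate \code{beta}; component 2 (true
#' duplications) is the constant-rate birth-death branching-time density
#' with birth rate \code{lam}, death rate \code{mu} and origin time fixed
#' elsewhere; \code{pi1}, \code{pi2} are the mixing proportions.
#'
#' @slot alpha,beta gamma shape and rate, both > 0.
#' @slot lam,mu birth and death rates; lam > 0, mu >= 0.
#' @slot pi1,pi2 mixing proportions in [0, 1] summing to 1.
#'
#' @seealso [mixtureDensity()], [gibbsFit()], [selectThreshold()]
#' @export
setClass("MixtureParams",
    representation(alpha = "numeric", beta = "numeric", lam = "numeric",
                   mu = "numeric", pi1 = "numeric", pi2 = "numeric"))

setValidity("MixtureParams", function(object) {
    one <- function(v) length(v) == 1L && is.finite(v)
    for (s in c("alpha", "beta", "lam", "mu", "pi1", "pi2"))
        if (!one(slot(object, s))) return(sprintf("'%s' must be a single finite number", s))
    if (object@alpha <= 0 || object@beta <= 0) return("alpha and beta must be > 0")
    if (object@lam <= 0) return("lam must be > 0")
    if (object@mu < 0) return("mu must be >= 0")
    if (object@pi1 < 0 || object@pi2 < 0) return("mixing proportions must be >= 0")
    if (abs(object@pi1 + object@pi2 - 1) > 1e-8) return("pi1 + pi2 must equal 1")
    TRUE
})

#' PosteriorSamples: retained MCMC draws and their summaries
#'
#' Post-burn-in, thinned draws of the mixture parameters across chains,
#' together with posterior summaries (mean, 95\% interval, Monte Carlo
#' error), split-Rhat convergence diagnostics, the posterior component-1
#' membership probability of every observation, and the sampler
#' configuration.
#'
#' @slot draws matrix of retained draws (rows) by parameter (columns
#'   alpha, beta, lam, mu, pi1).
#' @slot chain integer chain index per retained draw.
#' @slot summary data.frame: parameter, mean, lower95, upper95, mcerr.
#' @slot rhat named numeric split-Rhat per parameter.
#' @slot memberProb numeric, posterior P(z = 1 | x) per observation.
#' @slot config list of sampler settings used.
#'
#' @seealso [gibbsFit()], [posteriorMeans()]
#' @export
setClass("PosteriorSamples",
    representation(draws = "matrix", chain = "integer", summary = "data.frame",
                   rhat = "numeric", memberProb = "numeric", config = "list"))

#' DecisionRule: the fitted flagging rule
#'
#' The decision-theoretic translation of the mixture fit: at error rate
#' \code{errRate} the implied loss matrix penalises flagging a true
#' duplication \code{lossRatio} = (1 - errRate)/errRate times more than
#' missing a spurious one; \code{tStar} is the duplication-time boundary
#' where P(z = 2 | x) crosses errRate, and \code{lengthThreshold} is its
#' back-calibration onto subtree lengths in the original trees.
#'
#' @slot errRate significance level for misflagging a true duplication.
#' @slot lossRatio implied off-diagonal loss ratio.
#' @slot tStar duplication-time boundary (origin = 1 scale).
#' @slot lengthThreshold back-calibrated subtree-length threshold
#'   (substitutions/site); NA until [backCalibrate()] is run.
#'
#' @seealso [selectThreshold()], [backCalibrate()]
#' @export
setClass("DecisionRule",
    representation(errRate = "numeric", lossRatio = "numeric",
                   tStar = "numeric", lengthThreshold = "numeric"))

setValidity("DecisionRule", function(object) {
    if (object@errRate <= 0 || object@errRate >= 1)
        return("errRate must be in (0, 1)")
    if (abs(object@lossRatio - (1 - object@errRate) / object@errRate) > 1e-6)
        return("lossRatio must equal (1 - errRate)/errRate")
    if (object@tStar < 0) return("tStar must be >= 0")
    if (!is.na(object@lengthThreshold) && object@lengthThreshold < 0)
        return("lengthThreshold must be >= 0")
    TRUE
})
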