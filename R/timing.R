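#' @include AllClasses.R flagging.R
NULL

#' Annotate internal nodes as duplication or speciation events
#'
#' Uses the species-overlap criterion: an internal node is a duplication
#' when at least two of its child clades share a species (the same species
#' appears on both sides of the split), and a speciation otherwise. This is
#' a fast approximation to full gene-tree/species-tree reconciliation; it
#' needs the species tree only to validate that every tip species is known.
#'
#' @param tree a [GeneTree-class].
#' @param speciesTree rooted species phylogeny (\code{ape::phylo}) whose tip
#'   labels include all species in \code{tree}; NULL skips the check.
#' @return character vector of \code{"duplication"}/\code{"speciation"}, one
#'   per internal node, in ape internal-node order.
#' @examples
#' g <- GeneTree(ape::read.tree(text = "((a@x@t:0.1,a@y@t2:0.1):0.3,b@x@t3:0.4);"))
#' annotateEvents(g)
#' @export
annotateEvents <- function(tree, speciesTree = NULL) {
    stopifnot(methods::is(tree, "GeneTree"))
    ti <- tipInfo(tree)
    if (!is.null(speciesTree)) {
        unknown <- setdiff(unique(ti$species), speciesTree$tip.label)
        if (length(unknown))
            stop(sprintf("species not in the species tree: %s",
                         paste(unknown, collapse = ", ")))
    }
    phy <- phyloTree(tree)
    st <- cladeStats(phy)
    ntip <- st$ntip
    spUnder <- lapply(st$tipsUnder, function(i) unique(ti$species[unlist(i)]))
    ev <- character(st$nnode)
    for (n in ntip + seq_len(st$nnode)) {
        children <- phy$edge[phy$edge[, 1L] == n, 2L]
        sets <- spUnder[children]
        overlap <- FALSE
        if (length(sets) > 1L) {
            pooled <- unlist(sets)
            overlap <- anyDuplicated(pooled) > 0L
        }
        ev[n - ntip] <- if (overlap) "duplication" else "speciation"
    }
    ev
}

#' Time-calibrate a gene tree into a chronogram
#'
#' Node times are obtained by mean-path-length smoothing: each internal
#' node's raw depth is the average branch-length distance to its descendant
#' tips, with a post-order pass enforcing parent >= child so the result is
#' a consistent ultrametric. Times are then rescaled so the deepest
#' speciation-labeled node sits at time 1 (the origin convention: tips at
#' 0, first speciation at 1). Trees whose root is a duplication older than
#' every speciation therefore get a time of origin above 1 and are meant to
#' be removed by [filterOrigin()]. With no event labels (or no speciation
#' node) the root itself is anchored at 1.
#'
#' Because the calibration divides by a depth, duplication times are
#' invariant under uniform rescaling of the input branch lengths.
#'
#' @param tree a [GeneTree-class] with positive total length.
#' @param events per-internal-node labels from [annotateEvents()]; computed
#'   on the fly when NULL.
#' @param speciesTree optional species tree passed to [annotateEvents()].
#' @return a [Chronogram-class].
#' @export
ultrametricize <- function(tree, events = NULL, speciesTree = NULL) {
    stopifnot(methods::is(tree, "GeneTree"))
    phy <- phyloTree(tree)
    if (sum(phy$edge.length) <= 0)
        stop(sprintf("tree '%s' has zero total length; cannot calibrate",
                     treeId(tree)))
    if (is.null(events)) events <- annotateEvents(tree, speciesTree)
    st <- cladeStats(phy)
    ntip <- st$ntip
    nn <- ntip + st$nnode
    raw <- numeric(nn)
    nodes <- ntip + seq_len(st$nnode)
    raw[nodes] <- st$pathSum[nodes] / st$nTips[nodes]
    # enforce ultrametric consistency (mean paths need not be monotone)
    po <- ape::reorder.phylo(phy, "postorder")
    for (e in seq_len(nrow(po$edge))) {
        par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
        if (raw[par] < raw[ch]) raw[par] <- raw[ch]
    }
    isSpec <- events == "speciation"
    anchor <- if (any(isSpec)) max(raw[nodes[isSpec]]) else raw[ntip + 1L]
    if (anchor <= 0) anchor <- max(raw)   # degenerate: all depth at tips
    times <- raw / anchor
    root <- ntip + 1L
    methods::new("Chronogram", geneTree = tree, times = times,
                 events = events, tor = times[root])
}

#' Build chronograms for a set of gene trees
#'
#' @param trees list of [GeneTree-class].
#' @param speciesTree optional rooted species tree for event validation.
#' @return list of [Chronogram-class].
#' @export
makeChronograms <- function(trees, speciesTree = NULL) {
    lapply(trees, ultrametricize, speciesTree = speciesTree)
}

#' Extract duplication times from chronograms
#'
#' One sample per duplication-labeled internal node; the time is the node's
#' calibrated age (0 = present, 1 = first speciation).
#'
#' @param chronograms a [Chronogram-class] or list of them.
#' @return data.frame with columns \code{treeId}, \code{node}, \code{time}.
#' @export
extractDuplicationTimes <- function(chronograms) {
    if (methods::is(chronograms, "Chronogram"))
        chronograms <- list(chronograms)
    if (length(chronograms) == 0L)
        return(data.frame(treeId = character(0), node = integer(0),
                          time = numeric(0)))
    out <- lapply(chronograms, function(ch) {
        phy <- phyloTree(ch)
        ntip <- length(phy$tip.label)
        dup <- which(nodeEvents(ch) == "duplication")
        data.frame(treeId = rep(treeId(ch), length(dup)), node = ntip + dup,
                   time = nodeTimes(ch)[ntip + dup])
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Drop chronograms whose time of origin exceeds 1
#'
#' Families whose root duplication predates the first speciation calibrate
#' to an origin above 1; their duplication times are not comparable to the
#' rest and they are removed from the mixture fit and downstream analyses.
#'
#' @param chronograms list of [Chronogram-class].
#' @param maxOrigin cut-off (default 1).
#' @param tol numerical slack on the comparison.
#' @return the retained sublist.
#' @export
filterOrigin <- function(chronograms, maxOrigin = 1, tol = 1e-8) {
    keep <- vapply(chronograms, function(ch) originTime(ch) <= maxOrigin + tol,
                   logical(1))
    chronograms[keep]
}

#' Prune merged genes out of gene trees
#'
#' The analogue of re-building trees after reassignment when only branch
#' lengths are available: within every merge group of the plan, all tips
#' but the one with the smallest gene id are dropped, and the kept tip is
#' relabeled with the merged gene id. Used to compare duplication-time
#' distributions before and after revision.
#'
#' @param trees list of [GeneTree-class].
#' @param plan a [ReassignmentPlan-class].
#' @return list of [GeneTree-class] (trees collapsing below 2 tips are dropped).
#' @export
pruneMerged <- function(trees, plan) {
    pt <- planTable(plan)
    if (nrow(pt) == 0L) return(trees)
    key <- paste(pt$species, pt$gene, sep = "|")
    target <- stats::setNames(
        vapply(split(pt$gene, pt$groupId), min, character(1)),
        vapply(split(pt$groupId, pt$groupId), `[`, character(1), 1L))
    grpOf <- stats::setNames(pt$groupId, key)
    out <- list()
    for (g in trees) {
        ti <- tipInfo(g)
        k <- paste(ti$species, ti$gene, sep = "|")
        grp <- grpOf[k]
        drop <- logical(nrow(ti))
        for (gr in unique(grp[!is.na(grp)])) {
            i <- which(!is.na(grp) & grp == gr)
            keep <- i[order(ti$gene[i])][1L]
            drop[setdiff(i, keep)] <- TRUE
            ti$gene[keep] <- target[[gr]]
        }
        if (sum(!drop) < 2L) next
        phy <- phyloTree(g)
        phy$tip.label <- paste(ti$species, ti$gene, ti$transcript, sep = "@")
        if (any(drop))
            phy <- ape::drop.tip(phy, which(drop))
        out[[length(out) + 1L]] <- GeneTree(phy, id = treeId(g))
    }
    out
}
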