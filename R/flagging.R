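#' @include AllClasses.R
NULL

# Post-order accumulation shared by several operations: for every node,
# the clade branch-length sum (stem excluded), descendant tip indices,
# and the sum/count of root-to-tip path lengths below it.
cladeStats <- function(tree) {
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    po <- ape::reorder.phylo(tree, "postorder")
    cladeLen <- numeric(nn)
    pathSum <- numeric(nn)         # sum over descendant tips of dist(node, tip)
    nTips <- integer(nn)
    nTips[seq_len(ntip)] <- 1L
    tipsUnder <- vector("list", nn)
    tipsUnder[seq_len(ntip)] <- as.list(seq_len(ntip))
    for (e in seq_len(nrow(po$edge))) {
        par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]; bl <- po$edge.length[e]
        cladeLen[par] <- cladeLen[par] + cladeLen[ch] + bl
        pathSum[par] <- pathSum[par] + pathSum[ch] + nTips[ch] * bl
        nTips[par] <- nTips[par] + nTips[ch]
        tipsUnder[[par]] <- c(tipsUnder[[par]], tipsUnder[[ch]])
    }
    list(cladeLen = cladeLen, pathSum = pathSum, nTips = nTips,
         tipsUnder = tipsUnder, ntip = ntip, nnode = tree$Nnode)
}

#' Subtree total lengths for every internal node
#'
#' Traverses the gene phylogeny and, for each internal node, sums the
#' branch lengths of the subtree the node defines. By default the stem
#' branch above the node is excluded ("sum of all branch lengths of the
#' subtree" reads most naturally as the edges within the clade);
#' \code{includeStem = TRUE} switches convention. Near-zero totals over
#' several same-species tips are the misassignment signal.
#'
#' @param tree a [GeneTree-class].
#' @param includeStem also count the branch above the defining node.
#' @return data.frame with one row per internal node: \code{node} (ape node
#'   number), \code{totalLength}, \code{nTips}, \code{nSpecies}, and
#'   list-columns \code{species} (species multiset of the descendant tips)
#'   and \code{genes} (their "species|gene" keys).
#' @examples
#' g <- GeneTree(ape::read.tree(text = "((a@x@t:0.1,a@y@t2:0.2):0.3,b@x@t3:0.4);"))
#' subtreeLengths(g)
#' @export
subtreeLengths <- function(tree, includeStem = FALSE) {
    stopifnot(methods::is(tree, "GeneTree"))
    phy <- phyloTree(tree)
    st <- cladeStats(phy)
    nodes <- st$ntip + seq_len(st$nnode)
    tot <- st$cladeLen[nodes]
    if (includeStem) {
        stem <- numeric(st$ntip + st$nnode)
        stem[phy$edge[, 2L]] <- phy$edge.length
        tot <- tot + stem[nodes]
    }
    ti <- tipInfo(tree)
    sp <- lapply(nodes, function(n) ti$species[unlist(st$tipsUnder[[n]])])
    gn <- lapply(nodes, function(n) {
        i <- unlist(st$tipsUnder[[n]])
        paste(ti$species[i], ti$gene[i], sep = "|")
    })
    out <- data.frame(node = nodes, totalLength = tot, nTips = st$nTips[nodes],
                      nSpecies = vapply(sp, function(s) length(unique(s)), 1L))
    out$species <- sp
    out$genes <- gn
    out
}

# Minimal union-find over character keys.
ufNew <- function() new.env(parent = emptyenv())
ufFind <- function(uf, x) {
    r <- x
    while (!is.null(p <- uf[[r]]) && p != r) r <- p
    # path compression
    while (!is.null(p <- uf[[x]]) && p != x) { uf[[x]] <- r; x <- p }
    if (is.null(uf[[r]])) uf[[r]] <- r
    r
}
ufUnion <- function(uf, a, b) {
    ra <- ufFind(uf, a); rb <- ufFind(uf, b)
    if (ra != rb) uf[[max(ra, rb)]] <- min(ra, rb)
    invisible(NULL)
}

#' Flag same-species gene sets in improbably short subtrees
#'
#' For every internal node whose subtree total length is strictly below the
#' threshold, genes of a single species with two or more tips in that
#' subtree are flagged as putative fragments of one gene. Qualifying sets
#' are merged transitively (union-find) across nested subtrees and across
#' trees, so a gene appearing in qualifying subtrees of two families joins
#' both into one group. Genes of different species are never merged.
#'
#' The default threshold 0.0005 (substitutions/site) is the fitted
#' pipeline-level default; [selectThreshold()] + [backCalibrate()] derive a
#' dataset-specific value.
#'
#' @param trees list of [GeneTree-class] (a single GeneTree is accepted).
#' @param threshold positive subtree-length bound; flagging uses strict
#'   \code{totalLength < threshold}.
#' @param includeStem passed to [subtreeLengths()].
#' @return a [ReassignmentPlan-class]; empty table when nothing qualifies.
#' @examples
#' g <- GeneTree(ape::read.tree(text =
#'   "((Hydra@g1@t1:0.0001,Hydra@g2@t2:0.0001):0.5,Nanomia@g1@t9:0.3);"))
#' flagCandidates(list(g), threshold = 0.0005)
#' @export
flagCandidates <- function(trees, threshold = 0.0005, includeStem = FALSE) {
    if (methods::is(trees, "GeneTree")) trees <- list(trees)
    stopifnot(length(threshold) == 1L, threshold > 0)
    uf <- ufNew()
    trigTree <- character(0); trigLen <- numeric(0); trigKey <- character(0)
    for (g in trees) {
        recs <- subtreeLengths(g, includeStem = includeStem)
        hit <- which(recs$totalLength < threshold)
        for (i in hit) {
            keys <- recs$genes[[i]]
            spl <- split(keys, recs$species[[i]])
            for (sameSp in spl) {
                gs <- unique(sameSp)
                if (length(gs) < 2L) next
                for (j in seq_along(gs)[-1L]) ufUnion(uf, gs[1L], gs[j])
                new <- !(gs %in% trigKey)
                trigKey <- c(trigKey, gs[new])
                trigTree <- c(trigTree, rep(treeId(g), sum(new)))
                trigLen <- c(trigLen, rep(recs$totalLength[i], sum(new)))
                # keep the shortest triggering subtree per gene
                old <- match(gs[!new], trigKey)
                upd <- old[trigLen[old] > recs$totalLength[i]]
                trigLen[upd] <- recs$totalLength[i]
                trigTree[upd] <- treeId(g)
            }
        }
    }
    if (length(trigKey) == 0L) {
        tb <- data.frame(groupId = character(0), species = character(0),
                         gene = character(0), triggerTree = character(0),
                         triggerLength = numeric(0))
        return(methods::new("ReassignmentPlan", table = tb, threshold = threshold))
    }
    root <- vapply(trigKey, function(k) ufFind(uf, k), character(1))
    sp <- sub("\\|.*$", "", trigKey)
    gene <- sub("^[^|]*\\|", "", trigKey)
    grp <- match(root, sort(unique(root)))
    tb <- data.frame(groupId = sprintf("m%04d", grp), species = sp, gene = gene,
                     triggerTree = trigTree, triggerLength = trigLen)
    tb <- tb[order(tb$groupId, tb$species, tb$gene), , drop = FALSE]
    rownames(tb) <- NULL
    methods::new("ReassignmentPlan", table = tb, threshold = threshold)
}

#' Apply a reassignment plan to a transcript catalog
#'
#' Transcripts of all genes in a merge group are reassigned to a single
#' gene, deterministically named after the lexicographically smallest
#' member id. All other rows are untouched; the transcript set is conserved
#' exactly. Applying a plan twice equals applying it once.
#'
#' @param catalog a [TranscriptCatalog-class].
#' @param plan a [ReassignmentPlan-class].
#' @return the revised [TranscriptCatalog-class].
#' @export
applyPlan <- function(catalog, plan) {
    stopifnot(methods::is(catalog, "TranscriptCatalog"),
              methods::is(plan, "ReassignmentPlan"))
    tb <- catalogTable(catalog)
    pt <- planTable(plan)
    if (nrow(pt) == 0L) return(catalog)
    missing <- setdiff(pt$gene, tb$gene)
    # idempotence: a gene already merged away is fine if its group target exists
    if (length(missing)) {
        tgt <- vapply(split(pt$gene, pt$groupId), min, character(1))
        bad <- vapply(missing, function(g) {
            grp <- pt$groupId[match(g, pt$gene)]
            !(tgt[[grp]] %in% tb$gene)
        }, logical(1))
        if (any(bad))
            stop(sprintf("plan references gene(s) absent from the catalog: %s",
                         paste(missing[bad], collapse = ", ")))
    }
    for (grp in split(pt, pt$groupId)) {
        newId <- min(grp$gene)
        sel <- tb$gene %in% grp$gene
        if (!all(tb$species[sel] == grp$species[1L]))
            stop(sprintf("species mismatch between plan group %s and catalog",
                         grp$groupId[1L]))
        tb$gene[sel] <- newId
    }
    TranscriptCatalog(tb$transcript, tb$gene, tb$species, tb$length)
}

#' Select the exemplar transcript of a gene
#'
#' Returns the longest transcript assigned to the gene, breaking ties by the
#' lexicographically smallest transcript id. (Expression-weighted exemplar
#' scoring is out of scope; length is the classical fallback.)
#'
#' @param catalog a [TranscriptCatalog-class] with lengths available.
#' @param gene gene id present in the catalog.
#' @return single transcript id.
#' @export
selectExemplar <- function(catalog, gene) {
    tb <- catalogTable(catalog)
    rows <- tb[tb$gene == gene, , drop = FALSE]
    if (nrow(rows) == 0L) stop(sprintf("gene '%s' not in catalog", gene))
    if (anyNA(rows$length))
        stop(sprintf("transcript length(s) missing for gene '%s'", gene))
    best <- rows$transcript[rows$length == max(rows$length)]
    min(best)
}

#' One-call revision of a transcript catalog
#'
#' Convenience wrapper: flag candidate merges across the gene trees at the
#' given subtree-length threshold (default 0.0005 when no fitted rule is
#' supplied) and apply them to the catalog.
#'
#' @param trees list of [GeneTree-class].
#' @param catalog a [TranscriptCatalog-class].
#' @param threshold subtree-length threshold, or a [DecisionRule-class]
#'   whose back-calibrated \code{lengthThreshold} is used.
#' @param includeStem passed to [flagCandidates()].
#' @return list with elements \code{plan} and \code{catalog} (revised).
#' @export
reviseTranscriptAssignments <- function(trees, catalog, threshold = 0.0005,
                                        includeStem = FALSE) {
    if (methods::is(threshold, "DecisionRule")) {
        threshold <- threshold@lengthThreshold
        if (is.na(threshold))
            stop("DecisionRule has no back-calibrated length threshold")
    }
    plan <- flagCandidates(trees, threshold = threshold,
                           includeStem = includeStem)
    list(plan = plan, catalog = applyPlan(catalog, plan))
}
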