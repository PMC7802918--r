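#' @include AllClasses.R treeio.R flagging.R mixture.R
NULL

#' Default 7-taxon balanced ultrametric species tree
#'
#' A depth-1 ultrametric species phylogeny on seven species
#' (\code{sp1..sp7}), shipped as a plain-text fixture; the scale of a small
#' multi-species phylotranscriptomic dataset.
#'
#' @return an \code{ape::phylo}.
#' @export
defaultSpeciesTree <- function() {
    ape::read.tree(system.file("extdata", "species_tree_7taxa.nwk",
                               package = "treecure", mustWork = TRUE))
}

#' Sample duplication times from the two-component mixture
#'
#' Draws each sample by first choosing the component (z = 1 with
#' probability pi1), then the time: gamma for component 1, birth-death
#' branching time (inverse-CDF on the origin-conditioned density, so
#' truncated to \code{[0, tor]}) for component 2. The true labels are
#' retained, which is what makes parameter-recovery checks possible.
#'
#' @param n number of samples.
#' @param params a [MixtureParams-class].
#' @param tor origin time (default 1).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{x} (time) and \code{z} (1 or 2).
#' @export
sampleMixture <- function(n, params, tor = 1, seed = NULL) {
    stopifnot(methods::is(params, "MixtureParams"), n >= 1)
    if (!is.null(seed)) set.seed(seed)
    z <- ifelse(stats::runif(n) < params@pi1, 1L, 2L)
    x <- numeric(n)
    n1 <- sum(z == 1L)
    x[z == 1L] <- stats::rgamma(n1, shape = params@alpha, rate = params@beta)
    x[z == 2L] <- bdDuptimeQuantile(stats::runif(n - n1), params@lam,
                                    params@mu, tor)
    data.frame(x = x, z = z)
}

# one gene lineage entering the branch above species node 'spNode' at age
# 'tTop' (time before present); returns a nested node/tip structure of the
# reconstructed (surviving) subtree, or NULL on extinction.
simLineage <- function(spNode, tTop, sp, lam, mu, counter) {
    aNode <- sp$age[spNode]
    repeat {
        w <- if (lam + mu > 0) stats::rexp(1L, lam + mu) else Inf
        tNext <- tTop - w
        if (tNext > aNode) {
            if (stats::runif(1L) < lam / (lam + mu)) {  # duplication
                counter$events <- counter$events + 1L
                if (counter$tips > counter$maxTips) stop("family size cap hit")
                left <- simLineage(spNode, tNext, sp, lam, mu, counter)
                right <- simLineage(spNode, tNext, sp, lam, mu, counter)
                if (is.null(left)) return(right)
                if (is.null(right)) return(left)
                return(list(type = "node", event = "duplication", age = tNext,
                            kids = list(left, right)))
            }
            return(NULL)                                # death
        }
        # reached the species node
        kidsIdx <- sp$children[[spNode]]
        if (length(kidsIdx) == 0L) {                    # species tip: a gene
            counter$tips <- counter$tips + 1L
            return(list(type = "tip", species = sp$label[spNode], age = 0))
        }
        kids <- lapply(kidsIdx, function(k)
            simLineage(k, aNode, sp, lam, mu, counter))
        kids <- kids[!vapply(kids, is.null, logical(1))]
        if (length(kids) == 0L) return(NULL)
        if (length(kids) == 1L) return(kids[[1L]])
        return(list(type = "node", event = "speciation", age = aNode,
                    kids = kids))
    }
}

nodeToNewick <- function(nd, parentAge, labelOf) {
    bl <- parentAge - nd$age
    if (nd$type == "tip")
        return(sprintf("%s:%.12g", labelOf(nd$species), bl))
    inner <- paste(vapply(nd$kids, nodeToNewick, character(1),
                          parentAge = nd$age, labelOf = labelOf),
                   collapse = ",")
    sprintf("(%s):%.12g", inner, bl)
}

collectDupAges <- function(nd) {
    if (nd$type == "tip") return(numeric(0))
    own <- if (nd$event == "duplication") nd$age else numeric(0)
    c(own, unlist(lapply(nd$kids, collectDupAges)))
}

#' Simulate gene families by duplication and loss along a species tree
#'
#' Each family starts as a single gene lineage at the species-tree root and
#' evolves by a constant-rate birth-death process embedded in the species
#' tree: duplications at rate \code{lam}, losses at rate \code{mu}
#' (per lineage per unit time), with lineages copied into both daughter
#' species at every speciation. Surviving tips become genes; each gene gets
#' \code{1 + Poisson(transcriptMean)} transcripts with random lengths (the
#' longest is the exemplar shown in the tree tip label
#' \code{species@gene@transcript}). Branch lengths are time durations, so
#' trees are ultrametric by construction; the time of origin is the species
#' root age. Families that go extinct or end with fewer than two genes are
#' resimulated (bounded retries).
#'
#' @param speciesTree rooted ultrametric \code{ape::phylo} (default
#'   [defaultSpeciesTree()]).
#' @param nFamilies number of gene families.
#' @param lam,mu duplication and loss rates (> 0, >= 0).
#' @param seed optional integer seed.
#' @param transcriptMean mean number of extra transcripts per gene.
#' @param maxTips per-family cap on surviving tips (guards the heavy tail
#'   of the supercritical process).
#' @param maxRetries resimulation bound per family.
#' @return list with \code{trees} (list of [GeneTree-class]),
#'   \code{catalog} (clean [TranscriptCatalog-class]) and \code{dupAges}
#'   (data.frame family/age of the true duplication events retained in the
#'   reconstructed trees).
#' @export
simulateGeneTrees <- function(speciesTree = defaultSpeciesTree(),
                              nFamilies = 500L, lam = 2.86, mu = 0.012,
                              seed = NULL, transcriptMean = 1.5,
                              maxTips = 2000L, maxRetries = 50L) {
    stopifnot(inherits(speciesTree, "phylo"), ape::is.rooted(speciesTree),
              lam >= 0, mu >= 0, nFamilies >= 1L)
    if (!is.null(seed)) set.seed(seed)
    ntip <- length(speciesTree$tip.label)
    depth <- ape::node.depth.edgelength(speciesTree)
    age <- max(depth) - depth
    age[seq_len(ntip)] <- 0
    children <- vector("list", ntip + speciesTree$Nnode)
    for (e in seq_len(nrow(speciesTree$edge)))
        children[[speciesTree$edge[e, 1L]]] <-
            c(children[[speciesTree$edge[e, 1L]]], speciesTree$edge[e, 2L])
    sp <- list(age = age, children = children,
               label = c(speciesTree$tip.label,
                         rep(NA_character_, speciesTree$Nnode)))
    root <- ntip + 1L
    trees <- vector("list", nFamilies)
    cat_tr <- character(0); cat_gene <- character(0)
    cat_sp <- character(0); cat_len <- numeric(0)
    dupAges <- list()
    for (fam in seq_len(nFamilies)) {
        famId <- sprintf("F%04d", fam)
        nd <- NULL
        for (try in seq_len(maxRetries)) {
            counter <- new.env(parent = emptyenv())
            counter$tips <- 0L; counter$events <- 0L; counter$maxTips <- maxTips
            nd <- tryCatch(
                simLineage(root, sp$age[root], sp, lam, mu, counter),
                error = function(e) NULL)
            if (!is.null(nd) && nd$type == "node") break
            nd <- NULL
        }
        if (is.null(nd))
            stop(sprintf("family %s: no surviving tree in %d attempts",
                         famId, maxRetries))
        # name genes and transcripts, build catalog rows
        geneCount <- new.env(parent = emptyenv()); geneCount$i <- 0L
        labels <- character(0)
        labelOf <- function(species) {
            geneCount$i <- geneCount$i + 1L
            gid <- sprintf("%s_%s_g%03d", species, famId, geneCount$i)
            nT <- 1L + stats::rpois(1L, transcriptMean)
            tid <- sprintf("%s_t%02d", gid, seq_len(nT))
            len <- round(stats::runif(nT, 200, 3000))
            cat_tr <<- c(cat_tr, tid); cat_gene <<- c(cat_gene, rep(gid, nT))
            cat_sp <<- c(cat_sp, rep(species, nT)); cat_len <<- c(cat_len, len)
            ex <- tid[len == max(len)][1L]
            lab <- paste(species, gid, ex, sep = "@")
            labels <<- c(labels, lab)
            lab
        }
        nwk <- nodeToNewick(nd, parentAge = nd$age, labelOf = labelOf)
        phy <- ape::read.tree(text = paste0(nwk, ";"))
        trees[[fam]] <- GeneTree(phy, id = famId)
        da <- collectDupAges(nd)
        if (length(da))
            dupAges[[length(dupAges) + 1L]] <-
                data.frame(family = famId, age = da)
    }
    list(trees = trees,
         catalog = TranscriptCatalog(cat_tr, cat_gene, cat_sp, cat_len),
         dupAges = if (length(dupAges))
             do.call(rbind, c(dupAges, list(make.row.names = FALSE)))
         else NULL)
}

# caterpillar newick for m tips with every edge ~ eps * Beta(shape, 1)
spuriousCladeNewick <- function(labels, eps, shape = 0.25) {
    u <- function() eps * stats::rbeta(1L, shape, 1)
    s <- sprintf("%s:%.12g", labels[1L], u())
    for (i in seq_along(labels)[-1L])
        s <- sprintf("(%s,%s:%.12g):%.12g", s, labels[i], u(),
                     if (i < length(labels)) u() else NA)
    # the outer length is attached by the caller; strip the trailing ":NA"
    sub(":NA$", "", s)
}

#' Inject spurious same-gene splits into clean gene trees
#'
#' Emulates assembler transcript misassignment with known truth: each
#' eligible tip (a gene with at least two transcripts) is selected with
#' probability \code{splitRate}; its transcripts are partitioned across
#' \code{multiplicity} fake genes (the first keeps the original gene id,
#' the others get suffixes \code{_s2}, \code{_s3}, ...), and the tip is
#' replaced in the tree by a clade of the fake genes' exemplars whose
#' branch lengths are i.i.d. \code{epsilon * Beta(epsilonShape, 1)} --
#' bounded by \code{epsilon} and, with the default shape 0.25, strongly
#' concentrated at zero: misassigned transcripts are typically identical
#' sequences or differ by a small gap, so their apparent divergence piles
#' up at 0 (set \code{epsilonShape = 1} for uniform lengths instead).
#' Merging all truth groups (e.g. \code{applyPlan(catalog, truthPlan)})
#' restores the clean catalog exactly.
#'
#' @param trees list of clean [GeneTree-class].
#' @param catalog the matching clean [TranscriptCatalog-class] with lengths.
#' @param splitRate per-tip corruption probability in [0, 1].
#' @param multiplicity fake genes per split (>= 2; capped at the gene's
#'   transcript count).
#' @param epsilon spurious branch-length scale (substitutions/site, > 0).
#' @param epsilonShape Beta shape of the spurious length distribution on
#'   (0, epsilon); < 1 concentrates lengths at 0.
#' @param seed optional integer seed.
#' @return list with \code{trees}, \code{catalog} (both corrupted),
#'   \code{truth} (data.frame group = original gene, gene = fake gene id,
#'   species) and \code{truthPlan} (a [ReassignmentPlan-class] of the true
#'   merges).
#' @export
injectSpuriousSplits <- function(trees, catalog, splitRate = 0.1,
                                 multiplicity = 2L, epsilon = 1e-4,
                                 epsilonShape = 0.25, seed = NULL) {
    stopifnot(splitRate >= 0, splitRate <= 1, multiplicity >= 2L, epsilon > 0)
    if (!is.null(seed)) set.seed(seed)
    tb <- catalogTable(catalog)
    nTr <- table(tb$gene)
    outTrees <- vector("list", length(trees))
    truth <- list()
    for (k in seq_along(trees)) {
        g <- trees[[k]]
        ti <- tipInfo(g)
        nwk <- ape::write.tree(phyloTree(g), digits = 15)
        changed <- FALSE
        for (i in seq_len(nrow(ti))) {
            gene <- ti$gene[i]
            if (is.na(nTr[gene]) || nTr[gene] < 2L) next
            if (stats::runif(1L) >= splitRate) next
            m <- min(multiplicity, as.integer(nTr[gene]))
            rows <- which(tb$gene == gene)
            grp <- c(seq_len(m), sample(m, length(rows) - m, replace = TRUE))
            grp <- grp[sample.int(length(grp))]
            fake <- c(gene, sprintf("%s_s%d", gene, 2:m))
            tb$gene[rows] <- fake[grp]
            labs <- vapply(seq_len(m), function(j) {
                jr <- rows[grp == j]
                ex <- tb$transcript[jr][order(-tb$length[jr],
                                              tb$transcript[jr])][1L]
                paste(ti$species[i], fake[j], ex, sep = "@")
            }, character(1))
            clade <- spuriousCladeNewick(labs, epsilon, epsilonShape)
            old1 <- paste0("(", ti$label[i], ":")
            old2 <- paste0(",", ti$label[i], ":")
            new1 <- paste0("(", clade, ":")
            new2 <- paste0(",", clade, ":")
            nwk2 <- sub(old1, new1, nwk, fixed = TRUE)
            if (identical(nwk2, nwk)) nwk2 <- sub(old2, new2, nwk, fixed = TRUE)
            if (identical(nwk2, nwk))
                stop(sprintf("tip '%s' not found in tree '%s'",
                             ti$label[i], treeId(g)))
            nwk <- nwk2
            changed <- TRUE
            truth[[length(truth) + 1L]] <-
                data.frame(group = gene, gene = fake, species = ti$species[i])
        }
        outTrees[[k]] <- if (changed)
            GeneTree(ape::read.tree(text = nwk), id = treeId(g)) else g
    }
    truth <- if (length(truth))
        do.call(rbind, c(truth, list(make.row.names = FALSE)))
    else data.frame(group = character(0), gene = character(0),
                    species = character(0))
    corrupted <- TranscriptCatalog(tb$transcript, tb$gene, tb$species,
                                   tb$length)
    planTb <- data.frame(groupId = truth$group, species = truth$species,
                         gene = truth$gene,
                         triggerTree = rep(NA_character_, nrow(truth)),
                         triggerLength = rep(NA_real_, nrow(truth)))
    truthPlan <- methods::new("ReassignmentPlan", table = planTb,
                              threshold = epsilon)
    list(trees = outTrees, catalog = corrupted, truth = truth,
         truthPlan = truthPlan)
}

#' Gene-level clustering implied by a reassignment plan
#'
#' Maps every gene of the catalog to its merge-group target (the smallest
#' member id) if the plan contains it, else to itself; the named vector is
#' directly comparable with [pairPrecisionRecall()] or
#' [adjustedRandIndex()].
#'
#' @param catalog a [TranscriptCatalog-class] listing the gene universe.
#' @param plan a [ReassignmentPlan-class] (or NULL for the identity
#'   clustering).
#' @return named vector gene -> group label.
#' @export
geneClustering <- function(catalog, plan = NULL) {
    genes <- unique(catalogTable(catalog)$gene)
    lab <- stats::setNames(genes, genes)
    if (!is.null(plan)) {
        pt <- planTable(plan)
        if (nrow(pt)) {
            target <- vapply(split(pt$gene, pt$groupId), min, character(1))
            hit <- pt$gene %in% genes
            lab[pt$gene[hit]] <- target[pt$groupId[hit]]
        }
    }
    lab
}
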