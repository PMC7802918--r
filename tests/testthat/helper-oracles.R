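# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately implemented by a different route than the package code.

# random GeneTree: ape::rtree topology, species drawn from a small pool,
# genes/transcripts serialised so (species, gene) stays unique
randGeneTree <- function(ntips, nspecies = 3, id = "G1",
                         lengths = stats::runif(2 * ntips - 2, 0, 0.5)) {
    phy <- ape::rtree(ntips)
    phy$edge.length <- lengths
    sp <- sample(sprintf("sp%d", seq_len(nspecies)), ntips, replace = TRUE)
    phy$tip.label <- sprintf("%s@g%03d@t%03d", sp, seq_len(ntips), seq_len(ntips))
    GeneTree(phy, id = id)
}

# oracle subtree total length: extract the clade and sum its edges
oracleSubtreeLength <- function(phy, node) {
    ntip <- length(phy$tip.label)
    if (node <= ntip) stop("internal nodes only")
    sum(ape::extract.clade(phy, node)$edge.length)
}

# oracle flagging: exhaustive subtree enumeration + igraph transitive closure;
# returns a set of merge groups, each a sorted character vector of
# "species|gene" keys
oracleFlag <- function(trees, threshold) {
    edges <- character(0)
    verts <- character(0)
    for (g in trees) {
        phy <- phyloTree(g)
        ti <- tipInfo(g)
        ntip <- length(phy$tip.label)
        for (node in (ntip + 1L):(ntip + phy$Nnode)) {
            len <- oracleSubtreeLength(phy, node)
            if (len >= threshold) next
            tips <- match(ape::extract.clade(phy, node)$tip.label, phy$tip.label)
            key <- paste(ti$species[tips], ti$gene[tips], sep = "|")
            for (s in unique(ti$species[tips])) {
                ks <- unique(key[ti$species[tips] == s])
                if (length(ks) < 2L) next
                verts <- union(verts, ks)
                for (i in seq_along(ks)[-1L])
                    edges <- c(edges, ks[1L], ks[i])
            }
        }
    }
    if (!length(verts)) return(list())
    gr <- igraph::make_graph(edges, directed = FALSE)
    comp <- igraph::components(gr)
    grp <- split(names(comp$membership), comp$membership)
    unname(lapply(grp, function(v) sort(v)))
}

planGroups <- function(plan) {
    pt <- planTable(plan)
    if (!nrow(pt)) return(list())
    key <- paste(pt$species, pt$gene, sep = "|")
    unname(lapply(split(key, pt$groupId), sort))
}

sameGroupSets <- function(a, b) {
    norm <- function(x) sort(vapply(x, paste, character(1), collapse = ";"))
    identical(norm(a), norm(b))
}

# all labeled rooted binary tree topologies on a tip set (newick, no lengths)
enumLabeledTopologies <- function(labels) {
    n <- length(labels)
    if (n == 1L) return(labels)
    rest <- labels[-1L]
    out <- character(0)
    for (mask in 0:(2^(n - 1L) - 2L)) {
        inL <- as.logical(bitwAnd(mask, 2^(seq_len(n - 1L) - 1L)))
        left <- c(labels[1L], rest[inL])
        right <- rest[!inL]
        for (L in enumLabeledTopologies(left))
            for (R in enumLabeledTopologies(right))
                out <- c(out, sprintf("(%s,%s)", L, R))
    }
    out
}

# all rooted binary tree shapes on n tips (tips as "x")
enumShapes <- function(n) {
    if (n == 1L) return("x")
    out <- character(0)
    for (a in seq_len(n %/% 2L)) {
        A <- enumShapes(a); B <- enumShapes(n - a)
        for (i in seq_along(A)) for (j in seq_along(B)) {
            if (a == n - a && j < i) next
            out <- c(out, sprintf("(%s,%s)", A[[i]], B[[j]]))
        }
    }
    out
}

# turn a shape/topology newick into a GeneTree with random species labels and
# a mix of tiny and ordinary branch lengths
materializeTree <- function(nwk, id = "G1", nspecies = 2) {
    phy <- ape::read.tree(text = paste0(nwk, ";"))
    ntip <- length(phy$tip.label)
    sp <- sample(sprintf("sp%d", seq_len(nspecies)), ntip, replace = TRUE)
    phy$tip.label <- sprintf("%s@g%02d@t%02d", sp, seq_len(ntip), seq_len(ntip))
    phy$edge.length <- ifelse(stats::runif(nrow(phy$edge)) < 0.4,
                              stats::runif(nrow(phy$edge), 0, 2e-4),
                              stats::runif(nrow(phy$edge), 0.05, 0.5))
    GeneTree(phy, id = id)
}

# brute-force two-sample KS statistic: ECDF sweep over the pooled support
oracleKS <- function(a, b) {
    xs <- sort(unique(c(a, b)))
    max(abs(vapply(xs, function(v) mean(a <= v) - mean(b <= v), numeric(1))))
}

# brute-force pair confusion by O(n^2) enumeration
oraclePairs <- function(pred, truth) {
    truth <- truth[names(pred)]
    n <- length(pred)
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        p <- pred[i] == pred[j]; t <- truth[i] == truth[j]
        if (p && t) tp <- tp + 1L
        else if (p && !t) fp <- fp + 1L
        else if (!p && t) fn <- fn + 1L
        else tn <- tn + 1L
    }
    c(TP = tp, FP = fp, FN = fn, TN = tn)
}

randCatalog <- function(n, ngenes = max(2L, n %/% 3L), nspecies = 3L) {
    gene <- sprintf("g%03d", sample(ngenes, n, replace = TRUE))
    spOfGene <- stats::setNames(
        sample(sprintf("sp%d", seq_len(nspecies)), ngenes, replace = TRUE),
        sprintf("g%03d", seq_len(ngenes)))
    TranscriptCatalog(sprintf("t%05d", seq_len(n)), gene, spOfGene[gene],
                      round(stats::runif(n, 200, 3000)))
}

tab1Params <- function() MixtureParams(0.2548908, 1.9488374, 2.8621597,
                                       0.0119074, 0.3386287)
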