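#' @include AllClasses.R flagging.R
NULL

checkUniverse <- function(a, b) {
    if (is.null(names(a)) || is.null(names(b)))
        stop("clusterings must be named vectors (item -> cluster label)")
    if (!setequal(names(a), names(b)))
        stop("clusterings are over different item universes")
    b[names(a)]
}

#' Adjusted Rand Index between two clusterings
#'
#' Chance-corrected agreement between two partitions of the same items
#' under the permutation model: 1 iff the partitions are identical, around
#' 0 for random assignment. Computed from the contingency table as
#' \eqn{(\sum_{ij} \binom{n_{ij}}{2} - E) / (\frac12(\sum_i \binom{a_i}{2} +
#' \sum_j \binom{b_j}{2}) - E)} with
#' \eqn{E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}}.
#'
#' @param a,b named vectors mapping each item to a cluster label; the two
#'   name sets must coincide.
#' @return the index (single numeric; 1 for identical partitions).
#' @examples
#' adjustedRandIndex(c(a = 1, b = 1, c = 2), c(a = "x", b = "x", c = "y"))
#' @export
adjustedRandIndex <- function(a, b) {
    b <- checkUniverse(a, b)
    n <- length(a)
    if (n < 2L) stop("need >= 2 items")
    # sparse contingency counts: only occupied cells, so partitions with
    # many clusters stay linear in n
    sij <- sum(choose(table(paste(a, b, sep = "\r")), 2))
    ai <- sum(choose(table(as.character(a)), 2))
    bj <- sum(choose(table(as.character(b)), 2))
    expected <- ai * bj / choose(n, 2)
    maxidx <- (ai + bj) / 2
    if (maxidx == expected) return(1)   # both partitions trivial
    (sij - expected) / (maxidx - expected)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical CDFs, used to
#' compare subtree-length distributions between clustering methods.
#'
#' @param a,b non-empty numeric samples.
#' @return the D statistic.
#' @export
ksStatistic <- function(a, b) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Kullback-Leibler distance from a sample to a theoretical density
#'
#' Bins the sample into \code{nBins} equal-width bins on \code{[0, tor]}
#' (values above \code{tor} are dropped, mirroring the plotting clip),
#' integrates the theoretical density over the same bins, adds
#' \code{eps} to both distributions (renormalising) to avoid empty-bin
#' singularities, and returns \eqn{\sum_j p_j \log(p_j / q_j) \ge 0}.
#'
#' @param x non-empty sample of duplication times.
#' @param density either a function of one argument or a
#'   [MixtureParams-class] (whose full mixture density is used).
#' @param nBins number of bins (default 100).
#' @param tor support upper end (default 1).
#' @param eps additive smoothing (default 1e-10).
#' @return KL divergence (nats).
#' @export
klDistance <- function(x, density, nBins = 100L, tor = 1, eps = 1e-10) {
    if (!length(x)) stop("empty sample")
    if (methods::is(density, "MixtureParams")) {
        params <- density
        density <- function(v) mixtureDensity(v, params, tor)
    }
    stopifnot(is.function(density))
    x <- x[x >= 0 & x <= tor]
    if (!length(x)) stop("no observations inside [0, tor]")
    breaks <- seq(0, tor, length.out = nBins + 1L)
    p <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                            1L), nBins), nBins) / length(x)
    q <- vapply(seq_len(nBins), function(j)
        stats::integrate(density, breaks[j], breaks[j + 1L],
                         rel.tol = 1e-8, stop.on.error = FALSE)$value,
        numeric(1))
    p <- p + eps; p <- p / sum(p)
    q <- q + eps; q <- q / sum(q)
    sum(p * log(p / q))
}

#' Pairwise precision and recall of a clustering against a truth
#'
#' Over all unordered item pairs: TP = pairs co-clustered in both, FP =
#' co-clustered only in the prediction, FN = co-clustered only in the
#' truth. Precision = TP/(TP+FP) (reported as 0 with attribute
#' \code{undefined = TRUE} when the prediction has no positive pair);
#' recall = TP/(TP+FN) (an error when the truth has no positive pair).
#'
#' @param predicted,truth named vectors mapping items to cluster labels
#'   over the same universe.
#' @return list with \code{precision}, \code{recall} and \code{confusion}
#'   (named vector TP, FP, FN, TN summing to n(n-1)/2).
#' @export
pairPrecisionRecall <- function(predicted, truth) {
    truth <- checkUniverse(predicted, truth)
    n <- length(predicted)
    tp <- sum(choose(table(paste(predicted, truth, sep = "\r")), 2))
    predPos <- sum(choose(table(as.character(predicted)), 2))
    truthPos <- sum(choose(table(as.character(truth)), 2))
    fp <- predPos - tp
    fn <- truthPos - tp
    tn <- choose(n, 2) - tp - fp - fn
    if (truthPos == 0)
        stop("truth clustering has no co-clustered pair: recall undefined")
    precision <- if (predPos == 0) structure(0, undefined = TRUE) else tp / predPos
    list(precision = precision, recall = tp / truthPos,
         confusion = c(TP = tp, FP = fp, FN = fn, TN = tn))
}

#' Cluster-size count table
#'
#' @param clustering named vector mapping items to cluster labels.
#' @return data.frame with columns \code{size} and \code{count};
#'   \code{sum(size * count)} equals the number of items.
#' @export
clusterSizeCounts <- function(clustering) {
    sizes <- table(as.character(clustering))
    tab <- table(factor(sizes))
    data.frame(size = as.integer(names(tab)), count = as.integer(tab))
}

#' Catalog as a transcript clustering
#'
#' @param catalog a [TranscriptCatalog-class].
#' @return named vector: transcript -> gene (usable with
#'   [adjustedRandIndex()] and [pairPrecisionRecall()]).
#' @export
asClustering <- function(catalog) {
    tb <- catalogTable(catalog)
    stats::setNames(tb$gene, tb$transcript)
}

#' Subtree-length histogram data for same-species subtrees
#'
#' Collects, over all trees, the total length of every subtree containing
#' at least two tips of one species -- the diagnostic whose near-zero spike
#' signals transcript misassignment. Lengths above \code{clip} are dropped
#' for display (the long tail otherwise dwarfs the signal).
#'
#' @param trees list of [GeneTree-class].
#' @param clip upper display limit (default 1 substitutions/site).
#' @param includeStem subtree-length convention, see [subtreeLengths()].
#' @param plot draw a base-graphics histogram.
#' @param breaks passed to [graphics::hist()].
#' @return invisibly, the vector of retained subtree lengths.
#' @export
subtreeLengthHistogram <- function(trees, clip = 1, includeStem = FALSE,
                                   plot = FALSE, breaks = 100L) {
    lens <- unlist(lapply(trees, function(g) {
        recs <- subtreeLengths(g, includeStem = includeStem)
        same <- vapply(recs$species, function(s) anyDuplicated(s) > 0L,
                       logical(1))
        recs$totalLength[same]
    }))
    lens <- lens[lens <= clip]
    if (plot)
        graphics::hist(lens, breaks = breaks,
                       main = "Same-species subtree lengths",
                       xlab = "subtree total length (substitutions/site)")
    invisible(lens)
}
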