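test_that("adjusted Rand index matches the contingency-table formula", {
    a <- c(i1 = 1, i2 = 1, i3 = 2, i4 = 2)
    expect_equal(adjustedRandIndex(a, a), 1)
    b <- c(i1 = 1, i2 = 2, i3 = 1, i4 = 2)
    # hand computation: all n_ij = 1 -> sum C(n_ij,2) = 0; a_i = b_j = 2
    # ARI = (0 - 2/3) / (2 - 2/3) = -1/2
    expect_equal(adjustedRandIndex(a, b), -0.5)

    # invariant under label permutation and symmetric
    b2 <- c(i1 = "z", i2 = "q", i3 = "z", i4 = "q")
    expect_equal(adjustedRandIndex(a, b2), adjustedRandIndex(a, b))
    expect_equal(adjustedRandIndex(b, a), adjustedRandIndex(a, b))

    expect_error(adjustedRandIndex(a, c(i1 = 1, i9 = 2, i3 = 1, i4 = 2)),
                 "universe")

    skip_if_not_installed("mclust")
    withr::local_seed(12)
    for (k in seq_len(20L)) {
        n <- sample(5:40, 1L)
        x <- stats::setNames(sample(4L, n, replace = TRUE),
                             sprintf("i%d", seq_len(n)))
        y <- stats::setNames(sample(4L, n, replace = TRUE), names(x))
        expect_equal(adjustedRandIndex(x, y),
                     mclust::adjustedRandIndex(x, y[names(x)]))
        expect_lte(adjustedRandIndex(x, y), 1)
    }
})

test_that("KS statistic equals the brute-force ECDF sweep", {
    expect_equal(ksStatistic(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(ksStatistic(0, 1), 1)
    withr::local_seed(44)
    for (k in seq_len(20L)) {
        a <- stats::rgamma(sample(5:60, 1L), 1, 1)
        b <- stats::rgamma(sample(5:60, 1L), 2, 1)
        expect_equal(ksStatistic(a, b), oracleKS(a, b))
    }
    expect_error(ksStatistic(numeric(0), 1), "non-empty")
})

test_that("KL distance matches a hand summation on a 3-bin toy", {
    # sample of 10 values in [0,1], 3 bins; density uniform on [0,1]
    x <- c(rep(0.1, 5), rep(0.5, 3), rep(0.9, 2))
    unif <- function(v) rep(1, length(v))
    p <- c(0.5, 0.3, 0.2); q <- c(1, 1, 1) / 3
    hand <- sum(p * log(p / q))
    expect_equal(klDistance(x, unif, nBins = 3L), hand, tolerance = 1e-6)

    # non-negativity and self-distance behaviour
    withr::local_seed(15)
    p <- tab1Params()
    bd <- function(v) bdDuptimeDensity(v, p@lam, p@mu, 1)
    self <- bdDuptimeQuantile(stats::runif(20000L), p@lam, p@mu, 1)
    dSelf <- klDistance(self, bd)
    dShift <- klDistance(pmin(self + 0.3, 1), bd)
    expect_lt(dSelf, 0.02)
    expect_lt(dSelf, dShift)
    for (k in seq_len(10L)) {
        x <- stats::runif(50L)
        expect_gte(klDistance(x, bd), 0)
    }
    expect_error(klDistance(numeric(0), bd), "empty")
})

test_that("pairwise precision/recall agree with pair enumeration", {
    truth <- c(a = "g1", b = "g1", c = "g2")
    pred <- truth
    pr <- pairPrecisionRecall(pred, truth)
    expect_equal(pr$precision, 1)
    expect_equal(pr$recall, 1)

    singl <- c(a = "x", b = "y", c = "z")
    pr2 <- pairPrecisionRecall(singl, truth)
    expect_equal(unname(pr2$confusion[c("TP", "FN")]), c(0, 1))
    expect_equal(as.numeric(pr2$precision), 0)
    expect_true(isTRUE(attr(pr2$precision, "undefined")))
    expect_equal(pr2$recall, 0)

    expect_error(pairPrecisionRecall(truth, singl), "recall undefined")

    withr::local_seed(33)
    for (k in seq_len(15L)) {
        n <- sample(6:30, 1L)
        pred <- stats::setNames(sample(3L, n, replace = TRUE),
                                sprintf("i%d", seq_len(n)))
        tru <- stats::setNames(sample(3L, n, replace = TRUE), names(pred))
        got <- pairPrecisionRecall(pred, tru)
        want <- oraclePairs(pred, tru)
        expect_equal(got$confusion, want)
        expect_equal(sum(got$confusion), choose(n, 2))
        expect_gte(got$recall, 0); expect_lte(got$recall, 1)
        expect_gte(as.numeric(got$precision), 0)
        expect_lte(as.numeric(got$precision), 1)
    }
})

test_that("cluster-size counts conserve the item total", {
    cl <- c(a = "g1", b = "g1", c = "g2")
    tab <- clusterSizeCounts(cl)
    expect_equal(tab, data.frame(size = 1:2, count = c(1L, 1L)))
    n <- 17L
    singl <- stats::setNames(seq_len(n), sprintf("i%d", seq_len(n)))
    expect_equal(clusterSizeCounts(singl),
                 data.frame(size = 1L, count = n))
    withr::local_seed(3)
    for (k in seq_len(10L)) {
        cl <- sample(6L, 40L, replace = TRUE)
        tab <- clusterSizeCounts(cl)
        expect_equal(sum(tab$size * tab$count), 40L)
    }
})

test_that("same-species subtree lengths feed the diagnostic histogram", {
    g1 <- GeneTree(ape::read.tree(text =
        "((A@g1@t1:0.0001,A@g2@t2:0.0001):0.5,B@g1@t3:0.5);"), id = "T1")
    g2 <- GeneTree(ape::read.tree(text =
        "(A@g1@t1:0.2,B@g1@t2:0.2);"), id = "T2")
    lens <- subtreeLengthHistogram(list(g1, g2))
    # only the same-species cherry qualifies below the clip
    expect_equal(lens, 2e-4)
})
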