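test_that("gamma component follows the shape/rate density formula", {
    expect_equal(gammaDensity(0, 1, 2), 2)   # exponential at the origin
    withr::local_seed(2)
    x <- stats::runif(100L, 0, 3)
    a <- 0.7; b <- 2.3
    manual <- b^a * x^(a - 1) * exp(-b * x) / gamma(a)
    expect_equal(gammaDensity(x, a, b), manual)
    expect_equal(stats::integrate(gammaDensity, 0, Inf, alpha = a,
                                  beta = b)$value, 1, tolerance = 1e-6)
    expect_error(gammaDensity(1, -1, 1), "alpha")
    expect_error(gammaDensity(-0.1, 1, 1), "x")
})

test_that("birth-death duplication-time density normalizes and hits the Yule limit", {
    grid <- list(c(2.86, 0.012), c(1, 0.5), c(2, 1.999), c(0.3, 0.29),
                 c(5, 0), c(2, 2))
    for (lm in grid) {
        I <- stats::integrate(bdDuptimeDensity, 0, 1, lam = lm[1],
                              mu = lm[2], tor = 1, rel.tol = 1e-9)$value
        expect_equal(I, 1, tolerance = 1e-6)
    }
    # mu = 0: truncated-exponential branching times of the pure-birth process
    x <- seq(0, 1, by = 0.05)
    lam <- 1.7
    yule <- lam * exp(-lam * x) / (1 - exp(-lam))
    expect_equal(bdDuptimeDensity(x, lam, 0, 1), yule, tolerance = 1e-10)
    # zero outside the support
    expect_equal(bdDuptimeDensity(c(-0.1, 1.2), 2, 0.5, 1), c(0, 0))

    # CDF is the integral of the density; quantile inverts the CDF
    for (lm in grid) {
        for (q in c(0.1, 0.5, 0.9)) {
            xq <- bdDuptimeQuantile(q, lm[1], lm[2], 1)
            expect_equal(bdDuptimeCDF(xq, lm[1], lm[2], 1), q,
                         tolerance = 1e-8)
            expect_equal(stats::integrate(bdDuptimeDensity, 0, xq,
                                          lam = lm[1], mu = lm[2],
                                          tor = 1)$value, q,
                         tolerance = 1e-6)
        }
    }
})

test_that("mixture density interpolates its components and normalizes", {
    x <- seq(0.001, 0.999, length.out = 50L)
    pOnly1 <- MixtureParams(0.3, 2, 2.9, 0.01, 1)
    expect_equal(mixtureDensity(x, pOnly1), gammaDensity(x, 0.3, 2))
    pOnly2 <- MixtureParams(0.3, 2, 2.9, 0.01, 0)
    expect_equal(mixtureDensity(x, pOnly2), bdDuptimeDensity(x, 2.9, 0.01))
    p <- tab1Params()
    I <- stats::integrate(function(v) mixtureDensity(v, p), 0, Inf,
                          rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
})

test_that("posterior component probabilities normalize and behave at limits", {
    p <- tab1Params()
    withr::local_seed(8)
    x <- stats::runif(50L, 0, 1)
    post <- posteriorComponent(x, p)
    expect_equal(rowSums(post), rep(1, 50L))
    pOnly2 <- MixtureParams(0.3, 2, 2.9, 0.01, 0)
    expect_equal(posteriorComponent(x, pOnly2)[, "p1"], rep(0, 50L))
    # with shape < 1 the gamma diverges at 0, so P(z=1|x) -> 1
    expect_gt(posteriorComponent(1e-12, p)[, "p1"], 0.999999)
    # monotone in pi1
    for (xi in c(0.001, 0.1, 0.5)) {
        p1s <- vapply(c(0.1, 0.3, 0.6, 0.9), function(w)
            posteriorComponent(xi, MixtureParams(0.3, 2, 2.9, 0.01, w))[, "p1"],
            numeric(1))
        expect_true(all(diff(p1s) > 0))
    }
})

test_that("threshold selection implements the loss-matrix rule", {
    p <- tab1Params()
    rule <- selectThreshold(p, errRate = 0.05)
    expect_equal(rule@lossRatio, 19)
    # the boundary is the crossing of P(z=2|x) with the error rate
    expect_equal(unname(posteriorComponent(rule@tStar, p)[, "p2"]),
                 0.05, tolerance = 1e-6)
    expect_lt(posteriorComponent(rule@tStar / 2, p)[, "p2"], 0.05)

    # monotone: larger error rate never yields a smaller boundary
    ts <- vapply(c(0.01, 0.05, 0.1, 0.2), function(e)
        selectThreshold(p, e)@tStar, numeric(1))
    expect_true(all(diff(ts) > 0))

    expect_error(selectThreshold(MixtureParams(0.3, 2, 2.9, 0.01, 0), 0.05),
                 "pi1 = 0")
    # shape > 1: the gamma vanishes at 0 and nothing is confidently spurious
    expect_error(selectThreshold(MixtureParams(3, 2, 2.9, 0.01, 0.3), 0.05),
                 "not separated")
})

test_that("the Gibbs sampler is deterministic under a fixed seed", {
    withr::local_seed(4)
    xs <- sampleMixture(800L, tab1Params(), seed = 21)
    cfg <- gibbsConfig(chains = 2L, iter = 400L, thin = 2L, seed = 7L)
    f1 <- suppressWarnings(gibbsFit(xs$x, config = cfg))
    f2 <- suppressWarnings(gibbsFit(xs$x, config = cfg))
    expect_identical(f1@draws, f2@draws)
    expect_identical(f1@summary, f2@summary)
})

test_that("data from a lone gamma component drive pi1 toward 1", {
    withr::local_seed(6)
    x <- stats::rgamma(3000L, shape = 0.25, rate = 2)
    fit <- suppressWarnings(gibbsFit(
        x, config = gibbsConfig(chains = 2L, iter = 1200L, thin = 1L,
                                seed = 3L)))
    s <- fit@summary
    pi1 <- s$mean[s$parameter == "pi1"]
    expect_gt(pi1, 0.7)
    expect_gt(s$upper95[s$parameter == "pi1"], 0.85)
})

test_that("back-calibration takes the max subtree length below the boundary", {
    g <- GeneTree(ape::read.tree(text = paste0(
        "((A@g1@t1:0.0001,A@g2@t2:0.0001):0.5,",
        "(A@g3@t3:0.3,B@g1@t9:0.3):0.2);")), id = "T1")
    ch <- ultrametricize(g)
    # only the shallow duplication sits below the boundary: clade sum 0.0002
    shallow <- min(extractDuplicationTimes(ch)$time)
    expect_equal(backCalibrate(list(ch), list(g), shallow * 1.5), 2e-4)
    expect_equal(backCalibrate(list(ch), list(g), 1e-12), 0)

    gBad <- GeneTree(ape::read.tree(text =
        "((A@g1@t1:0.1,A@g2@t2:0.1):0.2,B@g1@t3:0.3);"), id = "T2")
    expect_error(backCalibrate(list(ch), list(gBad), 0.5), "no raw tree")

    # brute force over random tree sets
    withr::local_seed(77)
    for (k in seq_len(8L)) {
        trees <- lapply(seq_len(5L), function(j)
            randGeneTree(sample(5:15, 1L), id = sprintf("G%d", j)))
        chs <- lapply(trees, ultrametricize)
        tstar <- stats::runif(1L, 0.05, 0.6)
        got <- backCalibrate(chs, trees, tstar)
        want <- 0
        for (j in seq_along(trees)) {
            phy <- phyloTree(trees[[j]])
            ntip <- length(phy$tip.label)
            ev <- nodeEvents(chs[[j]]); tm <- nodeTimes(chs[[j]])
            for (nd in which(ev == "duplication")) {
                node <- ntip + nd
                if (tm[node] < tstar)
                    want <- max(want, oracleSubtreeLength(phy, node))
            }
        }
        expect_equal(got, want)
    }
})
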