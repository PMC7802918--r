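#' @include AllClasses.R timing.R
NULL

#' Construct mixture parameters
#'
#' @param alpha,beta gamma shape and rate of the spurious component.
#' @param lam,mu birth and death rates of the true-duplication component.
#' @param pi1 mixing proportion of the spurious component; pi2 = 1 - pi1.
#' @return a [MixtureParams-class].
#' @export
MixtureParams <- function(alpha, beta, lam, mu, pi1) {
    methods::new("MixtureParams", alpha = alpha, beta = beta, lam = lam,
                 mu = mu, pi1 = pi1, pi2 = 1 - pi1)
}

#' Gamma density of the spurious-duplication component
#'
#' The density \eqn{\Gamma(x | \alpha, \beta) = \beta^\alpha x^{\alpha - 1}
#' e^{-\beta x} / \Gamma(\alpha)} (shape/rate parameterisation). With shape
#' < 1 it diverges at 0, capturing duplication times of misassigned
#' transcripts that pile up at the present.
#'
#' @param x non-negative times.
#' @param alpha shape > 0.
#' @param beta rate > 0.
#' @return density values.
#' @export
gammaDensity <- function(x, alpha, beta) {
    if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be > 0")
    if (!is.finite(beta) || beta <= 0) stop("'beta' must be > 0")
    if (any(x < 0)) stop("'x' must be >= 0")
    stats::dgamma(x, shape = alpha, rate = beta)
}

# p0/p1 of the constant-rate birth-death process: probability that a single
# lineage alive t time units before the present leaves 0 (resp. exactly 1)
# surviving descendant. Supercritical/critical/pure-birth branches.
bdP0 <- function(t, lam, mu) {
    if (mu < 1e-12) return(rep(0, length(t)))
    if (abs(lam - mu) < 1e-10) return(mu * t / (1 + lam * t))
    r <- lam - mu
    mu * (1 - exp(-r * t)) / (lam - mu * exp(-r * t))
}
bdP1 <- function(t, lam, mu) {
    if (abs(lam - mu) < 1e-10) return(1 / (1 + lam * t)^2)
    r <- lam - mu
    r^2 * exp(-r * t) / (lam - mu * exp(-r * t))^2
}
# closed-form normalizer: int_0^t lam * p1(s) ds
bdNorm <- function(t, lam, mu) {
    if (mu < 1e-12) return(1 - exp(-lam * t))
    if (abs(lam - mu) < 1e-10) return(lam * t / (1 + lam * t))
    (lam / mu) * bdP0(t, lam, mu)
}

#' Birth-death duplication-time density conditioned on the origin
#'
#' Density of a branching (duplication) time \code{x}, measured from the
#' tips (0) toward the origin, under a constant-rate birth-death process
#' with birth rate \code{lam}, death rate \code{mu}, conditioned on origin
#' time \code{tor}: branching times are i.i.d. with density proportional to
#' \eqn{\lambda p_1(x)} on \eqn{[0, t_{or}]}, where \eqn{p_1} is the
#' one-surviving-descendant probability (the origin-conditioned
#' reconstructed-process result). The normalizer has the closed form
#' \eqn{(\lambda/\mu) p_0(t_{or})}; with \code{mu = 0} the density reduces
#' to the Yule truncated exponential
#' \eqn{\lambda e^{-\lambda x} / (1 - e^{-\lambda t_{or}})}.
#'
#' Values of \code{x} outside \eqn{[0, t_{or}]} get density 0.
#'
#' @param x times.
#' @param lam birth rate > 0.
#' @param mu death rate >= 0.
#' @param tor origin time (default 1, the chronogram calibration).
#' @return density values.
#' @export
bdDuptimeDensity <- function(x, lam, mu, tor = 1) {
    if (!is.finite(lam) || lam <= 0) stop("'lam' must be > 0")
    if (!is.finite(mu) || mu < 0) stop("'mu' must be >= 0")
    if (!is.finite(tor) || tor <= 0) stop("'tor' must be > 0")
    out <- numeric(length(x))
    ok <- x >= 0 & x <= tor
    out[ok] <- lam * bdP1(x[ok], lam, mu) / bdNorm(tor, lam, mu)
    out
}

#' Birth-death duplication-time CDF conditioned on the origin
#'
#' @inheritParams bdDuptimeDensity
#' @return P(X <= x) for the density of [bdDuptimeDensity()].
#' @export
bdDuptimeCDF <- function(x, lam, mu, tor = 1) {
    x <- pmin(pmax(x, 0), tor)
    vapply(x, function(xi) bdNorm(xi, lam, mu), numeric(1)) /
        bdNorm(tor, lam, mu)
}

#' Quantile function of the birth-death duplication-time distribution
#'
#' Closed-form inverse of [bdDuptimeCDF()], used for inverse-CDF sampling.
#'
#' @param p probabilities in [0, 1].
#' @inheritParams bdDuptimeDensity
#' @return times in [0, tor].
#' @export
bdDuptimeQuantile <- function(p, lam, mu, tor = 1) {
    stopifnot(all(p >= 0 & p <= 1))
    if (mu < 1e-12)
        return(-log(1 - p * (1 - exp(-lam * tor))) / lam)
    if (abs(lam - mu) < 1e-10) {
        cv <- p * lam * tor / (1 + lam * tor)  # target value of lam*x/(1+lam*x)
        return(cv / (lam * (1 - cv)))
    }
    r <- lam - mu
    cv <- p * bdP0(tor, lam, mu)               # target p0(x)
    -log((mu - cv * lam) / (mu * (1 - cv))) / r
}

#' Two-component duplication-time mixture density
#'
#' \eqn{P(x) = \pi_1 \Gamma(x | \alpha, \beta) + \pi_2 f(x | t_{or},
#' \lambda, \mu)}: a gamma component for spurious duplications created by
#' transcript misassignment plus a birth-death branching-time component for
#' true duplications.
#'
#' @param x non-negative times.
#' @param params a [MixtureParams-class].
#' @param tor origin time of the birth-death component.
#' @return density values.
#' @export
mixtureDensity <- function(x, params, tor = 1) {
    stopifnot(methods::is(params, "MixtureParams"))
    params@pi1 * gammaDensity(x, params@alpha, params@beta) +
        params@pi2 * bdDuptimeDensity(x, params@lam, params@mu, tor)
}

#' Posterior component membership P(z | x)
#'
#' Probability that a duplication time was generated by the spurious
#' component (z = 1) or the true component (z = 2), given the mixture
#' parameters: \eqn{P(z = 1 | x) = \pi_1 f_1(x) / (\pi_1 f_1(x) + \pi_2
#' f_2(x))}.
#'
#' @inheritParams mixtureDensity
#' @return two-column matrix \code{p1}, \code{p2}; rows sum to 1.
#' @export
posteriorComponent <- function(x, params, tor = 1) {
    stopifnot(methods::is(params, "MixtureParams"))
    a <- params@pi1 * gammaDensity(x, params@alpha, params@beta)
    b <- params@pi2 * bdDuptimeDensity(x, params@lam, params@mu, tor)
    tot <- a + b
    if (any(tot == 0))
        stop("posterior undefined: both component densities are 0 at some x")
    cbind(p1 = a / tot, p2 = b / tot)
}

#' Sampler configuration for gibbsFit
#'
#' @param chains number of chains (default 4).
#' @param iter iterations per chain (default 10000).
#' @param burnin fraction of iterations discarded (default 0.5).
#' @param thin keep every thin-th retained draw (default 5).
#' @param seed integer RNG seed.
#' @param rhatTol split-Rhat convergence gate (default 1.01).
#' @return list of settings.
#' @export
gibbsConfig <- function(chains = 4L, iter = 10000L, burnin = 0.5, thin = 5L,
                        seed = 1L, rhatTol = 1.01) {
    stopifnot(chains >= 1L, iter >= 10L, burnin > 0, burnin < 1, thin >= 1L)
    list(chains = as.integer(chains), iter = as.integer(iter), burnin = burnin,
         thin = as.integer(thin), seed = as.integer(seed), rhatTol = rhatTol)
}

# split-Rhat (two halves per chain) for one parameter.
splitRhat <- function(x, chain) {
    halves <- unlist(lapply(split(x, chain), function(v) {
        h <- length(v) %/% 2L
        list(v[seq_len(h)], v[h + seq_len(h)])
    }), recursive = FALSE)
    m <- length(halves); n <- min(lengths(halves))
    if (n < 2L || m < 2L) return(NA_real_)
    halves <- lapply(halves, function(v) v[seq_len(n)])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    B <- n * stats::var(means); W <- mean(vars)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
}

# batch-means Monte Carlo standard error.
mcErr <- function(x, nb = 20L) {
    n <- length(x)
    if (n < 2L * nb) return(stats::sd(x) / sqrt(n))
    bs <- n %/% nb
    bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1L) * bs + 1L):(i * bs)]),
                 numeric(1))
    stats::sd(bm) / sqrt(nb)
}

#' Gibbs sampler for the duplication-time mixture
#'
#' Fits the gamma + birth-death mixture by Markov chain Monte Carlo:
#' latent component labels are drawn exactly (Bernoulli with
#' [posteriorComponent()] probabilities), the mixing proportion by Beta
#' conjugacy on the component counts, the gamma rate \code{beta} by Gamma
#' conjugacy given \code{alpha}, and \code{alpha}, \code{lam}, \code{mu} by
#' Metropolis-within-Gibbs with log-normal proposals whose scales adapt
#' during burn-in only. Default priors are per-parameter: near-flat
#' Gamma(1, 0.001) on alpha, beta and lam (shape-below-1 gamma priors put
#' an infinite spike at 0 that can trap rates on small samples), and a
#' deliberately informative shrinkage prior Gamma(1, 100) (exponential,
#' mean 0.01) on the death rate mu. The profile likelihood of mu from
#' origin-conditioned branching times is flat over an order of magnitude
#' or more -- extinction rates are notoriously hard to identify from
#' reconstructed trees -- so without shrinkage the mu posterior simply
#' wanders; the default keeps the process near its pure-birth limit unless
#' the data insist otherwise. Users fitting data where gene loss matters
#' should widen it via \code{priors}. pi1 gets Beta(1, 1).
#'
#' Zero times are floored at \code{xFloor} (the gamma likelihood is
#' unbounded at 0 when shape < 1); a warning reports how many.
#'
#' @param x duplication times (from [extractDuplicationTimes()]).
#' @param tor origin time of the birth-death component (default 1).
#' @param config a [gibbsConfig()] list.
#' @param priors named list of \code{c(shape, rate)} gamma priors for
#'   \code{alpha}, \code{beta}, \code{lam}, \code{mu}; omitted entries keep
#'   their defaults.
#' @param init optional named list of starting values
#'   (alpha, beta, lam, mu, pi1).
#' @param xFloor lower clamp for observed times.
#' @return a [PosteriorSamples-class]; a warning (never silence) is issued
#'   when any split-Rhat exceeds the configured tolerance.
#' @export
gibbsFit <- function(x, tor = 1, config = gibbsConfig(), priors = list(),
                     init = NULL, xFloor = 1e-12) {
    x <- as.numeric(x)
    if (length(x) < 2L) stop("need >= 2 duplication times")
    if (any(!is.finite(x)) || any(x < 0)) stop("times must be finite and >= 0")
    if (any(x == 0)) {
        warning(sprintf("%d zero time(s) floored at %g", sum(x == 0), xFloor))
        x[x == 0] <- xFloor
    }
    n <- length(x); lx <- log(x)
    pri <- list(alpha = c(1, 0.001), beta = c(1, 0.001), lam = c(1, 0.001),
                mu = c(1, 100))
    pri[names(priors)] <- priors
    cfg <- config
    nkeep <- floor((cfg$iter - floor(cfg$iter * cfg$burnin)) / cfg$thin)
    pars <- c("alpha", "beta", "lam", "mu", "pi1")
    draws <- matrix(NA_real_, nkeep * cfg$chains, 5L,
                    dimnames = list(NULL, pars))
    chainId <- integer(nkeep * cfg$chains)
    pzsum <- numeric(n); pzn <- 0L
    logPrior <- function(par, v)
        stats::dgamma(v, pri[[par]][1L], pri[[par]][2L], log = TRUE)
    for (ch in seq_len(cfg$chains)) {
        set.seed(cfg$seed + 1000L * (ch - 1L))
        # data-informed, chain-jittered initial values: split the sample at
        # the log-scale midpoint (spurious times sit orders of magnitude
        # below true duplication times when both components are present)
        t0 <- exp(mean(log(range(x))))
        z0 <- x < t0
        if (sum(z0) < 2L || sum(!z0) < 2L) z0 <- x < stats::median(x)
        m1 <- max(mean(x[z0]), xFloor); m2 <- max(mean(x[!z0]), xFloor)
        ini <- list(alpha = 0.7, beta = 0.7 / m1,
                    lam = min(max(1 / m2, 0.1), 100), mu = 0.05,
                    pi1 = min(max(mean(z0), 0.05), 0.95))
        if (!is.null(init)) ini[names(init)] <- init
        jit <- stats::rlnorm(4L, 0, 0.1)
        alpha <- ini$alpha * jit[1L]; beta <- ini$beta * jit[2L]
        lam <- ini$lam * jit[3L]; mu <- ini$mu * jit[4L]; pi1 <- ini$pi1
        sds <- c(alpha = 0.15, lam = 0.1, mu = 1.0)
        acc <- c(alpha = 0L, lam = 0L, mu = 0L)
        nburn <- floor(cfg$iter * cfg$burnin)
        kept <- 0L
        f2 <- bdDuptimeDensity(x, lam, mu, tor)
        for (it in seq_len(cfg$iter)) {
            ## z | params
            d1 <- pi1 * stats::dgamma(x, alpha, rate = beta)
            d2 <- (1 - pi1) * f2
            p1 <- d1 / (d1 + d2)
            p1[is.na(p1)] <- 0.5
            z1 <- stats::runif(n) < p1
            n1 <- sum(z1); n2 <- n - n1
            ## pi | z  (Beta(1,1) prior)
            pi1 <- stats::rbeta(1L, 1 + n1, 1 + n2)
            sx1 <- sum(x[z1]); slx1 <- sum(lx[z1])
            ## beta | alpha, z  (conjugate)
            beta <- stats::rgamma(1L, pri$beta[1L] + n1 * alpha,
                                  pri$beta[2L] + sx1)
            ## alpha | beta, z  (MH, log-normal proposal)
            ll <- function(a) n1 * (a * log(beta) - lgamma(a)) + (a - 1) * slx1
            prop <- alpha * exp(stats::rnorm(1L, 0, sds["alpha"]))
            num <- ll(prop) + logPrior("alpha", prop) + log(prop)
            den <- ll(alpha) + logPrior("alpha", alpha) + log(alpha)
            if (is.finite(num) && log(stats::runif(1L)) < num - den) {
                alpha <- prop; acc["alpha"] <- acc["alpha"] + 1L
            }
            ## lam | mu, z and mu | lam, z (MH on log scale)
            llbd <- function(f2v) sum(log(pmax(f2v[!z1], 1e-300)))
            propL <- lam * exp(stats::rnorm(1L, 0, sds["lam"]))
            f2p <- bdDuptimeDensity(x, propL, mu, tor)
            num <- llbd(f2p) + logPrior("lam", propL) + log(propL)
            den <- llbd(f2) + logPrior("lam", lam) + log(lam)
            if (is.finite(num) && log(stats::runif(1L)) < num - den) {
                lam <- propL; f2 <- f2p; acc["lam"] <- acc["lam"] + 1L
            }
            propM <- mu * exp(stats::rnorm(1L, 0, sds["mu"]))
            f2p <- bdDuptimeDensity(x, lam, propM, tor)
            num <- llbd(f2p) + logPrior("mu", propM) + log(propM)
            den <- llbd(f2) + logPrior("mu", mu) + log(mu)
            if (is.finite(num) && log(stats::runif(1L)) < num - den) {
                mu <- propM; f2 <- f2p; acc["mu"] <- acc["mu"] + 1L
            }
            ## joint ridge moves along the weakly identified directions:
            ## common scale on (alpha, beta) preserves the gamma mean ...
            cs <- exp(stats::rnorm(1L, 0, 0.05))
            llg <- function(a, b) n1 * (a * log(b) - lgamma(a)) +
                (a - 1) * slx1 - b * sx1
            num <- llg(alpha * cs, beta * cs) +
                logPrior("alpha", alpha * cs) + logPrior("beta", beta * cs) +
                log(alpha * cs) + log(beta * cs)
            den <- llg(alpha, beta) +
                logPrior("alpha", alpha) + logPrior("beta", beta) +
                log(alpha) + log(beta)
            if (is.finite(num) && log(stats::runif(1L)) < num - den) {
                alpha <- alpha * cs; beta <- beta * cs
            }
            ## ... and a common additive shift on (lam, mu) preserves the
            ## net diversification rate lam - mu
            dd <- stats::rnorm(1L, 0, 0.1)
            if (lam + dd > 0 && mu + dd > 0) {
                f2p <- bdDuptimeDensity(x, lam + dd, mu + dd, tor)
                num <- llbd(f2p) + logPrior("lam", lam + dd) +
                    logPrior("mu", mu + dd)
                den <- llbd(f2) + logPrior("lam", lam) + logPrior("mu", mu)
                if (is.finite(num) && log(stats::runif(1L)) < num - den) {
                    lam <- lam + dd; mu <- mu + dd; f2 <- f2p
                }
            }
            ## proposal adaptation, burn-in only
            if (it <= nburn && it %% 50L == 0L) {
                rate <- acc / 50
                sds <- pmin(pmax(sds * exp(rate - 0.35), 1e-3), 5)
                acc[] <- 0L
            }
            if (it > nburn && (it - nburn) %% cfg$thin == 0L && kept < nkeep) {
                kept <- kept + 1L
                draws[(ch - 1L) * nkeep + kept, ] <- c(alpha, beta, lam, mu, pi1)
                chainId[(ch - 1L) * nkeep + kept] <- ch
                pzsum <- pzsum + p1; pzn <- pzn + 1L
            }
        }
    }
    summ <- data.frame(
        parameter = pars,
        mean = unname(colMeans(draws)),
        lower95 = unname(apply(draws, 2L, stats::quantile, 0.025)),
        upper95 = unname(apply(draws, 2L, stats::quantile, 0.975)),
        mcerr = unname(apply(draws, 2L, mcErr)), row.names = NULL)
    rhat <- vapply(pars, function(p) splitRhat(draws[, p], chainId), numeric(1))
    if (any(rhat > cfg$rhatTol, na.rm = TRUE))
        warning(sprintf("split-Rhat above %.3f for: %s", cfg$rhatTol,
                        paste(sprintf("%s (%.3f)", pars[which(rhat > cfg$rhatTol)],
                                      rhat[rhat > cfg$rhatTol]), collapse = ", ")))
    methods::new("PosteriorSamples", draws = draws, chain = chainId,
                 summary = summ, rhat = rhat, memberProb = pzsum / max(pzn, 1L),
                 config = c(cfg, list(tor = tor, n = n)))
}

#' Posterior-mean mixture parameters
#'
#' @param fit a [PosteriorSamples-class] from [gibbsFit()].
#' @return a [MixtureParams-class] at the posterior means.
#' @export
posteriorMeans <- function(fit) {
    stopifnot(methods::is(fit, "PosteriorSamples"))
    m <- stats::setNames(fit@summary$mean, fit@summary$parameter)
    MixtureParams(m[["alpha"]], m[["beta"]], m[["lam"]], m[["mu"]], m[["pi1"]])
}

#' Select the duplication-time decision boundary
#'
#' Bayesian decision theory with error rate \code{errRate} implies the loss
#' matrix \eqn{[0, 1; (1-\alpha)/\alpha, 0]} (penalty for flagging a true
#' duplication vs missing a spurious one) and the rule: flag all
#' \code{x < T} where \code{T} is the largest time such that
#' \eqn{P(z = 2 | x) < errRate} for all \code{x < T}. The boundary (the
#' "intersection point") is found by root-solving \eqn{P(z = 2 | x) =
#' errRate} with bisection on the component-1-dominant region near 0.
#'
#' @param params a [MixtureParams-class] (e.g. [posteriorMeans()]) or a
#'   [PosteriorSamples-class].
#' @param errRate significance level in (0, 1); default 0.05 ("flagged
#'   times are spurious with probability > 95\%").
#' @param tor origin time.
#' @param tol bisection tolerance on x.
#' @return a [DecisionRule-class] with \code{lengthThreshold = NA} (see
#'   [backCalibrate()]).
#' @export
selectThreshold <- function(params, errRate = 0.05, tor = 1, tol = 1e-12) {
    if (methods::is(params, "PosteriorSamples")) params <- posteriorMeans(params)
    stopifnot(methods::is(params, "MixtureParams"))
    if (errRate <= 0 || errRate >= 1) stop("'errRate' must be in (0, 1)")
    if (params@pi1 == 0)
        stop("pi1 = 0: no spurious component, nothing to flag")
    h <- function(x) posteriorComponent(x, params, tor)[, "p2"] - errRate
    lo <- tor * 1e-14
    if (h(lo) >= 0)
        stop(sprintf(paste0("components are not separated: P(z = 2 | x) >= %g ",
                            "already at x -> 0"), errRate))
    grid <- tor * 10^seq(-13, 0, by = 0.25)
    up <- grid[which(h(grid) >= 0)[1L]]
    if (is.na(up))
        stop("no crossing of P(z = 2 | x) with errRate in (0, tor): components not separated")
    tstar <- stats::uniroot(h, lower = lo, upper = up, tol = tol)$root
    methods::new("DecisionRule", errRate = errRate,
                 lossRatio = (1 - errRate) / errRate, tStar = tstar,
                 lengthThreshold = NA_real_)
}

#' Back-calibrate the time boundary to a subtree-length threshold
#'
#' Takes every duplication node whose chronogram time is below \code{tStar},
#' computes the corresponding subtree total length on the original
#' (uncalibrated) gene tree, and returns the maximum of those lengths --
#' i.e. the subtree-length threshold that captures exactly the flagged
#' duplication events. Chronograms and raw trees are paired by family id
#' and must share topology (here the chronograms are derived from the same
#' trees, so node numbers coincide).
#'
#' @param chronograms list of [Chronogram-class].
#' @param trees list of [GeneTree-class] (superset of the chronogram
#'   families is fine).
#' @param tStar time boundary, or a [DecisionRule-class].
#' @param includeStem subtree-length convention, see [subtreeLengths()].
#' @return when \code{tStar} is a DecisionRule, the rule with
#'   \code{lengthThreshold} filled in; otherwise the numeric threshold
#'   (0 when no duplication falls below the boundary).
#' @export
backCalibrate <- function(chronograms, trees, tStar, includeStem = FALSE) {
    rule <- NULL
    if (methods::is(tStar, "DecisionRule")) { rule <- tStar; tStar <- rule@tStar }
    byId <- stats::setNames(trees, vapply(trees, treeId, character(1)))
    best <- 0
    for (ch in chronograms) {
        id <- treeId(ch)
        g <- byId[[id]]
        if (is.null(g)) stop(sprintf("no raw tree for chronogram '%s'", id))
        if (!identical(phyloTree(g)$tip.label, phyloTree(ch)$tip.label))
            stop(sprintf("topology mismatch between chronogram and tree '%s'", id))
        phy <- phyloTree(g)
        ntip <- length(phy$tip.label)
        dup <- which(nodeEvents(ch) == "duplication") + ntip
        qual <- dup[nodeTimes(ch)[dup] < tStar]
        if (!length(qual)) next
        recs <- subtreeLengths(g, includeStem = includeStem)
        best <- max(best, recs$totalLength[match(qual, recs$node)])
    }
    if (is.null(rule)) return(best)
    methods::new("DecisionRule", errRate = rule@errRate,
                 lossRatio = rule@lossRatio, tStar = rule@tStar,
                 lengthThreshold = best)
}

#' Fit the mixture and derive the full decision rule
#'
#' Convenience wrapper for the threshold-selection stage: fit the mixture
#' to the duplication times by [gibbsFit()], take posterior means, solve
#' for the time boundary at \code{errRate}, and back-calibrate it onto the
#' raw trees' subtree lengths.
#'
#' @param chronograms origin-filtered list of [Chronogram-class].
#' @param trees the matching raw [GeneTree-class] list.
#' @param errRate decision error rate (default 0.05).
#' @param config sampler settings, see [gibbsConfig()].
#' @param ... further arguments to [gibbsFit()].
#' @return list with \code{fit} ([PosteriorSamples-class]) and \code{rule}
#'   ([DecisionRule-class] with back-calibrated length threshold).
#' @export
fitThreshold <- function(chronograms, trees, errRate = 0.05,
                         config = gibbsConfig(), ...) {
    dt <- extractDuplicationTimes(chronograms)
    fit <- gibbsFit(dt$time, tor = 1, config = config, ...)
    rule <- selectThreshold(posteriorMeans(fit), errRate = errRate, tor = 1)
    rule <- backCalibrate(chronograms, trees, rule)
    list(fit = fit, rule = rule)
}
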