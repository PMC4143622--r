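# Fixtures built in code: small longitudinal datasets drawn from the
# mixture's own generative process, trio pedigrees, and a minimal valid
# FittedTrajectoryModel for phenotype-builder tests.

# Intercept-(+optional slope) mixture data on the visit-index time scale.
simMixData <- function(seed, N, intercepts, pi, sigma, Tn = 3,
                       slopes = rep(0, length(intercepts))) {
    set.seed(seed)
    k <- length(intercepts)
    grp <- sample.int(k, N, replace = TRUE, prob = pi)
    tm <- matrix(rep(0:(Tn - 1), each = N), N, Tn)
    mu <- intercepts[grp] + outer(slopes[grp], 0:(Tn - 1))
    y <- mu + matrix(rnorm(N * Tn, 0, sigma), N, Tn)
    ld <- LongitudinalData(iid = sprintf("I%04d", seq_len(N)),
                           values = y, times = tm)
    attr(ld, "trueGroup") <- grp
    ld
}

# A pedigree of independent trios (father, mother, child), child affected.
trioPedigree <- function(nTrios) {
    data.frame(
        FID = rep(sprintf("T%03d", seq_len(nTrios)), each = 3),
        IID = rep(c("dad", "mum", "kid"), nTrios),
        PAT = rep(c("0", "0", "dad"), nTrios),
        MAT = rep(c("0", "0", "mum"), nTrios),
        SEX = rep(c(1L, 2L, 1L), nTrios))
}

# Simulate one SNP on a trio pedigree under random (null) transmission.
trioDosage <- function(ped, maf) {
    n <- nrow(ped)
    d <- integer(n)
    dad <- seq(1, n, by = 3); mum <- dad + 1; kid <- dad + 2
    d[dad] <- rbinom(length(dad), 2, maf)
    d[mum] <- rbinom(length(mum), 2, maf)
    tr <- function(g) ifelse(g == 1L, rbinom(length(g), 1, 0.5), g / 2L)
    d[kid] <- tr(d[dad]) + tr(d[mum])
    as.integer(d)
}

# A hand-assembled valid FittedTrajectoryModel (for subgroup-ranking and
# trait-extraction tests that do not need a real fit).
mkModel <- function(beta, pi = rep(1 / length(beta), length(beta)),
                    bpp = NULL, sigma = 1) {
    k <- length(beta)
    orders <- vapply(beta, function(b) length(b) - 1L, integer(1))
    if (is.null(bpp)) bpp <- matrix(1 / k, 2, k)
    bpp <- bpp / rowSums(bpp)
    n <- nrow(bpp)
    new("FittedTrajectoryModel",
        spec = TrajectoryModelSpec(k, orders = orders),
        beta = beta, gamma = list(), pi = pi, sigma = sigma,
        loglik = 0, nParams = 0L, bic = 0, bicN = 1,
        bpp = bpp, coefPvalues = list(), gammaPvalues = list(),
        converged = TRUE, nRestartsUsed = 1L, emTrace = numeric(0),
        fid = sprintf("F%d", seq_len(n)), iid = sprintf("I%d", seq_len(n)),
        selection = list())
}

# Brute-force Benjamini-Hochberg step-up oracle (definition, not p.adjust).
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}
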