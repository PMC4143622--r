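# Trajectory mixture: parameter counting, EM correctness, pruning, BIC
# selection.

test_that("free-parameter count covers polynomials, mixing weights, sigma and covariates", {
    expect_identical(countParams(TrajectoryModelSpec(1, orders = 3L), 0), 5L)
    expect_identical(countParams(TrajectoryModelSpec(3, orders = rep(2L, 3)), 0), 12L)
    expect_identical(
        countParams(TrajectoryModelSpec(2, orders = c(1L, 1L),
                                        useCovariates = TRUE,
                                        covariateSharing = "shared"), 4),
        10L)
    expect_identical(
        countParams(TrajectoryModelSpec(2, orders = c(1L, 1L),
                                        useCovariates = TRUE), 4),
        4L + 1L + 1L + 8L)
})

test_that("single-component fit reproduces the OLS Gaussian log-likelihood", {
    for (s in 1:3) {
        set.seed(s)
        N <- 80
        Tn <- 4
        ld <- simMixData(s, N, intercepts = 100, pi = 1, sigma = 5, Tn = Tn,
                         slopes = 2)
        fit <- fitMixture(ld, TrajectoryModelSpec(1, orders = 3L),
                          nRestarts = 1, seed = s, computeSE = FALSE)
        y <- as.vector(phenoMatrix(ld)); tt <- as.vector(timeMatrix(ld))
        X <- cbind(1, tt, tt^2, tt^3)
        b <- solve(crossprod(X), crossprod(X, y))
        rss <- sum((y - X %*% b)^2)
        n <- length(y)
        ols <- -n / 2 * (log(2 * pi * rss / n) + 1)
        expect_equal(fit@loglik, ols, tolerance = 1e-6)
        expect_true(all(bppMatrix(fit) == 1))
    }
})

test_that("two-group recovery: mixing weights, intercepts and sharp BPPs", {
    ld <- simMixData(42, 400, intercepts = c(100, 150), pi = c(0.6, 0.4),
                     sigma = 5)
    fit <- fitMixture(ld, TrajectoryModelSpec(2, orders = c(0L, 0L)),
                      nRestarts = 3, seed = 7, computeSE = FALSE)
    ord <- order(vapply(fit@beta, `[`, numeric(1), 1))
    ints <- vapply(fit@beta, `[`, numeric(1), 1)[ord]
    expect_lt(abs(fit@pi[ord][1] - 0.6), 0.05)
    expect_lt(abs(ints[1] - 100), 1.5)
    expect_lt(abs(ints[2] - 150), 1.5)
    expect_gt(mean(apply(bppMatrix(fit), 1, max) > 0.99), 0.95)
})

test_that("BPP rows normalize, BIC matches its definition, EM trace is monotone", {
    ld <- simMixData(3, 150, intercepts = c(100, 130), pi = c(0.5, 0.5),
                     sigma = 8)
    fit <- fitMixture(ld, TrajectoryModelSpec(2, orders = c(1L, 1L)),
                      nRestarts = 2, seed = 2, computeSE = FALSE)
    expect_true(all(abs(rowSums(bppMatrix(fit)) - 1) < 1e-10))
    expect_lt(abs(sum(fit@pi) - 1), 1e-12)
    expect_equal(fit@bic, fit@loglik - fit@nParams / 2 * log(150))
    expect_true(all(diff(fit@emTrace) > -1e-6))
})

test_that("missing visits contribute nothing: fit runs on ragged data", {
    ld <- simMixData(11, 120, intercepts = c(95, 140), pi = c(0.5, 0.5),
                     sigma = 6)
    v <- phenoMatrix(ld)
    set.seed(5)
    v[cbind(sample(120, 25), sample(3, 25, TRUE))] <- NA
    ld2 <- LongitudinalData(iid = individualIds(ld), values = v,
                            times = timeMatrix(ld))
    fit <- fitMixture(ld2, TrajectoryModelSpec(2, orders = c(0L, 0L)),
                      nRestarts = 2, seed = 9, computeSE = FALSE)
    expect_true(fit@converged)
    expect_true(is.finite(fit@loglik))
    expect_true(all(abs(rowSums(bppMatrix(fit)) - 1) < 1e-10))
})

test_that("relabelling subgroups leaves the likelihood unchanged", {
    ld <- simMixData(8, 200, intercepts = c(100, 125, 150),
                     pi = c(0.4, 0.35, 0.25), sigma = 5)
    spec <- TrajectoryModelSpec(3, orders = rep(0L, 3))
    fit <- fitMixture(ld, spec, nRestarts = 2, seed = 4, computeSE = FALSE)
    perm <- c(3, 1, 2)
    ll0 <- trajbpp:::.evalLoglik(ld, spec, fit@beta, fit@gamma, fit@pi,
                                 fit@sigma)
    llP <- trajbpp:::.evalLoglik(ld, spec, fit@beta[perm], fit@gamma,
                                 fit@pi[perm], fit@sigma)
    expect_equal(ll0, fit@loglik, tolerance = 1e-8)
    expect_equal(llP, ll0, tolerance = 1e-10)
})

test_that("estimates tighten toward the truth as N grows", {
    err <- vapply(c(200, 800), function(N) {
        ld <- simMixData(21, N, intercepts = c(100, 150), pi = c(0.6, 0.4),
                         sigma = 5)
        fit <- fitMixture(ld, TrajectoryModelSpec(2, orders = c(0L, 0L)),
                          nRestarts = 2, seed = 3, computeSE = FALSE)
        ints <- sort(vapply(fit@beta, `[`, numeric(1), 1))
        max(abs(ints - c(100, 150)))
    }, numeric(1))
    expect_lt(err[2], err[1] + 0.5)   # allow sampling slack, require no blow-up
    expect_lt(err[2], 1.0)
})

test_that("order pruning keeps the highest degree still significant", {
    rule <- trajbpp:::.ordersFromPvalues
    expect_identical(rule(list(c(0.9, 0.001, 0.20, 0.60)), 0.05), 1L)
    expect_identical(rule(list(c(0.5, 0.30, 0.70, 0.90)), 0.05), 0L)
    expect_identical(rule(list(c(0.5, 0.30, 0.01, 0.90)), 0.05), 2L)
    expect_identical(rule(list(c(0.5, 0.04, 0.01, 0.001)), 0.05), 3L)
    expect_identical(rule(list(c(0.5, NA, 0.01, NA)), 0.05), 2L)
})

test_that("pruning recovers a quadratic trajectory from cubic first runs", {
    hits <- 0L
    nRuns <- 10L
    for (s in seq_len(nRuns)) {
        set.seed(400 + s)
        N <- 250; Tn <- 5
        tm <- matrix(rep(0:(Tn - 1), each = N), N, Tn)
        y <- 100 + 3 * tm - 2 * tm^2 + matrix(rnorm(N * Tn, 0, 4), N, Tn)
        ld <- LongitudinalData(iid = sprintf("I%04d", 1:N), values = y,
                               times = tm)
        spec <- pruneOrders(ld, k = 1, alpha = 0.05, nRestarts = 1,
                            seed = s)
        if (spec@orders[1] == 2L) hits <- hits + 1L
    }
    expect_gte(hits, ceiling(0.9 * nRuns))
})

test_that("BIC selection keeps one group for single-group data", {
    ld <- simMixData(17, 300, intercepts = 120, pi = 1, sigma = 6,
                     slopes = 1.5)
    fit <- suppressWarnings(selectModel(ld, kMax = 3, nRestarts = 2,
                                        seed = 5))
    expect_identical(fit@spec@k, 1L)
})

test_that("BIC ties break toward fewer subgroups", {
    ld <- simMixData(30, 60, intercepts = 110, pi = 1, sigma = 5)
    f1 <- fitMixture(ld, TrajectoryModelSpec(1, orders = 0L), nRestarts = 1,
                     seed = 1, computeSE = FALSE)
    f2 <- f1   # same BIC, nominally larger k later in the candidate list
    expect_identical(trajbpp:::.bestByBic(list(f1, f2)), f1)
})

test_that("k larger than N is rejected", {
    ld <- simMixData(1, 5, intercepts = 100, pi = 1, sigma = 5)
    expect_error(fitMixture(ld, TrajectoryModelSpec(6, orders = rep(0L, 6)),
                            nRestarts = 1, seed = 1),
                 "exceeds the number of individuals")
})
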