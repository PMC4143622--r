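# Association tests: Wald regression, BH-FDR, within-family permutation
# regression, TDT transmission counting, max-statistic correction.

test_that("Wald regression matches the normal-equations oracle to 1e-10", {
    x <- c(0, 0, 1, 1, 2, 2)
    y <- c(1.0, 1.2, 1.9, 2.1, 3.0, 3.2)
    r <- waldQtTest(y, x)
    # independent oracle: explicit normal equations
    X <- cbind(1, x)
    bh <- solve(t(X) %*% X) %*% t(X) %*% y
    res <- y - X %*% bh
    s2 <- sum(res^2) / (length(y) - 2)
    seb <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    tt <- bh[2] / seb
    expect_equal(r$BETA, bh[2], tolerance = 1e-10)
    expect_equal(r$SE, seb, tolerance = 1e-10)
    expect_equal(r$STAT, tt, tolerance = 1e-10)
    expect_equal(r$P, 2 * pt(-abs(tt), 4), tolerance = 1e-10)
})

test_that("Wald regression edge cases: constant trait, constant genotype, tiny n", {
    expect_equal(waldQtTest(rep(2, 6), c(0, 0, 1, 1, 2, 2))$BETA, 0)
    r <- waldQtTest(rnorm(6), rep(1, 6))
    expect_true(is.na(r$P))
    expect_equal(r$REASON, "constant_genotype")
    expect_error(waldQtTest(c(1, 2), c(0, 1)), "at least 3")
})

test_that("Wald regression is invariant to individual order", {
    set.seed(2)
    y <- rnorm(40); x <- rbinom(40, 2, 0.3)
    o <- sample(40)
    expect_equal(waldQtTest(y, x)[, 1:5], waldQtTest(y[o], x[o])[, 1:5])
})

test_that("waldScan agrees with per-SNP tests and attaches BH q-values", {
    set.seed(5)
    y <- rnorm(60)
    X <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
    X[3, 2] <- NA                      # exercise the missing-genotype path
    tab <- waldScan(y, X)
    for (j in c(1, 2, 8)) {
        r <- waldQtTest(y, X[, j])
        expect_equal(tab$P[j], r$P, tolerance = 1e-12)
        expect_equal(tab$BETA[j], r$BETA, tolerance = 1e-12)
    }
    expect_equal(tab$Q, bhFdr(tab$P))
})

test_that("BH adjustment equals the step-up definition oracle", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(0.37), 0.37)
    expect_equal(bhFdr(c(1, 1)), c(1, 1))
    expect_identical(bhFdr(numeric(0)), numeric(0))
    expect_error(bhFdr(c(0.5, 0)), "\\(0, 1\\]")
    set.seed(7)
    for (i in 1:200) {
        p <- runif(sample(1:20, 1))
        q <- bhFdr(p)
        expect_equal(q, bhOracle(p), tolerance = 1e-12)
        o <- sample(length(p))
        expect_equal(bhFdr(p[o]), q[o], tolerance = 1e-12)
    }
})

test_that("TDT counts transmissions from heterozygous parents only", {
    # 14 trios, father het, mother 0/0: child dosage 1 = coded transmitted
    ped <- trioPedigree(14)
    d <- integer(42)
    d[seq(1, 42, 3)] <- 1L                       # fathers het
    d[seq(2, 42, 3)] <- 0L                       # mothers hom
    d[seq(3, 42, 3)] <- rep(c(1L, 0L), c(10, 4)) # 10 transmit coded, 4 not
    r <- tdtTest(rep(1L, 42), d, ped)
    expect_identical(c(r$B_COUNT, r$C_COUNT), c(10, 4))
    expect_equal(r$STAT, 36 / 14)
    expect_equal(r$P, pchisq(36 / 14, 1, lower.tail = FALSE))
    # per-trio enumeration oracle
    b <- c <- 0
    for (i in seq(1, 42, 3)) {
        h <- (d[i] == 1) + (d[i + 1] == 1)
        hom <- (d[i] != 1) * d[i] / 2 + (d[i + 1] != 1) * d[i + 1] / 2
        tr <- d[i + 2] - hom
        b <- b + tr; c <- c + h - tr
    }
    expect_identical(c(r$B_COUNT, r$C_COUNT), c(b, c))
})

test_that("TDT symmetry, homozygous parents, unaffected offspring, Mendel errors", {
    ped <- trioPedigree(8)
    d <- integer(24)
    d[seq(1, 24, 3)] <- 1L; d[seq(2, 24, 3)] <- 1L
    d[seq(3, 24, 3)] <- 1L                       # both-het, child het: b=c
    r <- tdtTest(rep(1L, 24), d, ped)
    expect_equal(r$B_COUNT, r$C_COUNT)
    expect_equal(r$STAT, 0)
    expect_equal(r$P, 1)
    # only homozygous parents: nothing informative
    d2 <- rep(c(0L, 2L, 1L), 8)
    r2 <- tdtTest(rep(1L, 24), d2, ped)
    expect_identical(r2$B_COUNT + r2$C_COUNT, 0)
    expect_true(is.na(r2$P))
    expect_equal(r2$REASON, "no_informative_transmissions")
    # unaffected offspring contribute no trios
    expect_error(tdtTest(rep(0L, 24), d, ped), "affected")
    # Mendelian-inconsistent trio (0/0 x 0/0 -> child 2) is skipped and tallied
    d3 <- d
    d3[1:3] <- c(0L, 0L, 2L)
    r3 <- tdtTest(rep(1L, 24), d3, ped)
    expect_identical(r3$SKIPPED, 1)
    expect_identical(r3$N_TRIOS, 7)
})

test_that("missing genotypes drop the trio for that SNP", {
    ped <- trioPedigree(3)
    d <- rep(c(1L, 0L, 1L), 3)
    d[2] <- NA
    r <- tdtTest(rep(1L, 9), d, ped)
    expect_identical(r$N_TRIOS, 2)
})

test_that("within-family permutation p has the add-one lower bound", {
    set.seed(9)
    n <- 60
    ped <- data.frame(FID = rep(sprintf("F%02d", 1:15), each = 4))
    x <- rbinom(n, 2, 0.4)
    y <- 2 * x + rnorm(n, 0, 0.1)      # overwhelming association
    r <- qfamPermTest(y, x, ped, nPerm = 99, seed = 1)
    expect_equal(r$EMP_P, 1 / 100)
    expect_error(qfamPermTest(y, x, ped, nPerm = 0), "nPerm")
    solo <- data.frame(FID = as.character(1:n))
    expect_error(qfamPermTest(y, x, solo, nPerm = 9, seed = 1),
                 "size 1")
})

test_that("family-constant confounding inflates the naive test but not the within-family one", {
    set.seed(31)
    nf <- 40
    ped <- data.frame(FID = rep(sprintf("F%02d", 1:nf), each = 5))
    famMaf <- rep(sample(c(0.1, 0.5), nf, TRUE), each = 5)
    x <- rbinom(nf * 5, 2, famMaf)
    yClean <- rnorm(nf * 5)
    conf <- ifelse(famMaf > 0.3, 3, -3)          # family-constant confounder
    y <- yClean + conf
    naive <- waldQtTest(y, x)
    perm <- qfamPermTest(y, x, ped, nPerm = 999, seed = 8)
    expect_lt(naive$P, 1e-6)
    expect_gt(perm$EMP_P, 0.05)
})

test_that("max-statistic correction dominates pointwise empirical p-values", {
    set.seed(12)
    ped <- trioPedigree(60)
    D <- vapply(1:10, function(s) trioDosage(ped, 0.3), integer(180))
    gd <- GenotypeData(D, data.frame(snp = paste0("s", 1:10), chrom = "1",
                                     pos = 1:10, A1 = "A", A2 = "B"), ped)
    tab <- tdtScan(gd, rep(1L, 180))
    corr <- permCorrectFamily(tab, nPerm = 499, seed = 3)
    ok <- !is.na(corr$EMP_P)
    expect_true(all(corr$EMP_P_CORR[ok] >= corr$EMP_P[ok]))
    # single SNP: the maximum is the statistic itself
    one <- permCorrectFamily(tab[1, ], nPerm = 499, seed = 3)
    expect_equal(one$EMP_P_CORR, one$EMP_P)
})

test_that("qfam max-T correction reuses the same permutation stream", {
    set.seed(21)
    n <- 80
    ped <- data.frame(FID = rep(sprintf("F%02d", 1:20), each = 4),
                      IID = paste0("I", 1:n), PAT = "0", MAT = "0",
                      SEX = 1L)
    X <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
    y <- rnorm(n)
    sc <- qfamScan(y, X, ped, nPerm = 199, seed = 4)
    expect_true(all(sc$EMP_P_CORR >= sc$EMP_P))
    one <- qfamScan(y, X[, 1, drop = FALSE], ped, nPerm = 199, seed = 4)
    expect_equal(one$EMP_P_CORR, one$EMP_P)
    expect_equal(one$EMP_P,
                 qfamPermTest(y, X[, 1], ped, nPerm = 199, seed = 4)$EMP_P)
})

test_that("Wald power rises with the simulated effect size", {
    set.seed(77)
    n <- 150
    rate <- vapply(c(0, 0.15, 0.4), function(b) {
        hits <- vapply(1:150, function(i) {
            x <- rbinom(n, 2, 0.3)
            y <- b * x + rnorm(n)
            waldQtTest(y, x)$P < 0.05
        }, logical(1))
        mean(hits)
    }, numeric(1))
    expect_true(all(diff(rate) >= -0.02))
    expect_gt(rate[3], rate[1] + 0.3)
})
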