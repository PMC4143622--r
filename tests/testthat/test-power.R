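# Replicate-set power procedure: set sampling, gene hit rules, YES/NO
# scoring, total power, condition comparisons.

test_that("replicate sets are distinct within a set and deterministic under seed", {
    s <- buildReplicateSets(200, 100, 3, seed = 5)
    expect_identical(dim(s), c(100L, 3L))
    expect_true(all(apply(s, 1, function(r) length(unique(r)) == 3)))
    expect_true(all(s >= 1 & s <= 200))
    # bookkeeping: 100 discovery + 200 confirmatory data sets
    expect_identical(length(s[, 1]), 100L)
    expect_identical(length(s[, -1]), 200L)
    expect_identical(s, buildReplicateSets(200, 100, 3, seed = 5))
    expect_false(identical(s, buildReplicateSets(200, 100, 3, seed = 6)))
    expect_identical(sort(as.vector(buildReplicateSets(3, 1, 3, seed = 1))),
                     1:3)
    expect_error(buildReplicateSets(2, 5, 3), "exceeds")
})

mkAssoc <- function(p, posStart = 100) {
    data.frame(CHR = "1", SNP = paste0("s", seq_along(p)),
               BP = posStart + seq_along(p) - 1, P = p)
}

test_that("gene hit rules: alpha threshold and top-percent rank", {
    gene <- GRanges("1", IRanges(100, 104))
    names(gene) <- "G"
    expect_true(geneHit(mkAssoc(c(0.004, 0.5)), gene,
                        hitCriterion("alpha_threshold", 0.01)))
    expect_false(geneHit(mkAssoc(c(0.02, 0.5)), gene,
                         hitCriterion("alpha_threshold", 0.01)))
    # 100 SNPs, the in-gene SNP ranks 2nd, top 1% keeps ceil(1) = 1 SNP
    p <- c(0.002, runif(99, 0.01, 1))
    tab <- mkAssoc(p)
    tab$BP[1] <- 100                       # in gene, rank 2
    tab$BP[-1] <- 1000 + seq_len(99)
    tab$P[2] <- 0.0001                     # rank-1 SNP outside the gene
    tab$BP[2] <- 2000
    expect_false(geneHit(tab, gene, hitCriterion("top_percent", 1)))
    expect_true(geneHit(tab, gene, hitCriterion("top_percent", 2)))
    # empty gene scores NO with a warning
    far <- GRanges("1", IRanges(1, 10)); names(far) <- "empty"
    expect_warning(hit <- geneHit(mkAssoc(0.001), far,
                                  hitCriterion("alpha_threshold", 0.05)),
                   "no tested SNPs")
    expect_false(hit)
})

test_that("a set scores YES only when all three replicates hit", {
    genes <- GRanges("1", IRanges(c(100, 200), c(104, 204)))
    names(genes) <- c("A", "B")
    mcols(genes)$isNull <- c(FALSE, FALSE)
    # replicates 1-3 hit gene A; replicate 4 misses it; gene B never hits
    tabs <- list(
        "1" = rbind(mkAssoc(0.001, 100), mkAssoc(0.9, 200)),
        "2" = rbind(mkAssoc(0.002, 100), mkAssoc(0.8, 200)),
        "3" = rbind(mkAssoc(0.003, 100), mkAssoc(0.7, 200)),
        "4" = rbind(mkAssoc(0.500, 100), mkAssoc(0.6, 200)))
    sets <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(1, 2, 4))
    crit <- hitCriterion("alpha_threshold", 0.05)
    pw <- perGenePower(sets, tabs, genes, crit)
    expect_equal(unname(pw), c(0.75, 0))
    # invariant to set and gene order
    pw2 <- perGenePower(sets[c(4, 2, 1, 3), ], tabs, rev(genes), crit)
    expect_equal(pw2[names(pw)], pw)
    expect_error(perGenePower(rbind(c(1, 2, 5)), tabs, genes, crit),
                 "replicate")
})

test_that("total power averages per-gene power over non-null genes", {
    expect_equal(totalPower(c(1.0, 0.5)), 0.75)
    expect_equal(totalPower(c(0, 0, 0)), 0)
    expect_equal(totalPower(c(a = 1.0, b = 0.5, n = 0.9),
                            isNull = c(FALSE, FALSE, TRUE)), 0.75)
    expect_error(totalPower(c(0.5), isNull = TRUE), "non-null")
    set.seed(1)
    pg <- runif(10)
    expect_gte(totalPower(pg), min(pg))
    expect_lte(totalPower(pg), max(pg))
})

test_that("condition comparison matches a hand-computed paired t-test", {
    a <- c(0.9, 0.8, 0.6); b <- c(0.6, 0.5, 0.45)
    r <- compareConditions(a, b)
    d <- a - b
    tHand <- mean(d) / (sd(d) / sqrt(3))
    expect_equal(r$statistic, tHand)
    expect_equal(r$p.value, 2 * pt(-abs(tHand), 2))
    # antisymmetry
    r2 <- compareConditions(b, a)
    expect_equal(r2$statistic, -r$statistic)
    expect_equal(r2$p.value, r$p.value)
    # degenerate: no variance in the differences
    expect_equal(compareConditions(a, a)$reason, "zero_variance_differences")
    expect_equal(compareConditions(c(0.9, 0.8, 0.7),
                                   c(0.6, 0.5, 0.4))$reason,
                 "zero_variance_differences")
})

test_that("powerReport aggregates thresholds, null rates and validates totals", {
    genes <- GRanges("1", IRanges(c(100, 200, 300), c(104, 204, 304)))
    names(genes) <- c("A", "B", "N1")
    mcols(genes)$isNull <- c(FALSE, FALSE, TRUE)
    tabs <- lapply(1:3, function(i)
        rbind(mkAssoc(0.0005, 100), mkAssoc(0.03, 200), mkAssoc(0.5, 300)))
    names(tabs) <- as.character(1:3)
    sets <- rbind(c(1, 2, 3))
    rep <- powerReport(sets, tabs, genes, thresholds = c(0.001, 0.05),
                       criterionType = "alpha_threshold")
    expect_identical(dim(rep@genePower), c(3L, 2L))
    expect_equal(unname(rep@genePower[, "0.001"]), c(1, 0, 0))
    expect_equal(unname(rep@totalPower), c(0.5, 1))
    expect_equal(unname(rep@nullRates), c(0, 0))
    expect_true(validObject(rep))
})
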