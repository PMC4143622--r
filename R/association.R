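# SNP association tests on the derived BPP trait:
#  - population arm: per-SNP Wald regression + Benjamini-Hochberg FDR;
#  - family arm: within-family permutation regression (quantitative trait)
#    and a transmission disequilibrium test on the dichotomized trait, with
#    optional max-statistic permutation correction for multiple testing.

# Simple-regression Wald core; returns beta, se, t, p, n.
.waldCore <- function(y, x) {
    n <- length(y)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    b <- sxy / sxx
    rss <- sum((y - mean(y) - b * (x - mean(x)))^2)
    se <- sqrt(rss / (n - 2) / sxx)
    stat <- b / se
    c(beta = b, se = se, stat = stat,
      p = 2 * stats::pt(-abs(stat), n - 2), n = n)
}

#' Wald test of a quantitative trait on one SNP
#'
#' Simple linear regression \code{trait ~ dosage}; the two-sided p-value
#' comes from \code{t = b/SE(b)} on \code{n - 2} degrees of freedom.
#' Individuals with a missing trait or genotype are dropped pairwise.
#'
#' @param trait numeric quantitative trait (the BPP).
#' @param dosage coded-allele counts (0/1/2) for one SNP.
#' @return one-row data.frame with \code{BETA}, \code{SE}, \code{STAT},
#'   \code{P}, \code{N} and a \code{REASON} code for degenerate cases.
#' @export
waldQtTest <- function(trait, dosage) {
    keep <- !is.na(trait) & !is.na(dosage)
    y <- trait[keep]; x <- dosage[keep]
    if (length(y) < 3L)
        stop("need at least 3 individuals with non-missing trait and genotype")
    if (stats::var(x) == 0)
        return(data.frame(BETA = NA_real_, SE = NA_real_, STAT = NA_real_,
                          P = NA_real_, N = length(y),
                          REASON = "constant_genotype"))
    w <- .waldCore(y, x)
    reason <- NA_character_
    if (!is.finite(w["p"])) reason <- "degenerate_fit"
    data.frame(BETA = unname(w["beta"]), SE = unname(w["se"]),
               STAT = unname(w["stat"]),
               P = if (is.finite(w["p"])) unname(w["p"]) else NA_real_,
               N = length(y), REASON = reason)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement, returned in the
#' input order.
#'
#' @param pvalues p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bhFdr <- function(pvalues) {
    if (!length(pvalues)) return(numeric(0))
    if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Wald scan over all SNPs with FDR control
#'
#' Runs \code{\link{waldQtTest}} across SNPs (vectorized over columns
#' without missing genotypes) and appends BH-FDR q-values.
#'
#' @param trait quantitative trait aligned with the genotype columns.
#' @param geno a \code{GenotypeData}, or an individuals x SNPs dosage matrix.
#' @return an association table: \code{CHR SNP BP BETA SE STAT P EMP_P Q}.
#' @export
waldScan <- function(trait, geno) {
    X <- if (is(geno, "GenotypeData")) dosageMatrix(geno) else as.matrix(geno)
    stopifnot(length(trait) == nrow(X))
    keep <- !is.na(trait)
    y <- trait[keep]; X <- X[keep, , drop = FALSE]
    m <- ncol(X)
    out <- data.frame(BETA = rep(NA_real_, m), SE = NA_real_, STAT = NA_real_,
                      P = NA_real_)
    hasNA <- colSums(is.na(X)) > 0L
    if (any(!hasNA)) {
        Xc <- X[, !hasNA, drop = FALSE]
        n <- length(y)
        sx <- colSums(Xc); sxx <- colSums(Xc * Xc)
        sy <- sum(y); syy <- sum(y * y)
        Sxx <- sxx - sx^2 / n
        Sxy <- drop(crossprod(Xc, y)) - sx * sy / n
        Syy <- syy - sy^2 / n
        ok <- Sxx > 0
        b <- ifelse(ok, Sxy / Sxx, NA_real_)
        rss <- pmax(Syy - b * Sxy, 0)
        se <- ifelse(ok, sqrt(rss / (n - 2) / Sxx), NA_real_)
        out$BETA[!hasNA] <- b
        out$SE[!hasNA] <- se
        out$STAT[!hasNA] <- b / se
        out$P[!hasNA] <- 2 * stats::pt(-abs(b / se), n - 2)
    }
    for (jj in which(hasNA)) {
        r <- tryCatch(waldQtTest(y, X[, jj]), error = function(e) NULL)
        if (!is.null(r)) {
            out$BETA[jj] <- r$BETA; out$SE[jj] <- r$SE
            out$STAT[jj] <- r$STAT; out$P[jj] <- r$P
        }
    }
    out$EMP_P <- NA_real_
    out$Q <- NA_real_
    ok <- !is.na(out$P)
    if (any(ok)) out$Q[ok] <- bhFdr(out$P[ok])
    cbind(.snpAnnotation(geno, m), out)
}

.snpAnnotation <- function(geno, m) {
    if (is(geno, "GenotypeData")) {
        si <- snpInfo(geno)
        data.frame(CHR = si$chrom, SNP = si$snp, BP = si$pos)
    } else {
        data.frame(CHR = "0", SNP = paste0("snp", seq_len(m)), BP = seq_len(m))
    }
}

# ---------------------------------------------------------------------------
# Within-family permutation machinery
# ---------------------------------------------------------------------------

# n x nPerm matrix of row positions, each column one within-family shuffle.
.familyPermIndex <- function(fid, nPerm) {
    fams <- split(seq_along(fid), fid)
    fams <- fams[lengths(fams) > 1L]
    if (!length(fams))
        stop("all families have size 1; within-family permutation impossible")
    P <- matrix(rep(seq_along(fid), nPerm), ncol = nPerm)
    for (b in seq_len(nPerm))
        for (f in fams) P[f, b] <- f[sample.int(length(f))]
    P
}

# |t| statistics for one SNP against many permuted trait vectors.
.tStatsMany <- function(x, Y) {
    keep <- !is.na(x)
    x <- x[keep]; Y <- Y[keep, , drop = FALSE]
    n <- length(x)
    Sxx <- sum((x - mean(x))^2)
    sy <- colSums(Y); syy <- colSums(Y * Y)
    Sxy <- drop(crossprod(x, Y)) - sum(x) * sy / n
    Syy <- syy - sy^2 / n
    rss <- pmax(Syy - Sxy^2 / Sxx, 0)
    abs(Sxy / sqrt(Sxx * rss / (n - 2)))
}

#' Family-structure-respecting permutation regression (one SNP)
#'
#' The observed statistic is the Wald t from \code{\link{waldQtTest}}; the
#' empirical p-value compares it with statistics recomputed after shuffling
#' trait values among the members of each family (family structure
#' preserved), using the add-one estimator
#' \code{(1 + #permuted >= observed)/(nPerm + 1)}.
#'
#' @inheritParams waldQtTest
#' @param pedigree data.frame with \code{FID} aligned with \code{trait}.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return one-row data.frame with \code{BETA SE STAT P EMP_P N}.
#' @export
qfamPermTest <- function(trait, dosage, pedigree, nPerm = 999L, seed = NULL) {
    stopifnot(nPerm >= 1L)
    fid <- as.character(pedigree$FID)
    stopifnot(length(fid) == length(trait))
    keep <- !is.na(trait)
    y <- trait[keep]; x <- dosage[keep]; fid <- fid[keep]
    if (length(unique(fid)) < 2L) stop("need at least 2 families")
    obs <- waldQtTest(y, x)
    if (!is.null(seed)) set.seed(as.integer(seed))
    P <- .familyPermIndex(fid, nPerm)
    tPerm <- .tStatsMany(x, matrix(y[P], ncol = nPerm))
    empP <- (1 + sum(tPerm >= abs(obs$STAT) - 1e-12)) / (nPerm + 1)
    data.frame(BETA = obs$BETA, SE = obs$SE, STAT = obs$STAT, P = obs$P,
               EMP_P = empP, N = obs$N)
}

#' Permutation regression scan over SNPs
#'
#' Runs the within-family permutation regression across all SNPs with one
#' shared permutation stream, returning pointwise empirical p-values and
#' max-statistic family-wise corrected p-values.
#'
#' @inheritParams qfamPermTest
#' @param geno a \code{GenotypeData} or an individuals x SNPs dosage matrix.
#' @return association table with \code{STAT P EMP_P EMP_P_CORR}.
#' @export
qfamScan <- function(trait, geno, pedigree = NULL, nPerm = 999L, seed = NULL) {
    X <- if (is(geno, "GenotypeData")) dosageMatrix(geno) else as.matrix(geno)
    if (is.null(pedigree) && is(geno, "GenotypeData"))
        pedigree <- as.data.frame(colData(geno))   # FID/IID/PAT/MAT/SEX
    fid <- as.character(pedigree$FID)
    keep <- !is.na(trait)
    y <- trait[keep]; X <- X[keep, , drop = FALSE]; fid <- fid[keep]
    if (length(unique(fid)) < 2L) stop("need at least 2 families")
    base <- waldScan(y, X)
    if (!is.null(seed)) set.seed(as.integer(seed))
    P <- .familyPermIndex(fid, nPerm)
    Y <- matrix(y[P], ncol = nPerm)
    m <- ncol(X)
    absT <- matrix(NA_real_, m, nPerm)
    for (jj in seq_len(m)) {
        if (is.na(base$STAT[jj])) next
        absT[jj, ] <- .tStatsMany(X[, jj], Y)
    }
    obsT <- abs(base$STAT)
    empP <- rep(NA_real_, m)
    for (jj in seq_len(m)) {
        if (is.na(obsT[jj])) next
        empP[jj] <- (1 + sum(absT[jj, ] >= obsT[jj] - 1e-12)) / (nPerm + 1)
    }
    maxT <- apply(absT, 2, function(col) max(col, na.rm = TRUE))
    corrP <- ifelse(is.na(obsT), NA_real_,
                    (1 + vapply(obsT, function(t0)
                        sum(maxT >= t0 - 1e-12), numeric(1))) / (nPerm + 1))
    out <- .snpAnnotation(geno, m)
    out$BETA <- base$BETA; out$SE <- base$SE; out$STAT <- base$STAT
    out$P <- base$P
    out$EMP_P <- empP
    out$EMP_P_CORR <- corrP
    out$Q <- NA_real_
    out
}

# ---------------------------------------------------------------------------
# Transmission disequilibrium test
# ---------------------------------------------------------------------------

# Row indices (offspring, father, mother) of every trio whose offspring is
# affected and whose parents are both present in the data.
.extractTrios <- function(ped, affected) {
    key <- paste(ped$FID, ped$IID)
    fa <- match(paste(ped$FID, ped$PAT), key)
    mo <- match(paste(ped$FID, ped$MAT), key)
    off <- which(!is.na(fa) & !is.na(mo) & affected)
    data.frame(off = off, fa = fa[off], mo = mo[off])
}

# b/c transmission counts for a dosage matrix (trios x SNP columns).
.tdtCounts <- function(Gc, G1, G2) {
    ok <- !is.na(Gc) & !is.na(G1) & !is.na(G2)
    h <- (G1 == 1L) + (G2 == 1L)
    homContrib <- (G1 != 1L) * G1 / 2 + (G2 != 1L) * G2 / 2
    tcod <- Gc - homContrib
    mendel <- ok & tcod >= 0 & tcod <= h
    skip <- ok & !mendel
    tcod[!mendel] <- 0; h[!mendel] <- 0
    list(b = colSums(tcod * mendel), c = colSums((h - tcod) * mendel),
         skipped = colSums(skip), used = colSums(mendel))
}

#' Transmission disequilibrium test (one SNP)
#'
#' Counts transmissions of the coded allele (\code{b}) versus the
#' non-transmitted allele (\code{c}) from heterozygous parents to affected
#' offspring over all parent-offspring trios, and tests
#' \code{chi2 = (b - c)^2/(b + c)} against a 1-df chi-square. Trios with a
#' missing genotype are excluded for that SNP; Mendelian-inconsistent trios
#' are skipped and tallied.
#'
#' @param binaryTrait 0/1 affection status aligned with \code{pedigree} rows
#'   (from \code{\link{dichotomize}}).
#' @param dosage coded-allele counts for one SNP, aligned with pedigree rows.
#' @param pedigree data.frame with \code{FID IID PAT MAT} ("0" = founder).
#' @return one-row data.frame with \code{B_COUNT C_COUNT STAT P N_TRIOS
#'   SKIPPED REASON}.
#' @export
tdtTest <- function(binaryTrait, dosage, pedigree) {
    trios <- .extractTrios(pedigree, binaryTrait %in% 1L)
    if (!nrow(trios))
        stop("no genotyped parent-offspring trio with an affected offspring")
    cnt <- .tdtCounts(cbind(dosage[trios$off]), cbind(dosage[trios$fa]),
                      cbind(dosage[trios$mo]))
    b <- cnt$b[1]; cc <- cnt$c[1]
    if (b + cc > 0) {
        stat <- (b - cc)^2 / (b + cc)
        p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
        reason <- NA_character_
    } else {
        stat <- NA_real_; p <- NA_real_
        reason <- "no_informative_transmissions"
    }
    data.frame(B_COUNT = b, C_COUNT = cc, STAT = stat, P = p,
               N_TRIOS = cnt$used[1], SKIPPED = cnt$skipped[1],
               REASON = reason)
}

#' TDT scan over all SNPs
#'
#' @param geno a \code{GenotypeData}.
#' @param binaryTrait 0/1 affection status aligned with the genotype columns
#'   (a \code{DerivedPhenotype} is also accepted).
#' @return association table with per-SNP \code{B_COUNT C_COUNT STAT P}.
#' @export
tdtScan <- function(geno, binaryTrait) {
    if (is(binaryTrait, "DerivedPhenotype")) binaryTrait <- binaryTrait@binaryTrait
    ped <- pedigree(geno)
    trios <- .extractTrios(ped, binaryTrait %in% 1L)
    if (!nrow(trios))
        stop("no genotyped parent-offspring trio with an affected offspring")
    D <- dosageMatrix(geno)
    cnt <- .tdtCounts(D[trios$off, , drop = FALSE],
                      D[trios$fa, , drop = FALSE],
                      D[trios$mo, , drop = FALSE])
    n <- cnt$b + cnt$c
    stat <- ifelse(n > 0, (cnt$b - cnt$c)^2 / pmax(n, 1), NA_real_)
    out <- .snpAnnotation(geno, ncol(D))
    out$B_COUNT <- cnt$b
    out$C_COUNT <- cnt$c
    out$STAT <- stat
    out$P <- ifelse(n > 0, stats::pchisq(stat, 1, lower.tail = FALSE), NA_real_)
    out$EMP_P <- NA_real_
    out$Q <- NA_real_
    out$N_TRIOS <- cnt$used
    out$SKIPPED <- cnt$skipped
    out
}

#' Permutation correction for multiple testing in the family arm
#'
#' Max-statistic permutation correction. For TDT tables (detected by
#' \code{B_COUNT}/\code{C_COUNT} columns, or \code{mode = "tdt"}),
#' transmissions from heterozygous parents are re-randomized
#' (\code{b* ~ Binomial(b + c, 1/2)} per SNP per permutation); for the
#' quantitative arm (\code{mode = "qfam"}), trait values are re-shuffled
#' within families and the Wald statistics recomputed, which requires
#' \code{trait}, \code{geno} and \code{pedigree}. Per permutation the
#' maximum statistic over SNPs is recorded; the corrected p-value of SNP s is
#' \code{(1 + #\{max_perm >= observed_s\})/(nPerm + 1)}. Pointwise empirical
#' p-values from the same permutation stream are returned alongside, so
#' \code{EMP_P_CORR >= EMP_P} always holds.
#'
#' @param tables association table from \code{\link{tdtScan}} (TDT mode) or
#'   \code{\link{waldScan}} (qfam mode).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param mode \code{"auto"} (default), \code{"tdt"} or \code{"qfam"}.
#' @inheritParams qfamScan
#' @return \code{tables} with \code{EMP_P} and \code{EMP_P_CORR} filled in.
#' @export
permCorrectFamily <- function(tables, nPerm = 999L, seed = NULL,
                              mode = c("auto", "tdt", "qfam"),
                              trait = NULL, geno = NULL, pedigree = NULL) {
    stopifnot(nrow(tables) >= 1L, nPerm >= 1L)
    mode <- match.arg(mode)
    if (mode == "auto")
        mode <- if (all(c("B_COUNT", "C_COUNT") %in% colnames(tables)))
            "tdt" else "qfam"
    if (mode == "tdt") {
        H <- tables$B_COUNT + tables$C_COUNT
        obs <- tables$STAT
        m <- nrow(tables)
        if (!is.null(seed)) set.seed(as.integer(seed))
        geCount <- numeric(m)
        maxGe <- numeric(m)
        for (perm in seq_len(nPerm)) {
            bStar <- stats::rbinom(m, H, 0.5)
            chiStar <- ifelse(H > 0, (2 * bStar - H)^2 / pmax(H, 1), 0)
            geCount <- geCount + (chiStar >= obs - 1e-12)
            mx <- max(chiStar)
            maxGe <- maxGe + (mx >= obs - 1e-12)
        }
        tables$EMP_P <- ifelse(is.na(obs), NA_real_, (1 + geCount) / (nPerm + 1))
        tables$EMP_P_CORR <- ifelse(is.na(obs), NA_real_,
                                    (1 + maxGe) / (nPerm + 1))
        tables
    } else {
        if (is.null(trait) || is.null(geno) || is.null(pedigree))
            stop("qfam mode needs trait, geno and pedigree to re-permute")
        sc <- qfamScan(trait, geno, pedigree, nPerm = nPerm, seed = seed)
        tables$EMP_P <- sc$EMP_P
        tables$EMP_P_CORR <- sc$EMP_P_CORR
        tables
    }
}
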