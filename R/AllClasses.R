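#' @import methods
#' @import SummarizedExperiment
#' @import GenomicRanges
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
NULL

# ---------------------------------------------------------------------------
# LongitudinalData: repeated measurements on a visit grid.
# Rows are visits, columns are individuals; assays hold the trait value, the
# model time of each visit and any time-varying covariates. Static covariates
# live in colData alongside FID/IID.
# ---------------------------------------------------------------------------

#' @rdname LongitudinalData
#' @export
setClass("LongitudinalData", contains = "SummarizedExperiment")

setValidity("LongitudinalData", function(object) {
    msgs <- character(0)
    an <- assayNames(object)
    if (!all(c("value", "time") %in% an))
        return("assays must include 'value' and 'time'")
    if (!all(c("FID", "IID") %in% colnames(colData(object))))
        return("colData must contain FID and IID")
    val <- assay(object, "value")
    tim <- assay(object, "time")
    if (!identical(dim(val), dim(tim)))
        return("'value' and 'time' assays must have identical dimensions")
    obs <- !is.na(val)
    if (any(colSums(obs) < 1L))
        msgs <- c(msgs, "every individual needs at least one non-missing visit")
    if (any(obs & is.na(tim)))
        msgs <- c(msgs, "observed values must have a non-missing time")
    # times strictly increasing within an individual (over observed visits)
    incr <- vapply(seq_len(ncol(val)), function(i) {
        ti <- tim[obs[, i], i]
        length(ti) < 2L || all(diff(ti) > 0)
    }, logical(1))
    if (!all(incr))
        msgs <- c(msgs, "visit times must be strictly increasing within an individual")
    if (length(msgs)) msgs else TRUE
})

#' Longitudinal phenotype container
#'
#' Builds a \code{LongitudinalData} object from per-individual visit grids.
#' Individuals are columns; visits are rows. A missing \code{value} marks a
#' skipped visit; individuals contribute to the mixture likelihood only over
#' observed visits.
#'
#' @param iid character vector of individual identifiers.
#' @param values numeric matrix, individuals x visits, \code{NA} = missing.
#' @param times numeric matrix, individuals x visits, the model time of each
#'   visit (visit index \code{0,1,2} by default conventions, or age).
#' @param fid family identifiers (defaults to \code{iid}, i.e. singletons).
#' @param covariatesTV named list of individuals x visits numeric matrices of
#'   time-varying covariates (e.g. age, medication, smoking).
#' @param covariatesTI data.frame of static covariates (e.g. sex), one row per
#'   individual.
#' @return a \code{LongitudinalData} object.
#' @export
LongitudinalData <- function(iid, values, times, fid = iid,
                             covariatesTV = list(), covariatesTI = NULL) {
    values <- as.matrix(values)
    times <- as.matrix(times)
    n <- length(iid)
    stopifnot(nrow(values) == n, identical(dim(values), dim(times)))
    assays <- list(value = t(values), time = t(times))
    for (nm in names(covariatesTV)) {
        m <- as.matrix(covariatesTV[[nm]])
        stopifnot(identical(dim(m), dim(values)))
        assays[[nm]] <- t(m)
    }
    cd <- DataFrame(FID = as.character(fid), IID = as.character(iid))
    if (!is.null(covariatesTI)) {
        stopifnot(nrow(covariatesTI) == n)
        for (nm in colnames(covariatesTI)) cd[[nm]] <- covariatesTI[[nm]]
    }
    rownames(cd) <- iid
    se <- SummarizedExperiment(assays = assays, colData = cd)
    rownames(se) <- paste0("visit", seq_len(nrow(se)))
    new("LongitudinalData", se)
}

# ---------------------------------------------------------------------------
# TrajectoryModelSpec / FittedTrajectoryModel
# ---------------------------------------------------------------------------

#' @rdname TrajectoryModelSpec
#' @export
setClass("TrajectoryModelSpec",
    representation(k = "integer", orders = "integer",
                   useCovariates = "logical", covariateSharing = "character"))

setValidity("TrajectoryModelSpec", function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (length(object@orders) != object@k) return("length(orders) must equal k")
    if (any(object@orders < 0L | object@orders > 3L))
        return("polynomial orders must be in 0..3")
    if (!object@covariateSharing %in% c("shared", "group-specific"))
        return("covariateSharing must be 'shared' or 'group-specific'")
    TRUE
})

#' Trajectory mixture model specification
#'
#' @param k number of latent trajectory subgroups (>= 1).
#' @param orders per-subgroup polynomial order in 0..3 (default: cubic for
#'   every subgroup, the starting point of the two-run pruning procedure).
#' @param useCovariates whether covariates enter the subgroup means.
#' @param covariateSharing \code{"group-specific"} (default) or
#'   \code{"shared"} covariate coefficients.
#' @return a \code{TrajectoryModelSpec}.
#' @export
TrajectoryModelSpec <- function(k, orders = rep(3L, k), useCovariates = FALSE,
                                covariateSharing = c("group-specific", "shared")) {
    new("TrajectoryModelSpec", k = as.integer(k), orders = as.integer(orders),
        useCovariates = isTRUE(useCovariates),
        covariateSharing = match.arg(covariateSharing))
}

#' @rdname fitMixture
#' @export
setClass("FittedTrajectoryModel",
    representation(spec = "TrajectoryModelSpec",
                   beta = "list",           # per-group polynomial coefficients
                   gamma = "list",          # covariate coefficients (per group, or length-1 if shared)
                   pi = "numeric",
                   sigma = "numeric",
                   loglik = "numeric",
                   nParams = "integer",
                   bic = "numeric",
                   bicN = "numeric",        # sample size used in the BIC penalty
                   bpp = "matrix",
                   coefPvalues = "list",    # per-group Wald p for polynomial coefficients
                   gammaPvalues = "list",
                   converged = "logical",
                   nRestartsUsed = "integer",
                   emTrace = "numeric",
                   fid = "character",
                   iid = "character",
                   selection = "list"))     # per-k summary when produced by selectModel

setValidity("FittedTrajectoryModel", function(object) {
    msgs <- character(0)
    if (abs(sum(object@pi) - 1) > 1e-12) msgs <- c(msgs, "pi must sum to 1")
    if (any(object@pi < 0)) msgs <- c(msgs, "pi must be nonnegative")
    if (object@sigma <= 0) msgs <- c(msgs, "sigma must be positive")
    if (nrow(object@bpp) > 0) {
        rs <- rowSums(object@bpp)
        if (any(abs(rs - 1) > 1e-10) || any(object@bpp < 0))
            msgs <- c(msgs, "BPP rows must be nonnegative and sum to 1")
    }
    expected <- object@loglik - (object@nParams / 2) * log(object@bicN)
    if (is.finite(expected) && abs(object@bic - expected) > 1e-8)
        msgs <- c(msgs, "bic must equal loglik - (p/2) * log(N)")
    if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# DerivedPhenotype
# ---------------------------------------------------------------------------

#' @rdname extractTrait
#' @export
setClass("DerivedPhenotype",
    representation(fid = "character", iid = "character",
                   bppTrait = "numeric",      # raw BPP of the relevant subgroup
                   trait = "numeric",         # analysis trait (possibly transformed)
                   binaryTrait = "integer",   # 0/1 from the dichotomization rule
                   relevantGroup = "integer",
                   transform = "list"))       # list(type = "none"|"boxcox", lambda, offset)

setValidity("DerivedPhenotype", function(object) {
    msgs <- character(0)
    n <- length(object@iid)
    if (length(object@bppTrait) != n || length(object@binaryTrait) != n ||
        length(object@trait) != n || length(object@fid) != n)
        return("fid, iid, bppTrait, trait and binaryTrait must be the same length")
    if (any(object@bppTrait < 0 | object@bppTrait > 1, na.rm = TRUE))
        msgs <- c(msgs, "bppTrait must lie in [0, 1]")
    if (!all(object@binaryTrait %in% c(0L, 1L, NA)))
        msgs <- c(msgs, "binaryTrait must be 0/1")
    if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# GenotypeData: SNP dosages + pedigree, as a RangedSummarizedExperiment.
# Rows are SNPs (rowRanges carries position and alleles), columns individuals
# (colData carries the pedigree: FID, IID, PAT, MAT, SEX).
# ---------------------------------------------------------------------------

#' @rdname GenotypeData
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msgs <- character(0)
    if (!"dosage" %in% assayNames(object)) return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
        msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
    cd <- colData(object)
    need <- c("FID", "IID", "PAT", "MAT", "SEX")
    if (!all(need %in% colnames(cd)))
        return("colData must contain FID, IID, PAT, MAT, SEX")
    key <- paste(cd$FID, cd$IID)
    parents <- c(paste(cd$FID, cd$PAT)[cd$PAT != "0"],
                 paste(cd$FID, cd$MAT)[cd$MAT != "0"])
    if (!all(parents %in% key))
        msgs <- c(msgs, "non-founder parent references must resolve within the family")
    if (!all(c("A1", "A2") %in% colnames(mcols(rowRanges(object)))))
        msgs <- c(msgs, "rowRanges mcols must carry alleles A1 (coded) and A2")
    if (length(msgs)) msgs else TRUE
})

#' SNP genotype container with pedigree structure
#'
#' @param dosage integer matrix, individuals x SNPs, counts of the coded
#'   allele (0/1/2, \code{NA} = missing).
#' @param snpInfo data.frame with columns \code{snp}, \code{chrom},
#'   \code{pos} (1-based bp), \code{A1} (coded allele), \code{A2}.
#' @param pedigree data.frame with columns \code{FID}, \code{IID},
#'   \code{PAT}, \code{MAT}, \code{SEX} ("0" = founder parent reference).
#' @return a \code{GenotypeData} object (a \code{RangedSummarizedExperiment}
#'   with SNPs as rows and individuals as columns).
#' @export
GenotypeData <- function(dosage, snpInfo, pedigree) {
    dosage <- as.matrix(dosage)
    stopifnot(nrow(dosage) == nrow(pedigree), ncol(dosage) == nrow(snpInfo))
    gr <- GRanges(seqnames = as.character(snpInfo$chrom),
                  ranges = IRanges(start = snpInfo$pos, width = 1L))
    names(gr) <- snpInfo$snp
    mcols(gr)$A1 <- as.character(snpInfo$A1)
    mcols(gr)$A2 <- as.character(snpInfo$A2)
    cd <- DataFrame(FID = as.character(pedigree$FID),
                    IID = as.character(pedigree$IID),
                    PAT = as.character(pedigree$PAT),
                    MAT = as.character(pedigree$MAT),
                    SEX = as.integer(pedigree$SEX))
    rownames(cd) <- paste(cd$FID, cd$IID, sep = ":")
    se <- SummarizedExperiment(assays = list(dosage = t(dosage)),
                               rowRanges = gr, colData = cd)
    new("GenotypeData", se)
}

# ---------------------------------------------------------------------------
# PowerReport
# ---------------------------------------------------------------------------

#' @rdname perGenePower
#' @export
setClass("PowerReport",
    representation(genePower = "matrix",     # genes x thresholds
                   isNull = "logical",
                   totalPower = "numeric",   # per threshold, over non-null genes
                   nullRates = "numeric",    # per threshold, over null regions
                   criterion = "character",  # "alpha_threshold" or "top_percent"
                   thresholds = "numeric",
                   nSets = "integer",
                   comparisons = "list",
                   meta = "list"))

setValidity("PowerReport", function(object) {
    msgs <- character(0)
    if (any(object@genePower < 0 | object@genePower > 1, na.rm = TRUE))
        msgs <- c(msgs, "per-gene power must lie in [0, 1]")
    if (length(object@isNull) != nrow(object@genePower))
        msgs <- c(msgs, "isNull must have one entry per gene")
    if (any(!object@isNull)) {
        tp <- colMeans(object@genePower[!object@isNull, , drop = FALSE])
        if (any(abs(tp - object@totalPower) > 1e-12, na.rm = TRUE))
            msgs <- c(msgs, "totalPower must be the mean per-gene power over non-null genes")
    }
    if (length(msgs)) msgs else TRUE
})
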