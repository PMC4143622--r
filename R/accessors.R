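# Accessors and show methods for the central classes.

#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))
#' @export
setGeneric("phenoMatrix", function(x) standardGeneric("phenoMatrix"))
#' @export
setGeneric("timeMatrix", function(x) standardGeneric("timeMatrix"))
#' @export
setGeneric("tvCovariates", function(x) standardGeneric("tvCovariates"))
#' @export
setGeneric("tiCovariates", function(x) standardGeneric("tiCovariates"))
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @export
setGeneric("bppMatrix", function(x) standardGeneric("bppMatrix"))
#' @export
setGeneric("modelBIC", function(x) standardGeneric("modelBIC"))
#' @export
setGeneric("groupProbs", function(x) standardGeneric("groupProbs"))
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' Accessors for LongitudinalData
#'
#' \code{individualIds}/\code{familyIds} return identifiers;
#' \code{phenoMatrix}/\code{timeMatrix} return individuals x visits matrices;
#' \code{tvCovariates} the named list of time-varying covariate matrices;
#' \code{tiCovariates} the static covariate data.frame.
#'
#' @param x a \code{LongitudinalData}.
#' @name longitudinal-accessors
#' @aliases individualIds familyIds phenoMatrix timeMatrix tvCovariates tiCovariates
NULL

#' @rdname longitudinal-accessors
#' @export
setMethod("individualIds", "LongitudinalData", function(x) colData(x)$IID)
#' @rdname longitudinal-accessors
#' @export
setMethod("familyIds", "LongitudinalData", function(x) colData(x)$FID)
#' @rdname longitudinal-accessors
#' @export
setMethod("phenoMatrix", "LongitudinalData", function(x) t(assay(x, "value")))
#' @rdname longitudinal-accessors
#' @export
setMethod("timeMatrix", "LongitudinalData", function(x) t(assay(x, "time")))
#' @rdname longitudinal-accessors
#' @export
setMethod("tvCovariates", "LongitudinalData", function(x) {
    nms <- setdiff(assayNames(x), c("value", "time"))
    stats::setNames(lapply(nms, function(nm) t(assay(x, nm))), nms)
})
#' @rdname longitudinal-accessors
#' @export
setMethod("tiCovariates", "LongitudinalData", function(x) {
    cd <- colData(x)
    as.data.frame(cd[, setdiff(colnames(cd), c("FID", "IID")), drop = FALSE])
})

#' Accessors for GenotypeData
#'
#' \code{dosageMatrix} returns the individuals x SNPs coded-allele count
#' matrix; \code{pedigree} the FID/IID/PAT/MAT/SEX table; \code{snpInfo}
#' the SNP map (snp, chrom, pos, A1, A2).
#'
#' @param x a \code{GenotypeData}.
#' @name genotype-accessors
#' @aliases dosageMatrix pedigree snpInfo
NULL

#' @rdname genotype-accessors
#' @export
setMethod("dosageMatrix", "GenotypeData", function(x) t(assay(x, "dosage")))
#' @rdname genotype-accessors
#' @export
setMethod("pedigree", "GenotypeData", function(x) {
    as.data.frame(colData(x)[, c("FID", "IID", "PAT", "MAT", "SEX")])
})
#' @rdname genotype-accessors
#' @export
setMethod("snpInfo", "GenotypeData", function(x) {
    gr <- rowRanges(x)
    data.frame(snp = names(gr), chrom = as.character(seqnames(gr)),
               pos = start(gr), A1 = mcols(gr)$A1, A2 = mcols(gr)$A2,
               row.names = NULL)
})

#' Accessors for FittedTrajectoryModel
#'
#' \code{bppMatrix} returns the N x k Bayesian posterior probability matrix,
#' \code{modelBIC} the BIC (higher is better under the
#' \code{loglik - (p/2) log N} convention), \code{groupProbs} the mixing
#' proportions.
#'
#' @param x a \code{FittedTrajectoryModel}.
#' @name model-accessors
#' @aliases bppMatrix modelBIC groupProbs
NULL

#' @rdname model-accessors
#' @export
setMethod("bppMatrix", "FittedTrajectoryModel", function(x) x@bpp)
#' @rdname model-accessors
#' @export
setMethod("modelBIC", "FittedTrajectoryModel", function(x) x@bic)
#' @rdname model-accessors
#' @export
setMethod("groupProbs", "FittedTrajectoryModel", function(x) x@pi)

#' @rdname extractTrait
#' @param x a \code{DerivedPhenotype}.
#' @export
setMethod("traitValues", "DerivedPhenotype", function(x) {
    stats::setNames(x@trait, x@iid)
})

setMethod("show", "LongitudinalData", function(object) {
    cat("LongitudinalData:", ncol(object), "individuals x", nrow(object),
        "visits\n")
    tv <- setdiff(assayNames(object), c("value", "time"))
    cat("  time-varying covariates:",
        if (length(tv)) paste(tv, collapse = ", ") else "none", "\n")
    ti <- setdiff(colnames(colData(object)), c("FID", "IID"))
    cat("  static covariates:",
        if (length(ti)) paste(ti, collapse = ", ") else "none", "\n")
    cat("  missing cells:", sum(is.na(assay(object, "value"))), "\n")
})

setMethod("show", "TrajectoryModelSpec", function(object) {
    cat("TrajectoryModelSpec: k =", object@k,
        "orders =", paste(object@orders, collapse = ","),
        if (object@useCovariates)
            paste0("covariates (", object@covariateSharing, ")")
        else "no covariates", "\n")
})

setMethod("show", "FittedTrajectoryModel", function(object) {
    cat("FittedTrajectoryModel: k =", object@spec@k,
        "orders =", paste(object@spec@orders, collapse = ","), "\n")
    cat(sprintf("  loglik = %.4f  BIC = %.4f  (p = %d, N = %d)\n",
                object@loglik, object@bic, object@nParams,
                as.integer(object@bicN)))
    cat("  pi =", paste(sprintf("%.3f", object@pi), collapse = ", "),
        " sigma =", sprintf("%.3f", object@sigma), "\n")
    cat("  converged:", object@converged,
        " restarts used:", object@nRestartsUsed, "\n")
})

setMethod("show", "DerivedPhenotype", function(object) {
    cat("DerivedPhenotype:", length(object@iid), "individuals; relevant group",
        object@relevantGroup, "\n")
    cat(sprintf("  mean BPP = %.3f; %d labelled affected; transform: %s\n",
                mean(object@bppTrait), sum(object@binaryTrait == 1L),
                object@transform$type))
})

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", ncol(object), "individuals x", nrow(object), "SNPs\n")
    fams <- table(colData(object)$FID)
    cat("  families:", length(fams), "( size 1:", sum(fams == 1L), ")\n")
    cat("  missing dosages:", sum(is.na(assay(object, "dosage"))), "\n")
})

setMethod("show", "PowerReport", function(object) {
    cat("PowerReport:", nrow(object@genePower), "regions (",
        sum(object@isNull), "null ),", object@nSets, "replicate sets\n")
    cat("  criterion:", object@criterion, "at",
        paste(object@thresholds, collapse = ", "), "\n")
    cat("  total power:", paste(sprintf("%.3f", object@totalPower),
                                collapse = ", "), "\n")
    if (length(object@nullRates))
        cat("  null-region rates:", paste(sprintf("%.3f", object@nullRates),
                                          collapse = ", "), "\n")
})
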