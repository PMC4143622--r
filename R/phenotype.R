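# Derive the analysis phenotype from a fitted trajectory mixture: identify
# the clinically relevant subgroup, take each individual's BPP of belonging
# to it as the quantitative trait, and dichotomize for the family-based
# dichotomous test.

#' Polynomial trajectory value of each subgroup at a given time
#'
#' Evaluates each subgroup's fitted polynomial at \code{t}; covariate terms
#' are excluded (reference level zero).
#'
#' @param model a \code{FittedTrajectoryModel}.
#' @param t time value on the model's time scale.
#' @return numeric vector of fitted values, one per subgroup.
#' @export
groupTrajectoryAt <- function(model, t) {
    vapply(model@beta, function(b) sum(b * t^(seq_along(b) - 1L)), numeric(1))
}

#' Identify the clinically relevant subgroup
#'
#' The clinically relevant subgroup is the one whose fitted polynomial has
#' the highest (for e.g. hypertension severity) or lowest (for declining
#' phenotypes such as renal function) value at the last time point.
#'
#' @param model a converged \code{FittedTrajectoryModel}.
#' @param tLast the final time point on the model's time scale.
#' @param direction \code{"highest"} (default) or \code{"lowest"}.
#' @return the subgroup index.
#' @export
pickRelevantSubgroup <- function(model, tLast,
                                 direction = c("highest", "lowest")) {
    direction <- match.arg(direction)
    if (!model@converged)
        stop("model did not converge; refusing to rank subgroups")
    v <- groupTrajectoryAt(model, tLast)
    target <- if (direction == "highest") max(v) else min(v)
    hits <- which(abs(v - target) < 1e-12 * max(1, abs(target)))
    if (length(hits) > 1L)
        stop("subgroups ", paste(hits, collapse = ", "),
             " are tied at the last time point (fitted value ",
             signif(target, 8), "); cannot pick a relevant subgroup")
    hits
}

#' Dichotomize a posterior probability
#'
#' BPPs above 0.5 become 1 (affected) and below 0.5 become 0; a BPP of
#' exactly 0.5 is labelled 1 (inclusive upper rule, configurable).
#'
#' @param bpp probabilities in [0, 1].
#' @param boundary label assigned at exactly 0.5 (default \code{1L}).
#' @return integer vector of 0/1 labels.
#' @export
dichotomize <- function(bpp, boundary = 1L) {
    if (any(bpp < 0 | bpp > 1, na.rm = TRUE))
        stop("BPP values must lie in [0, 1]")
    out <- ifelse(bpp > 0.5, 1L, ifelse(bpp < 0.5, 0L, as.integer(boundary)))
    as.integer(out)
}

#' Extract the BPP phenotype for one subgroup
#'
#' Takes column \code{group} of the model's BPP matrix as the quantitative
#' trait and applies the dichotomization rule for the binary trait.
#'
#' @param model a \code{FittedTrajectoryModel}.
#' @param group subgroup index (see \code{\link{pickRelevantSubgroup}}).
#' @return a \code{DerivedPhenotype}.
#' @export
extractTrait <- function(model, group) {
    stopifnot(group >= 1L, group <= model@spec@k)
    bpp <- model@bpp[, group]
    new("DerivedPhenotype", fid = model@fid, iid = model@iid,
        bppTrait = as.numeric(bpp), trait = as.numeric(bpp),
        binaryTrait = dichotomize(bpp), relevantGroup = as.integer(group),
        transform = list(type = "none", lambda = NA_real_, offset = 0))
}

#' Box-Cox transformation
#'
#' \code{(y^lambda - 1)/lambda} for \code{lambda != 0}, \code{log(y)} for
#' \code{lambda == 0}. With \code{lambda = "mle"} the exponent maximizing the
#' profile log-likelihood is used. Values must be positive; supply
#' \code{offset} to shift nonpositive data.
#'
#' @param values positive numeric vector.
#' @param lambda a number, or \code{"mle"}.
#' @param offset added to \code{values} before transforming (default 0).
#' @param interval search interval for the MLE.
#' @return list with \code{values} (transformed) and \code{lambda} used.
#' @export
boxcoxTransform <- function(values, lambda = "mle", offset = 0,
                            interval = c(-3, 3)) {
    y <- values + offset
    if (any(y <= 0, na.rm = TRUE))
        stop("Box-Cox requires positive values; supply a suitable offset")
    profile <- function(l) {
        z <- if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
        n <- sum(!is.na(z))
        -n / 2 * log(stats::var(z, na.rm = TRUE) * (n - 1) / n) +
            (l - 1) * sum(log(y), na.rm = TRUE)
    }
    if (identical(lambda, "mle"))
        lambda <- stats::optimize(profile, interval = interval,
                                  maximum = TRUE)$maximum
    z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
    list(values = z, lambda = lambda)
}

#' Apply a Box-Cox transform to a derived phenotype
#'
#' Replaces the analysis trait with Box-Cox-transformed BPPs (the raw BPPs
#' and the binary labels are unchanged). Off by default in the pipeline: the
#' bimodal BPP distribution gives regression results that are insensitive to
#' this normalization.
#'
#' @param phenotype a \code{DerivedPhenotype}.
#' @inheritParams boxcoxTransform
#' @return the updated \code{DerivedPhenotype}.
#' @export
transformTrait <- function(phenotype, lambda = "mle", offset = 1e-6) {
    bc <- boxcoxTransform(phenotype@bppTrait, lambda = lambda, offset = offset)
    phenotype@trait <- bc$values
    phenotype@transform <- list(type = "boxcox", lambda = bc$lambda,
                                offset = offset)
    phenotype
}
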