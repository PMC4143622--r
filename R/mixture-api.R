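# User-facing trajectory mixture interface: fitting, parameter counting,
# two-run polynomial-order pruning, and BIC model selection.

#' EM control parameters
#'
#' @param maxIter maximum EM iterations per restart.
#' @param tol convergence threshold on the change in log-likelihood.
#' @param sigmaFloorFactor the residual SD is floored at this multiple of the
#'   pooled SD of the trait, preventing degenerate zero-variance spikes.
#' @param bicN sample size used in the BIC penalty: number of individuals
#'   (default, the group-based trajectory convention) or number of
#'   observations.
#' @return a list of control settings.
#' @export
mixControl <- function(maxIter = 500L, tol = 1e-8, sigmaFloorFactor = 1e-6,
                       bicN = c("individuals", "observations")) {
    list(maxIter = as.integer(maxIter), tol = tol,
         sigmaFloorFactor = sigmaFloorFactor, bicN = match.arg(bicN))
}

#' Number of free parameters of a trajectory mixture
#'
#' Counts polynomial coefficients (order + 1 per subgroup), the k - 1 free
#' mixing proportions, the shared residual SD, and covariate coefficients
#' (one set if shared, one per subgroup otherwise).
#'
#' @param spec a \code{\link{TrajectoryModelSpec}}.
#' @param nCovariates number of covariate columns entering the means.
#' @return integer parameter count used in the BIC penalty.
#' @examples
#' countParams(TrajectoryModelSpec(1, orders = 3L), 0)        # 5
#' countParams(TrajectoryModelSpec(3, orders = rep(2L, 3)), 0) # 12
#' @export
countParams <- function(spec, nCovariates = 0L) {
    stopifnot(is(spec, "TrajectoryModelSpec"))
    p <- sum(spec@orders + 1L) + (spec@k - 1L) + 1L
    if (spec@useCovariates && nCovariates > 0L) {
        p <- p + if (spec@covariateSharing == "shared") nCovariates
                 else spec@k * nCovariates
    }
    as.integer(p)
}

#' Fit a finite mixture of polynomial trajectories
#'
#' Maximum-likelihood fit of a k-subgroup Gaussian mixture of polynomial mean
#' trajectories over the observed visits of each individual, by EM with
#' multiple seeded restarts. The residual SD is shared across subgroups.
#' Each individual's Bayesian posterior probability (BPP) of subgroup
#' membership is returned alongside the parameters, the maximized
#' log-likelihood and the BIC (\code{loglik - (p/2) log N}, higher is
#' better).
#'
#' @param data a \code{\link{LongitudinalData}}.
#' @param spec a \code{\link{TrajectoryModelSpec}}.
#' @param nRestarts number of EM restarts (k-means initialization first, then
#'   perturbed restarts); the best converged run is returned.
#' @param seed integer seed; the fit is deterministic given it.
#' @param computeSE compute per-coefficient Wald p-values from the numerical
#'   observed information (needed for order pruning; costs extra
#'   log-likelihood evaluations).
#' @param control see \code{\link{mixControl}}.
#' @return a \code{FittedTrajectoryModel}.
#' @export
fitMixture <- function(data, spec, nRestarts = 10L, seed = NULL,
                       computeSE = TRUE, control = mixControl()) {
    stopifnot(is(data, "LongitudinalData"), is(spec, "TrajectoryModelSpec"),
              nRestarts >= 1L)
    validObject(spec)
    ld <- .longFormat(data, spec@useCovariates)
    if (spec@k > ld$N)
        stop("k = ", spec@k, " exceeds the number of individuals (", ld$N, ")")
    if (!is.null(seed)) set.seed(as.integer(seed))
    best <- NULL
    used <- 0L
    for (r in seq_len(nRestarts)) {
        w0 <- .initResp(ld, spec@k, r)
        run <- .emRun(ld, spec, w0, control)
        used <- r
        better <- is.null(best) ||
            (run$converged && !best$converged) ||
            (run$converged == best$converged && run$loglik > best$loglik)
        if (better) best <- run
    }
    if (!best$converged)
        warning("no EM restart converged within ", control$maxIter,
                " iterations (best |trace| = ", length(best$trace), ")")
    C <- if (spec@useCovariates && !is.null(ld$Xcov)) ncol(ld$Xcov) else 0L
    p <- countParams(spec, C)
    nBic <- if (control$bicN == "individuals") ld$N else ld$nobs
    pv <- list(coefPvalues = list(), gammaPvalues = list())
    if (computeSE && best$converged)
        pv <- .waldPvalues(ld, spec, best$par, C)
    bpp <- best$w
    colnames(bpp) <- paste0("group", seq_len(spec@k))
    new("FittedTrajectoryModel", spec = spec, beta = best$par$beta,
        gamma = best$par$gamma, pi = as.numeric(best$par$pi),
        sigma = best$par$sigma, loglik = best$loglik, nParams = p,
        bic = best$loglik - (p / 2) * log(nBic), bicN = as.numeric(nBic),
        bpp = bpp, coefPvalues = pv$coefPvalues,
        gammaPvalues = pv$gammaPvalues, converged = best$converged,
        nRestartsUsed = used, emTrace = best$trace,
        fid = as.character(familyIds(data)),
        iid = as.character(individualIds(data)),
        selection = list())
}

# The pruning rule: per subgroup, keep the largest order d in 1..3 whose
# coefficient is significant at alpha; 0 if none. The intercept is never
# removed.
.ordersFromPvalues <- function(coefPvalues, alpha) {
    vapply(coefPvalues, function(pv) {
        d <- setdiff(seq_along(pv) - 1L, 0L)   # candidate orders 1..order
        sig <- d[!is.na(pv[d + 1L]) & pv[d + 1L] < alpha]
        if (length(sig)) max(sig) else 0L
    }, integer(1))
}

#' Two-run polynomial order pruning
#'
#' First run: all subgroups cubic, no covariates. Each subgroup's order is
#' then reduced to the highest polynomial degree whose coefficient is still
#' significant at \code{alpha} (Wald test from the observed information), or
#' to 0 when no degree is. The returned spec drives the second, final run.
#'
#' @inheritParams fitMixture
#' @param k number of subgroups.
#' @param alpha significance level for retaining a polynomial degree
#'   (default 0.05).
#' @return a \code{TrajectoryModelSpec} with pruned orders (covariates off;
#'   they are introduced at the final fit).
#' @export
pruneOrders <- function(data, k, alpha = 0.05, nRestarts = 10L, seed = NULL,
                        control = mixControl()) {
    stopifnot(alpha > 0, alpha < 1)
    spec0 <- TrajectoryModelSpec(k, orders = rep(3L, k))
    fit <- fitMixture(data, spec0, nRestarts = nRestarts, seed = seed,
                      computeSE = TRUE, control = control)
    if (!fit@converged)
        stop("initial all-cubic fit for k = ", k, " did not converge ",
             "(loglik ", signif(fit@loglik, 8), ", ",
             length(fit@emTrace), " iterations)")
    TrajectoryModelSpec(k, orders = .ordersFromPvalues(fit@coefPvalues, alpha))
}

# Pick the best fit: highest BIC, ties broken toward smaller k. `fits` is a
# list ordered by increasing k; NULL entries mark failed k.
.bestByBic <- function(fits) {
    best <- NULL
    for (f in fits) {
        if (is.null(f)) next
        if (is.null(best) || f@bic > best@bic) best <- f
    }
    best
}

#' Select the number of trajectory subgroups by BIC
#'
#' For each k from 1 to \code{kMax}, runs the two-run procedure (all-cubic
#' fit, order pruning, final fit) and returns the fit with the highest BIC.
#' Covariates, when enabled, are introduced only at the final fit of each k.
#' Ties in BIC are broken toward smaller k. The per-k summary is stored in
#' the \code{selection} slot.
#'
#' @inheritParams fitMixture
#' @param kMax largest number of subgroups evaluated (the reference analysis
#'   uses 6).
#' @param useCovariates add the data's covariates to the final fits.
#' @param alpha significance level of the order-pruning rule.
#' @param covariateSharing covariate coefficient sharing for the final fits.
#' @param computeSE compute Wald p-values for the returned final fit
#'   (pruning runs always compute them internally).
#' @return the selected \code{FittedTrajectoryModel}.
#' @export
selectModel <- function(data, kMax = 6L, useCovariates = FALSE, alpha = 0.05,
                        nRestarts = 10L, seed = NULL,
                        covariateSharing = c("group-specific", "shared"),
                        computeSE = FALSE, control = mixControl()) {
    stopifnot(kMax >= 1L)
    covariateSharing <- match.arg(covariateSharing)
    fits <- vector("list", kMax)
    summ <- data.frame(k = seq_len(kMax), loglik = NA_real_,
                       nParams = NA_integer_, bic = NA_real_,
                       converged = FALSE,
                       orders = NA_character_)
    for (k in seq_len(kMax)) {
        sk <- if (is.null(seed)) NULL else as.integer(seed) + 101L * k
        res <- tryCatch(suppressWarnings({
            ps <- pruneOrders(data, k, alpha = alpha, nRestarts = nRestarts,
                              seed = sk, control = control)
            spec <- TrajectoryModelSpec(k, orders = ps@orders,
                                        useCovariates = useCovariates,
                                        covariateSharing = covariateSharing)
            fitMixture(data, spec, nRestarts = nRestarts,
                       seed = if (is.null(sk)) NULL else sk + 51L,
                       computeSE = computeSE, control = control)
        }), error = function(e) e)
        if (is(res, "FittedTrajectoryModel") && res@converged) {
            fits[[k]] <- res
            summ$loglik[k] <- res@loglik
            summ$nParams[k] <- res@nParams
            summ$bic[k] <- res@bic
            summ$converged[k] <- TRUE
            summ$orders[k] <- paste(res@spec@orders, collapse = ",")
        } else {
            msg <- if (is(res, "condition")) conditionMessage(res)
                   else "final fit did not converge"
            summ$orders[k] <- paste0("failed: ", msg)
        }
    }
    best <- .bestByBic(fits)
    if (is.null(best))
        stop("no k in 1..", kMax, " produced a converged fit: ",
             paste(summ$orders, collapse = "; "))
    best@selection <- list(summary = summ, selectedK = best@spec@k)
    best
}
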