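# Internal machinery for the group-based trajectory mixture.
#
# Model: individual i in latent subgroup j has
#   y_it = sum_d beta_{jd} t^d + gamma' x_it + e_it,  e_it ~ N(0, sigma^2)
# with sigma shared across subgroups, group membership probabilities pi_j,
# and the individual-level density taken as the product over observed visits.
# Fitting is by EM; the M-step is exact (weighted least squares for beta and
# gamma, closed-form pi and sigma), so the observed-data log-likelihood is
# non-decreasing across iterations.

# Flatten a LongitudinalData into observation-long vectors. Each row of the
# result corresponds to one observed (individual, visit) cell.
.longFormat <- function(data, useCovariates = FALSE) {
    val <- phenoMatrix(data)
    tim <- timeMatrix(data)
    obs <- !is.na(val)
    idx <- row(val)[obs]
    y <- val[obs]
    tt <- tim[obs]
    Xpoly <- cbind(1, tt, tt^2, tt^3)
    Xcov <- NULL
    covNames <- character(0)
    if (useCovariates) {
        tv <- tvCovariates(data)
        ti <- tiCovariates(data)
        cols <- list()
        for (nm in names(tv)) cols[[nm]] <- tv[[nm]][obs]
        for (nm in colnames(ti)) {
            v <- as.numeric(ti[[nm]])
            cols[[nm]] <- v[idx]
        }
        if (length(cols)) {
            Xcov <- do.call(cbind, cols)
            covNames <- names(cols)
        }
    }
    ord <- order(idx)            # rowsum() wants sorted groups for stable rows
    list(idx = idx[ord], y = y[ord], t = tt[ord],
         Xpoly = Xpoly[ord, , drop = FALSE],
         Xcov = if (is.null(Xcov)) NULL else Xcov[ord, , drop = FALSE],
         covNames = covNames,
         # a degree-d polynomial is identifiable only with > d distinct times;
         # higher coefficients are pinned at zero
         nDistT = length(unique(tt)),
         N = nrow(val), nobs = length(y), sdY = stats::sd(y))
}

.covariateCount <- function(data) {
    length(tvCovariates(data)) + ncol(tiCovariates(data))
}

# Per-observation subgroup means, nobs x k.
.mixMeans <- function(ld, spec, beta, gamma) {
    k <- spec@k
    Bpad <- matrix(0, 4, k)
    for (j in seq_len(k)) Bpad[seq_len(spec@orders[j] + 1L), j] <- beta[[j]]
    Mu <- ld$Xpoly %*% Bpad
    if (spec@useCovariates && !is.null(ld$Xcov) && length(gamma)) {
        if (spec@covariateSharing == "shared") {
            Mu <- Mu + drop(ld$Xcov %*% gamma[[1L]])
        } else {
            Mu <- Mu + ld$Xcov %*% do.call(cbind, gamma)
        }
    }
    Mu
}

# Per-individual per-group log density (N x k) and derived quantities.
.indLogDens <- function(ld, Mu, sigma) {
    R <- (ld$y - Mu) / sigma
    LogD <- -0.5 * R * R - log(sigma) - 0.918938533204672870  # log(sqrt(2*pi))
    rowsum(LogD, ld$idx, reorder = FALSE)
}

.eStep <- function(ld, spec, par) {
    Mu <- .mixMeans(ld, spec, par$beta, par$gamma)
    Li <- .indLogDens(ld, Mu, par$sigma)
    a <- sweep(Li, 2, log(par$pi), "+")
    M <- a[, 1L]
    if (spec@k > 1L) for (j in 2:spec@k) M <- pmax(M, a[, j])
    lli <- M + log(rowSums(exp(a - M)))
    w <- exp(a - lli)
    list(w = w, loglik = sum(lli))
}

# Exact M-step given responsibilities w (N x k).
.mStep <- function(ld, spec, w, sigmaFloor, prev = NULL) {
    k <- spec@k
    pi <- colSums(w) / nrow(w)
    wObs <- w[ld$idx, , drop = FALSE]
    C <- if (spec@useCovariates && !is.null(ld$Xcov)) ncol(ld$Xcov) else 0L
    beta <- vector("list", k)
    gamma <- list()
    rss <- 0
    pfit <- pmin(spec@orders + 1L, ld$nDistT)   # identifiable columns
    if (C > 0L && spec@covariateSharing == "shared") {
        # beta and the shared gamma are coupled: one stacked WLS
        pcols <- pfit
        Xs <- matrix(0, ld$nobs * k, sum(pcols) + C)
        ys <- rep(ld$y, k)
        ws <- as.vector(wObs)
        off <- 0L
        for (j in seq_len(k)) {
            rows <- ((j - 1L) * ld$nobs + 1L):(j * ld$nobs)
            Xs[rows, (off + 1L):(off + pcols[j])] <-
                ld$Xpoly[, seq_len(pcols[j]), drop = FALSE]
            Xs[rows, (sum(pcols) + 1L):(sum(pcols) + C)] <- ld$Xcov
            off <- off + pcols[j]
        }
        cf <- .safeWls(Xs, ys, ws, prevCoef = NULL)
        off <- 0L
        for (j in seq_len(k)) {
            beta[[j]] <- rep(0, spec@orders[j] + 1L)
            beta[[j]][seq_len(pcols[j])] <- cf[(off + 1L):(off + pcols[j])]
            off <- off + pcols[j]
        }
        gamma <- list(cf[(sum(pcols) + 1L):(sum(pcols) + C)])
        Mu <- .mixMeans(ld, spec, beta, gamma)
        rss <- sum(wObs * (ld$y - Mu)^2)
    } else {
        for (j in seq_len(k)) {
            np <- pfit[j]
            Xj <- ld$Xpoly[, seq_len(np), drop = FALSE]
            if (C > 0L) Xj <- cbind(Xj, ld$Xcov)
            cf <- .safeWls(Xj, ld$y, wObs[, j],
                           prevCoef = if (!is.null(prev))
                               c(prev$beta[[j]][seq_len(np)],
                                 if (C > 0L) prev$gamma[[j]] else NULL))
            beta[[j]] <- rep(0, spec@orders[j] + 1L)
            beta[[j]][seq_len(np)] <- cf[seq_len(np)]
            if (C > 0L) gamma[[j]] <- cf[(np + 1L):(np + C)]
            res <- ld$y - Xj %*% cf
            rss <- rss + sum(wObs[, j] * res * res)
        }
    }
    sigma <- max(sqrt(rss / ld$nobs), sigmaFloor)
    list(beta = beta, gamma = gamma, pi = pi, sigma = sigma)
}

# WLS that survives near-zero total weight and rank deficiency. Solved via
# the normal equations (designs here are tiny and well scaled: polynomial
# in t plus a few covariates); falls back to a QR fit, then to the previous
# coefficients, when singular.
.safeWls <- function(X, y, w, prevCoef = NULL) {
    if (sum(w) < 1e-10) {
        if (!is.null(prevCoef)) return(prevCoef)
        w <- w + 1e-10
    }
    cf <- tryCatch(drop(solve(crossprod(X, X * w), crossprod(X, y * w))),
                   error = function(e)
                       tryCatch(stats::lm.wfit(X, y, w)$coefficients,
                                error = function(e2)
                                    rep(NA_real_, ncol(X))))
    bad <- !is.finite(cf)
    if (any(bad)) {
        if (!is.null(prevCoef) && length(prevCoef) == length(cf)) {
            cf[bad] <- prevCoef[bad]
        } else cf[bad] <- 0
    }
    cf
}

# Hard-ish initial responsibilities from k-means on individual mean values;
# later restarts perturb the assignment for multimodality protection.
.initResp <- function(ld, k, restart) {
    N <- ld$N
    if (k == 1L) return(matrix(1, N, 1L))
    means <- as.vector(rowsum(ld$y, ld$idx, reorder = FALSE)) /
        as.vector(rowsum(rep(1, ld$nobs), ld$idx, reorder = FALSE))
    cl <- NULL
    if (restart == 1L) {
        cl <- tryCatch(stats::kmeans(means, centers = k, nstart = 5L)$cluster,
                       error = function(e) NULL)
    } else {
        ctr <- sample(means, k) + stats::rnorm(k, 0, 0.25 * stats::sd(means))
        cl <- apply(abs(outer(means, ctr, "-")), 1L, which.min)
    }
    if (is.null(cl)) cl <- sample.int(k, N, replace = TRUE)
    if (length(unique(cl)) < k) cl[sample.int(N, k)] <- seq_len(k)
    w <- matrix(0.05 / max(k - 1L, 1L), N, k)
    w[cbind(seq_len(N), cl)] <- 0.95
    w / rowSums(w)
}

.emRun <- function(ld, spec, w0, control) {
    sigmaFloor <- control$sigmaFloorFactor * ld$sdY
    w <- w0
    par <- NULL
    llPrev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(control$maxIter)) {
        par <- .mStep(ld, spec, w, sigmaFloor, prev = par)
        es <- .eStep(ld, spec, par)
        trace <- c(trace, es$loglik)
        w <- es$w
        if (is.finite(es$loglik) && abs(es$loglik - llPrev) < control$tol) {
            converged <- TRUE
            llPrev <- es$loglik
            break
        }
        llPrev <- es$loglik
    }
    list(par = par, w = w, loglik = llPrev, converged = converged,
         trace = trace, iters = length(trace))
}

# ---------------------------------------------------------------------------
# Packed parameterization (used for the numerical observed information).
# Layout: beta_1, ..., beta_k, gamma (if any), eta_2..eta_k (multinomial
# logits with group 1 as reference), log sigma.
# ---------------------------------------------------------------------------

.packParams <- function(spec, par, C) {
    th <- unlist(par$beta)
    if (C > 0L) th <- c(th, unlist(par$gamma))
    if (spec@k > 1L) th <- c(th, log(par$pi[-1L] / par$pi[1L]))
    c(th, log(par$sigma))
}

.unpackParams <- function(theta, spec, C) {
    k <- spec@k
    pcols <- spec@orders + 1L
    beta <- vector("list", k)
    off <- 0L
    for (j in seq_len(k)) {
        beta[[j]] <- theta[(off + 1L):(off + pcols[j])]
        off <- off + pcols[j]
    }
    gamma <- list()
    if (C > 0L) {
        if (spec@covariateSharing == "shared") {
            gamma <- list(theta[(off + 1L):(off + C)])
            off <- off + C
        } else {
            for (j in seq_len(k)) {
                gamma[[j]] <- theta[(off + 1L):(off + C)]
                off <- off + C
            }
        }
    }
    if (k > 1L) {
        eta <- theta[(off + 1L):(off + k - 1L)]
        off <- off + k - 1L
        ex <- exp(c(0, eta))
        pi <- ex / sum(ex)
    } else pi <- 1
    sigma <- exp(theta[off + 1L])
    list(beta = beta, gamma = gamma, pi = pi, sigma = sigma)
}

.packedLoglik <- function(theta, ld, spec, C) {
    par <- .unpackParams(theta, spec, C)
    Mu <- .mixMeans(ld, spec, par$beta, par$gamma)
    Li <- .indLogDens(ld, Mu, par$sigma)
    a <- sweep(Li, 2, log(par$pi), "+")
    M <- a[, 1L]
    if (spec@k > 1L) for (j in 2:spec@k) M <- pmax(M, a[, j])
    sum(M + log(rowSums(exp(a - M))))
}

# Evaluate the observed-data log-likelihood of arbitrary parameter values
# (used by tests for label-permutation equivalence).
.evalLoglik <- function(data, spec, beta, gamma, pi, sigma) {
    ld <- .longFormat(data, spec@useCovariates)
    C <- if (spec@useCovariates && !is.null(ld$Xcov)) ncol(ld$Xcov) else 0L
    .packedLoglik(.packParams(spec, list(beta = beta, gamma = gamma, pi = pi,
                                         sigma = sigma), C),
                  ld, spec, C)
}

# Wald p-values from the numerical observed information at the optimum.
.waldPvalues <- function(ld, spec, par, C) {
    theta <- .packParams(spec, par, C)
    negll <- function(th) -.packedLoglik(th, ld, spec, C)
    H <- pracma::hessian(negll, theta)
    V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
    se <- sqrt(pmax(diag(V), 0))
    z <- ifelse(se > 0, theta / se, NA_real_)
    p <- 2 * stats::pnorm(-abs(z))
    pcols <- spec@orders + 1L
    coefP <- vector("list", spec@k)
    off <- 0L
    for (j in seq_len(spec@k)) {
        coefP[[j]] <- stats::setNames(p[(off + 1L):(off + pcols[j])],
                                      paste0("t^", 0:spec@orders[j]))
        off <- off + pcols[j]
    }
    gammaP <- list()
    if (C > 0L) {
        ng <- if (spec@covariateSharing == "shared") 1L else spec@k
        for (j in seq_len(ng)) {
            gammaP[[j]] <- stats::setNames(p[(off + 1L):(off + C)], ld$covNames)
            off <- off + C
        }
    }
    list(coefPvalues = coefP, gammaPvalues = gammaP)
}
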