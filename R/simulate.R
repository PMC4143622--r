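# Seeded simulator for method evaluation. It emulates the shape of the
# reference study design: ~20 three-generation extended pedigrees (~850
# members) plus an unrelated cohort (~157), SNP genotypes fixed across
# replicates, and per-replicate longitudinal blood-pressure-like phenotypes
# generated from a trajectory-mixture model with covariate and genetic
# effects whose variance-explained is tunable (headline gene ~6%).

#' Simulation configuration
#'
#' Defaults mirror the reference design: 20 extended pedigrees of 42 (2
#' founders, 5 children with founder spouses, 6 grandchildren per couple,
#' ~840 members total), 157 unrelated individuals, 3 visits, 200 phenotype
#' replicates, 15 causal genes (the first explaining 6\% of trait variance)
#' and 3 null regions. Trajectory truth is a 3-subgroup linear model with a
#' small high-blood-pressure subgroup (10\%).
#'
#' @param nFamilies,nChildren,nGrandchildren pedigree template: families,
#'   children per family (each married to a founder spouse), grandchildren
#'   per couple.
#' @param nUnrelated size of the unrelated cohort (singleton families).
#' @param nSnps,mafRange,chrom,posStart,posSpacing SNP map: count, minor
#'   allele frequency range (linkage equilibrium), chromosome, first
#'   position (bp) and spacing (bp).
#' @param nCausalGenes,nNullRegions,snpsPerGene region layout: consecutive
#'   blocks of \code{snpsPerGene} SNPs form the causal genes, then the null
#'   regions; remaining SNPs are background.
#' @param causalVE per-gene fraction of total trait variance explained
#'   (level-shift mode); the first entry is the headline gene.
#' @param nCausalPerGene causal SNPs per causal gene.
#' @param effectMode \code{"level-shift"}: genotype adds a level shift to
#'   the trait calibrated to \code{causalVE}; \code{"group-logit"}: genotype
#'   shifts the log-odds of membership in the high subgroup (a
#'   misspecification stressor).
#' @param logitEffect log-odds shift per centered causal-burden unit for the
#'   headline gene in group-logit mode (other genes scaled by
#'   \code{sqrt(causalVE/causalVE[1])}).
#' @param kTrue,betaTrue,piTrue,sigmaTrue trajectory truth: subgroup count,
#'   per-subgroup polynomial coefficients on the visit-index time scale
#'   (0, 1, ...), membership probabilities, residual SD (trait units, mmHg
#'   for SBP).
#' @param ageBaseMean,ageBaseSd,visitSpacing age covariate: baseline age
#'   distribution (years) and per-visit increment.
#' @param gammaAge,pSmoke,gammaSmoke,gammaMed,medBase,medFastShift,pMale,gammaSex
#'   covariate model: age slope (mmHg/yr), smoking prevalence and effect,
#'   medication effect, medication log-odds (base, shift for the high
#'   subgroup), male prevalence and sex effect.
#' @param nReplicates,nVisits,seed replicate count, visits per individual,
#'   base seed.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(nFamilies = 20L, nChildren = 5L, nGrandchildren = 6L,
                      nUnrelated = 157L,
                      nSnps = 120L, mafRange = c(0.05, 0.5), chrom = "3",
                      posStart = 1e6, posSpacing = 1e4,
                      nCausalGenes = 15L, nNullRegions = 3L, snpsPerGene = 5L,
                      causalVE = c(0.06, rep(0.005, 14)),
                      nCausalPerGene = 2L,
                      effectMode = c("level-shift", "group-logit"),
                      logitEffect = 1.0,
                      kTrue = 3L,
                      betaTrue = list(c(112, 0.5), c(128, 1.5), c(148, 3.5)),
                      piTrue = c(0.55, 0.35, 0.10), sigmaTrue = 10,
                      ageBaseMean = 45, ageBaseSd = 10, visitSpacing = 2.5,
                      gammaAge = 0.25, pSmoke = 0.25, gammaSmoke = 4,
                      gammaMed = -8, medBase = -1.5, medFastShift = 1.5,
                      pMale = 0.5, gammaSex = 3,
                      nReplicates = 200L, nVisits = 3L, seed = 1L) {
    effectMode <- match.arg(effectMode)
    stopifnot(nVisits >= 2L, length(betaTrue) == kTrue,
              length(piTrue) == kTrue, abs(sum(piTrue) - 1) < 1e-12,
              all(piTrue >= 0), sigmaTrue > 0,
              length(causalVE) == nCausalGenes,
              all(causalVE >= 0), sum(causalVE) < 1,
              (nCausalGenes + nNullRegions) * snpsPerGene <= nSnps,
              nCausalPerGene <= snpsPerGene,
              mafRange[1] > 0, mafRange[2] <= 0.5)
    structure(as.list(environment()), class = "SimConfig")
}

# ---------------------------------------------------------------------------
# Pedigree construction and gene-dropping
# ---------------------------------------------------------------------------

# One extended family: founder couple, their children married to founder
# spouses, grandchildren per couple.
.familyTemplate <- function(fid, nChildren, nGrandchildren) {
    rows <- list(data.frame(FID = fid, IID = c("F1", "F2"), PAT = "0",
                            MAT = "0", SEX = c(1L, 2L)))
    for (ch in seq_len(nChildren)) {
        cid <- paste0("C", ch)
        sid <- paste0("S", ch)
        csex <- if (ch %% 2L == 1L) 1L else 2L
        rows[[length(rows) + 1L]] <- data.frame(
            FID = fid, IID = c(cid, sid),
            PAT = c("F1", "0"), MAT = c("F2", "0"),
            SEX = c(csex, 3L - csex))
        if (nGrandchildren > 0L) {
            gids <- paste0("G", ch, "_", seq_len(nGrandchildren))
            pat <- if (csex == 1L) cid else sid
            mat <- if (csex == 1L) sid else cid
            rows[[length(rows) + 1L]] <- data.frame(
                FID = fid, IID = gids, PAT = pat, MAT = mat,
                SEX = rep_len(c(1L, 2L), nGrandchildren))
        }
    }
    do.call(rbind, rows)
}

# Topological order of a pedigree (parents before offspring); errors on
# unresolvable parent references or cycles.
.orderPedigree <- function(ped) {
    key <- paste(ped$FID, ped$IID)
    if (anyDuplicated(key)) stop("duplicate FID/IID in pedigree template")
    fa <- match(paste(ped$FID, ped$PAT), key)
    mo <- match(paste(ped$FID, ped$MAT), key)
    if (any(ped$PAT != "0" & is.na(fa)) || any(ped$MAT != "0" & is.na(mo)))
        stop("pedigree template has unresolvable parent references")
    placed <- logical(nrow(ped))
    ord <- integer(0)
    repeat {
        ready <- !placed & (is.na(fa) | placed[fa]) & (is.na(mo) | placed[mo])
        if (!any(ready)) break
        ord <- c(ord, which(ready))
        placed[ready] <- TRUE
    }
    if (!all(placed))
        stop("pedigree template contains a cycle (individuals: ",
             paste(key[!placed], collapse = ", "), ")")
    ord
}

# Transmit one allele from a parent of known dosage (exact for unlinked
# SNPs): homozygotes transmit deterministically, heterozygotes uniformly.
.transmit <- function(parentDosage) {
    het <- parentDosage == 1L
    out <- parentDosage / 2L
    out[het] <- stats::rbinom(sum(het), 1L, 0.5)
    as.integer(out)
}

#' Simulate genotypes for pedigrees and an unrelated cohort
#'
#' Founders draw each SNP as Binomial(2, MAF) in linkage equilibrium;
#' non-founders are gene-dropped (one allele from each parent, uniformly
#' from heterozygous parents), so the data are free of Mendelian errors by
#' construction. The unrelated cohort is drawn as founders in singleton
#' families.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @param pedigreeTemplate optional pedigree data.frame (\code{FID IID PAT
#'   MAT SEX}) overriding the built-in extended-family template; validated
#'   for resolvable, acyclic parent links.
#' @return a \code{\link{GenotypeData}}.
#' @export
simulateGenotypes <- function(config, seed = config$seed,
                              pedigreeTemplate = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(as.integer(seed))
    ped <- pedigreeTemplate
    if (is.null(ped) && config$nFamilies > 0L)
        ped <- do.call(rbind, lapply(seq_len(config$nFamilies), function(f)
            .familyTemplate(sprintf("FAM%02d", f), config$nChildren,
                            config$nGrandchildren)))
    if (config$nUnrelated > 0L) {
        u <- sprintf("U%04d", seq_len(config$nUnrelated))
        ped <- rbind(ped, data.frame(FID = u, IID = u, PAT = "0", MAT = "0",
                                     SEX = rep_len(c(1L, 2L),
                                                   config$nUnrelated)))
    }
    if (is.null(ped) || !nrow(ped)) stop("empty pedigree")
    ord <- .orderPedigree(ped)
    ped <- ped[ord, , drop = FALSE]
    rownames(ped) <- NULL
    key <- paste(ped$FID, ped$IID)
    fa <- match(paste(ped$FID, ped$PAT), key)
    mo <- match(paste(ped$FID, ped$MAT), key)
    n <- nrow(ped)
    m <- config$nSnps
    maf <- stats::runif(m, config$mafRange[1], config$mafRange[2])
    D <- matrix(NA_integer_, n, m)
    founder <- is.na(fa) & is.na(mo)
    nf <- sum(founder)
    D[founder, ] <- vapply(seq_len(m), function(s)
        stats::rbinom(nf, 2L, maf[s]), integer(nf))
    # rows are in topological order, so parents are always filled first
    for (i in which(!founder))
        D[i, ] <- .transmit(D[fa[i], ]) + .transmit(D[mo[i], ])
    snpInfo <- data.frame(
        snp = sprintf("rs%05d", seq_len(m)),
        chrom = config$chrom,
        pos = as.integer(config$posStart + (seq_len(m) - 1L) *
                             config$posSpacing),
        A1 = "A", A2 = "B")
    gd <- GenotypeData(D, snpInfo, ped)
    metadata(gd)$maf <- maf
    gd
}

#' Gene and null regions of a simulation design
#'
#' Consecutive blocks of \code{snpsPerGene} SNPs: first the causal genes
#' (with their variance-explained targets in \code{mcols()$ve}), then the
#' null regions (no simulated functional loci; \code{isNull = TRUE}).
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{GRanges} with \code{isNull} and \code{ve} metadata.
#' @export
simRegions <- function(config) {
    nr <- config$nCausalGenes + config$nNullRegions
    idx0 <- (seq_len(nr) - 1L) * config$snpsPerGene
    startPos <- config$posStart + idx0 * config$posSpacing
    endPos <- config$posStart + (idx0 + config$snpsPerGene - 1L) *
        config$posSpacing
    gr <- GRanges(config$chrom, IRanges(start = startPos, end = endPos))
    names(gr) <- c(sprintf("GENE%02d", seq_len(config$nCausalGenes)),
                   sprintf("NULL%02d", seq_len(config$nNullRegions)))
    mcols(gr)$isNull <- rep(c(FALSE, TRUE),
                            c(config$nCausalGenes, config$nNullRegions))
    mcols(gr)$ve <- c(config$causalVE, rep(0, config$nNullRegions))
    gr
}

# SNP column indices of the causal SNPs, per causal gene.
.causalSnpIndices <- function(config) {
    lapply(seq_len(config$nCausalGenes), function(g)
        (g - 1L) * config$snpsPerGene + seq_len(config$nCausalPerGene))
}

#' Simulate one longitudinal phenotype replicate
#'
#' Genotypes stay fixed across replicates; subgroup assignments, covariates
#' and noise are redrawn per replicate. In level-shift mode the causal
#' burden adds a constant shift to every visit, scaled so each gene's share
#' of total trait variance matches its \code{causalVE} target; in
#' group-logit mode the burden shifts the log-odds of high-subgroup
#' membership. The truth (subgroup labels, realized variance shares) is
#' stored in \code{metadata()$truth}.
#'
#' @param genotypes a \code{\link{GenotypeData}} from
#'   \code{\link{simulateGenotypes}}.
#' @param config the same \code{\link{simConfig}}.
#' @param replicateSeed integer seed for this replicate.
#' @return a \code{\link{LongitudinalData}} with time-varying covariates
#'   age, med, smoke and static covariate sex.
#' @export
simulatePhenotypeReplicate <- function(genotypes, config, replicateSeed) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(as.integer(replicateSeed))
    ped <- pedigree(genotypes)
    D <- dosageMatrix(genotypes)
    n <- nrow(ped)
    Tn <- config$nVisits
    tvis <- matrix(rep(0:(Tn - 1L), each = n), n, Tn)
    k <- config$kTrue
    tLast <- Tn - 1L
    trajAt <- vapply(config$betaTrue, function(b)
        sum(b * tLast^(seq_along(b) - 1L)), numeric(1))
    fast <- which.max(trajAt)
    # centered causal burden per causal gene
    csnp <- .causalSnpIndices(config)
    burden <- vapply(csnp, function(ix) {
        b <- rowSums(D[, ix, drop = FALSE])
        b - mean(b)
    }, numeric(n))
    ve <- config$causalVE
    if (config$effectMode == "group-logit") {
        eta <- matrix(rep(log(config$piTrue), each = n), n, k)
        theta <- config$logitEffect *
            sqrt(ifelse(ve[1] > 0, ve / ve[1], 0))
        eta[, fast] <- eta[, fast] + drop(burden %*% theta)
        pr <- exp(eta - apply(eta, 1L, max))
        pr <- pr / rowSums(pr)
        group <- vapply(seq_len(n), function(i)
            sample.int(k, 1L, prob = pr[i, ]), integer(1))
    } else {
        group <- sample.int(k, n, replace = TRUE, prob = config$piTrue)
    }
    # covariates
    sex <- stats::rbinom(n, 1L, config$pMale)            # 1 = male
    smoke <- stats::rbinom(n, 1L, config$pSmoke)
    ageBase <- stats::rnorm(n, config$ageBaseMean, config$ageBaseSd)
    age <- ageBase + tvis * config$visitSpacing
    medP <- stats::plogis(config$medBase +
                              config$medFastShift * (group == fast))
    med <- matrix(stats::rbinom(n * Tn, 1L, rep(medP, Tn)), n, Tn)
    smokeM <- matrix(smoke, n, Tn)
    # trajectory + covariates + noise
    mu <- t(vapply(group, function(g) {
        b <- config$betaTrue[[g]]
        vapply(0:(Tn - 1L), function(t) sum(b * t^(seq_along(b) - 1L)),
               numeric(1))
    }, numeric(Tn)))
    y <- mu + config$gammaAge * age + config$gammaSmoke * smokeM +
        config$gammaMed * med + config$gammaSex * matrix(sex, n, Tn) +
        matrix(stats::rnorm(n * Tn, 0, config$sigmaTrue), n, Tn)
    veShare <- rep(0, config$nCausalGenes)
    if (config$effectMode == "level-shift" && any(ve > 0)) {
        vb <- apply(burden, 2L, stats::var)
        if (any(ve > 0 & vb == 0)) {
            bad <- which(ve > 0 & vb == 0)[1]
            stop("causal gene ", bad, " has zero burden variance ",
                 "(monomorphic causal SNPs); attainable variance ",
                 "explained is 0, requested ", ve[bad])
        }
        vRest <- stats::var(as.vector(y))
        vTot <- vRest / (1 - sum(ve))
        betaG <- ifelse(ve > 0, sqrt(ve * vTot / pmax(vb, 1e-300)), 0)
        shift <- drop(burden %*% betaG)
        y <- y + shift
        veShare <- (betaG^2 * vb) / stats::var(as.vector(y))
    }
    ld <- LongitudinalData(
        iid = ped$IID, fid = ped$FID, values = y, times = tvis,
        covariatesTV = list(age = age, med = med, smoke = smokeM),
        covariatesTI = data.frame(sex = sex))
    metadata(ld)$truth <- list(group = group, fastGroup = fast,
                               veRealized = veShare,
                               effectMode = config$effectMode)
    ld
}

#' Write a complete simulated study bundle to disk
#'
#' Simulates genotypes once, then writes PLINK text PED/MAP (plus a
#' reference-allele file fixing the coded allele), one long-format phenotype
#' TSV per replicate, the gene/null region BED and the configuration JSON.
#' All files round-trip through the package readers.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir output directory (created if needed).
#' @param nReplicates number of phenotype replicates to write (defaults to
#'   \code{config$nReplicates}).
#' @param seed base seed (defaults to \code{config$seed}); replicate r uses
#'   \code{seed + 10000 + r}.
#' @return (invisibly) a manifest list of the written paths.
#' @export
makeSimBundle <- function(config, dir, nReplicates = config$nReplicates,
                          seed = config$seed) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    geno <- simulateGenotypes(config, seed = seed)
    paths <- list(
        ped = file.path(dir, "study.ped"),
        map = file.path(dir, "study.map"),
        ref = file.path(dir, "study.ref"),
        regions = file.path(dir, "regions.bed"),
        config = file.path(dir, "config.json"))
    writePedMap(geno, paths$ped, paths$map, refPath = paths$ref)
    writeRegions(simRegions(config), paths$regions)
    paths$phenotypes <- character(nReplicates)
    for (r in seq_len(nReplicates)) {
        ld <- simulatePhenotypeReplicate(geno, config,
                                         replicateSeed = seed + 10000L + r)
        paths$phenotypes[r] <- file.path(dir, sprintf("pheno_rep%03d.tsv", r))
        writeLongPhenotypes(ld, paths$phenotypes[r])
    }
    cfg <- unclass(config)
    cfg$betaTrue <- lapply(cfg$betaTrue, as.numeric)
    jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
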