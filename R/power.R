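# Replicate-set power procedure: a set is one discovery plus two
# confirmatory phenotype replicates over fixed genotypes; a gene scores YES
# for a set only when every replicate in the set shows a qualifying marker
# inside the gene. Per-gene power is the YES fraction over sets; total power
# is its mean over non-null genes; null regions estimate empirical type-I
# error.

#' Draw replicate sets
#'
#' Each set samples \code{setSize} distinct replicate ids without
#' replacement from the pool; sets are drawn independently, so ids may recur
#' across sets (with a pool of 200 and 100 sets of 3 they must). The first
#' id of a set is the discovery replicate, the rest are confirmatory.
#'
#' @param nPool number of phenotype replicates available.
#' @param nSets number of sets to draw (reference design: 100, giving 100
#'   discovery and 200 confirmatory data sets).
#' @param setSize replicates per set (default 3).
#' @param seed integer seed; output is deterministic given it.
#' @return integer matrix, \code{nSets} x \code{setSize}; column 1 is the
#'   discovery replicate.
#' @export
buildReplicateSets <- function(nPool, nSets, setSize = 3L, seed = NULL) {
    if (setSize > nPool)
        stop("setSize (", setSize, ") exceeds the replicate pool (", nPool, ")")
    if (!is.null(seed)) set.seed(as.integer(seed))
    out <- t(vapply(seq_len(nSets),
                    function(s) sample.int(nPool, setSize),
                    integer(setSize)))
    colnames(out) <- c("discovery", paste0("confirm", seq_len(setSize - 1L)))
    out
}

#' Hit criterion for gene scoring
#'
#' @param type \code{"alpha_threshold"} (family-style: p at or below alpha)
#'   or \code{"top_percent"} (population-style: p-value rank within the top
#'   x\% of all SNPs tested in the replicate's analysis).
#' @param value alpha in (0,1), or x in percent.
#' @return a criterion object for \code{\link{geneHit}}.
#' @export
hitCriterion <- function(type = c("alpha_threshold", "top_percent"), value) {
    type <- match.arg(type)
    stopifnot(is.numeric(value), length(value) == 1L, value > 0)
    structure(list(type = type, value = value), class = "hitCriterion")
}

#' Does a gene contain a qualifying marker?
#'
#' \code{alpha_threshold}: YES iff some SNP inside the gene has
#' \code{p <= alpha}. \code{top_percent}: YES iff some SNP inside the gene
#' has p-value rank \code{<= ceiling(x/100 * m)} where m counts all SNPs
#' tested in this association table.
#'
#' @param assoc association table (\code{CHR}, \code{BP}, \code{P}).
#' @param gene a length-1 \code{GRanges} (1-based inclusive coordinates).
#' @param criterion from \code{\link{hitCriterion}}.
#' @return logical.
#' @export
geneHit <- function(assoc, gene, criterion) {
    stopifnot(nrow(assoc) >= 1L, inherits(criterion, "hitCriterion"))
    tested <- !is.na(assoc$P)
    inside <- tested & assoc$CHR == as.character(seqnames(gene))[1] &
        assoc$BP >= start(gene)[1] & assoc$BP <= end(gene)[1]
    if (!any(inside)) {
        warning("gene ", if (!is.null(names(gene))) names(gene)[1] else "",
                " contains no tested SNPs; scoring NO")
        return(FALSE)
    }
    if (criterion$type == "alpha_threshold") {
        any(assoc$P[inside] <= criterion$value)
    } else {
        m <- sum(tested)
        ranks <- rank(assoc$P[tested], ties.method = "min")
        cutoff <- ceiling(criterion$value / 100 * m)
        any(ranks[inside[tested]] <= cutoff)
    }
}

#' Per-gene power over replicate sets
#'
#' A set scores YES for a gene iff \code{\link{geneHit}} is YES in all of
#' the set's replicates; per-gene power is the YES fraction over sets.
#'
#' @param sets matrix from \code{\link{buildReplicateSets}}.
#' @param assocTables named list of association tables, one per replicate id
#'   referenced by \code{sets} (names are the replicate ids as characters).
#' @param genes a \code{GRanges} of gene/null regions (names used as gene
#'   names; an \code{isNull} metadata column marks null regions).
#' @param criterion from \code{\link{hitCriterion}}.
#' @return named numeric vector of per-gene power.
#' @export
perGenePower <- function(sets, assocTables, genes, criterion) {
    reps <- sort(unique(as.vector(sets)))
    missing <- setdiff(as.character(reps), names(assocTables))
    if (length(missing))
        stop("no association table for replicate(s): ",
             paste(missing, collapse = ", "))
    # hit matrix: replicates x genes, computed once per replicate
    hits <- matrix(FALSE, length(reps), length(genes),
                   dimnames = list(as.character(reps), names(genes)))
    for (r in as.character(reps))
        for (g in seq_along(genes))
            hits[r, g] <- suppressWarnings(
                geneHit(assocTables[[r]], genes[g], criterion))
    power <- vapply(seq_along(genes), function(g) {
        yes <- apply(sets, 1L, function(s) all(hits[as.character(s), g]))
        mean(yes)
    }, numeric(1))
    names(power) <- names(genes)
    power
}

#' Total power
#'
#' Arithmetic mean of per-gene power over non-null genes.
#'
#' @param perGene named numeric vector of per-gene power.
#' @param isNull logical vector marking null regions (excluded).
#' @return the mean power over non-null genes.
#' @export
totalPower <- function(perGene, isNull = rep(FALSE, length(perGene))) {
    if (!any(!isNull)) stop("need at least one non-null gene")
    mean(perGene[!isNull])
}

#' Compare per-gene power between two conditions
#'
#' Paired two-sided t-test on per-gene power differences (e.g. covariate vs
#' no-covariate analyses at one significance level). An unpaired Welch test
#' is available behind \code{paired = FALSE}.
#'
#' @param powerA,powerB per-gene power vectors over the same genes.
#' @param paired paired test (default) or unpaired.
#' @return list with \code{statistic}, \code{p.value}, \code{df} and a
#'   \code{reason} code when the test is degenerate.
#' @export
compareConditions <- function(powerA, powerB, paired = TRUE) {
    stopifnot(length(powerA) == length(powerB), length(powerA) >= 2L)
    d <- powerA - powerB
    if (paired && stats::sd(d) <= 1e-10 * max(1, abs(mean(d))))
        return(list(statistic = NA_real_, p.value = NA_real_,
                    df = NA_real_, reason = "zero_variance_differences"))
    tt <- tryCatch(stats::t.test(powerA, powerB, paired = paired),
                   error = function(e) NULL)
    if (is.null(tt))
        return(list(statistic = NA_real_, p.value = NA_real_,
                    df = NA_real_, reason = "zero_variance_differences"))
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         df = unname(tt$parameter), reason = NA_character_)
}

#' Assemble a power report
#'
#' Computes per-gene power at each threshold, total power over non-null
#' genes and the null-region YES rates, packaging them with the criterion.
#'
#' @inheritParams perGenePower
#' @param thresholds numeric vector of criterion values (alphas, or percent
#'   values for \code{top_percent}).
#' @param criterionType \code{"alpha_threshold"} or \code{"top_percent"}.
#' @param meta free-form metadata list stored in the report.
#' @return a \code{\link{PowerReport}}.
#' @export
powerReport <- function(sets, assocTables, genes, thresholds,
                        criterionType = c("alpha_threshold", "top_percent"),
                        meta = list()) {
    criterionType <- match.arg(criterionType)
    isNull <- if ("isNull" %in% colnames(mcols(genes)))
        as.logical(mcols(genes)$isNull) else rep(FALSE, length(genes))
    gp <- sapply(thresholds, function(th)
        perGenePower(sets, assocTables, genes,
                     hitCriterion(criterionType, th)))
    gp <- matrix(gp, nrow = length(genes),
                 dimnames = list(names(genes), as.character(thresholds)))
    tp <- colMeans(gp[!isNull, , drop = FALSE])
    nr <- if (any(isNull)) colMeans(gp[isNull, , drop = FALSE])
          else stats::setNames(numeric(0), character(0))
    new("PowerReport", genePower = gp, isNull = isNull, totalPower = tp,
        nullRates = nr, criterion = criterionType,
        thresholds = as.numeric(thresholds), nSets = nrow(sets),
        comparisons = list(), meta = meta)
}
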