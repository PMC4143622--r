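# File dialects: PLINK text PED/MAP, long-format phenotype TSV, BED regions
# (0-based half-open on disk, 1-based inclusive in memory), association and
# BPP tables, JSON reports.

#' Read PLINK text PED/MAP into a GenotypeData
#'
#' PED columns: FID IID PAT MAT SEX PHENO then two allele columns per SNP;
#' allele "0" means missing. MAP columns: chrom, snp, (optional cM,) bp.
#' The coded allele of each SNP is the first non-missing allele encountered
#' in file order unless a reference-allele file fixes it.
#'
#' @param pedPath,mapPath paths to the PED and MAP files.
#' @param refAlleles optional path to (or data.frame of) a reference-allele
#'   table with columns \code{snp}, \code{A1} (coded) and optionally
#'   \code{A2}, as written by \code{\link{writePedMap}}.
#' @return a \code{\link{GenotypeData}}.
#' @export
readPedMap <- function(pedPath, mapPath, refAlleles = NULL) {
    map <- utils::read.table(mapPath, header = FALSE,
                             colClasses = "character")
    if (!ncol(map) %in% c(3L, 4L))
        stop("MAP file must have 3 or 4 columns, found ", ncol(map))
    map <- data.frame(chrom = map[[1]], snp = map[[2]],
                      pos = as.integer(map[[ncol(map)]]))
    m <- nrow(map)
    fields <- utils::count.fields(pedPath)
    expect <- 6L + 2L * m
    if (any(fields != expect))
        stop("PED line(s) ", paste(which(fields != expect), collapse = ", "),
             " have ", paste(unique(fields[fields != expect]), collapse = "/"),
             " fields; expected ", expect, " for ", m, " SNPs")
    ped <- utils::read.table(pedPath, header = FALSE,
                             colClasses = "character")
    pedigree <- data.frame(FID = ped[[1]], IID = ped[[2]], PAT = ped[[3]],
                           MAT = ped[[4]], SEX = as.integer(ped[[5]]))
    n <- nrow(ped)
    A <- as.matrix(ped[, -(1:6), drop = FALSE])
    a1 <- A[, seq(1L, 2L * m, by = 2L), drop = FALSE]
    a2 <- A[, seq(2L, 2L * m, by = 2L), drop = FALSE]
    if (!is.null(refAlleles)) {
        if (is.character(refAlleles))
            refAlleles <- utils::read.table(refAlleles, header = TRUE,
                                            colClasses = "character")
        coded <- refAlleles$A1[match(map$snp, refAlleles$snp)]
        if (anyNA(coded))
            stop("reference-allele table is missing SNP(s): ",
                 paste(map$snp[is.na(coded)], collapse = ", "))
    } else {
        coded <- vapply(seq_len(m), function(s) {
            al <- c(a1[, s], a2[, s])
            al <- al[al != "0"]
            if (length(al)) al[1] else "0"
        }, character(1))
    }
    other <- vapply(seq_len(m), function(s) {
        al <- unique(c(a1[, s], a2[, s]))
        al <- setdiff(al, c("0", coded[s]))
        if (length(al)) al[1] else coded[s]
    }, character(1))
    D <- matrix(NA_integer_, n, m)
    for (s in seq_len(m)) {
        miss <- a1[, s] == "0" | a2[, s] == "0"
        D[, s] <- (a1[, s] == coded[s]) + (a2[, s] == coded[s])
        D[miss, s] <- NA_integer_
    }
    GenotypeData(D, data.frame(snp = map$snp, chrom = map$chrom,
                               pos = map$pos, A1 = coded, A2 = other),
                 pedigree)
}

#' Write a GenotypeData as PLINK text PED/MAP
#'
#' @param geno a \code{\link{GenotypeData}}.
#' @param pedPath,mapPath output paths.
#' @param refPath optional path for a reference-allele table (snp, A1, A2)
#'   that makes the round-trip through \code{\link{readPedMap}} exact even
#'   for monomorphic SNPs.
#' @export
writePedMap <- function(geno, pedPath, mapPath, refPath = NULL) {
    si <- snpInfo(geno)
    ped <- pedigree(geno)
    D <- dosageMatrix(geno)
    n <- nrow(D); m <- ncol(D)
    al <- matrix("0", n, 2L * m)
    for (s in seq_len(m)) {
        g <- D[, s]
        c1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, si$A1[s], si$A2[s]))
        c2 <- ifelse(is.na(g), "0", ifelse(g == 2L, si$A1[s], si$A2[s]))
        al[, 2L * s - 1L] <- c1
        al[, 2L * s] <- c2
    }
    out <- cbind(ped$FID, ped$IID, ped$PAT, ped$MAT, ped$SEX, "-9", al)
    utils::write.table(out, pedPath, quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(cbind(si$chrom, si$snp, 0, si$pos), mapPath,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (!is.null(refPath))
        utils::write.table(si[, c("snp", "A1", "A2")], refPath,
                           quote = FALSE, row.names = FALSE, sep = "\t")
    invisible(c(pedPath, mapPath))
}

#' Read a long-format phenotype TSV
#'
#' Columns FID, IID, VISIT, TIME, VALUE, then covariate columns; the missing
#' value token is "NA". Covariate columns constant within every individual
#' are treated as static, the rest as time-varying. Row order is irrelevant;
#' duplicate (FID, IID, VISIT) rows are an error.
#'
#' @param path TSV path.
#' @return a \code{\link{LongitudinalData}}.
#' @export
readLongPhenotypes <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            na.strings = "NA", stringsAsFactors = FALSE)
    need <- c("FID", "IID", "VISIT", "TIME", "VALUE")
    if (!all(need %in% colnames(df)))
        stop("phenotype file must have columns ", paste(need, collapse = ", "))
    key <- paste(df$FID, df$IID)
    if (anyDuplicated(paste(key, df$VISIT)))
        stop("duplicate (IID, VISIT) rows in ", path)
    ids <- unique(key)
    visits <- sort(unique(df$VISIT))
    ii <- match(key, ids)
    vv <- match(df$VISIT, visits)
    grab <- function(col) {
        m <- matrix(NA_real_, length(ids), length(visits))
        m[cbind(ii, vv)] <- as.numeric(col)
        m
    }
    values <- grab(df$VALUE)
    times <- grab(df$TIME)
    covCols <- setdiff(colnames(df), need)
    tv <- list(); ti <- list()
    for (nm in covCols) {
        m <- grab(df[[nm]])
        rng <- apply(m, 1L, function(r) {
            r <- r[!is.na(r)]
            if (length(r)) diff(range(r)) else 0
        })
        if (all(rng == 0)) {
            ti[[nm]] <- apply(m, 1L, function(r) r[!is.na(r)][1])
        } else tv[[nm]] <- m
    }
    fid <- df$FID[match(ids, key)]
    iid <- df$IID[match(ids, key)]
    LongitudinalData(iid = iid, fid = fid, values = values, times = times,
                     covariatesTV = tv,
                     covariatesTI = if (length(ti)) as.data.frame(ti) else NULL)
}

#' Write a LongitudinalData as a long-format phenotype TSV
#'
#' @param data a \code{\link{LongitudinalData}}.
#' @param path output path.
#' @export
writeLongPhenotypes <- function(data, path) {
    val <- phenoMatrix(data); tim <- timeMatrix(data)
    n <- nrow(val); Tn <- ncol(val)
    df <- data.frame(FID = rep(familyIds(data), Tn),
                     IID = rep(individualIds(data), Tn),
                     VISIT = rep(seq_len(Tn), each = n),
                     TIME = as.vector(tim), VALUE = as.vector(val))
    for (nm in names(tvCovariates(data)))
        df[[nm]] <- as.vector(tvCovariates(data)[[nm]])
    ti <- tiCovariates(data)
    for (nm in colnames(ti)) df[[nm]] <- rep(as.numeric(ti[[nm]]), Tn)
    df <- df[!is.na(df$VALUE), , drop = FALSE]
    utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
    invisible(path)
}

#' Read gene/null regions from a BED file
#'
#' BED is 0-based half-open on disk and converted to 1-based inclusive
#' coordinates. Columns: chrom, start, end, optional name, optional null
#' flag (1/0).
#'
#' @param path BED path.
#' @return a \code{GRanges} with \code{isNull} metadata.
#' @export
readRegions <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    gr <- GRanges(as.character(df[[1]]),
                  IRanges(start = as.integer(df[[2]]) + 1L,
                          end = as.integer(df[[3]])))
    names(gr) <- if (ncol(df) >= 4L) as.character(df[[4]])
                 else paste0("region", seq_len(nrow(df)))
    mcols(gr)$isNull <- if (ncol(df) >= 5L) as.logical(as.integer(df[[5]]))
                        else rep(FALSE, nrow(df))
    gr
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions a \code{GRanges} with optional \code{isNull} metadata.
#' @param path output path.
#' @export
writeRegions <- function(regions, path) {
    isNull <- if ("isNull" %in% colnames(mcols(regions)))
        as.integer(mcols(regions)$isNull) else 0L
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     name = names(regions), isNull = isNull)
    utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = "\t")
    invisible(path)
}

#' Write an association table as TSV
#'
#' Columns CHR SNP BP BETA SE STAT P EMP_P Q (missing columns are filled
#' with NA).
#'
#' @param assoc association table from the scan functions.
#' @param path output path.
#' @export
writeAssociationTable <- function(assoc, path) {
    cols <- c("CHR", "SNP", "BP", "BETA", "SE", "STAT", "P", "EMP_P", "Q")
    for (nm in setdiff(cols, colnames(assoc))) assoc[[nm]] <- NA
    utils::write.table(assoc[, cols], path, quote = FALSE,
                       row.names = FALSE, sep = "\t")
    invisible(path)
}

#' Write the per-individual BPP table
#'
#' TSV with FID, IID, BPP_1..BPP_k and the max-BPP assigned group.
#'
#' @param model a \code{FittedTrajectoryModel}.
#' @param path output path.
#' @export
writeBppTable <- function(model, path) {
    bpp <- model@bpp
    df <- data.frame(FID = model@fid, IID = model@iid)
    for (j in seq_len(ncol(bpp))) df[[paste0("BPP_", j)]] <- bpp[, j]
    df$assigned_group <- max.col(bpp, ties.method = "first")
    utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
    invisible(path)
}

#' Write phenotype files for the association stage
#'
#' Quantitative: FID IID TRAIT. Binary: FID IID AFF with 1/2 coding
#' (1 = unaffected, 2 = affected, 0 = missing), the conventional
#' pedigree-phenotype dialect.
#'
#' @param phenotype a \code{DerivedPhenotype}.
#' @param quantPath,binaryPath output paths (either may be NULL).
#' @export
writeDerivedPhenotype <- function(phenotype, quantPath = NULL,
                                  binaryPath = NULL) {
    if (!is.null(quantPath)) {
        df <- data.frame(FID = phenotype@fid, IID = phenotype@iid,
                         TRAIT = phenotype@trait)
        utils::write.table(df, quantPath, quote = FALSE, row.names = FALSE,
                           sep = "\t")
    }
    if (!is.null(binaryPath)) {
        aff <- ifelse(is.na(phenotype@binaryTrait), 0L,
                      phenotype@binaryTrait + 1L)
        df <- data.frame(FID = phenotype@fid, IID = phenotype@iid, AFF = aff)
        utils::write.table(df, binaryPath, quote = FALSE, row.names = FALSE,
                           sep = "\t")
    }
    invisible(NULL)
}

#' Write a model-selection report as JSON
#'
#' Records the per-k log-likelihood/parameter-count/BIC table, the selected
#' k and the selected model's parameters.
#'
#' @param model a \code{FittedTrajectoryModel} from \code{\link{selectModel}}.
#' @param path output path.
#' @export
writeModelReport <- function(model, path) {
    rep <- list(
        selectedK = model@spec@k,
        orders = model@spec@orders,
        useCovariates = model@spec@useCovariates,
        covariateSharing = model@spec@covariateSharing,
        pi = model@pi, sigma = model@sigma,
        beta = model@beta,
        gamma = model@gamma,
        loglik = model@loglik, nParams = model@nParams, bic = model@bic,
        converged = model@converged,
        perK = if (length(model@selection)) model@selection$summary else NULL)
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}
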