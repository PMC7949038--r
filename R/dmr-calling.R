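# DMC/DMR calling from per-CpG calls, following the published definition:
# all-sample >=5x coverage filter; a DMC is a CpG whose group-mean
# methylation changes by >= 30 percentage points; a DMR is a chain of >= 3
# consecutive same-direction DMCs with inter-DMC distance <= 50 bp passing a
# two-sided Mann-Whitney U test at p < 0.05. Thresholds mirror the printed
# comparisons exactly: |diff| >= delta is inclusive, p < 0.05 is strict.

#' Caller thresholds
#'
#' @param minCoverage minimum sequencing depth required in every sample for a
#'   CpG to enter the analysis (default 5)
#' @param deltaThreshold minimum absolute group-mean methylation difference,
#'   as a fraction, for a DMC (default 0.30; the comparison is inclusive)
#' @param maxGap maximal base-pair distance between consecutive DMCs inside
#'   one region (default 50)
#' @param minCpgs minimum number of member DMCs per region (default 3)
#' @param pThreshold strict upper bound on the regional Mann-Whitney U
#'   p-value (default 0.05)
#' @param mwuValues what the regional test compares: \code{"pooled"}
#'   (default) pools every sample's per-CpG fraction over the candidate's
#'   member CpGs, giving nCpGs x nSamples values per group; with
#'   \code{"group_means"} each side contributes its per-CpG group-mean vector
#'   (nCpGs values per side). Pooling is the default because an exact
#'   two-sided rank test on two 3-vectors can never reach p < 0.05
#'   (minimum 2/20 = 0.1), which would silently outlaw 3-CpG regions.
#' @param strictConsecutive if \code{TRUE}, a retained non-DMC CpG between
#'   two DMCs breaks a chain; by default only distance and direction break
#'   chains, since the definition constrains inter-DMC distance only
#' @return a validated named list of thresholds
#' @export
callerConfig <- function(minCoverage = 5L, deltaThreshold = 0.30,
                         maxGap = 50L, minCpgs = 3L, pThreshold = 0.05,
                         mwuValues = c("pooled", "group_means"),
                         strictConsecutive = FALSE) {
    mwuValues <- match.arg(mwuValues)
    stopifnot(minCoverage >= 1, deltaThreshold > 0, deltaThreshold <= 1,
              maxGap >= 0, minCpgs >= 1, pThreshold > 0, pThreshold <= 1)
    list(minCoverage = as.integer(minCoverage),
         deltaThreshold = deltaThreshold, maxGap = as.integer(maxGap),
         minCpgs = as.integer(minCpgs), pThreshold = pThreshold,
         mwuValues = mwuValues, strictConsecutive = isTRUE(strictConsecutive))
}

#' Build the all-sample-filtered methylation matrix
#'
#' Retains exactly those CpG sites that are present with coverage at least
#' \code{config$minCoverage} in \emph{every} sample, and assembles fraction
#' and coverage matrices ordered by (chrom, pos).
#'
#' @param samples named list of per-sample CpG \code{GRanges} (as returned by
#'   \code{\link{readMethylBedGraph}} or \code{\link{simulateSample}})
#' @param groups character vector, one group label per sample (recycled
#'   against \code{names(samples)} by position)
#' @param config a \code{\link{callerConfig}}
#' @return a \code{\linkS4class{MethylMatrix}}
#' @export
buildMethylMatrix <- function(samples, groups, config = callerConfig()) {
    stopifnot(is.list(samples), length(samples) >= 2L,
              !is.null(names(samples)), length(groups) == length(samples))
    keys <- lapply(samples, function(gr) {
        cov <- cpgCoverage(gr)
        paste0(as.character(seqnames(gr)), ":", start(gr))[cov >= config$minCoverage]
    })
    common <- Reduce(intersect, keys)
    if (!length(common))
        stop("no analyzable CpGs: no site reaches ", config$minCoverage,
             "x coverage in all ", length(samples), " samples", call. = FALSE)
    ref <- samples[[1L]]
    refkey <- paste0(as.character(seqnames(ref)), ":", start(ref))
    rows <- .sortByChromPos(granges(ref[match(common, refkey)]))
    rowkey <- paste0(as.character(seqnames(rows)), ":", start(rows))
    frac <- cov <- matrix(0, nrow = length(rows), ncol = length(samples),
                          dimnames = list(NULL, names(samples)))
    for (j in seq_along(samples)) {
        gr <- samples[[j]]
        i <- match(rowkey, paste0(as.character(seqnames(gr)), ":", start(gr)))
        cv <- cpgCoverage(gr)[i]
        cov[, j] <- cv
        frac[, j] <- mcols(gr)$meth[i] / cv
    }
    se <- SummarizedExperiment(
        assays = list(fraction = frac, coverage = cov), rowRanges = rows,
        colData = DataFrame(sample = names(samples), group = groups,
                            row.names = names(samples)))
    S4Vectors::metadata(se)$minCoverage <- config$minCoverage
    new("MethylMatrix", se)
}

.groupCols <- function(x, group) {
    grp <- sampleGroups(x)
    if (length(group) == 1L && group %in% grp) {
        which(grp == group)
    } else {
        i <- match(group, colnames(x))
        if (anyNA(i)) stop("unknown sample or group: ",
                           paste(group[is.na(i)], collapse = ", "),
                           call. = FALSE)
        i
    }
}

#' Per-CpG group means
#'
#' Unweighted mean of per-sample methylation fractions within each group.
#' Groups may be given as group labels (matched against
#' \code{colData()$group}) or as vectors of sample names, and must be
#' disjoint and non-empty.
#'
#' @param x a \code{\linkS4class{MethylMatrix}}
#' @param groupA,groupB group label or sample names of the control (A) and
#'   tumor (B) side
#' @return a two-column matrix \code{cbind(meanA, meanB)}, one row per CpG
#' @export
groupMeans <- function(x, groupA, groupB) {
    ia <- .groupCols(x, groupA)
    ib <- .groupCols(x, groupB)
    if (!length(ia) || !length(ib)) stop("empty group", call. = FALSE)
    if (length(intersect(ia, ib))) stop("groups must be disjoint", call. = FALSE)
    fr <- methFraction(x)
    cbind(meanA = rowMeans(fr[, ia, drop = FALSE]),
          meanB = rowMeans(fr[, ib, drop = FALSE]))
}

#' Call differentially methylated cytosines
#'
#' A CpG is a DMC iff the absolute difference between the two group means is
#' at least \code{deltaThreshold} (inclusive, mirroring the printed
#' ">= 30\%"). Direction is the sign of \code{meanB - meanA}: negative means
#' hypomethylated in the tumor group B.
#'
#' @inheritParams groupMeans
#' @param config a \code{\link{callerConfig}}
#' @return a width-1 \code{GRanges} with metadata columns \code{meanA},
#'   \code{meanB}, \code{diff}, \code{direction} and the row index
#'   \code{row} into \code{x}
#' @export
callDMCs <- function(x, groupA, groupB, config = callerConfig()) {
    gm <- groupMeans(x, groupA, groupB)
    d <- gm[, "meanB"] - gm[, "meanA"]
    keep <- which(abs(d) >= config$deltaThreshold - 1e-12)
    out <- granges(rowRanges(x))[keep]
    mcols(out) <- DataFrame(meanA = gm[keep, "meanA"],
                            meanB = gm[keep, "meanB"], diff = d[keep],
                            direction = ifelse(d[keep] < 0, "hypo", "hyper"),
                            row = keep)
    out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation enumeration (over all \code{choose(nA+nB, nA)} group
#' reassignments, with midranks so ties are handled exactly) when the pooled
#' size is at most \code{exactMax}; otherwise the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction. A pooled sample
#' with all values identical gives p = 1.
#'
#' @param a,b numeric vectors of the two groups (non-empty)
#' @param exactMax largest pooled size for the exact path (default 12)
#' @return the two-sided p-value
#' @export
mwuTest <- function(a, b, exactMax = 12L) {
    na <- length(a); nb <- length(b)
    if (na < 1L || nb < 1L) stop("both groups must be non-empty", call. = FALSE)
    pooled <- c(a, b)
    if (max(pooled) == min(pooled)) return(1)
    r <- rank(pooled)
    mu <- na * nb / 2
    uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    n <- na + nb
    if (n <= exactMax) {
        idx <- utils::combn(n, na)
        ra <- colSums(matrix(r[idx], nrow = na))
        dev <- abs(ra - na * (na + 1) / 2 - mu)
        # ranks are multiples of 1/2, so deviations are exact halves; the
        # epsilon only guards against decimal round-off in exotic inputs
        p <- mean(dev >= abs(uObs - mu) - 1e-9)
    } else {
        tie <- table(r)
        sigma2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
        if (sigma2 <= 0) return(1)
        z <- max(0, (abs(uObs - mu) - 0.5)) / sqrt(sigma2)
        p <- 2 * stats::pnorm(-z)
    }
    min(p, 1)
}

#' Call differentially methylated regions
#'
#' Greedy left-to-right chaining of the sorted DMCs: a chain extends while
#' the next DMC sits on the same chromosome, has the same direction, and
#' lies within \code{maxGap} bp of the previous member. Retained non-DMC
#' CpGs never break a chain unless \code{strictConsecutive} is set. A
#' maximal chain with at least \code{minCpgs} members becomes a candidate
#' and is kept iff the regional Mann-Whitney U p-value is strictly below
#' \code{pThreshold}. No multiple-testing correction is applied, matching
#' the published procedure.
#'
#' @inheritParams callDMCs
#' @param dmcs optional precomputed result of \code{\link{callDMCs}} on the
#'   same matrix and groups
#' @return a \code{GRanges} spanning first to last member CpG per region,
#'   with metadata columns \code{nCpgs}, \code{direction}, \code{meanDiff}
#'   and \code{pMWU}
#' @export
callDMRs <- function(x, groupA, groupB, config = callerConfig(),
                     dmcs = NULL) {
    if (is.null(dmcs)) dmcs <- callDMCs(x, groupA, groupB, config)
    if (!length(dmcs)) return(.emptyDMRs())
    o <- order(match(as.character(seqnames(dmcs)),
                     unique(as.character(seqnames(dmcs)))), start(dmcs))
    dmcs <- dmcs[o]
    chrom <- as.character(seqnames(dmcs))
    pos <- start(dmcs)
    dir <- mcols(dmcs)$direction
    newChain <- c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                        dir[-1L] != dir[-length(dir)] |
                        diff(pos) > config$maxGap)
    if (config$strictConsecutive && length(dmcs) > 1L) {
        allPos <- start(rowRanges(x))
        allChrom <- as.character(seqnames(rowRanges(x)))
        interven <- vapply(seq_len(length(dmcs) - 1L), function(i) {
            if (chrom[i] != chrom[i + 1L]) return(FALSE)
            any(allChrom == chrom[i] & allPos > pos[i] & allPos < pos[i + 1L] &
                !(allPos %in% pos[chrom == chrom[i]]))
        }, logical(1L))
        newChain[-1L] <- newChain[-1L] | interven
    }
    chainId <- cumsum(newChain)
    ia <- .groupCols(x, groupA)
    ib <- .groupCols(x, groupB)
    fr <- methFraction(x)
    out <- lapply(split(seq_along(dmcs), chainId), function(i) {
        if (length(i) < config$minCpgs) return(NULL)
        rows <- mcols(dmcs)$row[i]
        if (config$mwuValues == "pooled") {
            va <- as.vector(fr[rows, ia, drop = FALSE])
            vb <- as.vector(fr[rows, ib, drop = FALSE])
        } else {
            va <- mcols(dmcs)$meanA[i]
            vb <- mcols(dmcs)$meanB[i]
        }
        p <- mwuTest(va, vb)
        if (p >= config$pThreshold) return(NULL)
        GRanges(chrom[i[1L]], IRanges(pos[i[1L]], pos[i[length(i)]]),
                nCpgs = length(i), direction = dir[i[1L]],
                meanDiff = mean(mcols(dmcs)$diff[i]), pMWU = p)
    })
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out)) return(.emptyDMRs())
    res <- do.call(c, unname(out))
    validateIntervals(res)
    res
}

.emptyDMRs <- function() {
    GRanges(nCpgs = integer(), direction = character(),
            meanDiff = numeric(), pMWU = numeric())
}

#' Write and read DMR BED6+ files
#'
#' Columns: chrom, start, end, name, \code{int(1000 * |meanDiff|)} score,
#' \code{.} strand, then \code{nCpgs}, \code{meanDiff}, \code{pMWU},
#' \code{direction}.
#'
#' @param x a DMR \code{GRanges} from \code{\link{callDMRs}}
#' @param path file path
#' @export
writeDmrBed <- function(x, path) {
    nm <- sprintf("dmr_%d", seq_along(x))
    mcols(x)$name <- nm
    mcols(x)$score <- as.integer(round(1000 * abs(mcols(x)$meanDiff)))
    writeBedFile(x, path,
                 extraCols = data.frame(nCpgs = mcols(x)$nCpgs,
                                        meanDiff = mcols(x)$meanDiff,
                                        pMWU = mcols(x)$pMWU,
                                        direction = mcols(x)$direction))
    invisible(path)
}

#' @rdname writeDmrBed
#' @export
readDmrBed <- function(path) {
    dat <- .readLinesData(path)
    if (!length(dat$lines)) return(.emptyDMRs())
    fields <- strsplit(dat$lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 10L))
        stop("DMR BED needs 10 columns", call. = FALSE)
    m <- matrix(unlist(fields), ncol = lengths(fields)[1L], byrow = TRUE)
    GRanges(m[, 1L], IRanges(as.integer(m[, 2L]) + 1L, as.integer(m[, 3L])),
            nCpgs = as.integer(m[, 7L]), direction = m[, 10L],
            meanDiff = as.numeric(m[, 8L]), pMWU = as.numeric(m[, 9L]))
}
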