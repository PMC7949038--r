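# Metagene signal profiling: region bodies rescaled to a common length by
# boundary interpolation with coverage-weighted means (the mean of the
# per-base signal over each fractionally mapped span), unscaled flanks, and
# unscaled strand-oriented TSS windows; per-bin mean +/- SEM across regions
# and Student/Welch comparisons between region groups.

.chromSignal <- function(track, chrom) {
    if (chrom %in% names(track)) as.numeric(track[[chrom]]) else numeric(0)
}

# mean signal over the continuous 0-based span [a, b) of x (per-base
# values), fractional ends weighted by the covered fraction; positions
# outside x count as zero signal
.spanMean <- function(cs, len, a, b) {
    if (b <= a) return(0)
    integ <- function(t) {
        t <- min(max(t, 0), len)
        f <- floor(t)
        v <- cs[f + 1L]
        if (t > f) v <- v + (t - f) * (cs[f + 2L] - cs[f + 1L])
        v
    }
    (integ(b) - integ(a)) / (b - a)
}

.regionBins <- function(x, s0, e0, nBody, binSize, flank) {
    len <- length(x)
    cs <- c(0, cumsum(x))
    nFlank <- as.integer(flank / binSize)
    up <- vapply(seq_len(nFlank), function(j)
        .spanMean(cs, len, s0 - flank + (j - 1L) * binSize,
                  s0 - flank + j * binSize), 0)
    w <- (e0 - s0) / nBody
    body <- vapply(seq_len(nBody), function(j)
        .spanMean(cs, len, s0 + (j - 1L) * w, s0 + j * w), 0)
    down <- vapply(seq_len(nFlank), function(j)
        .spanMean(cs, len, e0 + (j - 1L) * binSize, e0 + j * binSize), 0)
    c(up, body, down)
}

#' Length-scaled region profile with unscaled flanks
#'
#' Each region body is rescaled to \code{targetLength} bp divided into
#' \code{targetLength / binSize} bins: bin boundaries are mapped linearly
#' onto the native region and each bin takes the coverage-weighted mean of
#' the per-base signal over its mapped span, so regions shorter than the
#' bin count are handled by fractional mapping rather than erroring.
#' Flanking \code{flank} bp on both sides are binned natively at
#' \code{binSize}. Regions are treated as unstranded. Positions without
#' track coverage contribute zero signal.
#'
#' @param regions a \code{GRanges}
#' @param track an \code{RleList} of per-base signal (e.g. from
#'   \code{\link{readSignalBedGraph}} or \code{\link{simulateSignalTrack}})
#' @param targetLength common body length in bp (default 200)
#' @param binSize bin width in bp (default 10)
#' @param flank unscaled flank width in bp on each side (default 100)
#' @return a \code{\linkS4class{ProfileMatrix}} with
#'   \code{2 * flank/binSize + targetLength/binSize} bins
#' @export
scaledRegionProfile <- function(regions, track, targetLength = 200L,
                                binSize = 10L, flank = 100L) {
    stopifnot(length(regions) >= 1L, targetLength %% binSize == 0,
              flank %% binSize == 0)
    validateIntervals(regions)
    nBody <- as.integer(targetLength / binSize)
    nFlank <- as.integer(flank / binSize)
    chroms <- as.character(seqnames(regions))
    sigCache <- new.env(parent = emptyenv())
    mat <- t(vapply(seq_along(regions), function(i) {
        ch <- chroms[i]
        if (is.null(sigCache[[ch]])) sigCache[[ch]] <- .chromSignal(track, ch)
        .regionBins(sigCache[[ch]], start(regions)[i] - 1L, end(regions)[i],
                    nBody, binSize, flank)
    }, numeric(nBody + 2L * nFlank)))
    bins <- c(sprintf("u%02d", seq_len(nFlank)),
              sprintf("b%02d", seq_len(nBody)),
              sprintf("d%02d", seq_len(nFlank)))
    newProfileMatrix(mat, bins)
}

#' Unscaled TSS-centered profiles per gene group
#'
#' Fixed-width window \code{[tss - halfWindow, tss + halfWindow)} oriented
#' 5' to 3' (minus-strand windows are reversed), binned at \code{binSize}.
#' Windows running off the chromosome start are zero-padded and flagged in
#' the \code{"padded"} attribute of each profile.
#'
#' @param genes gene table data.frame; when it has a non-NA \code{group}
#'   column one profile per group is returned, otherwise a single profile
#'   named \code{all}
#' @param track an \code{RleList} of per-base signal
#' @param halfWindow half window width in bp (default 2000)
#' @param binSize bin width in bp (default 10)
#' @return a named list of \code{\linkS4class{ProfileMatrix}} objects
#' @export
tssProfile <- function(genes, track, halfWindow = 2000L, binSize = 10L) {
    stopifnot(halfWindow %% binSize == 0,
              all(genes$strand %in% c("+", "-")))
    groups <- if ("group" %in% colnames(genes) && any(!is.na(genes$group)))
        split(seq_len(nrow(genes)), genes$group)
    else list(all = seq_len(nrow(genes)))
    nBins <- as.integer(2L * halfWindow / binSize)
    lapply(groups, function(idx) {
        if (!length(idx)) stop("no regions in gene group", call. = FALSE)
        padded <- logical(length(idx))
        mat <- t(vapply(seq_along(idx), function(k) {
            g <- genes[idx[k], ]
            x <- .chromSignal(track, g$chrom)
            cs <- c(0, cumsum(x))
            a <- g$tss - halfWindow
            if (a < 0) padded[k] <<- TRUE
            v <- vapply(seq_len(nBins), function(j)
                .spanMean(cs, length(x), a + (j - 1L) * binSize,
                          a + j * binSize), 0)
            if (g$strand == "-") rev(v) else v
        }, numeric(nBins)))
        offs <- seq(-halfWindow, halfWindow - binSize, by = binSize)
        pm <- newProfileMatrix(mat, sprintf("%+d", offs))
        attr(pm, "padded") <- padded
        pm
    })
}

.binTest <- function(va, vb, varEqual) {
    if (stats::sd(c(va, vb)) == 0 ||
        (stats::sd(va) == 0 && stats::sd(vb) == 0))
        return(if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0)
    tryCatch(stats::t.test(va, vb, var.equal = varEqual)$p.value,
             error = function(e) 1)
}

#' Compare two profile matrices
#'
#' Two-sided t-test (Student's equal-variance or Welch's) per bin on the
#' per-region values, plus a whole-region test on per-region mean signal.
#' Degenerate bins where both groups are constant give p = 1 when the
#' means agree and p = 0 otherwise.
#'
#' @param a,b \code{\linkS4class{ProfileMatrix}} objects with identical
#'   binning and at least two regions each
#' @param test \code{"student"} (default) or \code{"welch"}
#' @param alpha significance flag threshold (default 0.05)
#' @return list with \code{perBin} (data.frame bin, p, significant) and
#'   \code{regionMean} (list p, significant)
#' @export
compareProfiles <- function(a, b, test = c("student", "welch"),
                            alpha = 0.05) {
    test <- match.arg(test)
    stopifnot(is(a, "ProfileMatrix"), is(b, "ProfileMatrix"),
              identical(profileBins(a), profileBins(b)))
    ma <- profileMatrix(a); mb <- profileMatrix(b)
    if (nrow(ma) < 2L || nrow(mb) < 2L)
        stop("need at least 2 regions per group", call. = FALSE)
    varEqual <- test == "student"
    pBin <- vapply(seq_len(ncol(ma)), function(j)
        .binTest(ma[, j], mb[, j], varEqual), 0)
    pRegion <- .binTest(rowMeans(ma), rowMeans(mb), varEqual)
    list(perBin = data.frame(bin = profileBins(a), p = pBin,
                             significant = pBin < alpha,
                             stringsAsFactors = FALSE),
         regionMean = list(p = pRegion, significant = pRegion < alpha))
}
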