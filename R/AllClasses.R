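#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- Rle runValue queryHits subjectHits
#' @importFrom IRanges IRanges RleList CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#'   pintersect reduce granges sort GRangesList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowRanges
NULL

#' CpGs-by-samples methylation container
#'
#' A \code{MethylMatrix} holds, for the CpG sites that pass the all-sample
#' minimum-coverage filter, a \code{fraction} assay (methylated reads /
#' coverage, in \code{[0, 1]}) and a \code{coverage} assay (total reads),
#' with one column per sample. Sample-to-group assignment lives in
#' \code{colData()$group}. It extends
#' \linkS4class{RangedSummarizedExperiment}, so all the usual subsetting,
#' \code{rowRanges()} and \code{assay()} machinery applies.
#'
#' Use \code{\link{buildMethylMatrix}} to construct one from per-sample CpG
#' call tracks; direct construction is not supported.
#'
#' @seealso \code{\link{buildMethylMatrix}}, \code{\link{callDMCs}},
#'   \code{\link{callDMRs}}
#' @export
setClass("MethylMatrix", contains = "RangedSummarizedExperiment")

setValidity("MethylMatrix", function(object) {
    msg <- character()
    an <- names(SummarizedExperiment::assays(object))
    if (!all(c("fraction", "coverage") %in% an))
        msg <- c(msg, "assays must include 'fraction' and 'coverage'")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must carry a 'group' column")
    if ("fraction" %in% an) {
        fr <- SummarizedExperiment::assay(object, "fraction")
        if (length(fr) && (anyNA(fr) || min(fr) < 0 || max(fr) > 1))
            msg <- c(msg, "fractions must lie in [0, 1] and contain no NA")
    }
    if (all(c("fraction", "coverage") %in% an)) {
        cov <- SummarizedExperiment::assay(object, "coverage")
        if (length(cov) && min(cov) < 1)
            msg <- c(msg, "every retained CpG needs coverage >= 1 in every sample")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MethylMatrix-class compact display of dimensions and groups
#' @param object a \code{MethylMatrix}
#' @export
setMethod("show", "MethylMatrix", function(object) {
    grp <- SummarizedExperiment::colData(object)$group
    cat("MethylMatrix with", nrow(object), "CpGs x", ncol(object), "samples\n")
    cat("groups:", paste(sprintf("%s(%d)", names(table(grp)), table(grp)),
                         collapse = ", "), "\n")
    mc <- S4Vectors::metadata(object)$minCoverage
    if (!is.null(mc)) cat("all-sample minimum coverage:", mc, "x\n")
})

#' Binned signal profile over a region set
#'
#' Holds a regions-by-bins matrix of mean per-base signal together with bin
#' labels and a per-bin summary (mean and standard error of the mean across
#' regions, SEM = sd/sqrt(n) with the n-1 sd). Produced by
#' \code{\link{scaledRegionProfile}} and \code{\link{tssProfile}}.
#'
#' @slot profile numeric matrix, one row per region, one column per bin
#' @slot bins character vector of bin labels
#' @slot summary data.frame with columns \code{bin}, \code{mean}, \code{sem}
#' @export
setClass("ProfileMatrix",
    representation(profile = "matrix", bins = "character",
                   summary = "data.frame"))

setValidity("ProfileMatrix", function(object) {
    msg <- character()
    if (ncol(object@profile) != length(object@bins))
        msg <- c(msg, "bin labels must match profile columns")
    if (nrow(object@summary) != length(object@bins))
        msg <- c(msg, "summary must have one row per bin")
    if (length(object@profile) && any(!is.finite(object@profile)))
        msg <- c(msg, "profile values must be finite")
    if (length(msg)) msg else TRUE
})

#' @describeIn ProfileMatrix-class compact display
#' @param object a \code{ProfileMatrix}
#' @export
setMethod("show", "ProfileMatrix", function(object) {
    cat("ProfileMatrix:", nrow(object@profile), "regions x",
        length(object@bins), "bins\n")
    rng <- range(object@summary$mean)
    cat(sprintf("per-bin mean signal in [%.4g, %.4g]\n", rng[1], rng[2]))
})

#' @describeIn ProfileMatrix-class the regions-by-bins matrix
#' @param x a \code{ProfileMatrix}
#' @export
profileMatrix <- function(x) {
    stopifnot(is(x, "ProfileMatrix"))
    x@profile
}

#' @describeIn ProfileMatrix-class bin labels
#' @export
profileBins <- function(x) {
    stopifnot(is(x, "ProfileMatrix"))
    x@bins
}

#' @describeIn ProfileMatrix-class per-bin mean and SEM across regions
#' @export
profileSummary <- function(x) {
    stopifnot(is(x, "ProfileMatrix"))
    x@summary
}

newProfileMatrix <- function(mat, bins) {
    n <- nrow(mat)
    sem <- if (n > 1) apply(mat, 2, stats::sd) / sqrt(n) else rep(0, ncol(mat))
    new("ProfileMatrix", profile = mat, bins = bins,
        summary = data.frame(bin = bins, mean = colMeans(mat), sem = sem,
                             stringsAsFactors = FALSE))
}

#' Methylation fraction and coverage accessors
#'
#' @param x a \code{MethylMatrix}
#' @return \code{methFraction} and \code{methCoverage} return the
#'   CpGs-by-samples numeric/integer matrix; \code{sampleGroups} the named
#'   group factor per sample.
#' @export
methFraction <- function(x) {
    stopifnot(is(x, "MethylMatrix"))
    SummarizedExperiment::assay(x, "fraction")
}

#' @rdname methFraction
#' @export
methCoverage <- function(x) {
    stopifnot(is(x, "MethylMatrix"))
    SummarizedExperiment::assay(x, "coverage")
}

#' @rdname methFraction
#' @export
sampleGroups <- function(x) {
    stopifnot(is(x, "MethylMatrix"))
    stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                    colnames(x))
}
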