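# Truth-table scoring of a synthetic run: which planted regions were
# recovered by the caller and whether the genotype set logic reproduced the
# planted categories. Matching is by >= 1 bp overlap with the truth
# interval and agreeing direction (the same rule used across comparisons).

.regionAffects <- function(regions, genotype) {
    vapply(strsplit(mcols(regions)$genotypes, ",", fixed = TRUE),
           function(g) genotype %in% g, logical(1L))
}

.truthDirection <- function(regions) {
    ifelse(mcols(regions)$delta < 0, "hypo", "hyper")
}

#' Score DMR calls against the planted truth
#'
#' Callable truth regions for a genotype are the planted regions that
#' affect it with a nonzero shift and at least 3 CpGs. Sensitivity is the
#' fraction of those overlapped (>= 1 bp, same direction) by a called DMR;
#' the false-positive fraction is the share of called DMRs overlapping no
#' truth region of that genotype.
#'
#' @param dmrs called DMR \code{GRanges} for one tumor-versus-control
#'   comparison
#' @param truth a \code{MethylTruth}
#' @param genotype the tumor genotype of the comparison
#' @return list: \code{sensitivity}, \code{fpFraction}, \code{nTruth},
#'   \code{nCalled}, \code{recovered} (logical per truth region)
#' @export
dmrRecovery <- function(dmrs, truth, genotype) {
    stopifnot(inherits(truth, "MethylTruth"))
    regions <- truth$regions
    callable <- regions[.regionAffects(regions, genotype) &
                        abs(mcols(regions)$delta) > 0 &
                        mcols(regions)$nCpgs >= 3L]
    mcols(callable)$direction <- .truthDirection(callable)
    recovered <- if (length(callable) && length(dmrs))
        seq_along(callable) %in%
            queryHits(matchDMRs(callable, dmrs, sameDirection = TRUE))
    else rep(FALSE, length(callable))
    falsePos <- if (length(dmrs))
        !seq_along(dmrs) %in%
            queryHits(matchDMRs(dmrs, callable, sameDirection = TRUE))
    else logical(0)
    list(sensitivity = if (length(callable)) mean(recovered) else NA_real_,
         fpFraction = if (length(dmrs)) mean(falsePos) else 0,
         nTruth = length(callable), nCalled = length(dmrs),
         recovered = recovered)
}

#' Score the genotype set logic against the planted categories
#'
#' For each planted \code{af_target} / \code{ca_target} region the label is
#' recovered when a classified DMR with the true mechanism and direction
#' overlaps it; a \code{transformation} region is recovered when it was
#' removed by the transformation filter (matched in the removed set of any
#' genotype, same direction).
#'
#' @param classified output of \code{\link{classifyComparisons}}
#' @param truth a \code{MethylTruth}
#' @return data.frame with columns \code{category}, \code{n},
#'   \code{recovered}, \code{rate}
#' @export
setLogicRecovery <- function(classified, truth) {
    stopifnot(inherits(truth, "MethylTruth"))
    regions <- truth$regions
    scoreCat <- function(cat) {
        tr <- regions[mcols(regions)$category == cat]
        if (!length(tr))
            return(data.frame(category = cat, n = 0L, recovered = 0L,
                              rate = NA_real_, stringsAsFactors = FALSE))
        mcols(tr)$direction <- .truthDirection(tr)
        hit <- if (cat == "transformation") {
            rem <- do.call(c, unname(classified$removed))
            seq_along(tr) %in%
                queryHits(matchDMRs(tr, rem, sameDirection = TRUE))
        } else {
            lab <- classified$labels
            lab <- lab[mcols(lab)$mechanism == cat]
            seq_along(tr) %in%
                queryHits(matchDMRs(tr, lab, sameDirection = TRUE))
        }
        data.frame(category = cat, n = length(tr), recovered = sum(hit),
                   rate = mean(hit), stringsAsFactors = FALSE)
    }
    do.call(rbind, lapply(c("af_target", "ca_target", "transformation"),
                          scoreCat))
}

#' Score gene-group assignment against the planted tags
#'
#' @param assigned output of \code{\link{assignGroups}}
#' @param truth a \code{MethylTruth}
#' @param genotype tumor genotype whose comparison fed the assignment; only
#'   planted genes whose region affects this genotype are expected
#' @return list: \code{rate} (fraction of expected genes assigned their
#'   true group), \code{n} expected, \code{correct}
#' @export
gGroupRecovery <- function(assigned, truth, genotype) {
    stopifnot(inherits(truth, "MethylTruth"))
    regions <- truth$regions
    exp <- regions[!is.na(mcols(regions)$gene_id) &
                   .regionAffects(regions, genotype) &
                   mcols(regions)$delta < 0]
    expected <- data.frame(gene_id = mcols(exp)$gene_id,
                           group = mcols(exp)$gene_group,
                           stringsAsFactors = FALSE)
    got <- assigned$group[match(expected$gene_id, assigned$gene_id)]
    correct <- !is.na(got) & got == expected$group
    list(rate = if (nrow(expected)) mean(correct) else NA_real_,
         n = nrow(expected), correct = sum(correct))
}

#' Percentage of a count relative to a total
#'
#' The single-division summary used throughout count reporting, e.g. the
#' share of analyzable CpGs that are hypomethylated DMCs, or the share of
#' knockout-hypomethylated regions attributable to accessory function.
#'
#' @param count numerator
#' @param total denominator (> 0)
#' @return \code{100 * count / total}
#' @export
percentOf <- function(count, total) {
    stopifnot(total > 0)
    100 * count / total
}
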