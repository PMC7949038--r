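# Comparative set logic across genotype contrasts. Two DMRs from different
# comparisons are "the same region" when their intervals overlap by at
# least one bp on the same chromosome with the same direction (the
# bedtools-intersect default; no overlap fraction is imposed unless
# requested). On top of that matching rule sit: the specific/overlapping
# partition of two DMR sets, the transformation filter (regions shifted in
# every tumor genotype are attributed to transformation, not to the
# methyltransferase), and the catalytic-activity (CA) versus
# accessory-function (AF) target classification across the WT / KO / CI
# tumor trio.

#' Match DMRs across two comparisons
#'
#' A pair matches when the intervals overlap by at least one bp on the same
#' chromosome (half-open abutment is not an overlap) and, when
#' \code{sameDirection}, the directions agree. One DMR may participate in
#' several pairs; "present in both sets" means participating in at least
#' one pair. \code{reciprocalFrac} optionally requires the overlap to cover
#' that fraction of both intervals.
#'
#' @param a,b DMR \code{GRanges} with a \code{direction} metadata column
#' @param sameDirection require equal direction (default TRUE)
#' @param reciprocalFrac optional reciprocal overlap fraction in (0, 1]
#' @return a \code{Hits} object from \code{a} to \code{b}
#' @export
matchDMRs <- function(a, b, sameDirection = TRUE, reciprocalFrac = NULL) {
    hits <- findOverlaps(a, b, ignore.strand = TRUE)
    keep <- rep(TRUE, length(hits))
    if (sameDirection && length(hits))
        keep <- mcols(a)$direction[queryHits(hits)] ==
                mcols(b)$direction[subjectHits(hits)]
    if (!is.null(reciprocalFrac) && length(hits)) {
        ov <- width(pintersect(a[queryHits(hits)], b[subjectHits(hits)],
                               ignore.strand = TRUE))
        keep <- keep & ov >= reciprocalFrac * width(a)[queryHits(hits)] &
                       ov >= reciprocalFrac * width(b)[subjectHits(hits)]
    }
    hits[keep]
}

#' Partition two DMR sets into specific and overlapping regions
#'
#' Per direction: DMRs of A matched in B are \code{overlapping} (counted on
#' A's units), unmatched A DMRs are \code{specific_A}, unmatched B DMRs
#' \code{specific_B}. Both comparisons must share the same control for the
#' partition to be meaningful.
#'
#' @inheritParams matchDMRs
#' @return a list with \code{labelsA}, \code{labelsB} (character per DMR)
#'   and \code{counts} (data.frame direction x label)
#' @export
partitionSpecificOverlapping <- function(a, b) {
    hits <- matchDMRs(a, b, sameDirection = TRUE)
    labA <- ifelse(seq_along(a) %in% queryHits(hits), "overlapping",
                   "specific_A")
    labB <- ifelse(seq_along(b) %in% subjectHits(hits), "overlapping",
                   "specific_B")
    counts <- do.call(rbind, lapply(c("hypo", "hyper"), function(d) {
        ia <- mcols(a)$direction == d
        ib <- mcols(b)$direction == d
        data.frame(direction = d,
                   specific_A = sum(labA == "specific_A" & ia),
                   specific_B = sum(labB == "specific_B" & ib),
                   overlapping = sum(labA == "overlapping" & ia),
                   stringsAsFactors = FALSE)
    }))
    list(labelsA = labA, labelsB = labB, counts = counts)
}

.checkTrio <- function(results) {
    need <- c("WT", "KO", "CI")
    if (!all(need %in% names(results)))
        stop("need one comparison per genotype: ",
             paste(setdiff(need, names(results)), collapse = ", "),
             " missing", call. = FALSE)
    results[need]
}

# membership profile of each DMR of `own` across the three genotype lists
.membership <- function(own, results) {
    vapply(names(results), function(g) {
        if (identical(results[[g]], own)) rep(TRUE, length(own))
        else seq_along(own) %in%
            queryHits(matchDMRs(own, results[[g]], sameDirection = TRUE))
    }, logical(length(own)))
}

#' Filter out transformation-associated DMRs
#'
#' DMRs matched (same direction, >= 1 bp) across \emph{all three}
#' tumor-versus-control comparisons are attributed to transformation
#' rather than to the methyltransferase genotype, labeled
#' \code{transformation}, and removed from every genotype's list before
#' CA/AF classification.
#'
#' @param results named list of DMR \code{GRanges}, names \code{WT},
#'   \code{KO}, \code{CI}
#' @return a list with \code{filtered} (same shape, transformation DMRs
#'   removed) and \code{removed} (named list of the removed DMRs)
#' @export
transformationFilter <- function(results) {
    results <- .checkTrio(results)
    inAll <- lapply(names(results), function(g) {
        own <- results[[g]]
        if (!length(own)) return(logical(0))
        m <- .membership(own, results)
        m <- matrix(m, ncol = length(results),
                    dimnames = list(NULL, names(results)))
        rowSums(m) == ncol(m)
    })
    names(inAll) <- names(results)
    list(filtered = lapply(names(results), function(g)
             results[[g]][!inAll[[g]]]) |> stats::setNames(names(results)),
         removed = lapply(names(results), function(g)
             results[[g]][inAll[[g]]]) |> stats::setNames(names(results)))
}

#' Classify DMRs into catalytic versus accessory-function targets
#'
#' Applied after \code{\link{transformationFilter}}. Using each DMR's
#' membership profile across the three tumor-versus-control lists:
#' hypomethylated DMRs present only in KO (full knockout) are putative
#' accessory-function (AF) targets; present in both KO and CI
#' (catalytically inactive, AF retained) are putative catalytic-activity
#' (CA) targets. Hypermethylated DMRs present in CI but not KO are AF
#' targets; present only in WT are CA targets. Everything else is
#' \code{unassigned}. Every DMR entering the classifier receives exactly
#' one label.
#'
#' @param filtered named list (\code{WT}, \code{KO}, \code{CI}) of DMR
#'   \code{GRanges} with transformation DMRs already removed
#' @return a list with \code{labels} (one \code{GRanges} concatenating all
#'   units, metadata \code{source} genotype, \code{direction},
#'   \code{mechanism}) and \code{summary} (counts per label and direction
#'   on the reference units: KO for hypomethylated classes, CI for
#'   hypermethylated AF, WT for hypermethylated CA)
#' @export
classifyCAAF <- function(filtered) {
    filtered <- .checkTrio(filtered)
    labeled <- lapply(names(filtered), function(g) {
        own <- filtered[[g]]
        if (!length(own)) {
            mcols(own)$source <- character()
            mcols(own)$mechanism <- character()
            return(own)
        }
        m <- matrix(.membership(own, filtered), ncol = length(filtered),
                    dimnames = list(NULL, names(filtered)))
        dir <- mcols(own)$direction
        mech <- rep("unassigned", length(own))
        hypo <- dir == "hypo"
        mech[hypo & m[, "KO"] & !m[, "CI"] & !m[, "WT"]] <- "af_target"
        mech[hypo & m[, "KO"] & m[, "CI"]] <- "ca_target"
        hyper <- dir == "hyper"
        mech[hyper & m[, "CI"] & !m[, "KO"]] <- "af_target"
        mech[hyper & m[, "WT"] & !m[, "KO"] & !m[, "CI"]] <- "ca_target"
        mcols(own)$source <- g
        mcols(own)$mechanism <- mech
        own
    })
    labels <- do.call(c, labeled)
    src <- mcols(labels)$source
    dir <- mcols(labels)$direction
    mech <- mcols(labels)$mechanism
    refUnit <- (dir == "hypo" & src == "KO") |
               (dir == "hyper" & mech == "af_target" & src == "CI") |
               (dir == "hyper" & mech == "ca_target" & src == "WT") |
               (dir == "hyper" & mech == "unassigned" & src == "WT")
    summary <- do.call(rbind, lapply(c("hypo", "hyper"), function(d)
        do.call(rbind, lapply(c("af_target", "ca_target", "unassigned"),
            function(lbl) data.frame(
                direction = d, mechanism = lbl,
                n = sum(refUnit & dir == d & mech == lbl),
                stringsAsFactors = FALSE)))))
    list(labels = labels, summary = summary)
}

#' Transformation filter plus CA/AF classification
#'
#' Convenience wrapper running \code{\link{transformationFilter}} then
#' \code{\link{classifyCAAF}}.
#'
#' @inheritParams transformationFilter
#' @return list with \code{filtered}, \code{removed}, \code{labels},
#'   \code{summary}
#' @export
classifyComparisons <- function(results) {
    tf <- transformationFilter(results)
    cl <- classifyCAAF(tf$filtered)
    list(filtered = tf$filtered, removed = tf$removed,
         labels = cl$labels, summary = cl$summary)
}

#' Cross-reference mechanism labels with an external comparison
#'
#' Per mechanism label and direction, counts how many labeled DMRs are
#' matched (>= 1 bp, same direction) in an external DMR set (for example a
#' spontaneous-lymphoma comparison).
#'
#' @param labels the \code{labels} \code{GRanges} from
#'   \code{\link{classifyCAAF}}
#' @param external a DMR \code{GRanges}
#' @return data.frame with columns \code{direction}, \code{mechanism},
#'   \code{n_labeled}, \code{n_matched}
#' @export
crossReference <- function(labels, external) {
    matched <- if (length(external))
        seq_along(labels) %in%
            queryHits(matchDMRs(labels, external, sameDirection = TRUE))
    else rep(FALSE, length(labels))
    do.call(rbind, lapply(c("hypo", "hyper"), function(d)
        do.call(rbind, lapply(c("af_target", "ca_target", "unassigned"),
            function(lbl) {
                sel <- mcols(labels)$direction == d &
                       mcols(labels)$mechanism == lbl
                data.frame(direction = d, mechanism = lbl,
                           n_labeled = sum(sel),
                           n_matched = sum(sel & matched),
                           stringsAsFactors = FALSE)
            }))))
}
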