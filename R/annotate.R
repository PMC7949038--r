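# Genomic-element annotation of DMRs: strand-aware promoter windows around
# the TSS and a fractional-overlap rule — a DMR is assigned to an element
# class when the class's intervals jointly cover at least half (by default)
# of the DMR's length. Assignment is multi-label: element classes are
# counted independently, with no precedence hierarchy.

#' Annotation parameters
#'
#' Promoter windows are defined around the TSS: the long promoter spans
#' 1500 bp upstream to 500 bp downstream, the core promoter 300 bp upstream
#' to 150 bp downstream. A DMR is retained for an element class when the
#' class covers at least \code{minOverlapFrac} of the DMR's length.
#'
#' @param longPromoterUp,longPromoterDown,corePromoterUp,corePromoterDown
#'   window extents in bp (all positive)
#' @param minOverlapFrac required overlap as a fraction of DMR length,
#'   in (0, 1]
#' @return a validated named list
#' @export
annotationConfig <- function(longPromoterUp = 1500L, longPromoterDown = 500L,
                             corePromoterUp = 300L, corePromoterDown = 150L,
                             minOverlapFrac = 0.5) {
    stopifnot(longPromoterUp > 0, longPromoterDown > 0, corePromoterUp > 0,
              corePromoterDown > 0, minOverlapFrac > 0, minOverlapFrac <= 1)
    list(longPromoterUp = as.integer(longPromoterUp),
         longPromoterDown = as.integer(longPromoterDown),
         corePromoterUp = as.integer(corePromoterUp),
         corePromoterDown = as.integer(corePromoterDown),
         minOverlapFrac = minOverlapFrac)
}

.promoterWindows <- function(genes, up, down) {
    tss <- genes$tss   # 0-based TSS base
    plus <- genes$strand == "+"
    # 0-based half-open: + strand [tss-up, tss+down); - strand mirrored
    # around the TSS point: [tss-down, tss+up); clipped at 0
    s0 <- ifelse(plus, tss - up, tss - down)
    e0 <- ifelse(plus, tss + down, tss + up)
    s0 <- pmax(s0, 0)
    gr <- GRanges(genes$chrom, IRanges(s0 + 1L, e0),
                  strand = genes$strand, gene_id = genes$gene_id)
    validateIntervals(gr)
}

#' Strand-aware promoter windows
#'
#' On the plus strand the window runs \code{up} bp upstream to \code{down}
#' bp downstream of the TSS; on the minus strand the window is the mirror
#' image around the TSS. Windows are clipped at the chromosome start.
#'
#' @param genes gene table data.frame (\code{gene_id}, \code{chrom},
#'   \code{tss} 0-based, \code{strand})
#' @param config an \code{\link{annotationConfig}}
#' @return a \code{GRangesList} with elements \code{long_promoter} and
#'   \code{core_promoter}, each carrying \code{gene_id}
#' @export
makePromoters <- function(genes, config = annotationConfig()) {
    stopifnot(all(genes$strand %in% c("+", "-")))
    GRangesList(
        long_promoter = .promoterWindows(genes, config$longPromoterUp,
                                         config$longPromoterDown),
        core_promoter = .promoterWindows(genes, config$corePromoterUp,
                                         config$corePromoterDown))
}

.ELEMENT_CLASSES <- c("long_promoter", "core_promoter", "exon", "intron",
                      "cgi", "enhancer", "repeat")

# union of per-class overlap bp for each query range
.unionOverlapWidth <- function(query, subject) {
    red <- reduce(granges(subject), ignore.strand = TRUE)
    hits <- findOverlaps(query, red, ignore.strand = TRUE)
    ov <- width(pintersect(query[queryHits(hits)], red[subjectHits(hits)],
                           ignore.strand = TRUE))
    out <- numeric(length(query))
    if (length(hits)) {
        agg <- tapply(ov, queryHits(hits), sum)
        out[as.integer(names(agg))] <- agg
    }
    out
}

#' Annotate DMRs with genomic element classes
#'
#' For each DMR and element class, the total overlap (union over the
#' class's intervals, so splitting an element into abutting pieces never
#' changes a decision) must reach \code{minOverlapFrac} of the DMR's
#' length. A DMR may hit several classes or none.
#'
#' @param dmrs a DMR \code{GRanges}
#' @param elementSets named list or \code{GRangesList} of element-class
#'   interval sets; names must come from the closed vocabulary
#'   \code{long_promoter, core_promoter, exon, intron, cgi, enhancer,
#'   repeat}
#' @param config an \code{\link{annotationConfig}}
#' @return \code{dmrs} with an added \code{elementHits}
#'   \code{CharacterList} metadata column
#' @export
annotateDMRs <- function(dmrs, elementSets, config = annotationConfig()) {
    stopifnot(length(names(elementSets)) == length(elementSets))
    unknown <- setdiff(names(elementSets), .ELEMENT_CLASSES)
    if (length(unknown))
        stop("unknown element class(es): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    hitList <- vector("list", length(dmrs))
    for (i in seq_along(hitList)) hitList[[i]] <- character()
    for (cls in names(elementSets)) {
        ov <- .unionOverlapWidth(dmrs, elementSets[[cls]])
        hit <- which(ov >= config$minOverlapFrac * width(dmrs) - 1e-9)
        for (i in hit) hitList[[i]] <- c(hitList[[i]], cls)
    }
    mcols(dmrs)$elementHits <- CharacterList(hitList)
    dmrs
}

#' Count annotated DMRs per element class and direction
#'
#' One DMR increments every class it hit (multi-label), split by
#' hypo/hyper direction.
#'
#' @param annotated output of \code{\link{annotateDMRs}} (must carry
#'   \code{direction} and \code{elementHits})
#' @param classes element classes to tabulate; defaults to the full
#'   vocabulary
#' @return a data.frame with one row per class and columns \code{hypo},
#'   \code{hyper}
#' @export
countByClass <- function(annotated, classes = .ELEMENT_CLASSES) {
    out <- data.frame(class = classes, hypo = 0L, hyper = 0L,
                      stringsAsFactors = FALSE)
    if (length(annotated)) {
        hits <- mcols(annotated)$elementHits
        dirs <- mcols(annotated)$direction
        for (k in seq_along(classes)) {
            has <- vapply(seq_along(annotated),
                          function(i) classes[k] %in% hits[[i]], logical(1L))
            out$hypo[k] <- sum(has & dirs == "hypo")
            out$hyper[k] <- sum(has & dirs == "hyper")
        }
    }
    out
}
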