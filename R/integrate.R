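# Promoter methylation x expression integration: genes whose long-promoter
# window carries a hypomethylated DMR (under the 50%-of-DMR-length rule)
# are split into three response groups against the expression table:
# G1 (upregulated: fold change >= 2 at p < 0.05), G2 (unchanged, expressed
# in the control: FPKM above 0.2) and G3 (unchanged, near-silent). The
# FPKM = 0.2 boundary goes to G2; G1 requires upregulation only, so a
# significantly downregulated gene falls through to G2/G3 by FPKM.

#' Genes with a differentially methylated promoter
#'
#' A gene qualifies when its long-promoter window (strand-aware, from
#' \code{\link{makePromoters}}) received at least one DMR of the requested
#' direction under the fractional-overlap rule: the promoter must cover at
#' least \code{minOverlapFrac} of the DMR's length. When several DMRs hit
#' one promoter, the one with the largest \code{|meanDiff|} is kept as the
#' representative.
#'
#' @param dmrs a DMR \code{GRanges} (with \code{direction}, \code{meanDiff},
#'   \code{pMWU})
#' @param genes gene table data.frame
#' @param config an \code{\link{annotationConfig}}
#' @param direction \code{"hypo"} (default) or \code{"hyper"}
#' @param window \code{"long"} (default) or \code{"core"} promoter window
#' @return data.frame: \code{gene_id}, \code{chrom}, \code{dmr_start},
#'   \code{dmr_end} (0-based half-open), \code{mean_diff}, \code{p_mwu}
#' @export
hypomethylatedPromoterGenes <- function(dmrs, genes,
                                        config = annotationConfig(),
                                        direction = "hypo",
                                        window = c("long", "core")) {
    window <- match.arg(window)
    proms <- makePromoters(genes, config)[[paste0(window, "_promoter")]]
    sel <- dmrs[mcols(dmrs)$direction == direction]
    empty <- data.frame(gene_id = character(), chrom = character(),
                        dmr_start = integer(), dmr_end = integer(),
                        mean_diff = numeric(), p_mwu = numeric(),
                        stringsAsFactors = FALSE)
    if (!length(sel) || !nrow(genes)) return(empty)
    hits <- findOverlaps(sel, proms, ignore.strand = TRUE)
    if (!length(hits)) return(empty)
    ov <- width(pintersect(sel[queryHits(hits)], proms[subjectHits(hits)],
                           ignore.strand = TRUE))
    keep <- ov >= config$minOverlapFrac * width(sel)[queryHits(hits)] - 1e-9
    hits <- hits[keep]
    if (!length(hits)) return(empty)
    df <- data.frame(gene_id = mcols(proms)$gene_id[subjectHits(hits)],
                     dmr = queryHits(hits), stringsAsFactors = FALSE)
    df$absDiff <- abs(mcols(sel)$meanDiff[df$dmr])
    df <- df[order(df$gene_id, -df$absDiff), ]
    df <- df[!duplicated(df$gene_id), ]
    i <- df$dmr
    data.frame(gene_id = df$gene_id,
               chrom = as.character(seqnames(sel))[i],
               dmr_start = start(sel)[i] - 1L, dmr_end = end(sel)[i],
               mean_diff = mcols(sel)$meanDiff[i],
               p_mwu = mcols(sel)$pMWU[i], stringsAsFactors = FALSE)
}

#' Assign promoter-hypomethylated genes to expression response groups
#'
#' G1 iff fold change >= 2 and p < 0.05 (upregulation only); otherwise G2
#' when the control FPKM is at least 0.2, else G3. The three groups
#' partition the assigned genes. Genes absent from the expression table are
#' skipped with a warning (the count is attached as the
#' \code{"skipped"} attribute).
#'
#' @param geneDmr output of \code{\link{hypomethylatedPromoterGenes}}
#' @param expression expression table data.frame
#'   (\code{\link{readExpressionTable}} schema)
#' @param fcThreshold,pThreshold,fpkmThreshold group boundaries
#' @return \code{geneDmr} with added columns \code{group},
#'   \code{fold_change}, \code{p_value}, \code{control_fpkm}
#' @export
assignGroups <- function(geneDmr, expression, fcThreshold = 2,
                         pThreshold = 0.05, fpkmThreshold = 0.2) {
    i <- match(geneDmr$gene_id, expression$gene_id)
    if (anyNA(i)) {
        warning(sum(is.na(i)), " gene(s) missing from the expression table",
                " were skipped")
        geneDmr <- geneDmr[!is.na(i), , drop = FALSE]
        skipped <- sum(is.na(i))
        i <- i[!is.na(i)]
    } else skipped <- 0L
    out <- cbind(geneDmr,
                 expression[i, c("fold_change", "p_value", "control_fpkm")])
    rownames(out) <- NULL
    g1 <- out$fold_change >= fcThreshold & out$p_value < pThreshold
    out$group <- ifelse(g1, "G1",
                        ifelse(out$control_fpkm >= fpkmThreshold, "G2", "G3"))
    attr(out, "skipped") <- skipped
    out
}

#' Hypomethylated-and-overexpressed gene lists across tumor types
#'
#' Per tumor type: genes carrying a promoter hypo-DMR \emph{and} passing
#' the differential-expression cut (fold change >= 2, p < 0.05). The shared
#' list is the intersection across all tumor types.
#'
#' @param geneDmrList named list of
#'   \code{\link{hypomethylatedPromoterGenes}} outputs, one per tumor type
#' @param expressionList named list of expression tables, parallel to
#'   \code{geneDmrList}
#' @param fcThreshold,pThreshold expression cut
#' @return list with \code{perType} (named list of gene-id vectors) and
#'   \code{shared} (character vector)
#' @export
hypomethylatedOverexpressed <- function(geneDmrList, expressionList,
                                        fcThreshold = 2, pThreshold = 0.05) {
    stopifnot(length(geneDmrList) >= 1L,
              identical(names(geneDmrList), names(expressionList)))
    perType <- lapply(names(geneDmrList), function(tt) {
        gd <- geneDmrList[[tt]]
        ex <- expressionList[[tt]]
        up <- ex$gene_id[ex$fold_change >= fcThreshold &
                         ex$p_value < pThreshold]
        sort(intersect(gd$gene_id, up))
    })
    names(perType) <- names(geneDmrList)
    list(perType = perType, shared = sort(Reduce(intersect, perType)))
}
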