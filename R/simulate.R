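# Synthetic multi-genotype methylome generator. It emulates the statistical
# structure the caller assumes: CpG positions with geometric-like spacing,
# a bimodal beta baseline (most CpGs highly methylated, a minority
# unmethylated), planted differential regions of known category shifting the
# true methylation surface of selected tumor genotypes, Poisson coverage and
# binomial methylated counts per sample. Planted regions are CpG-dense
# (island-like spacing) and flanked by guard gaps so distinct truths can
# never chain together.

.CATEGORIES <- c("af_target", "ca_target", "transformation",
                 "specific_A", "specific_B", "none")

.defaultRegionSpec <- function(delta = 0.4, nCpgs = 5L) {
    data.frame(
        category = c("af_target", "ca_target", "transformation",
                     "af_target", "ca_target",
                     "specific_A", "specific_B", "none"),
        delta = c(-delta, -delta, -delta, delta, delta, -delta, -delta, 0),
        nCpgs = nCpgs,
        count = c(12L, 12L, 12L, 4L, 4L, 6L, 6L, 4L),
        stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Defaults reproduce the study conditions the caller is meant to face:
#' coverage lambda 30, two replicates per genotype, planted shifts of 0.4 in
#' 5-CpG regions, and a 70/30 high/low bimodal baseline (Beta(9,1) /
#' Beta(1,9)) mimicking genome-wide CpG methylation bimodality.
#'
#' @param nCpgs number of CpG sites on the synthetic chromosome (>= 10)
#' @param meanSpacing mean background CpG spacing in bp (geometric-like)
#' @param regionSpacing two integers: uniform spacing range inside planted
#'   regions (CpG-island-like density, so a single failed site never opens
#'   an irrecoverable gap)
#' @param regionGuard minimum bp separating a planted region from its
#'   neighbors (>= 2x the caller's 50 bp gap limit)
#' @param coverageLambda Poisson mean sequencing depth per CpG and sample
#' @param baselineHigh,baselineLow Beta (alpha, beta) pairs of the high and
#'   low methylation modes
#' @param highWeight mixture weight of the high mode, in [0, 1]
#' @param genotypes tumor genotype ids; the canonical trio is \code{WT}
#'   (tumor with intact Dnmt3b), \code{KO} (Dnmt3b null) and \code{CI}
#'   (catalytically inactive Dnmt3b, accessory function retained)
#' @param control control group id (healthy thymus)
#' @param replicates replicates per genotype (and control)
#' @param chrom synthetic chromosome name
#' @param regionSpec data.frame with columns \code{category} (one of
#'   af_target, ca_target, transformation, specific_A, specific_B, none),
#'   \code{delta} (true methylation shift, tumor minus control, in [-1, 1]),
#'   \code{nCpgs} (>= 3 for callable regions) and \code{count}
#' @param nBackgroundGenes genes with unshifted promoters added to the gene
#'   and expression tables
#' @param seed integer seed; everything downstream derives substreams from it
#' @return a validated named list of simulation parameters
#' @export
simulationConfig <- function(nCpgs = 50000L, meanSpacing = 100,
                             regionSpacing = c(5L, 15L), regionGuard = 150L,
                             coverageLambda = 30,
                             baselineHigh = c(9, 1), baselineLow = c(1, 9),
                             highWeight = 0.7,
                             genotypes = c("WT", "KO", "CI"),
                             control = "thymus", replicates = 2L,
                             chrom = "chrS1",
                             regionSpec = .defaultRegionSpec(),
                             nBackgroundGenes = 20L, seed = 1L) {
    stopifnot(nCpgs >= 10L, meanSpacing > 0, coverageLambda > 0,
              highWeight >= 0, highWeight <= 1, replicates >= 1L,
              length(regionSpacing) == 2L, regionSpacing[1L] >= 1L,
              regionSpacing[2L] >= regionSpacing[1L], regionGuard > 0,
              is.data.frame(regionSpec),
              all(c("category", "delta", "nCpgs", "count") %in%
                  colnames(regionSpec)),
              all(regionSpec$category %in% .CATEGORIES),
              all(abs(regionSpec$delta) <= 1),
              all(regionSpec$nCpgs >= 3L), all(regionSpec$count >= 0L),
              !control %in% genotypes, !anyDuplicated(genotypes))
    if (sum(regionSpec$nCpgs * regionSpec$count) > nCpgs / 2)
        stop("planted regions would cover more than half of all CpGs",
             call. = FALSE)
    list(nCpgs = as.integer(nCpgs), meanSpacing = meanSpacing,
         regionSpacing = as.integer(regionSpacing),
         regionGuard = as.integer(regionGuard),
         coverageLambda = coverageLambda, baselineHigh = baselineHigh,
         baselineLow = baselineLow, highWeight = highWeight,
         genotypes = genotypes, control = control,
         replicates = as.integer(replicates), chrom = chrom,
         regionSpec = regionSpec,
         nBackgroundGenes = as.integer(nBackgroundGenes),
         seed = as.integer(seed))
}

# Which tumor genotypes a planted region affects, from its category and the
# sign of its shift. Mirrors the genotype set logic read off the comparisons:
# hypo accessory-function targets lose methylation only on full knockout;
# hypo catalytic targets on knockout and catalytic inactivation;
# transformation regions shift in every tumor; hyper accessory targets gain
# only under the catalytically dead allele, hyper catalytic targets only in
# the intact tumor.
.affectedGenotypes <- function(category, delta, genotypes) {
    need <- function(g) {
        if (!all(g %in% genotypes))
            stop("region category requires genotype(s) ",
                 paste(setdiff(g, genotypes), collapse = ", "),
                 " absent from the configuration", call. = FALSE)
        g
    }
    switch(category,
        transformation = genotypes,
        af_target = if (delta < 0) need("KO") else need("CI"),
        ca_target = if (delta < 0) need(c("KO", "CI")) else need("WT"),
        specific_A = need("WT"),
        specific_B = need("CI"),
        none = character())
}

.subseed <- function(seed, stream) {
    as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}

#' Generate the true methylation landscape
#'
#' Lays out CpG positions, draws the per-CpG baseline methylation from the
#' bimodal beta mixture, plants the configured differential regions (regions
#' destined for hypomethylation start in the high mode, hypermethylation
#' targets in the low mode, so the shift is realizable without clipping),
#' and builds one true methylation surface per genotype plus control.
#' Deterministic for a fixed seed; planted regions never overlap and are
#' separated by at least \code{regionGuard} bp.
#'
#' @param config a \code{\link{simulationConfig}}
#' @return a list of class \code{MethylTruth}: \code{positions} (width-1
#'   \code{GRanges}), \code{surfaces} (CpGs x groups matrix of true
#'   fractions, control first), \code{regions} (truth \code{GRanges} with
#'   \code{category}, \code{delta}, \code{nCpgs}, \code{genotypes},
#'   \code{gene_id}, \code{gene_group}), \code{genes} (gene table
#'   data.frame) and the \code{config}
#' @export
generateTruth <- function(config = simulationConfig()) {
    set.seed(config$seed)
    spec <- config$regionSpec[rep(seq_len(nrow(config$regionSpec)),
                                  config$regionSpec$count), ]
    nRegions <- nrow(spec)
    if (nRegions) spec <- spec[sample.int(nRegions), ]  # interleave categories
    regionCpgs <- if (nRegions) sum(spec$nCpgs) else 0L
    nBg <- config$nCpgs - regionCpgs
    # split background CpGs into nRegions+1 runs, each non-empty
    segLen <- rep(nBg %/% (nRegions + 1L), nRegions + 1L)
    extra <- nBg %% (nRegions + 1L)
    if (extra) segLen[seq_len(extra)] <- segLen[seq_len(extra)] + 1L
    if (any(segLen < 1L))
        stop("too many planted regions for nCpgs", call. = FALSE)

    spacing <- integer(0)
    inRegion <- integer(0)   # region index per CpG, 0 = background
    drawBg <- function(k) 1L + stats::rgeom(k, 1 / config$meanSpacing)
    drawRg <- function(k) sample(seq(config$regionSpacing[1L],
                                     config$regionSpacing[2L]), k,
                                 replace = TRUE)
    for (i in seq_len(nRegions + 1L)) {
        bg <- drawBg(segLen[i])
        if (i > 1L) bg[1L] <- max(bg[1L], config$regionGuard)
        spacing <- c(spacing, bg)
        inRegion <- c(inRegion, rep(0L, segLen[i]))
        if (i <= nRegions) {
            k <- spec$nCpgs[i]
            rs <- drawRg(k)
            rs[1L] <- max(rs[1L], config$regionGuard)  # guard before region
            spacing <- c(spacing, rs)
            inRegion <- c(inRegion, rep(i, k))
        }
    }
    pos <- cumsum(spacing) + 1000L   # 0-based positions
    positions <- GRanges(config$chrom, IRanges(pos + 1L, width = 1L))

    # baseline: bimodal mixture; planted regions draw from the mode their
    # shift can act on
    n <- length(pos)
    mode <- ifelse(stats::runif(n) < config$highWeight, "high", "low")
    if (nRegions) {
        rDelta <- spec$delta[pmax(inRegion, 1L)]
        mode[inRegion > 0L & rDelta < 0] <- "high"
        mode[inRegion > 0L & rDelta > 0] <- "low"
    }
    base <- numeric(n)
    hi <- mode == "high"
    base[hi] <- stats::rbeta(sum(hi), config$baselineHigh[1L],
                             config$baselineHigh[2L])
    base[!hi] <- stats::rbeta(sum(!hi), config$baselineLow[1L],
                              config$baselineLow[2L])

    groupsAll <- c(config$control, config$genotypes)
    surfaces <- matrix(rep(base, length(groupsAll)), ncol = length(groupsAll),
                       dimnames = list(NULL, groupsAll))
    regionGeno <- vector("list", nRegions)
    for (i in seq_len(nRegions)) {
        g <- .affectedGenotypes(spec$category[i], spec$delta[i],
                                config$genotypes)
        regionGeno[[i]] <- g
        rows <- which(inRegion == i)
        for (gt in g)
            surfaces[rows, gt] <- pmin(1, pmax(0, base[rows] + spec$delta[i]))
    }

    if (nRegions) {
        firstPos <- vapply(seq_len(nRegions),
                           function(i) pos[which(inRegion == i)[1L]], 0L)
        lastPos <- vapply(seq_len(nRegions), function(i) {
            w <- which(inRegion == i); pos[w[length(w)]]
        }, 0L)
        hypo <- spec$delta < 0
        geneId <- ifelse(hypo, sprintf("gene_r%03d", seq_len(nRegions)),
                         NA_character_)
        geneGroup <- rep(NA_character_, nRegions)
        geneGroup[hypo] <- rep(c("G1", "G2", "G3"),
                               length.out = sum(hypo))
        regions <- GRanges(config$chrom, IRanges(firstPos + 1L, lastPos + 1L),
                           region_id = sprintf("r%03d", seq_len(nRegions)),
                           category = spec$category, delta = spec$delta,
                           nCpgs = spec$nCpgs,
                           genotypes = vapply(regionGeno, paste,
                                              "", collapse = ","),
                           gene_id = geneId, gene_group = geneGroup)
    } else {
        regions <- GRanges(region_id = character(), category = character(),
                           delta = numeric(), nCpgs = integer(),
                           genotypes = character(), gene_id = character(),
                           gene_group = character())
    }

    genes <- .layoutGenes(regions, pos, config)
    structure(list(positions = positions, surfaces = surfaces,
                   regions = regions, genes = genes, config = config),
              class = "MethylTruth")
}

# Gene models: each hypo region becomes the long-promoter content of one
# gene (TSS placed so the region sits inside the strand-aware
# [-1500, +500) window), strands alternating; background genes land far
# from any planted region.
.layoutGenes <- function(regions, pos, config) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      tss = integer(), strand = character(),
                      group = character(), stringsAsFactors = FALSE)
    withGene <- which(!is.na(mcols(regions)$gene_id))
    for (k in seq_along(withGene)) {
        i <- withGene[k]
        s0 <- start(regions)[i] - 1L   # 0-based
        e0 <- end(regions)[i]
        std <- if (k %% 2L == 1L) "+" else "-"
        tss <- if (std == "+") e0 + 100L else s0 - 100L
        out <- rbind(out, data.frame(
            gene_id = mcols(regions)$gene_id[i], chrom = config$chrom,
            tss = tss, strand = std, group = mcols(regions)$gene_group[i],
            stringsAsFactors = FALSE))
    }
    if (config$nBackgroundGenes > 0L) {
        anchor <- max(pos) + 10000L
        out <- rbind(out, data.frame(
            gene_id = sprintf("bg_gene_%03d", seq_len(config$nBackgroundGenes)),
            chrom = config$chrom,
            tss = anchor + 5000L * seq_len(config$nBackgroundGenes),
            strand = rep(c("+", "-"),
                         length.out = config$nBackgroundGenes),
            group = NA_character_, stringsAsFactors = FALSE))
    }
    out
}

#' Simulate one sample's CpG call track
#'
#' Per CpG: coverage ~ Poisson(\code{coverageLambda}), methylated count ~
#' Binomial(coverage, true fraction). Each (group, replicate) pair uses its
#' own deterministic RNG substream, so replicates differ but every call is
#' reproducible from the configuration seed.
#'
#' @param truth a \code{MethylTruth} from \code{\link{generateTruth}}
#' @param group control or genotype id (a column of \code{truth$surfaces})
#' @param replicate replicate number (1-based)
#' @return a width-1 CpG \code{GRanges} with \code{meth}, \code{unmeth} and
#'   \code{sample_id} metadata columns
#' @export
simulateSample <- function(truth, group, replicate = 1L) {
    stopifnot(inherits(truth, "MethylTruth"))
    if (!group %in% colnames(truth$surfaces))
        stop("unknown genotype or group: ", group, call. = FALSE)
    config <- truth$config
    gi <- match(group, colnames(truth$surfaces))
    set.seed(.subseed(config$seed, gi * 1000L + replicate))
    p <- truth$surfaces[, gi]
    n <- length(p)
    cov <- stats::rpois(n, config$coverageLambda)
    meth <- stats::rbinom(n, cov, p)
    out <- truth$positions
    mcols(out) <- DataFrame(meth = meth, unmeth = cov - meth,
                            sample_id = sprintf("%s_%d", group, replicate))
    out
}

#' Simulate the full sample set
#'
#' All replicates for the control and every tumor genotype.
#'
#' @param truth a \code{MethylTruth}
#' @return list with \code{samples} (named list of CpG \code{GRanges}) and
#'   \code{groups} (group label per sample, parallel to \code{samples})
#' @export
simulateMethylome <- function(truth) {
    stopifnot(inherits(truth, "MethylTruth"))
    config <- truth$config
    groupsAll <- colnames(truth$surfaces)
    samples <- list()
    groups <- character()
    for (g in groupsAll) {
        for (r in seq_len(config$replicates)) {
            samples[[sprintf("%s_%d", g, r)]] <- simulateSample(truth, g, r)
            groups <- c(groups, g)
        }
    }
    list(samples = samples, groups = groups)
}

#' Simulate the matched expression table
#'
#' Genes tagged G1 get fold change >= 2 at p < 0.05; G2 genes are unchanged
#' with control FPKM above 0.2; G3 genes are unchanged and near-silent
#' (control FPKM below 0.2). Untagged background genes behave like G2.
#' FPKM noise is lognormal.
#'
#' @param truth a \code{MethylTruth}
#' @return a data.frame with columns \code{gene_id}, \code{fold_change},
#'   \code{p_value}, \code{control_fpkm}
#' @export
simulateExpression <- function(truth) {
    stopifnot(inherits(truth, "MethylTruth"))
    config <- truth$config
    set.seed(.subseed(config$seed, 999983L))
    genes <- truth$genes
    n <- nrow(genes)
    fc <- exp(stats::rnorm(n, 0, 0.08))
    pv <- stats::runif(n, 0.2, 0.95)
    fpkm <- 0.25 + stats::rlnorm(n, log(3), 0.6)
    g1 <- which(!is.na(genes$group) & genes$group == "G1")
    fc[g1] <- 2 * exp(abs(stats::rnorm(length(g1), 0.4, 0.3)))
    pv[g1] <- stats::runif(length(g1), 1e-6, 0.049)
    g3 <- which(!is.na(genes$group) & genes$group == "G3")
    fpkm[g3] <- stats::runif(length(g3), 0.001, 0.15)
    data.frame(gene_id = genes$gene_id, fold_change = fc, p_value = pv,
               control_fpkm = fpkm, stringsAsFactors = FALSE)
}

#' Simulate a per-base signal track
#'
#' Background signal with multiplicative lognormal noise (mean exactly the
#' stated background level) plus smooth enrichment over designated regions:
#' the multiplier applies fully inside each region and decays linearly over
#' \code{rampWidth} bp outside it. Deterministic for a fixed seed.
#'
#' @param regions a \code{GRanges}; enrichment is looked up per region from
#'   \code{enrichment[mcols(regions)$category]} when \code{enrichment} is
#'   named, else recycled along regions
#' @param enrichment named (by category) or plain numeric multipliers;
#'   1 = no enrichment
#' @param chromLength track length per chromosome; defaults to the furthest
#'   region end plus 2000 bp
#' @param background mean background signal level
#' @param noiseSd lognormal sigma of the multiplicative noise
#' @param rampWidth linear decay width in bp
#' @param seed RNG seed
#' @return an \code{RleList} of per-base signal
#' @export
simulateSignalTrack <- function(regions, enrichment = 1,
                                chromLength = NULL, background = 1,
                                noiseSd = 0.05, rampWidth = 50L,
                                seed = 1L) {
    set.seed(.subseed(seed, 424243L))
    mult <- if (!is.null(names(enrichment))) {
        m <- enrichment[as.character(mcols(regions)$category)]
        m[is.na(m)] <- 1
        as.numeric(m)
    } else rep_len(as.numeric(enrichment), length(regions))
    chroms <- if (length(regions)) unique(as.character(seqnames(regions)))
              else "chrS1"
    out <- lapply(chroms, function(chrom) {
        on <- which(as.character(seqnames(regions)) == chrom)
        len <- if (is.null(chromLength)) {
            max(c(2000L, if (length(on)) end(regions)[on] + 2000L))
        } else chromLength
        shape <- numeric(len)
        for (i in on) {
            s <- start(regions)[i]; e <- end(regions)[i]
            shape[s:e] <- pmax(shape[s:e], 1)
            if (rampWidth > 0L) {
                up <- max(1L, s - rampWidth):max(1L, s - 1L)
                shape[up] <- pmax(shape[up],
                                  seq(0, 1, length.out = length(up) + 1L)[-1L])
                dn <- min(len, e + 1L):min(len, e + rampWidth)
                shape[dn] <- pmax(shape[dn],
                                  rev(seq(0, 1,
                                          length.out = length(dn) + 1L)[-1L]))
            }
            shape[s:e] <- 1
        }
        multPerBase <- numeric(len)
        for (i in on) {
            s <- max(1L, start(regions)[i] - rampWidth)
            e <- min(len, end(regions)[i] + rampWidth)
            multPerBase[s:e] <- pmax(multPerBase[s:e], mult[i] - 1)
        }
        noise <- exp(stats::rnorm(len, -noiseSd^2 / 2, noiseSd))
        Rle(background * (1 + multPerBase * shape) * noise)
    })
    names(out) <- chroms
    methods::as(out, "RleList")
}

#' Write the truth table
#'
#' @param truth a \code{MethylTruth}
#' @param path TSV output path (0-based half-open region coordinates)
#' @export
writeTruthTable <- function(truth, path) {
    r <- truth$regions
    df <- data.frame(chrom = as.character(seqnames(r)), start = start(r) - 1L,
                     end = end(r), region_id = mcols(r)$region_id,
                     category = mcols(r)$category, delta = mcols(r)$delta,
                     n_cpgs = mcols(r)$nCpgs,
                     genotypes = mcols(r)$genotypes,
                     gene_id = mcols(r)$gene_id,
                     gene_group = mcols(r)$gene_group,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
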