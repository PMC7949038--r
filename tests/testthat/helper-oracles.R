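# Independent oracles and shared fixtures. The oracles deliberately use
# different computational routes than the implementation: the rank-sum test
# is enumerated by direct pairwise comparison over explicit group
# reassignments, interval overlaps are counted per base, and profile bins
# are integrated with explicit per-base weights.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# exact two-sided Mann-Whitney p by enumerating all group reassignments and
# counting pairwise wins (ties worth 1/2) -- no ranks involved
mwuOracleP <- function(a, b) {
    na <- length(a); nb <- length(b)
    pooled <- c(a, b)
    if (max(pooled) == min(pooled)) return(1)
    n <- na + nb
    uOf <- function(idx) {
        x <- pooled[idx]; y <- pooled[-idx]
        sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    }
    mu <- na * nb / 2
    obs <- abs(uOf(seq_len(na)) - mu)
    subsets <- utils::combn(n, na)
    devs <- abs(apply(subsets, 2, uOf) - mu)
    mean(devs >= obs - 1e-9)
}

# per-base union overlap of one query interval with a set of intervals
# (all GRanges, 1-based closed)
unionOverlapOracle <- function(query, subject) {
    stopifnot(length(query) == 1L)
    bases <- seq(start(query), end(query))
    covered <- rep(FALSE, length(bases))
    same <- as.character(seqnames(subject)) ==
        as.character(seqnames(query))
    for (i in which(same))
        covered <- covered | (bases >= start(subject)[i] &
                              bases <= end(subject)[i])
    sum(covered)
}

# mean signal over the continuous 0-based span [a, b) using explicit
# per-base weights
spanMeanOracle <- function(x, a, b) {
    if (b <= a) return(0)
    w <- numeric(length(x))
    for (i in seq_along(x)) {
        lo <- i - 1; hi <- i
        ov <- max(0, min(b, hi) - max(a, lo))
        w[i] <- ov
    }
    sum(w * x) / (b - a)
}

# build a MethylMatrix from a per-sample list of exact fractions at the
# given 1-based positions (single chromosome), with constant coverage
matrixFromFractions <- function(fractions, positions, chrom = "chrT",
                                coverage = 20L, groups = NULL,
                                config = callerConfig()) {
    samples <- lapply(fractions, function(fr) {
        stopifnot(length(fr) == length(positions))
        GRanges(chrom, IRanges(positions, width = 1L),
                meth = as.integer(round(fr * coverage)),
                unmeth = as.integer(coverage - round(fr * coverage)),
                sample_id = "x")
    })
    if (is.null(groups)) groups <- names(fractions)
    buildMethylMatrix(samples, groups, config)
}

dmrGR <- function(starts, ends, direction, chrom = "chr1") {
    n <- length(starts)
    GRanges(rep(chrom, n), IRanges(starts, ends), direction = direction,
            nCpgs = rep(3L, n),
            meanDiff = ifelse(direction == "hypo", -0.4, 0.4),
            pMWU = rep(0.01, n))
}

# memoized canonical fixtures so the expensive default-scale run happens
# once per test session
.fixtureCache <- new.env(parent = emptyenv())
fixtureRun <- function(scale = "tiny", seed = 1L) {
    key <- paste(scale, seed, sep = "_")
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- makeFixtures(scale, seed = seed)
    .fixtureCache[[key]]
}
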