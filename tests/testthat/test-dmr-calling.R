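test_that("the all-sample coverage filter keeps exactly the deep CpGs", {
    mk <- function(covs, meths) {
        GRanges("chr1", IRanges(c(101, 201), width = 1L),
                meth = meths, unmeth = covs - meths, sample_id = "x")
    }
    samples <- list(a = mk(c(10L, 10L), c(5L, 5L)),
                    b = mk(c(10L, 4L), c(5L, 2L)))
    mm <- buildMethylMatrix(samples, c("ctrl", "tum"))
    expect_equal(nrow(mm), 1L)          # 10x/4x CpG dropped: 4 < 5
    expect_equal(start(rowRanges(mm)), 101L)
    expect_error(
        buildMethylMatrix(list(a = mk(c(4L, 4L), c(1L, 1L)),
                               b = mk(c(10L, 10L), c(1L, 1L))),
                          c("ctrl", "tum")),
        "no analyzable CpGs")
})

test_that("retained fraction matches the Poisson closed form", {
    cfg <- simulationConfig(nCpgs = 20000L, coverageLambda = 6,
                            regionSpec = data.frame(category = "none",
                                                    delta = 0, nCpgs = 5L,
                                                    count = 1L),
                            genotypes = "WT", replicates = 2L, seed = 17L)
    tr <- generateTruth(cfg)
    meth <- simulateMethylome(tr)
    mm <- buildMethylMatrix(meth$samples, meth$groups)
    pKeep <- (1 - ppois(4, 6))^length(meth$samples)
    expect_lt(abs(nrow(mm) / cfg$nCpgs - pKeep), 0.01)
})

test_that("group means are unweighted row means", {
    pos <- c(101, 151, 201)
    mm <- matrixFromFractions(
        list(a1 = c(0.4, 0.2, 1.0), a2 = c(0.6, 0.4, 0.8),
             b1 = c(0.1, 0.9, 0.5)),
        pos, groups = c("A", "A", "B"))
    gm <- groupMeans(mm, "A", "B")
    expect_equal(unname(gm[, "meanA"]), c(0.5, 0.3, 0.9))
    expect_equal(unname(gm[, "meanB"]), c(0.1, 0.9, 0.5))  # single sample
    set.seed(99)
    fr <- lapply(1:4, function(i) round(runif(100), 2))
    names(fr) <- paste0("s", 1:4)
    mm2 <- matrixFromFractions(fr, seq(101, by = 50, length.out = 100),
                               coverage = 100L,
                               groups = c("A", "A", "B", "B"))
    gm2 <- groupMeans(mm2, "A", "B")
    expect_equal(unname(gm2[, "meanA"]), (fr$s1 + fr$s2) / 2)
    expect_equal(unname(gm2[, "meanB"]), (fr$s3 + fr$s4) / 2)
    expect_error(groupMeans(mm, "A", "nope"), "unknown")
    expect_error(groupMeans(mm2, c("s1", "s2"), c("s2", "s3")), "disjoint")
})

test_that("DMC calling applies the inclusive 30-point threshold", {
    pos <- c(101, 201, 301)
    mm <- matrixFromFractions(
        list(a = c(0.80, 0.80, 0.80), b = c(0.45, 0.55, 0.50)),
        pos, groups = c("ctrl", "tum"))
    dmcs <- callDMCs(mm, "ctrl", "tum")
    # diffs: -0.35 (DMC), -0.25 (not), -0.30 (DMC: threshold inclusive)
    expect_equal(start(dmcs), c(101L, 301L))
    expect_equal(mcols(dmcs)$diff, c(-0.35, -0.30))
    expect_equal(mcols(dmcs)$direction, c("hypo", "hypo"))
    hyper <- callDMCs(mm, "tum", "ctrl")
    expect_equal(mcols(hyper)$direction, c("hyper", "hyper"))
})

test_that("the Mann-Whitney U test matches exact enumeration and handles ties", {
    expect_equal(mwuTest(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(mwuTest(c(5, 5, 5), c(5, 5)), 1)      # all identical
    expect_equal(mwuTest(c(0, 0, 0), c(1, 1, 1)), 0.1) # 2/choose(6,3)
    set.seed(31)
    for (i in 1:200) {
        na <- sample(1:6, 1); nb <- sample(1:6, 1)
        vals <- sample(0:3, na + nb, replace = TRUE)   # force ties
        a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
        expect_equal(mwuTest(a, b), mwuOracleP(a, b), tolerance = 1e-12)
    }
})

test_that("the large-sample path matches the tie-corrected normal formula", {
    set.seed(41)
    for (i in 1:50) {
        a <- sample(0:5, 10, replace = TRUE)
        b <- sample(0:5, 12, replace = TRUE)
        if (max(c(a, b)) == min(c(a, b))) next
        ref <- suppressWarnings(
            stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
        expect_equal(mwuTest(a, b), ref, tolerance = 1e-10)
    }
})

test_that("DMR chaining follows the gap and direction rules", {
    # hypo DMCs at 0-based 100, 130, 170 (gaps 30, 40): one 3-CpG region
    mk <- function(pos0) matrixFromFractions(
        list(a1 = rep(0.9, 3), a2 = rep(0.95, 3),
             b1 = rep(0.45, 3), b2 = rep(0.5, 3)),
        pos0 + 1, groups = c("ctrl", "ctrl", "tum", "tum"))
    dmrs <- callDMRs(mk(c(100, 130, 170)), "ctrl", "tum")
    expect_length(dmrs, 1L)
    expect_equal(mcols(dmrs)$nCpgs, 3L)
    expect_equal(mcols(dmrs)$direction, "hypo")
    expect_equal(start(dmrs) - 1L, 100L)
    expect_equal(end(dmrs), 171L)        # 0-based half-open [100, 171)
    expect_lt(mcols(dmrs)$pMWU, 0.05)
    # gap 65 breaks the chain: only 2 consecutive DMCs remain
    expect_length(callDMRs(mk(c(100, 130, 195)), "ctrl", "tum"), 0L)
})

test_that("an intervening non-DMC CpG breaks chains only in strict mode", {
    pos0 <- c(100, 130, 150, 170)
    mm <- matrixFromFractions(
        list(a1 = c(0.9, 0.9, 0.6, 0.9), a2 = c(0.95, 0.95, 0.6, 0.95),
             b1 = c(0.45, 0.45, 0.6, 0.45), b2 = c(0.5, 0.5, 0.6, 0.5)),
        pos0 + 1, groups = c("ctrl", "ctrl", "tum", "tum"))
    lax <- callDMRs(mm, "ctrl", "tum")
    expect_length(lax, 1L)
    expect_equal(mcols(lax)$nCpgs, 3L)   # DMCs at 100, 130, 170 chained
    strict <- callDMRs(mm, "ctrl", "tum",
                       callerConfig(strictConsecutive = TRUE))
    expect_length(strict, 0L)            # the 0.6 CpG at 150 interrupts
})

test_that("group swap flips directions and keeps p-values (antisymmetry)", {
    cfg <- simulationConfig(nCpgs = 3000L, genotypes = "WT", seed = 23L,
                            regionSpec = data.frame(
                                category = c("specific_A", "specific_A"),
                                delta = c(-0.4, 0.4), nCpgs = 5L,
                                count = c(3L, 3L)))
    tr <- generateTruth(cfg)
    meth <- simulateMethylome(tr)
    mm <- buildMethylMatrix(meth$samples, meth$groups)
    fwd <- callDMRs(mm, "thymus", "WT")
    rev <- callDMRs(mm, "WT", "thymus")
    expect_gt(length(fwd), 0L)
    expect_equal(start(fwd), start(rev))
    expect_equal(mcols(fwd)$meanDiff, -mcols(rev)$meanDiff)
    expect_equal(mcols(fwd)$pMWU, mcols(rev)$pMWU)
    flip <- c(hypo = "hyper", hyper = "hypo")
    expect_equal(unname(flip[mcols(fwd)$direction]), mcols(rev)$direction)
    dmcF <- callDMCs(mm, "thymus", "WT")
    dmcR <- callDMCs(mm, "WT", "thymus")
    expect_equal(mcols(dmcF)$diff, -mcols(dmcR)$diff)
})

test_that("lowering the delta threshold never loses DMCs", {
    cfg <- simulationConfig(nCpgs = 2000L, genotypes = "WT", seed = 29L,
                            regionSpec = data.frame(
                                category = "specific_A", delta = -0.4,
                                nCpgs = 5L, count = 3L))
    tr <- generateTruth(cfg)
    meth <- simulateMethylome(tr)
    mm <- buildMethylMatrix(meth$samples, meth$groups)
    counts <- vapply(c(0.5, 0.4, 0.3, 0.2, 0.1), function(d)
        length(callDMCs(mm, "thymus", "WT",
                        callerConfig(deltaThreshold = d))), 0L)
    expect_true(all(diff(counts) >= 0))
})

test_that("null data yields under one DMR per Mb", {
    cfg <- simulationConfig(nCpgs = 10000L,
                            regionSpec = data.frame(category = "none",
                                                    delta = 0, nCpgs = 5L,
                                                    count = 1L),
                            genotypes = "WT", seed = 37L)
    tr <- generateTruth(cfg)
    meth <- simulateMethylome(tr)
    mm <- buildMethylMatrix(meth$samples, meth$groups)
    dmrs <- callDMRs(mm, "thymus", "WT")
    spanMb <- (max(end(rowRanges(mm))) - min(start(rowRanges(mm)))) / 1e6
    expect_lt(length(dmrs) / spanMb, 1)
})

test_that("DMR BED files round-trip", {
    run <- fixtureRun("tiny")
    dmrs <- run$comparisons$KO$dmrs
    f <- withr::local_tempfile(fileext = ".bed")
    writeDmrBed(dmrs, f)
    back <- readDmrBed(f)
    expect_equal(start(back), start(dmrs))
    expect_equal(end(back), end(dmrs))
    expect_equal(mcols(back)$direction, mcols(dmrs)$direction)
    expect_equal(mcols(back)$nCpgs, mcols(dmrs)$nCpgs)
    expect_equal(mcols(back)$pMWU, mcols(dmrs)$pMWU, tolerance = 1e-9)
})
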