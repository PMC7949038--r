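tinySpec <- function(delta) {
    data.frame(category = c("af_target", "ca_target", "transformation"),
               delta = delta, nCpgs = 5L, count = 1L,
               stringsAsFactors = FALSE)
}

test_that("null shift yields identical surfaces across genotypes", {
    cfg <- simulationConfig(nCpgs = 300L, regionSpec = tinySpec(0),
                            seed = 5L)
    tr <- generateTruth(cfg)
    for (g in cfg$genotypes)
        expect_identical(tr$surfaces[, g], tr$surfaces[, cfg$control])
})

test_that("planted shifts move exactly the region CpGs of the affected genotypes", {
    cfg <- simulationConfig(nCpgs = 400L, regionSpec = tinySpec(-0.4),
                            seed = 9L)
    tr <- generateTruth(cfg)
    base <- tr$surfaces[, cfg$control]
    pos <- granges(tr$positions)
    for (i in seq_along(tr$regions)) {
        inside <- queryHits(findOverlaps(pos, tr$regions[i]))
        affected <- strsplit(mcols(tr$regions)$genotypes[i], ",")[[1]]
        for (g in cfg$genotypes) {
            expected <- if (g %in% affected)
                pmin(1, pmax(0, base[inside] - 0.4)) else base[inside]
            expect_equal(tr$surfaces[inside, g], expected)
        }
    }
    # outside planted regions every genotype equals the control
    outside <- setdiff(seq_along(pos),
                       queryHits(findOverlaps(pos, tr$regions)))
    for (g in cfg$genotypes)
        expect_identical(tr$surfaces[outside, g], base[outside])
})

test_that("truth generation and sampling are seed-deterministic", {
    cfg <- simulationConfig(nCpgs = 300L, regionSpec = tinySpec(-0.4),
                            seed = 21L)
    t1 <- generateTruth(cfg)
    t2 <- generateTruth(cfg)
    expect_identical(t1$surfaces, t2$surfaces)
    expect_identical(start(t1$regions), start(t2$regions))
    expect_identical(t1$genes, t2$genes)
    s1 <- simulateSample(t1, "KO", 1L)
    s2 <- simulateSample(t2, "KO", 1L)
    expect_identical(mcols(s1)$meth, mcols(s2)$meth)
    # replicates use distinct substreams
    s3 <- simulateSample(t1, "KO", 2L)
    expect_false(identical(mcols(s1)$meth, mcols(s3)$meth))
})

test_that("planted regions never overlap and respect the guard gap", {
    cfg <- simulationConfig(seed = 3L)
    tr <- generateTruth(cfg)
    r <- sort(tr$regions)
    expect_true(all(start(r)[-1] - end(r)[-length(r)] >= cfg$regionGuard))
})

test_that("degenerate binomial: fraction 1 gives fully methylated reads", {
    cfg <- simulationConfig(nCpgs = 500L, regionSpec = tinySpec(0),
                            seed = 2L)
    tr <- generateTruth(cfg)
    tr$surfaces[, "KO"] <- 1
    s <- simulateSample(tr, "KO", 1L)
    expect_true(all(mcols(s)$unmeth == 0L))
    expect_identical(mcols(s)$meth, cpgCoverage(s))
})

test_that("sampling matches its law: binomial mean and Poisson tail", {
    cfg <- simulationConfig(nCpgs = 10000L, regionSpec = tinySpec(0),
                            coverageLambda = 6, seed = 13L)
    tr <- generateTruth(cfg)
    tr$surfaces[, "WT"] <- 0.5
    s <- simulateSample(tr, "WT", 1L)
    fr <- cpgFraction(s)
    expect_lt(abs(mean(fr, na.rm = TRUE) - 0.5), 0.01)
    expect_lt(abs(mean(cpgCoverage(s) < 5) - ppois(4, 6)), 0.01)
    # at the default depth of 30x essentially nothing falls under 5x
    cfg30 <- simulationConfig(nCpgs = 10000L, regionSpec = tinySpec(0),
                              seed = 13L)
    s30 <- simulateSample(generateTruth(cfg30), "WT", 1L)
    expect_lt(abs(mean(cpgCoverage(s30) < 5) - ppois(4, 30)), 0.01)
})

test_that("expression simulation satisfies the planted group definitions", {
    cfg <- simulationConfig(nCpgs = 2000L, seed = 8L)
    tr <- generateTruth(cfg)
    ex <- simulateExpression(tr)
    tag <- tr$genes$group[match(ex$gene_id, tr$genes$gene_id)]
    g1 <- which(!is.na(tag) & tag == "G1")
    expect_true(all(ex$fold_change[g1] >= 2 & ex$p_value[g1] < 0.05))
    g2 <- which(!is.na(tag) & tag == "G2")
    expect_true(all(ex$control_fpkm[g2] > 0.2))
    expect_true(all(ex$fold_change[g2] < 2))
    g3 <- which(!is.na(tag) & tag == "G3")
    expect_true(all(ex$control_fpkm[g3] < 0.2))
    expect_true(all(ex$fold_change[g3] < 2))
})

test_that("signal tracks have the stated background and enrichment", {
    regions <- GRanges("chrS1", IRanges(c(2001, 6001), width = 200),
                       category = c("af_target", "none"))
    flat <- simulateSignalTrack(regions, enrichment = c(af_target = 1),
                                chromLength = 10000L, seed = 4L)
    expect_lt(abs(mean(as.numeric(flat$chrS1)) - 1), 0.02)
    enr <- simulateSignalTrack(regions, enrichment = c(af_target = 5),
                               chromLength = 10000L, seed = 4L)
    x <- as.numeric(enr$chrS1)
    inRegion <- mean(x[2001:2200])
    background <- mean(x[8000:10000])
    expect_lt(abs(inRegion / background - 5), 0.5)     # 5x within 10%
    # untargeted region stays at background
    expect_lt(abs(mean(x[6001:6200]) / background - 1), 0.1)
    # determinism
    enr2 <- simulateSignalTrack(regions, enrichment = c(af_target = 5),
                                chromLength = 10000L, seed = 4L)
    expect_identical(as.numeric(enr$chrS1), as.numeric(enr2$chrS1))
})

test_that("overlapping planted-region specs are impossible by construction", {
    spec <- data.frame(category = "af_target", delta = -0.4, nCpgs = 100L,
                       count = 10L)
    expect_error(simulationConfig(nCpgs = 1000L, regionSpec = spec),
                 "half of all CpGs")
})
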