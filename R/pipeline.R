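# End-to-end orchestration: simulate -> call -> annotate -> classify ->
# integrate, with per-stage outputs, one-line counts per stage and a JSON
# manifest that fully reproduces the run. A single global seed fans out to
# per-stage substreams, so the pipeline is idempotent for a fixed seed.

#' Assemble a pipeline configuration
#'
#' @param simulation a \code{\link{simulationConfig}}
#' @param caller a \code{\link{callerConfig}}
#' @param annotation an \code{\link{annotationConfig}}
#' @param fcThreshold,pThreshold,fpkmThreshold integration thresholds
#' @param seed global seed; overrides \code{simulation$seed}
#' @return a named list of validated sections
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           caller = callerConfig(),
                           annotation = annotationConfig(),
                           fcThreshold = 2, pThreshold = 0.05,
                           fpkmThreshold = 0.2, seed = NULL) {
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
    list(simulation = simulation, caller = caller, annotation = annotation,
         fcThreshold = fcThreshold, pThreshold = pThreshold,
         fpkmThreshold = fpkmThreshold)
}

.stageLog <- function(verbose, stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full synthetic-data pipeline
#'
#' Stages, in order: simulate the methylome, expression table and truth;
#' build the all-sample-filtered matrix; call DMCs and DMRs per tumor
#' genotype against the control; annotate DMRs with promoter windows;
#' apply the transformation filter and CA/AF classification; integrate
#' promoter hypomethylation with expression for the knockout comparison;
#' score everything against the truth table. Writes per-stage files plus a
#' \code{manifest.json} when \code{outdir} is given.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param outdir optional output directory (created if missing)
#' @param verbose log one line per stage with its counts
#' @return a list with \code{truth}, \code{matrix}, \code{comparisons}
#'   (per-genotype list: \code{dmcs}, \code{dmrs}), \code{classified},
#'   \code{annotated}, \code{assigned}, \code{recovery} (per-genotype DMR
#'   scores, set-logic table, gene-group score) and \code{manifest}
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL,
                        verbose = TRUE) {
    sim <- config$simulation
    truth <- generateTruth(sim)
    meth <- simulateMethylome(truth)
    expr <- simulateExpression(truth)
    .stageLog(verbose, "simulate", "%d CpGs, %d planted regions, %d samples",
              sim$nCpgs, length(truth$regions), length(meth$samples))

    mm <- buildMethylMatrix(meth$samples, meth$groups, config$caller)
    .stageLog(verbose, "filter", "%d CpGs retained at %dx in all samples",
              nrow(mm), config$caller$minCoverage)

    comparisons <- lapply(sim$genotypes, function(g) {
        dmcs <- callDMCs(mm, sim$control, g, config$caller)
        dmrs <- callDMRs(mm, sim$control, g, config$caller, dmcs = dmcs)
        .stageLog(verbose, "call", "%s vs %s: %d DMCs (%d hypo), %d DMRs (%d hypo)",
                  g, sim$control, length(dmcs),
                  sum(mcols(dmcs)$direction == "hypo"), length(dmrs),
                  sum(mcols(dmrs)$direction == "hypo"))
        list(dmcs = dmcs, dmrs = dmrs)
    })
    names(comparisons) <- sim$genotypes

    proms <- makePromoters(truth$genes, config$annotation)
    annotated <- lapply(comparisons, function(cp)
        annotateDMRs(cp$dmrs, as.list(proms), config$annotation))
    classified <- classifyComparisons(lapply(comparisons, `[[`, "dmrs"))
    .stageLog(verbose, "classify", "%d transformation DMRs removed; labels: %s",
              length(classified$removed$KO),
              paste(sprintf("%s/%s=%d", classified$summary$direction,
                            classified$summary$mechanism,
                            classified$summary$n), collapse = " "))

    geneDmr <- hypomethylatedPromoterGenes(comparisons$KO$dmrs, truth$genes,
                                           config$annotation)
    assigned <- assignGroups(geneDmr, expr, config$fcThreshold,
                             config$pThreshold, config$fpkmThreshold)
    .stageLog(verbose, "integrate", "%d promoter-hypomethylated genes: %s",
              nrow(assigned),
              paste(names(table(assigned$group)), table(assigned$group),
                    sep = "=", collapse = " "))

    recovery <- list(
        dmr = lapply(stats::setNames(nm = sim$genotypes), function(g)
            dmrRecovery(comparisons[[g]]$dmrs, truth, g)),
        setLogic = setLogicRecovery(classified, truth),
        gGroup = gGroupRecovery(assigned, truth, "KO"))

    manifest <- list(
        seed = sim$seed,
        parameters = list(simulation = sim[setdiff(names(sim), "regionSpec")],
                          caller = config$caller,
                          annotation = config$annotation),
        counts = list(
            cpgs_retained = nrow(mm),
            dmcs = lapply(comparisons, function(cp)
                table(factor(mcols(cp$dmcs)$direction,
                             c("hypo", "hyper"))) |> as.list()),
            dmrs = lapply(comparisons, function(cp)
                table(factor(mcols(cp$dmrs)$direction,
                             c("hypo", "hyper"))) |> as.list()),
            transformation_removed = length(classified$removed$KO),
            genes_assigned = nrow(assigned)))

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        files <- list()
        for (nm in names(meth$samples)) {
            f <- file.path(outdir, paste0(nm, ".bedGraph"))
            writeMethylBedGraph(meth$samples[[nm]], f)
            files[[paste0("sample_", nm)]] <- f
        }
        files$truth <- writeTruthTable(truth, file.path(outdir, "truth.tsv"))
        files$genes <- writeGeneTable(truth$genes,
                                      file.path(outdir, "genes.tsv"))
        files$expression <- writeExpressionTable(
            expr, file.path(outdir, "expression.tsv"))
        for (g in sim$genotypes) {
            f <- file.path(outdir, sprintf("dmrs_%s.bed", g))
            writeDmrBed(comparisons[[g]]$dmrs, f)
            files[[paste0("dmrs_", g)]] <- f
        }
        manifest$files <- files
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }

    list(truth = truth, matrix = mm, comparisons = comparisons,
         annotated = annotated, classified = classified,
         expression = expr, assigned = assigned, recovery = recovery,
         manifest = manifest)
}

#' Canonical test fixtures
#'
#' \code{tiny}: ~200 CpGs with 3 planted regions (one accessory-function
#' target, one catalytic target, one transformation region), for fast
#' exhaustive checks. \code{default}: ~50,000 CpGs with ~60 regions across
#' all categories, the scale used for recovery scoring.
#'
#' @param scale \code{"tiny"} or \code{"default"}
#' @param dir optional directory; when given, all fixture files are written
#'   there
#' @param seed seed forwarded to the simulation
#' @return the \code{\link{runPipeline}} result, invisibly carrying the
#'   fixture files when \code{dir} was given
#' @export
makeFixtures <- function(scale = c("tiny", "default"), dir = NULL,
                         seed = 1L) {
    scale <- match.arg(scale)
    sim <- if (scale == "tiny") {
        spec <- data.frame(
            category = c("af_target", "ca_target", "transformation"),
            delta = -0.4, nCpgs = 5L, count = 1L, stringsAsFactors = FALSE)
        simulationConfig(nCpgs = 200L, regionSpec = spec,
                         nBackgroundGenes = 2L, seed = seed)
    } else {
        simulationConfig(seed = seed)
    }
    runPipeline(pipelineConfig(simulation = sim), outdir = dir,
                verbose = FALSE)
}
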