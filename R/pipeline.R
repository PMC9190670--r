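#' @importFrom utils write.table
NULL

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(structure(class = c("pedmeth_stage_error", "error",
                                 "condition"),
                       list(message = paste0("stage '", name,
                                             "' failed: ",
                                             conditionMessage(e)),
                            call = NULL, stage = name))))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stage sequence preprocess, categorize, diffmeth, aberrant,
#' events, mutex on data generated by [simulateStudy()] (or a pre-built
#' study object), serializing intermediate tables under \code{outDir} and
#' returning an aggregate report. All randomness derives from
#' \code{config$seed}, so reruns with the same configuration are
#' reproducible.
#'
#' Stage notes: per-dataset gene categories are computed on the raw
#' (uncorrected) cohorts, since batch correction would remove exactly the
#' between-dataset signal the consistency analysis quantifies; the pooled
#' variance track, the differential models, and the aberration reference
#' all use the batch-corrected normal pool. Differential testing in the
#' pipeline runs at the gene level; probe-level contrasts are available by
#' calling [fitLinearDM()] on the probe matrices directly.
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory for serialized intermediates.
#' @param study optional pre-built [simulateStudy()] result (must match
#'   \code{config}); generated when NULL.
#' @param stages character vector of stages to run; prerequisite stages
#'   are always run.
#' @param thresholds a [categoryThresholds()] list.
#' @param windowBp promoter TSS window in bp.
#' @param alpha FDR threshold.
#' @param lfc absolute log2 fold-change gate.
#' @param zK aberration z-score threshold.
#' @param minEvents per-gene event filter for the mutual-exclusivity test.
#' @param nPermutations permutations for the mutual-exclusivity test.
#' @return a report list with one element per executed stage.
#' @export
runPipeline <- function(config = simulationConfig(),
                        outDir = tempfile("pedmeth_run"),
                        study = NULL,
                        stages = c("preprocess", "categorize", "diffmeth",
                                   "aberrant", "events", "mutex"),
                        thresholds = categoryThresholds(),
                        windowBp = 300L, alpha = 0.05, lfc = 2, zK = 3,
                        minEvents = 5L, nPermutations = 10000L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    report <- list(seed = config$seed, stages = stages)
    tsv <- function(d, name) {
        write.table(d, file.path(outDir, paste0(name, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (is.null(study))
        study <- .stage("simulate",
                        simulateStudy(config,
                                      file.path(outDir, "events")))

    ## ---- preprocess ----
    pp <- .stage("preprocess", {
        prom <- filterPromoterProbes(study$normals$annotation, windowBp)
        geneNormals <- lapply(study$normals$datasets, summarizeGeneLevel,
                              annotation = prom$annotation)
        combined <- Reduce(.combine_me, study$normals$datasets)
        combinedGenes <- Reduce(.combine_me, geneNormals)
        inv <- filterInvariantCategoryProbes(
            c(study$normals$datasets, list(study$tumors$tumors)),
            thresholds)
        pcaBefore <- pcaQC(combinedGenes)
        corrected <- batchCorrect(combinedGenes)
        pcaAfter <- pcaQC(corrected)
        tumorGenes <- summarizeGeneLevel(study$tumors$tumors,
                                         prom$annotation)
        list(promoter = prom, geneNormals = geneNormals,
             normalCorrected = corrected, tumorGenes = tumorGenes,
             invariantReport = inv$report,
             pcaBefore = pcaBefore, pcaAfter = pcaAfter)
    })
    report$preprocess <- list(
        promoter = unclass(pp$promoter$report)[1:3],
        invariant = unclass(pp$invariantReport)[1:3])

    ## ---- categorize ----
    if ("categorize" %in% stages) {
        ct <- .stage("categorize", {
            profs <- do.call(rbind, lapply(names(pp$geneNormals),
                function(d) categorizeDataset(pp$geneNormals[[d]], d,
                                              thresholds)))
            cons <- classifyConsistency(profs)
            info <- sampleInfo(pp$tumorGenes)
            tumorProfs <- do.call(rbind, lapply(
                unique(info$tumor_type), function(ty) {
                    sel <- rownames(info)[info$tumor_type == ty]
                    categorizeDataset(
                        methValues(pp$tumorGenes)[, sel, drop = FALSE],
                        ty, thresholds)
                }))
            normalModal <- vapply(split(profs$category, profs$gene),
                function(x) modalCategory(x)$category, character(1L))
            tumorModal <- vapply(split(tumorProfs$category,
                                       tumorProfs$gene),
                function(x) modalCategory(x)$category, character(1L))
            chg <- categoryChangeTable(normalModal, tumorModal)
            pooled <- categorizeDataset(pp$normalCorrected, "pooled",
                                        thresholds)
            hv <- highVarianceOverlap(
                profs, structure(pooled$variance == "high",
                                 names = pooled$gene))
            list(profiles = profs, tumorProfiles = tumorProfs,
                 consistency = cons, change = chg, highVar = hv)
        })
        tsv(ct$consistency, "consistency")
        tsv(ct$change$table, "category_changes")
        report$categorize <- list(
            consistency = consistencySummary(ct$consistency),
            n_changed = ct$change$n_changed,
            pct_level_increased = ct$change$pct_level_increased,
            high_variance_overlap = ct$highVar)
        report$categorize$recovery <- ct
    }

    ## ---- diffmeth ----
    if ("diffmeth" %in% stages) {
        dm <- .stage("diffmeth", {
            tvn <- tumorVsNormalDM(asM(pp$tumorGenes),
                                   asM(pp$normalCorrected),
                                   alpha = alpha, lfcThreshold = lfc)
            pw <- pairwiseTumorDM(asM(pp$tumorGenes),
                                  alpha = alpha, lfcThreshold = lfc)
            list(tumorVsNormal = tvn, pairwise = pw)
        })
        for (nm in names(dm$tumorVsNormal$results))
            tsv(volcanoTable(dm$tumorVsNormal$results[[nm]]),
                paste0("volcano_", nm))
        report$diffmeth <- list(
            n_significant_per_type = vapply(dm$tumorVsNormal$results,
                function(r) sum(r$significant), integer(1L)),
            n_significant_any_pair =
                sum(dm$pairwise$summary$significant_any_pair))
        report$diffmeth$detail <- dm
    }

    ## ---- aberrant ----
    ab <- .stage("aberrant", {
        ref <- buildNormalReference(pp$normalCorrected)
        calls <- callAberrations(pp$tumorGenes, ref, k = zK)
        props <- tumorAberrationProportions(calls)
        ems <- aberrationEventMatrices(calls)
        list(reference = ref, calls = calls, proportions = props,
             hyper = ems$hyper, hypo = ems$hypo)
    })
    tsv(ab$proportions, "aberration_proportions")
    report$aberrant <- list(
        mean_frac_hyper = mean(ab$proportions$frac_hyper),
        mean_frac_hypo = mean(ab$proportions$frac_hypo))
    report$aberrant$detail <- ab

    ## ---- events ----
    ev <- .stage("events", {
        recs <- do.call(rbind, lapply(names(study$events$vcf),
            function(s) readVcfMutations(study$events$vcf[[s]], s)))
        fus <- do.call(rbind, lapply(names(study$events$bedpe),
            function(s) readBedpeFusions(study$events$bedpe[[s]], s)))
        damaging <- filterDamaging(recs)
        mm <- buildMutationMatrix(damaging, fus,
                                  genes = study$events$genes,
                                  samples = names(study$events$vcf))
        combinedAb <- combineEventMatrices(
            EventMatrix(hits(ab$hyper)[study$events$genes, , drop = FALSE],
                        "hyper"),
            EventMatrix(hits(ab$hypo)[study$events$genes, , drop = FALSE],
                        "hypo"))
        info <- sampleInfo(study$tumors$tumors)
        freq <- eventFrequencySummary(
            mm, combinedAb,
            structure(info$tumor_type, names = rownames(info)))
        list(mutation = mm, aberrantCombined = combinedAb,
             frequency = freq)
    })
    report$events <- ev$frequency
    report$events$detail <- ev

    ## ---- mutex ----
    if ("mutex" %in% stages) {
        mx <- .stage("mutex", {
            genes <- filterTestableGenes(ev$mutation,
                                         ev$aberrantCombined, minEvents)
            if (length(genes) == 0L)
                stop("no testable genes")
            permutationTest(ev$mutation, ev$aberrantCombined, genes,
                            nPermutations = nPermutations,
                            seed = config$seed + 3L)
        })
        report$mutex <- list(
            n_genes_tested = mx@nGenesTested,
            observed = mx@observed,
            null_mean = mx@nullMean,
            empirical_p = mx@empiricalP)
        report$mutex$detail <- mx
    }

    json <- list(seed = report$seed,
                 preprocess = report$preprocess,
                 categorize = report$categorize[
                     setdiff(names(report$categorize), "recovery")],
                 diffmeth = report$diffmeth[
                     setdiff(names(report$diffmeth), "detail")],
                 aberrant = report$aberrant[
                     setdiff(names(report$aberrant), "detail")],
                 events = report$events[
                     setdiff(names(report$events), "detail")],
                 mutex = report$mutex[
                     setdiff(names(report$mutex), "detail")])
    jsonlite::write_json(json, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report$outDir <- outDir
    invisible(report)
}
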