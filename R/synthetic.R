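#' @importFrom stats rbinom rnorm runif
NULL

#' Configuration for the synthetic study generator
#'
#' The generator emulates the structure of a multi-cohort 450K promoter
#' methylation study: several normal datasets with per-gene methylation
#' archetypes and batch effects, tumor cohorts with planted hyper-/hypo-
#' methylation and optional type-specific differential genes, and
#' mutation/fusion events with a controllable relationship to the planted
#' methylation aberrations.
#'
#' Noise is generated on the M scale and mapped through the inverse logit
#' (logistic-normal), so beta values respect \[0, 1\]. Archetype noise
#' levels are stated on the beta scale for low-variance genes
#' (\code{noiseSD}) and as fixed M-scale spreads for high-variance genes,
#' calibrated so that the planted coefficient of variation falls on the
#' intended side of the 0.5 threshold. A high-level/high-variance archetype
#' is not generated by default: on the bounded beta scale a gene with
#' median above 0.6 cannot sustain a CV of 0.5, matching how rarely that
#' combination occurs in real arrays.
#'
#' @param nGenes number of genes.
#' @param probesPerGene promoter probes per gene.
#' @param nNormalDatasets number of normal cohorts (batches).
#' @param samplesPerDataset samples per normal cohort.
#' @param tumorTypes named integer vector, tumor type -> cohort size.
#' @param archetypeFractions named fractions over
#'   \code{"level/variance"} archetypes; must sum to 1.
#' @param noiseSD beta-scale within-dataset SD for low-variance genes.
#' @param batchShiftSD SD (M scale) of per-gene per-dataset batch shifts.
#' @param sexEffectFrac fraction of genes with a sex effect.
#' @param sexEffectSD SD (M scale) of sex effect sizes.
#' @param probeOffsetSD SD (M scale) of fixed per-probe offsets.
#' @param probeNoiseSD SD (M scale) of probe-level measurement noise.
#' @param fracHyper,fracHypo per-tumor fractions of genes planted hyper-/
#'   hypomethylated.
#' @param aberrationShiftSDUnits planted shift in normal-reference SDs.
#' @param tumorNoiseFrac tumor within-type gene-level noise as a fraction
#'   of the normal reference SD (a single tumor type is more homogeneous
#'   than the pooled multi-tissue normal reference).
#' @param nDMGenesPerType type-specific differentially methylated genes.
#' @param dmShiftM M-scale shift applied to those genes.
#' @param mutationRate per gene-by-tumor mutation probability.
#' @param fracNondamaging fraction of mutation events emitted with
#'   annotations that fail the damaging filter (these do not count as
#'   events).
#' @param fracFusion fraction of (damaging) events emitted as RNA fusions
#'   instead of SNVs.
#' @param cooccurrenceMode \code{"independent"}, \code{"exclusive"} or
#'   \code{"cooccurring"} placement of mutations relative to planted
#'   aberrant methylation.
#' @param seed RNG seed.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 2000L, probesPerGene = 2L,
                             nNormalDatasets = 4L, samplesPerDataset = 30L,
                             tumorTypes = c(wilms = 40L,
                                            neuroblastoma = 40L,
                                            osteosarcoma = 40L),
                             archetypeFractions = c("low/low" = 0.62,
                                                    "low/high" = 0.055,
                                                    "medium/low" = 0.115,
                                                    "medium/high" = 0.015,
                                                    "high/low" = 0.195),
                             noiseSD = 0.02, batchShiftSD = 0.15,
                             sexEffectFrac = 0.02, sexEffectSD = 0.5,
                             probeOffsetSD = 0.08, probeNoiseSD = 0.05,
                             fracHyper = 0.05, fracHypo = 0.10,
                             aberrationShiftSDUnits = 4,
                             tumorNoiseFrac = 0.25,
                             nDMGenesPerType = 0L, dmShiftM = 4,
                             mutationRate = 0.05, fracNondamaging = 0.3,
                             fracFusion = 0.1,
                             cooccurrenceMode = c("independent",
                                                  "exclusive",
                                                  "cooccurring"),
                             seed = 1L) {
    cooccurrenceMode <- match.arg(cooccurrenceMode)
    stopifnot(abs(sum(archetypeFractions) - 1) < 1e-8,
              all(archetypeFractions >= 0),
              all(names(archetypeFractions) %in% .CATEGORY_ORDER),
              fracHyper >= 0, fracHypo >= 0, fracHyper + fracHypo < 1,
              mutationRate >= 0, mutationRate <= 1,
              fracNondamaging >= 0, fracNondamaging <= 1,
              !is.null(names(tumorTypes)), all(tumorTypes >= 1L))
    cfg <- as.list(environment())
    class(cfg) <- "SimulationConfig"
    cfg
}

# fixed M-scale spreads realizing CV >= 0.5 per level band (see vignette)
.HIGHVAR_SIGMA <- c(low = 1.6, medium = 2.4, high = 2.4)
.LEVEL_BANDS <- list(low = c(0.05, 0.15), medium = c(0.32, 0.48),
                     high = c(0.65, 0.85))

.gene_model <- function(config) {
    arche <- sample(names(config$archetypeFractions), config$nGenes,
                    replace = TRUE, prob = config$archetypeFractions)
    level <- sub("/.*$", "", arche)
    varcat <- sub("^.*/", "", arche)
    baseline <- numeric(config$nGenes)
    for (lv in names(.LEVEL_BANDS)) {
        sel <- level == lv
        baseline[sel] <- runif(sum(sel), .LEVEL_BANDS[[lv]][1L],
                               .LEVEL_BANDS[[lv]][2L])
    }
    sigma <- ifelse(varcat == "high",
                    .HIGHVAR_SIGMA[level],
                    config$noiseSD / (log(2) * baseline * (1 - baseline)))
    sexGenes <- runif(config$nGenes) < config$sexEffectFrac
    sexEffect <- ifelse(sexGenes, rnorm(config$nGenes, 0,
                                        config$sexEffectSD), 0)
    genes <- sprintf("GENE%04d", seq_len(config$nGenes))
    list(genes = genes, archetype = arche, baseline_beta = baseline,
         sigma_m = unname(sigma), sex_effect_m = sexEffect)
}

.probe_model <- function(config, gm) {
    nP <- config$nGenes * config$probesPerGene
    probes <- sprintf("cg%07d", seq_len(nP))
    geneIdx <- rep(seq_len(config$nGenes), each = config$probesPerGene)
    tss <- runif(nP, 0, 500)
    tss[seq(1L, nP, by = config$probesPerGene)] <- runif(config$nGenes,
                                                         0, 300)
    offset <- rnorm(nP, 0, config$probeOffsetSD)
    list(probes = probes, gene_idx = geneIdx,
         annotation = data.frame(probe_id = probes,
                                 gene_symbol = gm$genes[geneIdx],
                                 tss_distance_bp = round(tss),
                                 stringsAsFactors = FALSE),
         offset = offset)
}

.probe_matrix <- function(config, gm, pm, geneM, sexMale) {
    # geneM: genes x samples gene-level M values; expand to probes
    m <- geneM[pm$gene_idx, , drop = FALSE] + pm$offset +
        matrix(rnorm(length(pm$probes) * ncol(geneM), 0,
                     config$probeNoiseSD),
               length(pm$probes), ncol(geneM))
    dimnames(m) <- list(pm$probes, colnames(geneM))
    clampBeta(mToBeta(m))
}

#' Simulate the normal cohorts
#'
#' Per gene, an archetype fixes a baseline beta regime and a variance
#' regime; datasets add per-gene batch shifts; samples add logistic-normal
#' noise shared across the gene's probes plus small probe-level measurement
#' noise; a random gene subset carries a sex effect.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{datasets} (named list of probe-level beta
#'   \linkS4class{MethylationExperiment}s), \code{annotation},
#'   \code{truth} (planted per-gene archetypes), \code{geneModel},
#'   \code{probeModel} and \code{reference} (pooled gene-level mean/SD of
#'   the generated data, used to scale planted tumor aberrations).
#' @export
simulateNormals <- function(config = simulationConfig()) {
    set.seed(config$seed)
    gm <- .gene_model(config)
    pm <- .probe_model(config, gm)
    baseM <- log2(gm$baseline_beta / (1 - gm$baseline_beta))
    datasets <- list()
    geneBetaAll <- NULL
    for (d in seq_len(config$nNormalDatasets)) {
        dsId <- sprintf("ND%d", d)
        n <- config$samplesPerDataset
        ids <- sprintf("%s_S%02d", dsId, seq_len(n))
        male <- rbinom(n, 1L, 0.5)
        batch <- rnorm(config$nGenes, 0, config$batchShiftSD)
        noise <- matrix(rnorm(config$nGenes * n), config$nGenes, n) *
            gm$sigma_m
        geneM <- baseM + batch + noise +
            outer(gm$sex_effect_m, male)
        colnames(geneM) <- ids
        beta <- .probe_matrix(config, gm, pm, geneM, male)
        md <- data.frame(sample_id = ids, dataset_id = dsId,
                         sex = ifelse(male == 1L, "male", "female"),
                         condition = "normal",
                         tumor_type = NA_character_,
                         stringsAsFactors = FALSE)
        datasets[[dsId]] <- MethylationExperiment(beta, "beta", md)
        gb <- clampBeta(mToBeta(geneM))
        rownames(gb) <- gm$genes
        geneBetaAll <- cbind(geneBetaAll, gb)
    }
    list(datasets = datasets,
         annotation = pm$annotation,
         truth = data.frame(gene = gm$genes, archetype = gm$archetype,
                            baseline_beta = gm$baseline_beta,
                            sigma_m = gm$sigma_m,
                            sex_effect_m = gm$sex_effect_m,
                            stringsAsFactors = FALSE),
         geneModel = gm, probeModel = pm,
         reference = data.frame(gene = gm$genes,
                                mean = rowMeans(geneBetaAll),
                                sd = apply(geneBetaAll, 1L, sd),
                                stringsAsFactors = FALSE))
}

#' Simulate the tumor cohorts with planted aberrations
#'
#' Tumors are drawn from the normal generative model (no batch shifts;
#' within-type noise is \code{tumorNoiseFrac} of the normal reference SD).
#' Per tumor, a random eligible gene subset is shifted by
#' \code{aberrationShiftSDUnits} reference SDs up (hyper) or down (hypo) on
#' the beta scale; a gene is eligible when the shifted value still fits
#' inside (0, 1), since a bounded scale cannot represent large SD shifts
#' for genes whose baseline variability already spans the range.
#' Optionally, \code{nDMGenesPerType} genes per tumor type receive a fixed
#' M-scale shift in every tumor of that type (type-specific differential
#' methylation).
#'
#' @param config a [simulationConfig()].
#' @param normals output of [simulateNormals()] under the same config.
#' @return list with \code{tumors} (probe-level beta
#'   \linkS4class{MethylationExperiment}, all types combined, metadata
#'   column \code{tumor_type}), \code{aberrationTruth} (data.frame: gene,
#'   sample, direction), \code{dmTruth} (data.frame: gene, tumor_type) and
#'   \code{eligible} (genes eligible for planting).
#' @export
simulateTumors <- function(config, normals) {
    set.seed(config$seed + 1L)
    gm <- normals$geneModel
    pm <- normals$probeModel
    ref <- normals$reference
    k <- config$aberrationShiftSDUnits
    eligUp <- ref$mean + (k + 0.5) * ref$sd < 0.98 & ref$sd > 0
    eligDn <- ref$mean - (k + 0.5) * ref$sd > 0.02 & ref$sd > 0
    nHyper <- round(config$fracHyper * config$nGenes)
    nHypo <- round(config$fracHypo * config$nGenes)
    if (sum(eligUp) < nHyper || sum(eligDn) < nHypo)
        stop("not enough eligible genes for the requested aberration ",
             "fractions")
    dmTruth <- NULL
    dmShift <- matrix(0, config$nGenes, length(config$tumorTypes),
                      dimnames = list(gm$genes, names(config$tumorTypes)))
    if (config$nDMGenesPerType > 0L) {
        lowVar <- grepl("/low$", gm$archetype)
        pool <- sample(which(lowVar))
        for (ti in seq_along(config$tumorTypes)) {
            pick <- pool[seq_len(config$nDMGenesPerType) +
                             (ti - 1L) * config$nDMGenesPerType]
            dmShift[pick, ti] <- config$dmShiftM
            dmTruth <- rbind(dmTruth, data.frame(
                gene = gm$genes[pick],
                tumor_type = names(config$tumorTypes)[ti],
                stringsAsFactors = FALSE))
        }
    }
    allBeta <- NULL
    md <- NULL
    abTruth <- list()
    for (ti in seq_along(config$tumorTypes)) {
        ty <- names(config$tumorTypes)[ti]
        n <- config$tumorTypes[[ti]]
        ids <- sprintf("%s_T%03d", toupper(substr(ty, 1L, 3L)),
                       seq_len(n))
        male <- rbinom(n, 1L, 0.5)
        geneM <- matrix(0, config$nGenes, n,
                        dimnames = list(gm$genes, ids))
        for (s in seq_len(n)) {
            center <- ref$mean
            hyperG <- sample(which(eligUp), nHyper)
            hypoG <- sample(setdiff(which(eligDn), hyperG), nHypo)
            center[hyperG] <- center[hyperG] + k * ref$sd[hyperG]
            center[hypoG] <- center[hypoG] - k * ref$sd[hypoG]
            val <- clampBeta(center + rnorm(config$nGenes) *
                                 config$tumorNoiseFrac * ref$sd)
            geneM[, s] <- log2(val / (1 - val)) + dmShift[, ti] +
                gm$sex_effect_m * male[s]
            if (nHyper + nHypo > 0L)
                abTruth[[length(abTruth) + 1L]] <- data.frame(
                    gene = gm$genes[c(hyperG, hypoG)],
                    sample = ids[s],
                    direction = rep(c("hyper", "hypo"),
                                    c(nHyper, nHypo)),
                    stringsAsFactors = FALSE)
        }
        beta <- .probe_matrix(config, gm, pm, geneM, male)
        allBeta <- cbind(allBeta, beta)
        md <- rbind(md, data.frame(
            sample_id = ids, dataset_id = paste0("TD_", ty),
            sex = ifelse(male == 1L, "male", "female"),
            condition = "tumor", tumor_type = ty,
            stringsAsFactors = FALSE))
    }
    list(tumors = MethylationExperiment(allBeta, "beta", md),
         aberrationTruth = if (length(abTruth))
             do.call(rbind, abTruth) else
                 data.frame(gene = character(), sample = character(),
                            direction = character()),
         dmTruth = dmTruth,
         genes = gm$genes,
         eligible = gm$genes[eligUp | eligDn])
}

.damaging_annotation <- function(n) {
    kind <- sample(3L, n, replace = TRUE)
    data.frame(
        impact = c("HIGH", "MODERATE", "MODERATE")[kind],
        sift = c(NA, "deleterious", NA)[kind],
        polyphen = c(NA, NA, "probably_damaging")[kind],
        stringsAsFactors = FALSE)
}

.benign_annotation <- function(n) {
    kind <- sample(3L, n, replace = TRUE)
    data.frame(
        impact = c("MODERATE", "LOW", "MODIFIER")[kind],
        sift = c("tolerated", NA, "tolerated")[kind],
        polyphen = c("benign", "benign", NA)[kind],
        stringsAsFactors = FALSE)
}

#' Simulate somatic-mutation and fusion events
#'
#' Mutation events are placed per gene-by-tumor with probability
#' \code{mutationRate}; under \code{exclusive} mode placement avoids pairs
#' where the gene is planted aberrantly methylated, under
#' \code{cooccurring} mode it is restricted to such pairs, and
#' \code{independent} ignores the methylation truth. A fraction of events
#' is emitted with benign annotations (these fail the damaging filter and
#' are excluded from the truth matrix); of the damaging events a fraction
#' is emitted as an RNA fusion with a random partner gene rather than an
#' SNV. Files are written through the package's own VCF/BEDPE writers so
#' the parsers are exercised end-to-end.
#'
#' @param config a [simulationConfig()].
#' @param tumors output of [simulateTumors()].
#' @param dir directory for per-sample VCF and BEDPE files.
#' @return list with \code{truth} (mutation \linkS4class{EventMatrix}
#'   implied by the damaging records and fusions), \code{vcf} and
#'   \code{bedpe} (named file vectors), \code{records}, \code{fusions}.
#' @export
simulateEvents <- function(config, tumors, dir = tempfile("events")) {
    set.seed(config$seed + 2L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    info <- sampleInfo(tumors$tumors)
    samples <- rownames(info)
    geneUniverse <- tumors$genes
    aberrant <- matrix(FALSE, length(geneUniverse), length(samples),
                       dimnames = list(geneUniverse, samples))
    at <- tumors$aberrationTruth
    at <- at[at$gene %in% geneUniverse, , drop = FALSE]
    aberrant[cbind(match(at$gene, geneUniverse),
                   match(at$sample, samples))] <- TRUE
    p <- matrix(config$mutationRate, length(geneUniverse),
                length(samples))
    if (config$cooccurrenceMode == "exclusive") p[aberrant] <- 0
    if (config$cooccurrenceMode == "cooccurring") {
        p[!aberrant] <- config$mutationRate * 0.1
        p[aberrant] <- pmin(1, config$mutationRate * 5)
    }
    ev <- matrix(runif(length(p)) < p, nrow(p), ncol(p),
                 dimnames = dimnames(aberrant))
    idx <- which(ev, arr.ind = TRUE)
    nEv <- nrow(idx)
    damaging <- runif(nEv) >= config$fracNondamaging
    asFusion <- damaging & runif(nEv) < config$fracFusion
    truth <- matrix(FALSE, nrow(ev), ncol(ev), dimnames = dimnames(ev))
    recs <- data.frame(sample_id = samples[idx[, 2L]],
                       gene_symbol = geneUniverse[idx[, 1L]],
                       stringsAsFactors = FALSE)
    snv <- which(damaging & !asFusion)
    ben <- which(!damaging)
    snvRecs <- cbind(recs[snv, , drop = FALSE],
                     .damaging_annotation(length(snv)))
    benRecs <- cbind(recs[ben, , drop = FALSE],
                     .benign_annotation(length(ben)))
    allRecs <- rbind(snvRecs, benRecs)
    fus <- which(asFusion)
    fusions <- data.frame(sample_id = recs$sample_id[fus],
                          gene_a = recs$gene_symbol[fus],
                          gene_b = sample(geneUniverse, length(fus),
                                          replace = TRUE),
                          stringsAsFactors = FALSE)
    same <- fusions$gene_a == fusions$gene_b
    if (any(same))  # re-draw partners colliding with the source gene
        fusions$gene_b[same] <- sample(
            setdiff(geneUniverse, fusions$gene_a[same])[
                seq_len(sum(same))], sum(same))
    truth[cbind(match(snvRecs$gene_symbol, geneUniverse),
                match(snvRecs$sample_id, samples))] <- TRUE
    truth[cbind(match(fusions$gene_a, geneUniverse),
                match(fusions$sample_id, samples))] <- TRUE
    truth[cbind(match(fusions$gene_b, geneUniverse),
                match(fusions$sample_id, samples))] <- TRUE
    vcfFiles <- bedpeFiles <- character(0)
    for (s in samples) {
        vf <- file.path(dir, paste0(s, ".vcf"))
        writeVcfMutations(allRecs[allRecs$sample_id == s, , drop = FALSE],
                          vf)
        bf <- file.path(dir, paste0(s, ".bedpe"))
        writeBedpeFusions(fusions[fusions$sample_id == s, , drop = FALSE],
                          bf)
        vcfFiles[s] <- vf
        bedpeFiles[s] <- bf
    }
    list(truth = EventMatrix(truth, "mutation"),
         vcf = vcfFiles, bedpe = bedpeFiles,
         records = allRecs, fusions = fusions,
         genes = geneUniverse)
}

#' Paired event matrices with fixed per-gene event counts
#'
#' Convenience generator for mutual-exclusivity calibration and power
#' studies: every gene gets exactly \code{nMut} mutation events and
#' \code{nMeth} methylation events across \code{nTumors} tumors, placed
#' independently, disjointly (\code{exclusive}) or preferentially together
#' (\code{cooccurring}).
#'
#' @param nGenes,nTumors matrix dimensions.
#' @param nMut,nMeth events per gene of each type.
#' @param mode placement mode.
#' @param seed RNG seed.
#' @return list with \code{mutation} and \code{methylation}
#'   \linkS4class{EventMatrix} objects.
#' @export
simulateEventPair <- function(nGenes = 20L, nTumors = 40L, nMut = 10L,
                              nMeth = 10L,
                              mode = c("independent", "exclusive",
                                       "cooccurring"),
                              seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(nMut + nMeth <= nTumors || mode != "exclusive")
    set.seed(seed)
    genes <- sprintf("G%03d", seq_len(nGenes))
    tumors <- sprintf("T%03d", seq_len(nTumors))
    mut <- meth <- matrix(FALSE, nGenes, nTumors,
                          dimnames = list(genes, tumors))
    for (g in seq_len(nGenes)) {
        mi <- sample.int(nTumors, nMut)
        mut[g, mi] <- TRUE
        if (mode == "cooccurring") {
            nIn <- min(nMeth, nMut)
            take <- sample(mi, nIn)
            if (nMeth > nIn)
                take <- c(take, sample(setdiff(seq_len(nTumors), mi),
                                       nMeth - nIn))
        } else {
            pool <- if (mode == "exclusive")
                setdiff(seq_len(nTumors), mi) else seq_len(nTumors)
            take <- sample(pool, nMeth)
        }
        meth[g, take] <- TRUE
    }
    list(mutation = EventMatrix(mut, "mutation"),
         methylation = EventMatrix(meth, "hyper"))
}

#' Simulate a complete study
#'
#' Runs [simulateNormals()], [simulateTumors()] and [simulateEvents()]
#' under one config.
#'
#' @param config a [simulationConfig()].
#' @param eventsDir directory for the VCF/BEDPE files.
#' @return list with components \code{config}, \code{normals},
#'   \code{tumors}, \code{events}.
#' @export
simulateStudy <- function(config = simulationConfig(),
                          eventsDir = tempfile("events")) {
    normals <- simulateNormals(config)
    tumors <- simulateTumors(config, normals)
    events <- simulateEvents(config, tumors, eventsDir)
    list(config = config, normals = normals, tumors = tumors,
         events = events)
}
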