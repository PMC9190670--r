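test_that("normal reference computes mean/SD and flags degenerates", {
    v <- matrix(c(0.1, 0.2, 0.3,
                  0.5, 0.5, 0.5), 2, 3, byrow = TRUE,
                dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
    expect_message(ref <- buildNormalReference(me_beta(v)),
                   "zero reference SD")
    expect_equal(ref$mean[ref$gene == "gA"], 0.2)
    expect_equal(ref$sd[ref$gene == "gA"], 0.1)
    expect_false(ref$callable[ref$gene == "gB"])

    one <- me_beta(v[, 1, drop = FALSE])
    expect_error(buildNormalReference(one), ">= 2")
})

test_that("z-score calls follow the strict three-SD rule", {
    ref <- data.frame(gene = c("gA", "gB"), mean = c(0.30, 0.5),
                      sd = c(0.05, 0), n_samples = 10,
                      callable = c(TRUE, FALSE))
    tv <- matrix(c(0.46, 0.44, 0.14,
                   0.99, 0.01, 0.50), 2, 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("t1", "t2", "t3")))
    calls <- callAberrations(me_beta(tv, condition = "tumor",
                                     tumor_type = "wilms"), ref)
    ga <- calls[calls$gene == "gA", ]
    expect_equal(ga$z, c(3.2, 2.8, -3.2), tolerance = 1e-12)
    expect_equal(ga$state, c("hyper", "none", "hypo"))
    # non-callable gene is never aberrant
    expect_true(all(calls$state[calls$gene == "gB"] == "none"))
    expect_true(all(is.na(calls$z[calls$gene == "gB"])))
    # no pair is both hyper and hypo by construction of the state machine
    expect_false(any(calls$state == "hyper" & calls$state == "hypo"))
})

test_that("aberration proportions are over callable genes and sum right", {
    calls <- data.frame(
        gene = rep(sprintf("g%03d", 1:100), 2),
        sample = rep(c("t1", "t2"), each = 100),
        z = 0,
        state = c(rep("hypo", 40), rep("none", 60),
                  rep("hyper", 100)),
        stringsAsFactors = FALSE)
    got <- tumorAberrationProportions(calls)
    expect_equal(got$frac_hypo[got$sample == "t1"], 0.40)
    expect_equal(got$frac_hyper[got$sample == "t2"], 1)
    expect_equal(got$frac_hypo[got$sample == "t2"], 0)
    expect_true(all(got$frac_hyper + got$frac_hypo <= 1))
})

test_that("tumors drawn from the normal distribution hit the Gaussian tail", {
    set.seed(21)
    G <- 20000
    ref <- data.frame(gene = sprintf("g%05d", 1:G), mean = 0.5,
                      sd = 0.03, n_samples = 100, callable = TRUE)
    tv <- matrix(rnorm(G, 0.5, 0.03), G, 1,
                 dimnames = list(ref$gene, "t1"))
    calls <- callAberrations(
        MethylationExperiment(pmin(pmax(tv, 0), 1), "beta"), ref)
    props <- tumorAberrationProportions(calls)
    # P(Z > 3) ~ 0.00135 each side
    expect_lt(abs(props$frac_hyper - pnorm(-3)), 3 * sqrt(pnorm(-3) / G))
    expect_lt(props$frac_hyper + props$frac_hypo, 0.01)
})

test_that("planted 4-SD shifts are recovered with low false calls", {
    cfg <- simulationConfig(nGenes = 400L, samplesPerDataset = 15L,
                            tumorTypes = c(wilms = 15L),
                            seed = 22)
    normals <- simulateNormals(cfg)
    tumors <- simulateTumors(cfg, normals)
    ann <- filterPromoterProbes(normals$annotation)$annotation
    geneN <- lapply(normals$datasets, summarizeGeneLevel,
                    annotation = ann)
    corr <- batchCorrect(Reduce(pedmeth:::.combine_me, geneN))
    ref <- buildNormalReference(corr)
    calls <- callAberrations(summarizeGeneLevel(tumors$tumors, ann), ref)
    truth <- tumors$aberrationTruth
    key <- paste(calls$gene, calls$sample)
    tkey <- paste(truth$gene, truth$sample)
    expect_gte(mean(calls$state[match(tkey, key)] == truth$direction),
               0.95)
    unplanted <- calls[!(key %in% tkey), ]
    expect_lte(mean(unplanted$state != "none"), 0.01)
})

test_that("class-stratified rates are exact counting", {
    genes <- c("ONC1", "ONC2", "TSG1", "AMB1", "OTH1")
    samples <- sprintf("t%d", 1:5)
    hyper <- matrix(FALSE, 5, 5, dimnames = list(genes, samples))
    hyper[c("ONC1", "ONC2"), c("t1", "t2")] <- TRUE  # leave 1 off
    hyper["ONC2", "t2"] <- FALSE
    hypo <- mutation <- matrix(FALSE, 5, 5,
                               dimnames = list(genes, samples))
    mutation["TSG1", "t1"] <- TRUE
    mutation["AMB1", ] <- TRUE   # ambiguous: must not leak anywhere
    tt <- structure(rep("wilms", 5), names = samples)
    got <- classStratifiedRates(EventMatrix(hyper, "hyper"),
                                EventMatrix(hypo, "hypo"),
                                EventMatrix(mutation, "mutation"),
                                tt, census_df())
    pick <- function(ev, cl)
        got$rate[got$event_type == ev & got$class == cl]
    expect_equal(pick("hyper", "oncogene"), 3 / 10)  # 2 onc x 5 tumors
    expect_equal(pick("mutation", "tsg"), 1 / 5)
    expect_equal(pick("mutation", "other"), 0)
    expect_equal(pick("hypo", "oncogene"), 0)
    # rows recompute from the raw matrices
    expect_equal(pick("hyper", "oncogene"),
                 sum(hyper[c("ONC1", "ONC2"), ]) / 10)

    # empty class reported as missing
    noTsg <- census_df()[census_df()$role != "tsg", ]
    got2 <- classStratifiedRates(EventMatrix(hyper, "hyper"),
                                 EventMatrix(hypo, "hypo"),
                                 EventMatrix(mutation, "mutation"),
                                 tt, noTsg)
    expect_true(all(is.na(got2$rate[got2$class == "tsg"])))
})

test_that("planted class-specific enrichment is recovered", {
    set.seed(23)
    nT <- 50; nG <- 200
    genes <- sprintf("g%03d", 1:nG)
    census <- data.frame(gene_symbol = genes[1:20], role = "oncogene",
                         tier = 1L)
    base <- 0.05
    p <- matrix(base, nG, nT, dimnames = list(genes,
                                              sprintf("t%02d", 1:nT)))
    p[1:20, ] <- base * 2                          # 2x in oncogenes
    hyper <- matrix(runif(nG * nT) < p, nG, nT,
                    dimnames = dimnames(p))
    none <- matrix(FALSE, nG, nT, dimnames = dimnames(p))
    tt <- structure(rep("wilms", nT), names = colnames(p))
    got <- classStratifiedRates(EventMatrix(hyper, "hyper"),
                                EventMatrix(none, "hypo"),
                                EventMatrix(none, "mutation"),
                                tt, census)
    ratio <- got$rate[got$event_type == "hyper" &
                          got$class == "oncogene"] /
        got$rate[got$event_type == "hyper" & got$class == "other"]
    expect_lt(abs(ratio - 2) / 2, 0.2)
})

test_that("oncogene vs TSG mean-M test is one-sided the right way", {
    set.seed(24)
    mk <- function(shift) {
        g <- c(sprintf("ONC%02d", 1:10), sprintf("TSG%02d", 1:10))
        v <- matrix(rnorm(20 * 12, 0, 0.5), 20, 12,
                    dimnames = list(g, sprintf("s%02d", 1:12)))
        v[1:10, ] <- v[1:10, ] + shift
        MethylationExperiment(v, "M")
    }
    census <- data.frame(
        gene_symbol = c(sprintf("ONC%02d", 1:10), sprintf("TSG%02d", 1:10)),
        role = rep(c("oncogene", "tsg"), each = 10), tier = 1L)
    up <- compareOncTsgMeanM(mk(2), census)
    expect_lt(up$p_value, 0.01)
    expect_gt(up$mean_oncogene, up$mean_tsg)
    down <- compareOncTsgMeanM(mk(-2), census)
    expect_gt(down$p_value, 0.5)
    # null: one-sided p averages near 0.5
    ps <- replicate(30, compareOncTsgMeanM(mk(0), census)$p_value)
    expect_lt(abs(mean(ps) - 0.5), 0.2)
})
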