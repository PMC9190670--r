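test_that("beta/M transforms hit their reference points and invert", {
    expect_equal(betaToM(0.5), 0)
    expect_equal(betaToM(0.8), 2)
    expect_equal(betaToM(0.2), -2)
    expect_equal(mToBeta(0), 0.5)
    expect_equal(mToBeta(2), 0.8)

    set.seed(1)
    x <- runif(1000, 1e-6, 1 - 1e-6)
    expect_lt(max(abs(mToBeta(betaToM(x)) - x)), 1e-12)

    # strictly increasing
    xs <- sort(runif(200))
    expect_true(all(diff(betaToM(xs)) > 0))

    # clamping makes the boundary safe
    expect_true(all(is.finite(betaToM(c(0, 1)))))
})

test_that("promoter filter is inclusive at the window boundary", {
    ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                      gene_symbol = "G1",
                      tss_distance_bp = c(250L, 350L, 300L))
    got <- filterPromoterProbes(ann, 300L)
    expect_setequal(got$annotation$probe_id, c("p1", "p3"))
    expect_equal(got$report$n_features_in, 3L)
    expect_equal(got$report$n_features_out, 2L)
    expect_equal(got$report$removed_ids, "p2")
})

test_that("gene-level summarization averages probes per gene", {
    v <- matrix(c(0.2, 0.4, 0.9,
                  0.1, 0.2, 0.6), 3, 2,
                dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
    ann <- data.frame(probe_id = c("p1", "p2", "p3", "p1"),
                      gene_symbol = c("G1", "G1", "G2", "G3"),
                      tss_distance_bp = 0L)
    g <- methValues(summarizeGeneLevel(me_beta(v), ann))
    expect_equal(g["G1", "s1"], 0.3)
    expect_equal(g["G1", "s2"], 0.15)
    expect_equal(g["G2", ], v["p3", ])          # single probe: identity
    expect_equal(g["G3", ], v["p1", ])          # multi-gene probe reused
    expect_equal(mean(c(0.1, 0.2, 0.6)), 0.3)   # three-probe reference
})

test_that("promoter filter and summarization commute with subsetting", {
    sim <- simulateNormals(simulationConfig(nGenes = 40L,
                                            samplesPerDataset = 6L,
                                            seed = 5))
    me <- sim$datasets[[1L]]
    ann <- filterPromoterProbes(sim$annotation)$annotation
    full <- summarizeGeneLevel(me, ann)
    sub <- me[, 1:3]
    expect_equal(methValues(summarizeGeneLevel(sub, ann)),
                 methValues(full)[, 1:3])
})

test_that("invariant-category probes are flagged, straddlers kept", {
    v1 <- matrix(c(0.05, 0.10, 0.15,   # all low
                   0.10, 0.70, 0.12,   # one high
                   0.18, 0.22, 0.19),  # straddles 0.2
                 3, 3, byrow = TRUE,
                 dimnames = list(c("pA", "pB", "pC"),
                                 c("s1", "s2", "s3")))
    v2 <- v1
    v2[, 1] <- c(0.02, 0.5, 0.3)       # second matrix differs for pB/pC
    got <- filterInvariantCategoryProbes(list(me_beta(v1),
                                              me_beta(v2, dataset = "D2")))
    expect_equal(got$report$removed_ids, "pA")
    expect_setequal(got$keep, c("pB", "pC"))
})

test_that("expression-correlation filter keeps correlated probes", {
    set.seed(2)
    n <- 20
    e <- rnorm(n)
    v <- rbind(corr = -2 * e + rnorm(n, 0, 0.01),  # near-perfect, negative
               flat = rnorm(n))
    colnames(v) <- sprintf("t%02d", seq_len(n))
    rownames(v) <- c("p1", "p2")
    expr <- rbind(G1 = e, G2 = rep(1, n), G3 = e)
    colnames(expr) <- colnames(v)
    ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                      gene_symbol = c("G1", "G2", "G1"),
                      tss_distance_bp = 0L)
    me <- MethylationExperiment(v, "M")
    got <- filterExpressionCorrelatedProbes(me, expr, ann)
    expect_true("p1" %in% got$keep)          # anticorrelated: retained
    expect_false("p2" %in% got$keep)         # constant expression: removed

    # probe whose gene lacks expression is removed and counted
    v2 <- rbind(v, orphan = rnorm(n))
    rownames(v2)[3] <- "p9"
    got2 <- filterExpressionCorrelatedProbes(
        MethylationExperiment(v2, "M"), expr,
        rbind(ann, data.frame(probe_id = "p9", gene_symbol = "NOPE",
                              tss_distance_bp = 0L)))
    expect_false("p9" %in% got2$keep)
    expect_equal(got2$report$n_no_expression, 1L)
})

test_that("single-pair correlation test holds its nominal type-I rate", {
    set.seed(3)
    n <- 15
    hits <- replicate(2000, {
        suppressWarnings(cor.test(rnorm(n), rnorm(n),
                                  method = "spearman",
                                  exact = FALSE)$p.value) < 0.05
    })
    expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("cross-normal divergent probes are excluded, stable ones kept", {
    set.seed(4)
    n <- 12
    mk <- function(shift, ds) {
        v <- rbind(div = rnorm(n, shift, 0.3),
                   stable = rnorm(n, 1, 0.3),
                   noisy = rnorm(n, shift * 0.5, 6))
        colnames(v) <- sprintf("%s_s%02d", ds, seq_len(n))
        v
    }
    v <- cbind(mk(0, "A"), mk(4, "B"))
    md <- rbind(sample_meta(colnames(v)[1:n], "A"),
                sample_meta(colnames(v)[n + 1:n], "B"))
    got <- filterCrossNormalDivergentProbes(
        MethylationExperiment(v, "M", md))
    expect_true("div" %in% got$report$removed_ids)
    expect_true("stable" %in% got$keep)
    # large shift but huge variance: fails the FDR gate, kept
    expect_true("noisy" %in% got$keep)
})

test_that("batch correction removes planted shifts and keeps range", {
    set.seed(5)
    G <- 200; n <- 50
    base <- runif(G, -3, 1)
    m1 <- base + matrix(rnorm(G * n, 0, 0.3), G, n)
    m2 <- base + 0.5 + matrix(rnorm(G * n, 0, 0.3), G, n)
    v <- mToBeta(cbind(m1, m2))
    dimnames(v) <- list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:(2 * n)))
    md <- rbind(sample_meta(colnames(v)[1:n], "B1"),
                sample_meta(colnames(v)[n + 1:n], "B2"))
    me <- MethylationExperiment(v, "beta", md)
    corr <- batchCorrect(me)
    cm <- betaToM(methValues(corr))
    gap <- abs(rowMeans(cm[, 1:n]) - rowMeans(cm[, n + 1:n]))
    expect_lt(mean(gap), 0.05)
    expect_true(all(methValues(corr) > 0 & methValues(corr) < 1))

    # identity contract when disabled; hard error on singleton batches
    expect_identical(batchCorrect(me, enabled = FALSE), me)
    mdBad <- md; mdBad$dataset_id[1] <- "B3"
    expect_error(batchCorrect(MethylationExperiment(v, "beta", mdBad)),
                 "batch of size 1")

    # non-EB adjustment preserves per-feature grand means exactly
    noEB <- betaToM(methValues(batchCorrect(me, eb = FALSE)))
    expect_lt(max(abs(rowMeans(noEB) - rowMeans(betaToM(v)))), 1e-6)
    expect_lt(max(abs(rowMeans(cm) - rowMeans(betaToM(v)))), 0.05)
})

test_that("batch adjustment agrees with the sva reference implementation", {
    skip_if_not_installed("sva")
    set.seed(6)
    v <- matrix(runif(150 * 30, 0.05, 0.95), 150, 30,
                dimnames = list(sprintf("g%03d", 1:150),
                                sprintf("s%02d", 1:30)))
    batch <- rep(c("B1", "B2", "B3"), each = 10)
    md <- sample_meta(colnames(v), dataset = batch)
    mine <- betaToM(methValues(batchCorrect(
        MethylationExperiment(v, "beta", md))))
    theirs <- suppressMessages(
        sva::ComBat(betaToM(v), batch = batch))
    expect_lt(max(abs(mine - theirs)), 1e-8)
})

test_that("PCA separates planted batches before correction, not after", {
    set.seed(7)
    G <- 300; n <- 25
    base <- runif(G, -2, 2)
    m1 <- base + matrix(rnorm(G * n, 0, 0.2), G, n)
    m2 <- base + rnorm(G, 0, 1.5) + matrix(rnorm(G * n, 0, 0.2), G, n)
    v <- mToBeta(cbind(m1, m2))
    dimnames(v) <- list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:(2 * n)))
    md <- rbind(sample_meta(colnames(v)[1:n], "B1"),
                sample_meta(colnames(v)[n + 1:n], "B2"))
    me <- MethylationExperiment(v, "beta", md)
    sepStat <- function(p) {
        g <- split(p$PC1, p$dataset_id)
        abs(mean(g[[1]]) - mean(g[[2]])) / mean(sapply(g, sd))
    }
    before <- sepStat(pcaQC(me))
    after <- sepStat(pcaQC(batchCorrect(me)))
    expect_gt(before, 3)
    expect_lt(after, before / 2)

    const <- MethylationExperiment(matrix(0.5, 4, 3,
        dimnames = list(letters[1:4], c("s1", "s2", "s3"))), "beta")
    expect_true(all(pcaQC(const)$PC1 == 0))
})

test_that("chained filter reports stay consistent", {
    sim <- simulateNormals(simulationConfig(nGenes = 30L,
                                            samplesPerDataset = 5L,
                                            seed = 8))
    r1 <- filterPromoterProbes(sim$annotation)
    kept <- r1$annotation
    r2 <- filterPromoterProbes(kept, 200L)
    expect_equal(r2$report$n_features_in, r1$report$n_features_out)
    expect_equal(r1$report$n_features_out,
                 r1$report$n_features_in - length(r1$report$removed_ids))
})
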