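test_that("BH adjustment equals the brute-force step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
    expect_equal(bhAdjust(0.3), 0.3)

    set.seed(11)
    for (i in 1:50) {
        p <- runif(sample(2:80, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
        # monotone in the raw p-values
        o <- order(p)
        expect_true(all(diff(adj[o]) >= -1e-15))
    }
})

test_that("moderated t matches limma and collapses to OLS without prior", {
    skip_if_not_installed("limma")
    set.seed(12)
    G <- 300; n <- 16
    s2 <- 1 / rgamma(G, 4, 1)
    Y <- matrix(rnorm(G * n, 0, sqrt(s2)), G, n,
                dimnames = list(sprintf("f%03d", 1:G),
                                sprintf("s%02d", 1:n)))
    grp <- rep(c(1, 0), each = 8)
    sex <- rep(c("male", "female"), 8)
    Y[, grp == 1] <- Y[, grp == 1] + rnorm(G)
    me <- MethylationExperiment(Y, "M",
                                sample_meta(colnames(Y), sex = sex))
    res <- fitLinearDM(me, colnames(Y)[grp == 1], colnames(Y)[grp == 0])
    fit <- limma::eBayes(limma::lmFit(
        Y, cbind(1, grp, as.numeric(sex == "male"))))
    expect_equal(res$t_stat, unname(fit$t[, 2]), tolerance = 1e-10)
    expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-10)
    expect_equal(attr(res, "df_prior"), fit$df.prior, tolerance = 1e-8)

    # d0 = 0 limit: plain OLS t
    res0 <- fitLinearDM(me, colnames(Y)[grp == 1], colnames(Y)[grp == 0],
                        moderated = FALSE)
    i <- c(3, 57, 200)
    tref <- vapply(i, function(k)
        summary(lm(Y[k, ] ~ grp + I(sex == "male")))$coefficients[2, 3],
        numeric(1))
    expect_equal(res0$t_stat[i], tref, tolerance = 1e-10)
})

test_that("planted shifts are detected and nulls stay quiet", {
    set.seed(13)
    G <- 400; n <- 40
    Y <- matrix(rnorm(G * n, 0, 0.5), G, n,
                dimnames = list(sprintf("f%03d", 1:G),
                                sprintf("s%02d", 1:n)))
    Y[1:40, 1:20] <- Y[1:40, 1:20] + 4    # planted 4 M-unit shift
    me <- MethylationExperiment(Y, "M", sample_meta(colnames(Y)))
    res <- fitLinearDM(me, colnames(Y)[1:20], colnames(Y)[21:40])
    expect_gte(mean(res$significant[1:40]), 0.95)
    expect_lte(sum(res$significant[-(1:40)]), 2)
    # significance flag is exactly the fdr/lfc conjunction
    expect_identical(res$significant,
                     !is.na(res$fdr) & res$fdr < 0.05 &
                         abs(res$log2_fc) >= 2)
})

test_that("unknown-sex samples are dropped and sex effects absorbed", {
    set.seed(14)
    G <- 200; n <- 40
    sex <- rep(c("male", "female"), each = 20)
    ids <- sprintf("s%02d", 1:n)
    # group labels correlated with sex (15/5 vs 5/15); effect is pure sex
    groupA <- c(ids[1:15], ids[21:25])
    groupB <- setdiff(ids, groupA)
    Y <- matrix(rnorm(G * n, 0, 0.5), G, n,
                dimnames = list(sprintf("f%03d", 1:G), ids))
    Y[, sex == "male"] <- Y[, sex == "male"] + 2
    me <- MethylationExperiment(Y, "M", sample_meta(ids, sex = sex))
    res <- fitLinearDM(me, groupA, groupB)
    # with sex in the model, the group coefficient carries no effect
    expect_lt(abs(mean(res$log2_fc)), 0.1)
    expect_lt(mean(abs(res$t_stat) > 3), 0.02)

    sexU <- sex; sexU[1:4] <- "unknown"
    meU <- MethylationExperiment(Y, "M", sample_meta(ids, sex = sexU))
    expect_message(resU <- fitLinearDM(meU, groupA, groupB),
                   "4 sample")
    expect_equal(attr(resU, "n_dropped_unknown_sex"), 4L)
})

test_that("per-type contrasts flag the planted types only", {
    set.seed(15)
    G <- 150; nPer <- 12
    types <- c("wilms", "neuroblastoma", "osteosarcoma")
    ids <- unlist(lapply(types, function(t)
        sprintf("%s_%02d", t, 1:nPer)))
    Y <- matrix(rnorm(G * length(ids), 0, 0.5), G, length(ids),
                dimnames = list(sprintf("g%03d", 1:G), ids))
    ty <- rep(types, each = nPer)
    Y[1, ty == "wilms"] <- Y[1, ty == "wilms"] + 4          # 1 type
    Y[2, ty != "osteosarcoma"] <- Y[2, ty != "osteosarcoma"] + 4  # 2 types
    mdT <- data.frame(sample_id = ids, dataset_id = "T",
                      sex = rep(c("male", "female"), length.out =
                                    length(ids)),
                      condition = "tumor", tumor_type = ty,
                      stringsAsFactors = FALSE)
    tum <- MethylationExperiment(Y, "M", mdT)
    nIds <- sprintf("n%02d", 1:20)
    Nv <- matrix(rnorm(G * 20, 0, 0.5), G, 20,
                 dimnames = list(rownames(Y), nIds))
    nor <- MethylationExperiment(Nv, "M", sample_meta(nIds, "ND"))
    got <- tumorVsNormalDM(tum, nor)
    expect_true(got$results$wilms$significant[1])
    expect_false(got$results$neuroblastoma$significant[1])
    expect_equal(got$flags$n_types_significant[1], 1)
    expect_equal(got$flags$n_types_significant[2], 2)
    expect_lte(median(got$flags$n_types_significant[-(1:2)]), 0)
})

test_that("pairwise contrasts cover all pairs and find separators", {
    set.seed(16)
    G <- 100; nPer <- 12
    types <- c("a", "b", "c", "d", "e")
    ids <- unlist(lapply(types, function(t) sprintf("%s%02d", t, 1:nPer)))
    ty <- rep(types, each = nPer)
    Y <- matrix(rnorm(G * length(ids), 0, 0.5), G, length(ids),
                dimnames = list(sprintf("g%03d", 1:G), ids))
    Y[1, ty == "e"] <- Y[1, ty == "e"] + 4   # one type vs all others
    md <- data.frame(sample_id = ids, dataset_id = "T",
                     sex = rep(c("male", "female"),
                               length.out = length(ids)),
                     condition = "tumor", tumor_type = ty,
                     stringsAsFactors = FALSE)
    got <- pairwiseTumorDM(MethylationExperiment(Y, "M", md))
    expect_length(got$results, choose(5, 2))
    sigPairs <- vapply(got$results, function(r) r$significant[1],
                       logical(1))
    expect_equal(sum(sigPairs), 4L)
    expect_true(got$summary$significant_any_pair[1])
    expect_match(got$summary$max_abs_pair[1], "e")
})

test_that("volcano table is a pure transformation", {
    res <- data.frame(feature_id = c("a", "b"), contrast = "x",
                      log2_fc = c(3, -1), t_stat = c(5, -1),
                      p_value = c(0.001, 0.5), fdr = c(0.01, 1),
                      significant = c(TRUE, FALSE))
    v <- volcanoTable(res)
    expect_equal(v$neg_log10_fdr, c(2, 0))
    expect_equal(nrow(volcanoTable(res[0, ])), 0L)
})
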