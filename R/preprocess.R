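#' @importFrom stats cor.test median prcomp sd var
NULL

.BETA_EPS <- 1e-6

.filter_report <- function(stage, idsIn, idsOut, extra = list()) {
    removed <- setdiff(idsIn, idsOut)
    out <- c(list(stage_name = stage,
                  n_features_in = length(idsIn),
                  n_features_out = length(idsOut),
                  removed_ids = removed), extra)
    stopifnot(out$n_features_out == out$n_features_in - length(removed))
    class(out) <- "FilterReport"
    out
}

#' @export
print.FilterReport <- function(x, ...) {
    cat("FilterReport [", x$stage_name, "]: ", x$n_features_in, " -> ",
        x$n_features_out, " features (", length(x$removed_ids),
        " removed)\n", sep = "")
    invisible(x)
}

#' Clamp beta values away from 0 and 1
#'
#' The logit transform is undefined at exactly 0 or 1; values are clamped
#' into \code{[eps, 1 - eps]} first.
#'
#' @param beta numeric vector or matrix of beta values.
#' @param eps clamp width (default \code{1e-6}).
#' @return clamped values, same shape.
#' @export
clampBeta <- function(beta, eps = .BETA_EPS) {
    pmin(pmax(beta, eps), 1 - eps)
}

#' Beta to M-value transform
#'
#' \code{M = log2(beta / (1 - beta))}, applied elementwise after clamping.
#' M-values are the variance-stabilized scale used for linear modelling.
#'
#' @param beta beta values (vector or matrix).
#' @param eps clamp width.
#' @return M-values, same shape.
#' @examples
#' betaToM(c(0.2, 0.5, 0.8))   # -2, 0, 2
#' @export
betaToM <- function(beta, eps = .BETA_EPS) {
    b <- clampBeta(beta, eps)
    log2(b / (1 - b))
}

#' M-value to beta transform (inverse logit, base 2)
#'
#' Exact inverse of [betaToM()] on the clamped domain.
#'
#' @param m M-values.
#' @return beta values in (0, 1), same shape.
#' @export
mToBeta <- function(m) {
    1 / (1 + 2^(-m))
}

#' Convert a MethylationExperiment to the M scale
#' @param x a \linkS4class{MethylationExperiment}.
#' @return the object on the M scale (identity if already M).
#' @export
setMethod("asM", "MethylationExperiment", function(x) {
    if (methScale(x) == "M") return(x)
    MethylationExperiment(betaToM(methValues(x)), "M", sampleInfo(x))
})

#' Convert a MethylationExperiment to the beta scale
#' @param x a \linkS4class{MethylationExperiment}.
#' @return the object on the beta scale (identity if already beta).
#' @export
setMethod("asBeta", "MethylationExperiment", function(x) {
    if (methScale(x) == "beta") return(x)
    MethylationExperiment(mToBeta(methValues(x)), "beta", sampleInfo(x))
})

#' Keep promoter probes (within a TSS window)
#'
#' Restricts the probe annotation to (probe, gene) pairs whose distance to
#' the nearest transcription start site is at most \code{windowBp}
#' (inclusive).
#'
#' @param annotation data.frame from [readProbeAnnotation()].
#' @param windowBp window size in base pairs (default 300).
#' @return list with \code{annotation} (filtered) and \code{report}
#'   (a FilterReport over distinct probe ids).
#' @export
filterPromoterProbes <- function(annotation, windowBp = 300L) {
    keep <- annotation$tss_distance_bp <= windowBp
    out <- annotation[keep, , drop = FALSE]
    list(annotation = out,
         report = .filter_report("promoter_window",
                                 unique(annotation$probe_id),
                                 unique(out$probe_id)))
}

#' Summarize a probe-level matrix to gene level
#'
#' Per gene and sample, the value is the arithmetic mean of the gene's
#' probes. Probes mapping to several genes contribute to each gene
#' independently; genes without any probe in the matrix are absent from the
#' output.
#'
#' @param x probe-level \linkS4class{MethylationExperiment}.
#' @param annotation data.frame of (probe_id, gene_symbol) pairs.
#' @return gene-level \linkS4class{MethylationExperiment} (same scale and
#'   sample metadata).
#' @export
summarizeGeneLevel <- function(x, annotation) {
    v <- methValues(x)
    ann <- annotation[annotation$probe_id %in% rownames(v), , drop = FALSE]
    if (nrow(ann) == 0L) stop("no annotated probes present in the matrix")
    m <- v[ann$probe_id, , drop = FALSE]
    sums <- rowsum(m, group = ann$gene_symbol)
    n <- as.vector(rowsum(rep(1, nrow(ann)), group = ann$gene_symbol))
    g <- sums / n
    MethylationExperiment(g, methScale(x), sampleInfo(x))
}

.level_category <- function(beta, low = 0.2, high = 0.6) {
    ifelse(beta < low, "low", ifelse(beta > high, "high", "medium"))
}

#' Flag probes whose per-sample level category never varies
#'
#' A probe is invariant when the level category (low/medium/high by the
#' 0.2/0.6 beta thresholds, applied to each individual sample value) is
#' identical for every sample of every supplied matrix. Such probes carry no
#' category information and are excluded before statistical testing.
#'
#' @param matrices list of beta-scale \linkS4class{MethylationExperiment}
#'   objects sharing feature ids (normal and tumor cohorts).
#' @param thresholds a [categoryThresholds()] list.
#' @return list with \code{keep} (retained probe ids) and \code{report}.
#' @export
filterInvariantCategoryProbes <- function(matrices,
                                          thresholds = categoryThresholds()) {
    stopifnot(length(matrices) >= 1L)
    ids <- rownames(methValues(matrices[[1L]]))
    for (m in matrices)
        stopifnot(identical(rownames(methValues(m)), ids))
    first <- NULL
    invariant <- rep(TRUE, length(ids))
    for (m in matrices) {
        stopifnot(methScale(m) == "beta")
        cat_m <- .level_category(methValues(m),
                                 thresholds$low_max_median,
                                 thresholds$high_min_median)
        if (is.null(first)) first <- cat_m[, 1L]
        invariant <- invariant & rowSums(cat_m != first) == 0L
    }
    keep <- ids[!invariant]
    list(keep = keep,
         report = .filter_report("invariant_category", ids, keep))
}

#' Retain probes whose methylation correlates with tumor expression
#'
#' Per probe, Spearman correlation between the probe's M-values and its
#' gene's expression across the tumor samples shared by both matrices.
#' Probes with a Benjamini-Hochberg-adjusted p below \code{alpha} (either
#' correlation sign) are retained; probes whose gene lacks expression data,
#' or whose correlation is undefined (constant vector), are removed and
#' counted separately in the report.
#'
#' @param meth probe-level M-scale \linkS4class{MethylationExperiment}
#'   (tumor samples).
#' @param expr numeric genes x samples expression matrix.
#' @param annotation (probe_id, gene_symbol) data.frame; for multi-gene
#'   probes the first mapping is used.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return list with \code{keep} (retained probe ids) and \code{report}
#'   (with \code{n_no_expression} in the extras).
#' @export
filterExpressionCorrelatedProbes <- function(meth, expr, annotation,
                                             alpha = 0.05) {
    stopifnot(methScale(meth) == "M")
    v <- methValues(meth)
    shared <- intersect(colnames(v), colnames(expr))
    if (length(shared) < 3L)
        stop("need at least 3 shared tumor samples")
    v <- v[, shared, drop = FALSE]
    expr <- expr[, shared, drop = FALSE]
    gene <- annotation$gene_symbol[match(rownames(v), annotation$probe_id)]
    hasExpr <- !is.na(gene) & gene %in% rownames(expr)
    p <- rep(NA_real_, nrow(v))
    for (i in which(hasExpr)) {
        e <- expr[gene[i], ]
        if (sd(e) == 0 || sd(v[i, ]) == 0) next
        p[i] <- suppressWarnings(
            cor.test(v[i, ], e, method = "spearman",
                     exact = FALSE)$p.value)
    }
    adj <- rep(NA_real_, length(p))
    adj[!is.na(p)] <- bhAdjust(p[!is.na(p)])
    keep <- rownames(v)[!is.na(adj) & adj < alpha]
    list(keep = keep,
         report = .filter_report("expression_correlation", rownames(v),
                                 keep,
                                 list(n_no_expression = sum(!hasExpr))))
}

#' Exclude probes divergent between any pair of normal datasets
#'
#' For every pair of normal datasets, fits the per-probe moderated linear
#' model of [fitLinearDM()] (sex as covariate) on the M scale; probes with
#' BH-adjusted p below \code{alpha} and absolute log2 fold-change at least
#' \code{lfc} in any pair are excluded. These probes differ systematically
#' between supposedly equivalent baselines and would contaminate
#' tumor-versus-normal contrasts.
#'
#' @param normals M-scale \linkS4class{MethylationExperiment} combining all
#'   normal datasets, with \code{dataset_id} and \code{sex} in the metadata.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 2).
#' @return list with \code{keep} (retained probe ids) and \code{report}.
#' @export
filterCrossNormalDivergentProbes <- function(normals, alpha = 0.05,
                                             lfc = 2) {
    stopifnot(methScale(normals) == "M")
    info <- sampleInfo(normals)
    ds <- unique(info$dataset_id)
    if (length(ds) < 2L) stop("need at least 2 normal datasets")
    ids <- rownames(methValues(normals))
    divergent <- rep(FALSE, length(ids))
    for (i in seq_len(length(ds) - 1L)) for (j in seq(i + 1L, length(ds))) {
        a <- rownames(info)[info$dataset_id == ds[i]]
        b <- rownames(info)[info$dataset_id == ds[j]]
        res <- fitLinearDM(normals, groupA = a, groupB = b,
                           alpha = alpha, lfcThreshold = lfc)
        divergent <- divergent | res$significant
    }
    keep <- ids[!divergent]
    list(keep = keep,
         report = .filter_report("cross_normal_divergent", ids, keep))
}

.trigamma_inverse <- function(x) {
    out <- x
    hi <- !is.na(x) & x > 1e7
    lo <- !is.na(x) & x < 1e-6
    out[hi] <- 1 / sqrt(x[hi])
    out[lo] <- 1 / x[lo]
    mid <- !is.na(x) & !hi & !lo
    y <- 0.5 + 1 / x[mid]
    for (iter in 1:60) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2L)
        y <- y + dif
        if (max(-dif / y, na.rm = TRUE) < 1e-8) break
    }
    out[mid] <- y
    out
}

#' Empirical-Bayes location-scale batch correction on the logit scale
#'
#' Removes additive and multiplicative per-batch, per-feature effects:
#' beta values are logit (base-2) transformed, features are standardized
#' against the batch-design fit, per-batch location (gamma) and scale
#' (delta^2) estimates are shrunk toward their priors (normal for gamma,
#' inverse-gamma for delta^2, both fit by moments across features), the data
#' are adjusted and de-standardized, and finally mapped back through the
#' inverse logit so the output stays in (0, 1).
#'
#' @param x beta-scale \linkS4class{MethylationExperiment} with a
#'   \code{dataset_id} metadata column identifying the batch.
#' @param eb use empirical-Bayes shrinkage (default). With
#'   \code{eb = FALSE} the raw per-batch location/scale estimates are used,
#'   which preserves per-feature grand means exactly.
#' @param enabled \code{FALSE} returns the input unchanged (identity
#'   contract for single-batch runs).
#' @return corrected beta-scale \linkS4class{MethylationExperiment}.
#' @export
batchCorrect <- function(x, eb = TRUE, enabled = TRUE) {
    if (!enabled) return(x)
    stopifnot(methScale(x) == "beta")
    info <- sampleInfo(x)
    batch <- factor(info$dataset_id)
    if (nlevels(batch) < 2L) stop("need at least 2 batches")
    ni <- table(batch)
    if (any(ni < 2L))
        stop("batch of size 1: ", paste(names(ni)[ni < 2L], collapse = ", "))
    Y <- betaToM(methValues(x))          # features x samples
    N <- ncol(Y)
    design <- stats::model.matrix(~ 0 + batch)
    # per-feature batch means (B x G) and pooled variance (denominator N)
    Bhat <- solve(crossprod(design), t(design) %*% t(Y))
    grand <- drop(crossprod(as.numeric(ni) / N, Bhat))
    resid <- Y - t(design %*% Bhat)
    varPooled <- rowSums(resid^2) / N
    varPooled[varPooled == 0] <- .Machine$double.eps
    Z <- (Y - grand) / sqrt(varPooled)
    gammaHat <- solve(crossprod(design), t(design) %*% t(Z))  # B x G
    out <- Z
    for (b in seq_len(nlevels(batch))) {
        sel <- batch == levels(batch)[b]
        n <- sum(sel)
        zb <- Z[, sel, drop = FALSE]
        g.hat <- gammaHat[b, ]
        d.hat <- apply(zb, 1L, var)
        if (eb) {
            g.bar <- mean(g.hat); t2 <- var(g.hat)
            m <- mean(d.hat); s2 <- var(d.hat)
            a.prior <- (2 * s2 + m^2) / s2
            b.prior <- (m * s2 + m^3) / s2
            g.new <- g.hat; d.new <- d.hat
            change <- 1
            while (change > 1e-4) {
                g.old <- g.new; d.old <- d.new
                g.new <- (n * t2 * g.hat + d.old * g.bar) /
                    (n * t2 + d.old)
                sum2 <- rowSums((zb - g.new)^2)
                d.new <- (0.5 * sum2 + b.prior) / (n / 2 + a.prior - 1)
                change <- max(abs(g.new - g.old) / abs(g.old),
                              abs(d.new - d.old) / d.old, na.rm = TRUE)
            }
            g.star <- g.new; d.star <- d.new
        } else {
            g.star <- g.hat
            d.star <- d.hat
            d.star[d.star == 0] <- 1
        }
        out[, sel] <- (zb - g.star) / sqrt(d.star)
    }
    adj <- out * sqrt(varPooled) + grand
    MethylationExperiment(clampBeta(mToBeta(adj)), "beta", info)
}

#' First two principal components of the samples, for batch QC
#'
#' Samples are projected onto the first two principal components of the
#' feature space (centered, unscaled). Used to inspect whether samples
#' cluster by dataset before and after batch correction.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @return data.frame with columns \code{sample_id}, \code{PC1}, \code{PC2},
#'   \code{dataset_id}.
#' @export
pcaQC <- function(x) {
    v <- t(methValues(x))
    if (all(apply(v, 2L, sd) == 0)) {
        pcs <- matrix(0, nrow(v), 2L)
    } else {
        pr <- prcomp(v, center = TRUE, scale. = FALSE, rank. = 2L)
        pcs <- pr$x[, seq_len(min(2L, ncol(pr$x))), drop = FALSE]
        if (ncol(pcs) < 2L) pcs <- cbind(pcs, 0)
    }
    info <- sampleInfo(x)
    data.frame(sample_id = rownames(v), PC1 = pcs[, 1L], PC2 = pcs[, 2L],
               dataset_id = if ("dataset_id" %in% colnames(info))
                   info$dataset_id else NA_character_,
               row.names = NULL, stringsAsFactors = FALSE)
}
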