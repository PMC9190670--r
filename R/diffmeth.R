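#' @importFrom stats lm.fit model.matrix p.adjust pt var
NULL

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}: sort ascending,
#' take running minima of \code{m * p_j / j} from the largest rank down,
#' cap at 1, restore input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values in input order.
#' @export
bhAdjust <- function(p) {
    stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
    p.adjust(p, method = "BH")
}

.squeeze_var <- function(s2, df) {
    pos <- s2 > 0
    if (!any(pos)) return(list(df_prior = 0, var_prior = NA_real_,
                               var_post = s2))
    z <- log(s2[pos])
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- if (length(e) > 1L) var(e) - trigamma(df / 2) else -1
    if (is.na(evar) || evar <= 0) {
        d0 <- Inf
        s02 <- exp(emean)
        post <- rep(s02, length(s2))
    } else {
        d0 <- 2 * .trigamma_inverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
        post <- (d0 * s02 + df * s2) / (d0 + df)
    }
    list(df_prior = d0, var_prior = s02, var_post = post)
}

#' Per-feature moderated linear model for differential methylation
#'
#' Fits, for every feature, ordinary least squares of
#' \code{M ~ intercept + group + sex} and tests the group coefficient
#' (the difference of group means on the M scale, reported as
#' \code{log2_fc}). Feature-wise residual variances are shrunk toward a
#' common prior by empirical Bayes: the prior degrees of freedom \code{d0}
#' and prior variance \code{s0^2} are estimated by moment-matching on the
#' log residual variances, and the posterior variance
#' \code{(d0 s0^2 + d s^2) / (d0 + d)} replaces \code{s^2} in the
#' t-statistic, which then has \code{d0 + d} degrees of freedom. Two-sided
#' p-values are BH-adjusted across features; a feature is significant when
#' \code{fdr < alpha} and \code{|log2_fc| >= lfcThreshold}.
#'
#' Samples of unknown sex are dropped (with a message) when sex is used as
#' a covariate; if sex is constant across the retained samples the
#' covariate is omitted.
#'
#' @param x M-scale \linkS4class{MethylationExperiment} containing both
#'   groups.
#' @param groupA,groupB character vectors of sample ids. \code{log2_fc} is
#'   the A-minus-B coefficient.
#' @param covariateSex include sex as a covariate (default TRUE; requires a
#'   \code{sex} metadata column).
#' @param moderated apply empirical-Bayes variance moderation (default).
#'   \code{FALSE} gives the ordinary OLS t-test (the \code{d0 = 0} limit).
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @param lfcThreshold absolute log2 fold-change gate (default 2).
#' @param contrast label stored in the result (default
#'   \code{"groupA_vs_groupB"}).
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{contrast}, \code{log2_fc}, \code{t_stat}, \code{p_value},
#'   \code{fdr}, \code{significant}; attributes \code{df_prior},
#'   \code{var_prior}, \code{df_residual}, \code{n_dropped_unknown_sex}.
#' @export
fitLinearDM <- function(x, groupA, groupB, covariateSex = TRUE,
                        moderated = TRUE, alpha = 0.05, lfcThreshold = 2,
                        contrast = NULL) {
    stopifnot(methScale(x) == "M")
    if (length(groupA) == 0L || length(groupB) == 0L)
        stop("both groups must be non-empty")
    if (length(intersect(groupA, groupB)))
        stop("groups overlap")
    v <- methValues(x)
    samples <- c(groupA, groupB)
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
        stop("sample(s) not in matrix: ", paste(head(missing, 3L),
                                                collapse = ", "))
    info <- sampleInfo(x)[samples, , drop = FALSE]
    grp <- rep(c(1, 0), c(length(groupA), length(groupB)))
    nDropped <- 0L
    useSex <- covariateSex && "sex" %in% colnames(info)
    if (useSex) {
        unknown <- info$sex == "unknown" | is.na(info$sex)
        nDropped <- sum(unknown)
        if (nDropped) {
            message(nDropped, " sample(s) of unknown sex dropped")
            samples <- samples[!unknown]
            info <- info[!unknown, , drop = FALSE]
            grp <- grp[!unknown]
        }
        if (length(unique(info$sex)) < 2L) useSex <- FALSE
    }
    if (sum(grp == 1) < 2L || sum(grp == 0) < 2L)
        stop("each group needs >= 2 samples after sex filtering")
    Y <- v[, samples, drop = FALSE]
    X <- if (useSex)
        cbind(intercept = 1, group = grp,
              sexmale = as.numeric(info$sex == "male"))
    else cbind(intercept = 1, group = grp)
    fit <- lm.fit(X, t(Y))
    dfres <- length(samples) - fit$rank
    coefs <- fit$coefficients["group", ]
    res <- as.matrix(fit$residuals)
    s2 <- colSums(res^2) / dfres
    vg <- chol2inv(qr.R(fit$qr))[2L, 2L]
    if (moderated) {
        sq <- .squeeze_var(s2, dfres)
        varPost <- sq$var_post
        dfTotal <- sq$df_prior + dfres
    } else {
        sq <- list(df_prior = 0, var_prior = NA_real_)
        varPost <- s2
        dfTotal <- dfres
    }
    tstat <- coefs / sqrt(varPost * vg)
    pval <- 2 * pt(-abs(tstat), df = dfTotal)
    pval[!is.finite(tstat)] <- NA_real_
    fdr <- rep(NA_real_, length(pval))
    ok <- !is.na(pval)
    fdr[ok] <- bhAdjust(pval[ok])
    out <- data.frame(
        feature_id = rownames(Y),
        contrast = if (is.null(contrast)) "groupA_vs_groupB" else contrast,
        log2_fc = unname(coefs),
        t_stat = unname(tstat),
        p_value = unname(pval),
        fdr = fdr,
        significant = !is.na(fdr) & fdr < alpha &
            abs(coefs) >= lfcThreshold,
        row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "df_prior") <- sq$df_prior
    attr(out, "var_prior") <- sq$var_prior
    attr(out, "df_residual") <- dfres
    attr(out, "n_dropped_unknown_sex") <- nDropped
    out
}

#' Combine cohorts into one MethylationExperiment
#'
#' Column-binds two or more objects on their shared features, keeping the
#' metadata columns they have in common.
#'
#' @param ... \linkS4class{MethylationExperiment} objects on the same
#'   scale.
#' @return the combined \linkS4class{MethylationExperiment}.
#' @export
combineCohorts <- function(...) {
    Reduce(.combine_me, list(...))
}

.combine_me <- function(a, b) {
    stopifnot(methScale(a) == methScale(b))
    shared <- intersect(rownames(methValues(a)), rownames(methValues(b)))
    if (length(shared) == 0L) stop("no shared features")
    va <- methValues(a)[shared, , drop = FALSE]
    vb <- methValues(b)[shared, , drop = FALSE]
    ia <- sampleInfo(a); ib <- sampleInfo(b)
    cols <- intersect(colnames(ia), colnames(ib))
    MethylationExperiment(cbind(va, vb), methScale(a),
                          rbind(ia[, cols, drop = FALSE],
                                ib[, cols, drop = FALSE]))
}

#' Differential methylation of each tumor type against the normal pool
#'
#' Runs [fitLinearDM()] for every tumor type against the (batch-adjusted)
#' normal samples and counts, per feature, in how many tumor types it is
#' significant.
#'
#' @param tumor M-scale \linkS4class{MethylationExperiment} of tumor
#'   samples with a \code{tumor_type} metadata column.
#' @param normal M-scale \linkS4class{MethylationExperiment} of the pooled
#'   normal samples.
#' @param ... passed to [fitLinearDM()] (\code{alpha}, \code{lfcThreshold},
#'   \code{moderated}, \code{covariateSex}).
#' @return list with \code{results} (named list of per-type result frames)
#'   and \code{flags} (data.frame: \code{feature_id},
#'   \code{n_types_significant}).
#' @export
tumorVsNormalDM <- function(tumor, normal, ...) {
    info <- sampleInfo(tumor)
    stopifnot("tumor_type" %in% colnames(info))
    combined <- .combine_me(tumor, normal)
    types <- unique(info$tumor_type)
    normSamples <- colnames(methValues(normal))
    results <- list()
    for (ty in types) {
        tumSamples <- rownames(info)[info$tumor_type == ty]
        results[[ty]] <- fitLinearDM(combined, groupA = tumSamples,
                                     groupB = normSamples,
                                     contrast = paste0(ty, "_vs_normal"),
                                     ...)
    }
    sig <- vapply(results, function(r) r$significant, logical(nrow(
        results[[1L]])))
    if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1L)
    list(results = results,
         flags = data.frame(feature_id = results[[1L]]$feature_id,
                            n_types_significant = rowSums(sig),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Pairwise differential methylation between tumor types
#'
#' Fits a two-group model ([fitLinearDM()]) for every unordered pair of
#' tumor types. A feature is reported as significant when it passes the FDR
#' and fold-change gates in any pair; the pair with the maximal absolute
#' log2 fold-change is recorded per feature.
#'
#' @param tumor M-scale \linkS4class{MethylationExperiment} with a
#'   \code{tumor_type} metadata column (>= 2 types).
#' @param ... passed to [fitLinearDM()].
#' @return list with \code{results} (named list, one per pair
#'   \code{"a_vs_b"}) and \code{summary} (data.frame: \code{feature_id},
#'   \code{significant_any_pair}, \code{max_abs_log2_fc},
#'   \code{max_abs_pair}).
#' @export
pairwiseTumorDM <- function(tumor, ...) {
    info <- sampleInfo(tumor)
    stopifnot("tumor_type" %in% colnames(info))
    types <- sort(unique(info$tumor_type))
    if (length(types) < 2L) stop("need >= 2 tumor types")
    results <- list()
    for (i in seq_len(length(types) - 1L))
        for (j in seq(i + 1L, length(types))) {
            a <- rownames(info)[info$tumor_type == types[i]]
            b <- rownames(info)[info$tumor_type == types[j]]
            nm <- paste0(types[i], "_vs_", types[j])
            results[[nm]] <- fitLinearDM(tumor, groupA = a, groupB = b,
                                         contrast = nm, ...)
        }
    feats <- results[[1L]]$feature_id
    sig <- vapply(results, function(r) r$significant, logical(length(feats)))
    lfc <- vapply(results, function(r) abs(r$log2_fc), numeric(length(feats)))
    if (is.null(dim(sig))) {
        sig <- matrix(sig, nrow = 1L); lfc <- matrix(lfc, nrow = 1L)
    }
    best <- max.col(lfc, ties.method = "first")
    list(results = results,
         summary = data.frame(
             feature_id = feats,
             significant_any_pair = rowSums(sig) > 0L,
             max_abs_log2_fc = lfc[cbind(seq_along(feats), best)],
             max_abs_pair = names(results)[best],
             row.names = NULL, stringsAsFactors = FALSE))
}

#' Plotting-ready volcano table
#'
#' @param results a result frame from [fitLinearDM()].
#' @return data.frame with \code{feature_id}, \code{log2_fc},
#'   \code{neg_log10_fdr}, \code{significant}.
#' @export
volcanoTable <- function(results) {
    data.frame(feature_id = results$feature_id,
               log2_fc = results$log2_fc,
               neg_log10_fdr = -log10(results$fdr),
               significant = results$significant,
               row.names = NULL, stringsAsFactors = FALSE)
}
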