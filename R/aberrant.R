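#' @importFrom stats pnorm t.test
NULL

#' Per-gene normal reference (mean, SD) for aberration calling
#'
#' Computed over all (batch-corrected) normal samples, on the beta scale by
#' default. Genes with zero SD cannot be z-scored; they are flagged
#' non-callable and never called aberrant.
#'
#' @param x gene-level \linkS4class{MethylationExperiment} of normal
#'   samples (>= 2).
#' @return data.frame with \code{gene}, \code{mean}, \code{sd},
#'   \code{n_samples}, \code{callable}.
#' @export
buildNormalReference <- function(x) {
    v <- methValues(x)
    if (ncol(v) < 2L) stop("need >= 2 normal samples")
    sds <- apply(v, 1L, sd)
    nzero <- sum(sds == 0)
    if (nzero) message(nzero, " gene(s) with zero reference SD flagged ",
                       "non-callable")
    data.frame(gene = rownames(v), mean = rowMeans(v), sd = sds,
               n_samples = ncol(v), callable = sds > 0,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Call hyper-/hypomethylation of tumors against the normal reference
#'
#' Per gene and tumor sample, \code{z = (value - mean) / sd} against the
#' normal reference; \code{z > k} is called hypermethylated, \code{z < -k}
#' hypomethylated (strict inequalities; default k = 3 standard deviations).
#' Non-callable genes (zero reference SD) get state \code{none} with
#' \code{z = NA}.
#'
#' @param tumor gene-level \linkS4class{MethylationExperiment} of tumor
#'   samples, same scale as the reference was built on.
#' @param ref data.frame from [buildNormalReference()].
#' @param k z-score threshold (default 3).
#' @return long data.frame: \code{gene}, \code{sample}, \code{z},
#'   \code{state} (\code{hyper}/\code{hypo}/\code{none}).
#' @export
callAberrations <- function(tumor, ref, k = 3) {
    v <- methValues(tumor)
    shared <- intersect(rownames(v), ref$gene)
    if (length(shared) == 0L) stop("no genes shared with the reference")
    v <- v[shared, , drop = FALSE]
    r <- ref[match(shared, ref$gene), ]
    z <- (v - r$mean) / r$sd
    z[!r$callable, ] <- NA_real_
    state <- matrix("none", nrow(z), ncol(z), dimnames = dimnames(z))
    state[!is.na(z) & z > k] <- "hyper"
    state[!is.na(z) & z < -k] <- "hypo"
    data.frame(gene = rep(rownames(z), ncol(z)),
               sample = rep(colnames(z), each = nrow(z)),
               z = as.vector(z),
               state = as.vector(state),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-tumor proportions of hyper-/hypomethylated genes
#'
#' Fractions are taken over the callable genes only (those with a defined
#' z-score); hyper, hypo and none fractions sum to 1 per tumor.
#'
#' @param calls data.frame from [callAberrations()].
#' @return data.frame: \code{sample}, \code{n_callable},
#'   \code{frac_hyper}, \code{frac_hypo}.
#' @export
tumorAberrationProportions <- function(calls) {
    callable <- calls[!is.na(calls$z), , drop = FALSE]
    sp <- split(callable$state, callable$sample)
    data.frame(sample = names(sp),
               n_callable = lengths(sp),
               frac_hyper = vapply(sp, function(s) mean(s == "hyper"),
                                   numeric(1L)),
               frac_hypo = vapply(sp, function(s) mean(s == "hypo"),
                                  numeric(1L)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert aberration calls to hyper and hypo event matrices
#'
#' @param calls data.frame from [callAberrations()].
#' @return list with \code{hyper} and \code{hypo}
#'   \linkS4class{EventMatrix} objects (genes x samples).
#' @export
aberrationEventMatrices <- function(calls) {
    genes <- unique(calls$gene)
    samples <- unique(calls$sample)
    mk <- function(st) {
        m <- matrix(FALSE, length(genes), length(samples),
                    dimnames = list(genes, samples))
        sel <- calls$state == st
        m[cbind(match(calls$gene[sel], genes),
                match(calls$sample[sel], samples))] <- TRUE
        EventMatrix(m, st)
    }
    list(hyper = mk("hyper"), hypo = mk("hypo"))
}

#' Combine hyper and hypo events into a single aberrant-methylation matrix
#'
#' "Aberrantly methylated" means hyper- or hypomethylated. The combined
#' matrix carries eventType \code{"hyper"} purely as a container label.
#'
#' @param hyper,hypo \linkS4class{EventMatrix} objects with identical
#'   dimnames.
#' @return an \linkS4class{EventMatrix} of the elementwise OR.
#' @export
combineEventMatrices <- function(hyper, hypo) {
    stopifnot(identical(dimnames(hits(hyper)), dimnames(hits(hypo))))
    EventMatrix(hits(hyper) | hits(hypo), "hyper")
}

.gene_class <- function(genes, classes) {
    cls <- rep("other", length(genes))
    cls[genes %in% classes$gene_symbol[classes$role == "oncogene"]] <-
        "oncogene"
    cls[genes %in% classes$gene_symbol[classes$role == "tsg"]] <- "tsg"
    # genes listed as both oncogene and TSG are excluded outright
    cls[genes %in% classes$gene_symbol[classes$role == "ambiguous"]] <-
        NA_character_
    cls
}

#' Aberration and mutation rates stratified by cancer-gene class
#'
#' For each tumor type, event type (hyper, hypo, mutation) and gene class
#' (oncogene, tumor suppressor, other), the rate is the fraction of
#' gene-by-tumor pairs of that class carrying the event. Genes with an
#' ambiguous census role are excluded from all classes; empty classes give
#' \code{NA}.
#'
#' @param hyper,hypo,mutation \linkS4class{EventMatrix} objects over a
#'   common gene and sample universe.
#' @param tumorTypes named character vector, sample -> tumor type.
#' @param classes data.frame from [readCancerGeneCensus()].
#' @return data.frame: \code{tumor_type}, \code{event_type}, \code{class},
#'   \code{rate}, \code{n_pairs}.
#' @export
classStratifiedRates <- function(hyper, hypo, mutation, tumorTypes,
                                 classes) {
    mats <- list(hyper = hits(hyper), hypo = hits(hypo),
                 mutation = hits(mutation))
    genes <- rownames(mats$hyper)
    samples <- colnames(mats$hyper)
    for (m in mats)
        stopifnot(identical(rownames(m), genes))
    cls <- .gene_class(genes, classes)
    rows <- list()
    for (ty in unique(tumorTypes)) {
        sIdx <- intersect(samples, names(tumorTypes)[tumorTypes == ty])
        for (ev in names(mats)) {
            sub <- mats[[ev]][, sIdx, drop = FALSE]
            for (cl in c("oncogene", "tsg", "other")) {
                gIdx <- !is.na(cls) & cls == cl
                n <- sum(gIdx) * length(sIdx)
                rows[[length(rows) + 1L]] <- data.frame(
                    tumor_type = ty, event_type = ev, class = cl,
                    rate = if (n) mean(sub[gIdx, , drop = FALSE]) else
                        NA_real_,
                    n_pairs = n, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

#' One-sided comparison of mean normal M-values: oncogenes vs TSGs
#'
#' Computes the per-gene mean M-value across the normal samples and runs a
#' Welch two-sample t-test of the hypothesis that oncogenes are methylated
#' at higher levels than tumor suppressor genes (alternative: oncogene mean
#' greater).
#'
#' @param normalM gene-level M-scale \linkS4class{MethylationExperiment}
#'   of normal samples.
#' @param classes data.frame from [readCancerGeneCensus()].
#' @return list with \code{t_stat}, \code{p_value} (one-sided),
#'   \code{mean_oncogene}, \code{mean_tsg}, \code{n_oncogene},
#'   \code{n_tsg}.
#' @export
compareOncTsgMeanM <- function(normalM, classes) {
    stopifnot(methScale(normalM) == "M")
    mu <- rowMeans(methValues(normalM))
    cls <- .gene_class(names(mu), classes)
    onc <- mu[!is.na(cls) & cls == "oncogene"]
    tsg <- mu[!is.na(cls) & cls == "tsg"]
    if (length(onc) < 2L || length(tsg) < 2L)
        stop("need >= 2 genes per class")
    tt <- t.test(onc, tsg, alternative = "greater", var.equal = FALSE)
    list(t_stat = unname(tt$statistic), p_value = tt$p.value,
         mean_oncogene = mean(onc), mean_tsg = mean(tsg),
         n_oncogene = length(onc), n_tsg = length(tsg))
}
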