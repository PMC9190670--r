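#' Thresholds for methylation level and variance categories
#'
#' A gene's level category within one dataset is determined by the median
#' beta across that dataset's samples: \code{low} below
#' \code{low_max_median}, \code{high} above \code{high_min_median},
#' \code{medium} otherwise (boundary values are medium; inequalities are
#' strict). Its variance category is determined by the coefficient of
#' variation (sample SD / mean of the betas): \code{low} below
#' \code{high_min_cv}, \code{high} otherwise (a CV of exactly the threshold
#' is high).
#'
#' @param low_max_median median below which a gene is "low" (default 0.2).
#' @param high_min_median median above which a gene is "high" (default 0.6).
#' @param high_min_cv CV at or above which variance is "high" (default 0.5).
#' @return a list of class \code{CategoryThresholds}.
#' @export
categoryThresholds <- function(low_max_median = 0.2,
                               high_min_median = 0.6,
                               high_min_cv = 0.5) {
    stopifnot(low_max_median > 0, high_min_median < 1,
              low_max_median < high_min_median, high_min_cv > 0)
    structure(list(low_max_median = low_max_median,
                   high_min_median = high_min_median,
                   high_min_cv = high_min_cv),
              class = "CategoryThresholds")
}

# fixed ordering used for deterministic modal-category tie-breaks
.CATEGORY_ORDER <- c("low/low", "low/high", "medium/low", "medium/high",
                     "high/low", "high/high")

#' Categorize one gene within one dataset
#'
#' @param values beta values for the gene across the dataset's samples
#'   (at least 2).
#' @param thresholds a [categoryThresholds()] list.
#' @return list with \code{median_beta}, \code{cv}, \code{level},
#'   \code{variance}, \code{category} (\code{"level/variance"}).
#' @examples
#' categorizeGene(c(0.08, 0.1, 0.12))$category   # "low/low"
#' @export
categorizeGene <- function(values, thresholds = categoryThresholds()) {
    stopifnot(length(values) >= 2L, all(values >= 0), all(values <= 1))
    med <- median(values)
    mu <- mean(values)
    cv <- if (mu == 0) 0 else sd(values) / mu
    level <- if (med < thresholds$low_max_median) "low"
        else if (med > thresholds$high_min_median) "high"
        else "medium"
    variance <- if (cv < thresholds$high_min_cv) "low" else "high"
    list(median_beta = med, cv = cv, level = level, variance = variance,
         category = paste(level, variance, sep = "/"))
}

#' Categorize every gene of a dataset
#'
#' Vectorized [categorizeGene()] over the rows of a gene-level beta matrix.
#'
#' @param x gene-level beta-scale \linkS4class{MethylationExperiment}, or a
#'   numeric matrix.
#' @param datasetId label recorded in the output.
#' @param thresholds a [categoryThresholds()] list.
#' @return data.frame with one row per gene: \code{gene},
#'   \code{dataset_id}, \code{median_beta}, \code{cv}, \code{level},
#'   \code{variance}, \code{category}.
#' @export
categorizeDataset <- function(x, datasetId = "dataset",
                              thresholds = categoryThresholds()) {
    v <- if (is(x, "MethylationExperiment")) {
        stopifnot(methScale(x) == "beta")
        methValues(x)
    } else as.matrix(x)
    stopifnot(ncol(v) >= 2L)
    med <- apply(v, 1L, median)
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, sd)
    cv <- ifelse(mu == 0, 0, sdv / mu)
    level <- ifelse(med < thresholds$low_max_median, "low",
             ifelse(med > thresholds$high_min_median, "high", "medium"))
    variance <- ifelse(cv < thresholds$high_min_cv, "low", "high")
    data.frame(gene = rownames(v), dataset_id = datasetId,
               median_beta = med, cv = cv, level = level,
               variance = variance,
               category = paste(level, variance, sep = "/"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Most common category across datasets, with deterministic tie-breaks
#'
#' Ties are broken by the fixed order low < medium < high on levels and
#' low < high on variance, so results are reproducible.
#'
#' @param categories character vector of \code{"level/variance"} strings.
#' @return list with \code{category} (the modal pair) and \code{n} (its
#'   count).
#' @export
modalCategory <- function(categories) {
    stopifnot(length(categories) >= 1L,
              all(categories %in% .CATEGORY_ORDER))
    tab <- table(factor(categories, levels = .CATEGORY_ORDER))
    winner <- names(tab)[which.max(tab)]   # first max in fixed order
    list(category = winner, n = as.integer(max(tab)))
}

#' Cross-dataset consistency of gene categories
#'
#' A gene is \code{consistent} when it has the same (level, variance)
#' category in all datasets, \code{semiconsistent} when in all but one, and
#' \code{inconsistent} otherwise (the four-dataset 4/3/<=2 rule
#' generalized to any dataset count).
#'
#' @param profiles long data.frame from [categorizeDataset()] covering the
#'   same genes in at least 2 datasets.
#' @return data.frame with one row per gene: \code{gene}, \code{label},
#'   \code{modal_category}, \code{n_agreeing}, \code{n_datasets}.
#' @export
classifyConsistency <- function(profiles) {
    sp <- split(profiles$category, profiles$gene)
    nds <- lengths(sp)
    if (any(nds < 2L)) stop("each gene needs profiles from >= 2 datasets")
    modal <- lapply(sp, modalCategory)
    n_agree <- vapply(modal, `[[`, integer(1L), "n")
    label <- ifelse(n_agree == nds, "consistent",
             ifelse(n_agree == nds - 1L, "semiconsistent", "inconsistent"))
    data.frame(gene = names(sp),
               label = label,
               modal_category = vapply(modal, `[[`, character(1L),
                                       "category"),
               n_agreeing = n_agree,
               n_datasets = as.integer(nds),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate consistency labels with percentages
#'
#' @param labels data.frame from [classifyConsistency()].
#' @return data.frame with \code{label}, \code{n}, \code{pct}
#'   (\code{100 * n / total}).
#' @export
consistencySummary <- function(labels) {
    lev <- c("consistent", "semiconsistent", "inconsistent")
    tab <- table(factor(labels$label, levels = lev))
    data.frame(label = lev, n = as.integer(tab),
               pct = 100 * as.integer(tab) / nrow(labels),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohort size and sex composition
#'
#' @param metadata sample metadata data.frame with \code{sex} and
#'   optionally \code{condition}.
#' @return list with \code{n}, \code{n_female}, \code{pct_female}.
#' @export
cohortSummary <- function(metadata) {
    n <- nrow(metadata)
    nf <- sum(metadata$sex == "female")
    list(n = n, n_female = nf, pct_female = 100 * nf / n)
}

#' Normal-to-tumor category-change table
#'
#' For every ordered pair of distinct categories, counts the genes whose
#' modal normal category is the source and whose modal tumor category is
#' the target, with the percentage relative to all genes in the source
#' category. Rows with zero changed genes are omitted. Also aggregates the
#' total number of changed genes, the number whose methylation level
#' increased one step (low to medium, or medium to high), and the number
#' whose variance went from low to high.
#'
#' @param normalModal named character vector, gene -> modal normal
#'   category (\code{"level/variance"}).
#' @param tumorModal named character vector, gene -> modal tumor category;
#'   must cover the same genes.
#' @return list with \code{table} (data.frame: \code{normal_category},
#'   \code{tumor_category}, \code{total}, \code{changed}, \code{pct}),
#'   \code{n_changed}, \code{n_level_increased}, \code{n_variance_increased},
#'   \code{pct_level_increased}, \code{pct_variance_increased}.
#' @export
categoryChangeTable <- function(normalModal, tumorModal) {
    genes <- intersect(names(normalModal), names(tumorModal))
    stopifnot(length(genes) > 0L)
    from <- normalModal[genes]
    to <- tumorModal[genes]
    changed <- from != to
    totals <- table(factor(from, levels = .CATEGORY_ORDER))
    rows <- list()
    for (f in .CATEGORY_ORDER) for (t in .CATEGORY_ORDER) {
        if (f == t) next
        n <- sum(from == f & to == t)
        if (n == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
            normal_category = f, tumor_category = t,
            total = as.integer(totals[[f]]), changed = n,
            pct = 100 * n / totals[[f]],
            stringsAsFactors = FALSE)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(normal_category = character(), tumor_category = character(),
                   total = integer(), changed = integer(), pct = numeric())
    lvl <- function(cat) sub("/.*$", "", cat)
    vr <- function(cat) sub("^.*/", "", cat)
    stepUp <- (lvl(from) == "low" & lvl(to) == "medium") |
        (lvl(from) == "medium" & lvl(to) == "high")
    varUp <- changed & vr(from) == "low" & vr(to) == "high"
    nCh <- sum(changed)
    list(table = tab,
         n_changed = nCh,
         n_level_increased = sum(stepUp),
         n_variance_increased = sum(varUp),
         pct_level_increased = if (nCh) 100 * sum(stepUp) / nCh else NA_real_,
         pct_variance_increased = if (nCh) 100 * sum(varUp) / nCh else NA_real_)
}

#' Overlap between per-dataset and pooled high-variance calls
#'
#' Counts genes that are high-variance in at least one individual dataset
#' and, among those, the fraction that is also high-variance when the CV is
#' computed on all normal samples pooled. Genes high-variance only in the
#' pooled matrix (e.g., through between-dataset mean differences) enter
#' neither numerator nor denominator.
#'
#' @param perDatasetVariance logical genes x datasets matrix (TRUE = high
#'   variance in that dataset), or a data.frame from [categorizeDataset()]
#'   stacked over datasets.
#' @param pooledVariance named logical vector, gene -> high variance on the
#'   pooled matrix.
#' @return list with \code{n_any_dataset}, \code{n_pooled_and_any},
#'   \code{fraction}, \code{pct}.
#' @export
highVarianceOverlap <- function(perDatasetVariance, pooledVariance) {
    if (is.data.frame(perDatasetVariance)) {
        sp <- split(perDatasetVariance$variance == "high",
                    perDatasetVariance$gene)
        anyHigh <- vapply(sp, any, logical(1L))
    } else {
        anyHigh <- apply(perDatasetVariance, 1L, any)
    }
    genes <- names(anyHigh)[anyHigh]
    nAny <- length(genes)
    nBoth <- sum(pooledVariance[genes], na.rm = TRUE)
    list(n_any_dataset = nAny, n_pooled_and_any = nBoth,
         fraction = if (nAny) nBoth / nAny else NA_real_,
         pct = if (nAny) 100 * nBoth / nAny else NA_real_)
}
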