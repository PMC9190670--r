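#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

.METH_SCALES <- c("beta", "M")
.EVENT_TYPES <- c("mutation", "hyper", "hypo")
.SEX_LEVELS <- c("female", "male", "unknown")

#' Container for a methylation matrix with sample metadata
#'
#' An extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"meth"}) of methylation values, either beta values in \[0, 1\]
#' (ratio of methylated to total array signal) or M-values
#' (\code{log2(beta/(1-beta))}, the variance-stabilized scale used for
#' statistical testing). Features are probes or genes in rows, samples in
#' columns; per-sample metadata (cohort/batch, sex, condition, tumor type)
#' lives in \code{colData}.
#'
#' @slot scale character, \code{"beta"} or \code{"M"}.
#'
#' @seealso [MethylationExperiment()] for the constructor,
#'   [asM()] and [asBeta()] for scale conversion.
#' @export
setClass("MethylationExperiment",
    contains = "SummarizedExperiment",
    representation(scale = "character"))

setValidity("MethylationExperiment", function(object) {
    msg <- NULL
    if (length(object@scale) != 1L || !object@scale %in% .METH_SCALES)
        msg <- c(msg, "'scale' must be \"beta\" or \"M\"")
    v <- assay(object, "meth")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "feature and sample ids (dimnames) are required")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate sample ids")
    if (any(!is.finite(v)))
        msg <- c(msg, "all methylation values must be finite")
    if (identical(object@scale, "beta") &&
        (any(v < 0) || any(v > 1)))
        msg <- c(msg, "beta values must lie in [0, 1]")
    cd <- colData(object)
    if (all(c("condition", "tumor_type") %in% colnames(cd))) {
        tum <- cd$condition == "tumor"
        if (any(tum & is.na(cd$tumor_type)))
            msg <- c(msg, "tumor samples must carry a tumor_type")
        if (any(!tum & !is.na(cd$tumor_type)))
            msg <- c(msg, "normal samples must not carry a tumor_type")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MethylationExperiment
#'
#' @param values numeric matrix, features x samples, with row and column
#'   names. Beta values must lie in \[0, 1\].
#' @param scale \code{"beta"} or \code{"M"}.
#' @param sampleData optional \code{data.frame} of per-sample metadata. If it
#'   has a \code{sample_id} column that column is used to match samples;
#'   otherwise row names are used. Every sample in \code{values} must have
#'   exactly one record. Recognised columns: \code{dataset_id} (batch label),
#'   \code{sex} (\code{"female"}, \code{"male"}, \code{"unknown"}),
#'   \code{condition} (\code{"normal"}, \code{"tumor"}), \code{tumor_type}
#'   (\code{NA} for normals).
#'
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' me <- MethylationExperiment(b, "beta")
#' methScale(me)
#' @export
MethylationExperiment <- function(values, scale = c("beta", "M"),
                                  sampleData = NULL) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(sampleData)) {
        cd <- DataFrame(row.names = colnames(values))
    } else {
        cd <- DataFrame(sampleData, check.names = FALSE)
        if ("sample_id" %in% colnames(cd))
            rownames(cd) <- cd$sample_id
        missing <- setdiff(colnames(values), rownames(cd))
        if (length(missing))
            stop("no metadata record for sample(s): ",
                 paste(head(missing, 5L), collapse = ", "))
        cd <- cd[colnames(values), , drop = FALSE]
        if ("sex" %in% colnames(cd) &&
            !all(cd$sex %in% .SEX_LEVELS))
            stop("sex must be one of: ", paste(.SEX_LEVELS, collapse = ", "))
    }
    se <- SummarizedExperiment(assays = list(meth = values), colData = cd)
    new("MethylationExperiment", se, scale = scale)
}

#' @describeIn MethylationExperiment the value scale (\code{"beta"}/\code{"M"}).
#' @param x a \code{MethylationExperiment}.
#' @export
setMethod("methScale", "MethylationExperiment", function(x) x@scale)

#' @describeIn MethylationExperiment the features x samples value matrix.
#' @export
setMethod("methValues", "MethylationExperiment",
    function(x) assay(x, "meth"))

#' @describeIn MethylationExperiment sample metadata as a base data.frame.
#' @export
setMethod("sampleInfo", "MethylationExperiment",
    function(x) as.data.frame(colData(x)))

setMethod("show", "MethylationExperiment", function(object) {
    v <- methValues(object)
    cat("MethylationExperiment (", object@scale, " scale): ",
        nrow(v), " features x ", ncol(v), " samples\n", sep = "")
    cd <- colData(object)
    if ("condition" %in% colnames(cd))
        cat("  condition:",
            paste(names(table(cd$condition)), table(cd$condition),
                  sep = "=", collapse = " "), "\n")
    if ("dataset_id" %in% colnames(cd))
        cat("  datasets: ", length(unique(cd$dataset_id)), "\n", sep = "")
})

#' Gene-by-sample binary event matrix
#'
#' Records, for one event type (damaging somatic mutation, hypermethylation
#' or hypomethylation), which genes carry the event in which tumors.
#'
#' @slot hits logical matrix, genes x samples, with unique dimnames.
#' @slot eventType one of \code{"mutation"}, \code{"hyper"}, \code{"hypo"}.
#' @export
setClass("EventMatrix",
    representation(hits = "matrix", eventType = "character"))

setValidity("EventMatrix", function(object) {
    msg <- NULL
    if (!is.logical(object@hits))
        msg <- c(msg, "'hits' must be a logical matrix")
    if (is.null(rownames(object@hits)) || is.null(colnames(object@hits)))
        msg <- c(msg, "gene and sample ids (dimnames) are required")
    if (anyDuplicated(rownames(object@hits)) ||
        anyDuplicated(colnames(object@hits)))
        msg <- c(msg, "duplicate gene or sample ids")
    if (length(object@eventType) != 1L ||
        !object@eventType %in% .EVENT_TYPES)
        msg <- c(msg, "'eventType' must be mutation, hyper or hypo")
    if (is.null(msg)) TRUE else msg
})

#' Construct an EventMatrix
#'
#' @param hits logical matrix (genes x samples) with dimnames.
#' @param eventType \code{"mutation"}, \code{"hyper"} or \code{"hypo"}.
#' @return An \linkS4class{EventMatrix}.
#' @export
EventMatrix <- function(hits, eventType = c("mutation", "hyper", "hypo")) {
    eventType <- match.arg(eventType)
    hits <- as.matrix(hits)
    if (!is.logical(hits)) {
        stopifnot(all(hits %in% c(0, 1)))
        hits <- hits > 0
    }
    new("EventMatrix", hits = hits, eventType = eventType)
}

#' @describeIn EventMatrix the logical genes x samples matrix.
#' @param x an \code{EventMatrix}.
#' @export
setMethod("hits", "EventMatrix", function(x) x@hits)

#' @describeIn EventMatrix the event type string.
#' @export
setMethod("eventType", "EventMatrix", function(x) x@eventType)

setMethod("show", "EventMatrix", function(object) {
    cat("EventMatrix [", object@eventType, "]: ",
        nrow(object@hits), " genes x ", ncol(object@hits),
        " samples, ", sum(object@hits), " events\n", sep = "")
})

#' Result of a mutation/methylation mutual-exclusivity permutation test
#'
#' @slot observed observed number of gene-by-tumor co-occurrences.
#' @slot nullCounts co-occurrence counts from each permutation.
#' @slot nullMean mean of the permutation null.
#' @slot empiricalP left-tail empirical p-value,
#'   \code{(#\{null <= observed\} + 1) / (n + 1)}; small values indicate
#'   mutual exclusivity.
#' @slot nPermutations number of permutations.
#' @slot nGenesTested number of genes entering the test.
#' @slot seed RNG seed used.
#' @export
setClass("MutexResult",
    representation(observed = "integer", nullCounts = "numeric",
                   nullMean = "numeric", empiricalP = "numeric",
                   nPermutations = "integer", nGenesTested = "integer",
                   seed = "integer"))

setValidity("MutexResult", function(object) {
    msg <- NULL
    if (length(object@nullCounts) != object@nPermutations)
        msg <- c(msg, "nullCounts length must equal nPermutations")
    if (abs(object@nullMean - mean(object@nullCounts)) > 1e-8)
        msg <- c(msg, "nullMean must equal mean(nullCounts)")
    pexp <- (sum(object@nullCounts <= object@observed) + 1) /
        (object@nPermutations + 1)
    if (abs(object@empiricalP - pexp) > 1e-12)
        msg <- c(msg, "empiricalP inconsistent with null counts")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MutexResult", function(object) {
    cat("MutexResult: observed co-occurrences = ", object@observed,
        ", null mean = ", signif(object@nullMean, 6),
        " (", object@nPermutations, " permutations, ",
        object@nGenesTested, " genes)\n",
        "  empirical p (left tail) = ",
        signif(object@empiricalP, 4), "\n", sep = "")
})

#' @describeIn MutexResult observed co-occurrence count.
#' @param x a \code{MutexResult}.
#' @export
observedCooccurrences <- function(x) x@observed

#' @describeIn MutexResult empirical p-value.
#' @export
empiricalP <- function(x) x@empiricalP

#' @describeIn MutexResult permutation-null co-occurrence counts.
#' @export
nullCounts <- function(x) x@nullCounts
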