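#' Genes testable for mutual exclusivity
#'
#' Both event types are rare, so the test is restricted to genes with at
#' least \code{minEvents} mutation events and at least \code{minEvents}
#' aberrant-methylation events across the tumors (both thresholds
#' inclusive).
#'
#' @param mutation mutation \linkS4class{EventMatrix}.
#' @param methylation combined aberrant-methylation
#'   \linkS4class{EventMatrix}.
#' @param minEvents minimum events of each type per gene (default 5).
#' @return character vector of testable gene ids.
#' @export
filterTestableGenes <- function(mutation, methylation, minEvents = 5L) {
    mu <- hits(mutation); me <- hits(methylation)
    genes <- intersect(rownames(mu), rownames(me))
    samples <- intersect(colnames(mu), colnames(me))
    mu <- mu[genes, samples, drop = FALSE]
    me <- me[genes, samples, drop = FALSE]
    genes[rowSums(mu) >= minEvents & rowSums(me) >= minEvents]
}

#' Observed gene-by-tumor co-occurrence count
#'
#' Number of (gene, tumor) pairs in which the gene is both mutated and
#' aberrantly methylated, restricted to the given genes and the tumors
#' shared by both matrices.
#'
#' @param mutation,methylation \linkS4class{EventMatrix} objects.
#' @param genes gene ids to count over.
#' @return integer count.
#' @export
countCooccurrences <- function(mutation, methylation, genes) {
    samples <- intersect(colnames(hits(mutation)),
                         colnames(hits(methylation)))
    mu <- hits(mutation)[genes, samples, drop = FALSE]
    me <- hits(methylation)[genes, samples, drop = FALSE]
    sum(mu & me)
}

#' Permutation test for mutation/methylation mutual exclusivity
#'
#' Keeps the mutation matrix fixed and, in each permutation, shuffles every
#' gene's methylation-status vector across the tumors independently
#' (preserving the gene's event count), then recounts co-occurrences. The
#' empirical p-value is left-tailed with the add-one correction,
#' \code{(#\{null <= observed\} + 1) / (n + 1)}: small values mean fewer
#' co-occurrences than chance, i.e. mutual exclusivity.
#'
#' @param mutation,methylation \linkS4class{EventMatrix} objects sharing
#'   tumors.
#' @param genes genes to test (e.g. from [filterTestableGenes()]).
#' @param nPermutations number of permutations (default 10000).
#' @param seed RNG seed (recorded in the result).
#' @return a \linkS4class{MutexResult}.
#' @export
permutationTest <- function(mutation, methylation, genes,
                            nPermutations = 10000L, seed = 1L) {
    if (length(genes) == 0L) stop("no testable genes")
    samples <- intersect(colnames(hits(mutation)),
                         colnames(hits(methylation)))
    nT <- length(samples)
    if (nT < 2L) stop("need >= 2 shared tumors")
    mu <- hits(mutation)[genes, samples, drop = FALSE]
    me <- hits(methylation)[genes, samples, drop = FALSE]
    observed <- sum(mu & me)
    mutRows <- lapply(seq_along(genes), function(g) mu[g, ])
    mCounts <- rowSums(me)
    set.seed(seed)
    null <- integer(nPermutations)
    for (p in seq_len(nPermutations)) {
        cnt <- 0L
        for (g in seq_along(genes)) {
            mg <- mCounts[g]
            if (mg == 0L) next
            # random placement of the gene's methylation events =
            # independent shuffle of its status vector
            cnt <- cnt + sum(mutRows[[g]][sample.int(nT, mg)])
        }
        null[p] <- cnt
        if (p == 1L)  # shuffle preserves per-gene event counts by design
            stopifnot(cnt <= sum(pmin(rowSums(mu), mCounts)))
    }
    new("MutexResult",
        observed = as.integer(observed),
        nullCounts = as.numeric(null),
        nullMean = mean(null),
        empiricalP = (sum(null <= observed) + 1) / (nPermutations + 1),
        nPermutations = as.integer(nPermutations),
        nGenesTested = length(genes),
        seed = as.integer(seed))
}

#' Direction-specific mutual-exclusivity tests for cancer-gene classes
#'
#' Two tests built on the same permutation machinery: (1) mutation in an
#' oncogene versus hypomethylation of the same gene, and (2) mutation in a
#' tumor suppressor gene versus hypermethylation of the same gene, each
#' restricted to the respective gene class.
#'
#' @param mutation mutation \linkS4class{EventMatrix}.
#' @param hypo,hyper \linkS4class{EventMatrix} objects of hypo- and
#'   hypermethylation events.
#' @param classes data.frame from [readCancerGeneCensus()].
#' @param nPermutations,seed passed to [permutationTest()].
#' @param minEvents optional per-gene event filter applied within each
#'   class (default 1, i.e. genes with at least one event of each type).
#' @return named list with \linkS4class{MutexResult} objects
#'   \code{oncogene_hypo} and \code{tsg_hyper}.
#' @export
directionalPermutationTest <- function(mutation, hypo, hyper, classes,
                                       nPermutations = 10000L, seed = 1L,
                                       minEvents = 1L) {
    one <- function(meth, role, offset) {
        cls <- classes$gene_symbol[classes$role == role]
        genes <- intersect(cls, filterTestableGenes(mutation, meth,
                                                    minEvents))
        if (length(genes) == 0L)
            stop("no testable ", role, " genes")
        permutationTest(mutation, meth, genes,
                        nPermutations = nPermutations,
                        seed = seed + offset)
    }
    list(oncogene_hypo = one(hypo, "oncogene", 0L),
         tsg_hyper = one(hyper, "tsg", 1L))
}
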