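#' Keep damaging mutation records
#'
#' A record is damaging when it has (1) HIGH impact, or (2) MODERATE impact
#' and is deleterious by SIFT, or damaging / probably_damaging by
#' PolyPhen-2. LOW and MODIFIER impacts are always removed. Order is
#' preserved; the output is a subset of the input.
#'
#' @param records data.frame of mutation records (see
#'   [readVcfMutations()]).
#' @return the damaging subset, same columns.
#' @export
filterDamaging <- function(records) {
    sift <- ifelse(is.na(records$sift), "", records$sift)
    poly <- ifelse(is.na(records$polyphen), "", records$polyphen)
    keep <- records$impact == "HIGH" |
        (records$impact == "MODERATE" &
             (sift == "deleterious" |
                  poly %in% c("damaging", "probably_damaging")))
    records[keep, , drop = FALSE]
}

#' Build the gene-by-tumor mutation event matrix
#'
#' A gene is "mutated" in a tumor when it has at least one damaging SNV or
#' indel, or at least one RNA fusion with the gene as either partner (a
#' fusion affects both genes). Records for genes or samples outside the
#' supplied universes are ignored with a logged count.
#'
#' @param mutations damaging mutation records ([filterDamaging()] output).
#' @param fusions fusion records ([readBedpeFusions()] output).
#' @param genes,samples character vectors defining the matrix universe.
#' @return an \linkS4class{EventMatrix} of type \code{"mutation"}.
#' @export
buildMutationMatrix <- function(mutations, fusions, genes, samples) {
    m <- matrix(FALSE, length(genes), length(samples),
                dimnames = list(genes, samples))
    pairs <- rbind(
        data.frame(gene = mutations$gene_symbol,
                   sample = mutations$sample_id,
                   stringsAsFactors = FALSE),
        data.frame(gene = c(fusions$gene_a, fusions$gene_b),
                   sample = c(fusions$sample_id, fusions$sample_id),
                   stringsAsFactors = FALSE))
    inUniverse <- pairs$gene %in% genes & pairs$sample %in% samples
    nOut <- sum(!inUniverse)
    if (nOut) message(nOut, " event record(s) outside the gene/sample ",
                      "universe ignored")
    pairs <- pairs[inUniverse, , drop = FALSE]
    m[cbind(match(pairs$gene, genes), match(pairs$sample, samples))] <- TRUE
    EventMatrix(m, "mutation")
}

#' Frequency summary of mutation and aberrant-methylation events
#'
#' @param mutation mutation \linkS4class{EventMatrix}.
#' @param aberrant combined aberrant-methylation
#'   \linkS4class{EventMatrix} (hyper OR hypo).
#' @param tumorTypes named character vector, sample -> tumor type.
#' @return list with \code{per_type} (data.frame: \code{tumor_type},
#'   \code{n_tumors}, \code{frac_tumors_aberrant} -- fraction of tumors
#'   with at least one aberrant gene) and \code{mutation_rate} (overall
#'   fraction of gene-by-tumor pairs mutated).
#' @export
eventFrequencySummary <- function(mutation, aberrant, tumorTypes) {
    ab <- hits(aberrant)
    anyAb <- colSums(ab) > 0L
    rows <- list()
    for (ty in unique(tumorTypes)) {
        sIdx <- intersect(colnames(ab),
                          names(tumorTypes)[tumorTypes == ty])
        rows[[length(rows) + 1L]] <- data.frame(
            tumor_type = ty, n_tumors = length(sIdx),
            frac_tumors_aberrant = if (length(sIdx))
                mean(anyAb[sIdx]) else NA_real_,
            stringsAsFactors = FALSE)
    }
    list(per_type = do.call(rbind, rows),
         mutation_rate = mean(hits(mutation)))
}
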