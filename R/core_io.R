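#' @importFrom utils read.delim write.table head count.fields
NULL

#' Read a methylation matrix from TSV
#'
#' The expected layout is the GEO series-matrix style: a
#' header row of sample ids and a first column of feature (probe or gene)
#' ids. Gzip-compressed files are read transparently. Rows containing any
#' non-numeric cell are dropped with a warning; duplicate feature or sample
#' ids and out-of-range beta values are hard errors.
#'
#' @param path path to a TSV (optionally .gz).
#' @param scale \code{"beta"} or \code{"M"}; beta values are range-checked.
#' @param sampleData optional per-sample metadata passed on to
#'   [MethylationExperiment()].
#' @return A \linkS4class{MethylationExperiment}.
#' @export
readMethylationTSV <- function(path, scale = c("beta", "M"),
                               sampleData = NULL) {
    scale <- match.arg(scale)
    d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
    if (nrow(d) == 0L)
        stop("no features in ", path)
    ids <- d[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate feature ids in ", path, ": ",
             paste(head(unique(ids[duplicated(ids)]), 3L), collapse = ", "))
    samples <- colnames(d)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample ids in ", path)
    v <- suppressWarnings(
        vapply(d[-1L], as.numeric, numeric(nrow(d))))
    if (nrow(d) == 1L) v <- matrix(v, nrow = 1L)
    dimnames(v) <- list(ids, samples)
    bad <- apply(v, 1L, anyNA)
    if (any(bad)) {
        warning(sum(bad), " row(s) with non-numeric cells dropped")
        v <- v[!bad, , drop = FALSE]
        if (nrow(v) == 0L) stop("no features left after dropping ",
                                "non-numeric rows in ", path)
    }
    if (scale == "beta") {
        out <- which(v < 0 | v > 1, arr.ind = TRUE)
        if (nrow(out)) {
            i <- out[1L, ]
            stop("beta value ", v[i[1L], i[2L]], " out of [0, 1] for probe ",
                 rownames(v)[i[1L]], ", sample ", colnames(v)[i[2L]])
        }
    }
    MethylationExperiment(v, scale, sampleData)
}

#' Write a methylation matrix to TSV at full precision
#'
#' Values are serialized with 17 significant digits so a write/read round
#' trip reproduces the matrix bit-exactly.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param path output file (plain TSV).
#' @return \code{path}, invisibly.
#' @export
writeMethylationTSV <- function(x, path) {
    v <- methValues(x)
    ch <- matrix(sprintf("%.17g", v), nrow(v), ncol(v),
                 dimnames = dimnames(v))
    d <- cbind(feature_id = rownames(v), as.data.frame(ch))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read probe annotation (probe, gene, TSS distance)
#'
#' @param path TSV with columns \code{probe_id}, \code{gene_symbol},
#'   \code{tss_distance_bp}. A probe may map to several genes (one row per
#'   pair); duplicate (probe, gene) pairs are an error.
#' @return data.frame with those three columns.
#' @export
readProbeAnnotation <- function(path) {
    d <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    need <- c("probe_id", "gene_symbol", "tss_distance_bp")
    if (!all(need %in% colnames(d)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    d <- d[need]
    if (anyDuplicated(d[c("probe_id", "gene_symbol")]))
        stop("duplicate (probe, gene) pairs in annotation")
    if (any(d$tss_distance_bp < 0))
        stop("negative TSS distance in annotation")
    d
}

#' Read per-sample metadata from TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{dataset_id},
#'   \code{sex}, \code{condition} and optionally \code{tumor_type}.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readSampleMetadata <- function(path) {
    d <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    need <- c("sample_id", "dataset_id", "sex", "condition")
    if (!all(need %in% colnames(d)))
        stop("metadata must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(d$sample_id))
        stop("duplicate sample ids in metadata")
    if (!"tumor_type" %in% colnames(d)) d$tumor_type <- NA_character_
    d$tumor_type[d$tumor_type %in% c("", "NA")] <- NA_character_
    d
}

.map_sift <- function(x) {
    x <- tolower(sub("\\(.*$", "", x))
    out <- rep(NA_character_, length(x))
    out[x != "" & !is.na(x)] <- "other"
    out[grepl("^deleterious", x)] <- "deleterious"
    out[grepl("^tolerated", x)] <- "tolerated"
    out
}

.map_polyphen <- function(x) {
    x <- tolower(sub("\\(.*$", "", x))
    out <- rep(NA_character_, length(x))
    out[x != "" & !is.na(x)] <- "other"
    out[grepl("^probably_damaging", x)] <- "probably_damaging"
    out[grepl("^benign", x)] <- "benign"
    out[x == "damaging"] <- "damaging"
    out
}

#' Read gene-level mutation records from an annotated VCF
#'
#' Parses a VCF 4.2 file with VEP-style \code{CSQ} consequence annotations
#' (via \pkg{VariantAnnotation}) and emits one record per
#' (variant, annotated gene). No consequence filtering happens here; see
#' [filterDamaging()]. The \code{CSQ} subfield layout is taken from the
#' header's \code{Format:} declaration; the subfield names used for gene
#' symbol, impact, SIFT and PolyPhen are configurable because annotation
#' dialects vary.
#'
#' @param path VCF file.
#' @param sampleId sample (tumor) id attached to every record.
#' @param csqFields named character vector mapping the record fields
#'   \code{gene}, \code{impact}, \code{sift}, \code{polyphen} to CSQ
#'   subfield names.
#' @return data.frame with columns \code{sample_id}, \code{gene_symbol},
#'   \code{impact}, \code{sift}, \code{polyphen} (the latter two may be
#'   \code{NA} when the annotation lacks them). Zero variant lines give a
#'   zero-row frame.
#' @export
readVcfMutations <- function(path, sampleId,
                             csqFields = c(gene = "SYMBOL",
                                           impact = "IMPACT",
                                           sift = "SIFT",
                                           polyphen = "PolyPhen")) {
    vcf <- tryCatch(
        suppressWarnings(VariantAnnotation::readVcf(path)),
        error = function(e)
            stop("failed to parse VCF ", path, ": ", conditionMessage(e)))
    empty <- data.frame(sample_id = character(), gene_symbol = character(),
                        impact = character(), sift = character(),
                        polyphen = character(), stringsAsFactors = FALSE)
    if (length(vcf) == 0L) return(empty)
    info <- VariantAnnotation::info(vcf)
    if (!"CSQ" %in% colnames(info))
        stop("VCF ", path, " has no CSQ annotation field")
    hdr <- VariantAnnotation::info(VariantAnnotation::header(vcf))
    desc <- hdr["CSQ", "Description"]
    fmt <- sub(".*Format:\\s*", "", desc)
    fields <- strsplit(fmt, "|", fixed = TRUE)[[1L]]
    idx <- match(csqFields, fields)
    names(idx) <- names(csqFields)
    if (anyNA(idx[c("gene", "impact")]))
        stop("CSQ format in ", path, " lacks required subfield(s): ",
             paste(csqFields[c("gene", "impact")][is.na(idx[c("gene",
                   "impact")])], collapse = ", "))
    ann <- unlist(info$CSQ, use.names = FALSE)
    if (length(ann) == 0L) return(empty)
    parts <- strsplit(ann, "|", fixed = TRUE)
    grab <- function(k) {
        if (is.na(idx[[k]])) return(rep(NA_character_, length(parts)))
        vapply(parts, function(p)
            if (length(p) >= idx[[k]]) p[[idx[[k]]]] else "", character(1L))
    }
    d <- data.frame(sample_id = sampleId,
                    gene_symbol = grab("gene"),
                    impact = toupper(grab("impact")),
                    sift = .map_sift(grab("sift")),
                    polyphen = .map_polyphen(grab("polyphen")),
                    stringsAsFactors = FALSE)
    known <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
    if (any(!d$impact %in% known)) {
        message(sum(!d$impact %in% known),
                " record(s) with unknown impact string treated as MODIFIER")
        d$impact[!d$impact %in% known] <- "MODIFIER"
    }
    d
}

#' Write mutation records to a minimal annotated VCF 4.2 file
#'
#' Used by the simulator so that the VCF reader is exercised end-to-end.
#' One variant line per record, annotated with a VEP-style CSQ entry.
#'
#' @param records data.frame as returned by [readVcfMutations()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeVcfMutations <- function(records, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=1>",
        paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"",
               "Consequence annotations. ",
               "Format: Allele|SYMBOL|IMPACT|SIFT|PolyPhen\">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(records)) {
        sift <- ifelse(is.na(records$sift), "", records$sift)
        poly <- ifelse(is.na(records$polyphen), "", records$polyphen)
        csq <- paste("T", records$gene_symbol, records$impact, sift, poly,
                     sep = "|")
        writeLines(sprintf("1\t%d\t.\tA\tT\t.\tPASS\tCSQ=%s",
                           seq_len(nrow(records)) * 100L, csq), con)
    }
    invisible(path)
}

#' Read RNA-fusion records from a BEDPE file
#'
#' Expects the STAR-Fusion-style layout: ten standard BEDPE columns plus two
#' gene-symbol columns. Self-fusions (both partners the same gene) are
#' skipped with a warning.
#'
#' @param path BEDPE file (no header).
#' @param sampleId sample id attached to every record.
#' @param geneCols indices of the two gene-symbol columns.
#' @return data.frame with columns \code{sample_id}, \code{gene_a},
#'   \code{gene_b}.
#' @export
readBedpeFusions <- function(path, sampleId, geneCols = c(11L, 12L)) {
    empty <- data.frame(sample_id = character(), gene_a = character(),
                        gene_b = character(), stringsAsFactors = FALSE)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) return(empty)
    d <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
    if (max(geneCols) > ncol(d))
        stop("BEDPE ", path, " has ", ncol(d),
             " columns; gene columns ", paste(geneCols, collapse = ","),
             " not present")
    out <- data.frame(sample_id = sampleId,
                      gene_a = as.character(d[[geneCols[1L]]]),
                      gene_b = as.character(d[[geneCols[2L]]]),
                      stringsAsFactors = FALSE)
    self <- out$gene_a == out$gene_b
    if (any(self)) {
        warning(sum(self), " self-fusion(s) skipped")
        out <- out[!self, , drop = FALSE]
    }
    out
}

#' Write fusion records to a BEDPE file
#'
#' @param fusions data.frame with columns \code{gene_a}, \code{gene_b}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBedpeFusions <- function(fusions, path) {
    n <- nrow(fusions)
    if (n == 0L) {
        file.create(path)
        return(invisible(path))
    }
    d <- data.frame(chrom1 = "1", start1 = seq_len(n) * 1000L,
                    end1 = seq_len(n) * 1000L + 1L,
                    chrom2 = "2", start2 = seq_len(n) * 2000L,
                    end2 = seq_len(n) * 2000L + 1L,
                    name = paste0(fusions$gene_a, "--", fusions$gene_b),
                    score = 0L, strand1 = "+", strand2 = "-",
                    gene_a = fusions$gene_a, gene_b = fusions$gene_b)
    write.table(d, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read tier-1 oncogene/TSG classifications from a cancer-gene-census TSV
#'
#' Keeps tier-1 rows only. The role column may contain several
#' comma-separated labels; genes listed as both oncogene and TSG get role
#' \code{"ambiguous"} (and are excluded from class-stratified analyses
#' downstream).
#'
#' @param path TSV with columns \code{gene_symbol} (or \code{Gene.Symbol}),
#'   \code{tier} (or \code{Tier}) and \code{role} (or
#'   \code{Role.in.Cancer}).
#' @return data.frame with columns \code{gene_symbol}, \code{role}
#'   (\code{oncogene}/\code{tsg}/\code{ambiguous}), \code{tier}.
#' @export
readCancerGeneCensus <- function(path) {
    d <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    cn <- tolower(colnames(d))
    pick <- function(cands, what) {
        i <- which(cn %in% cands)[1L]
        if (is.na(i)) stop("census file lacks a ", what, " column")
        d[[i]]
    }
    gene <- pick(c("gene_symbol", "gene.symbol", "gene"), "gene")
    tier <- suppressWarnings(
        as.integer(pick(c("tier"), "tier")))
    role <- tolower(pick(c("role", "role.in.cancer", "role_in_cancer"),
                         "role"))
    keep <- !is.na(tier) & tier == 1L
    gene <- gene[keep]; role <- role[keep]; tier <- tier[keep]
    onc <- grepl("oncogene", role)
    tsg <- grepl("tsg", role)
    cls <- rep(NA_character_, length(role))
    cls[onc & !tsg] <- "oncogene"
    cls[tsg & !onc] <- "tsg"
    cls[onc & tsg] <- "ambiguous"
    keep2 <- !is.na(cls)
    data.frame(gene_symbol = gene[keep2], role = cls[keep2],
               tier = tier[keep2], stringsAsFactors = FALSE)
}
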