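# in-code fixtures shared across test files

beta_matrix <- function(nr = 3, nc = 2, seed = 1) {
    set.seed(seed)
    matrix(runif(nr * nc, 0.05, 0.95), nr, nc,
           dimnames = list(sprintf("cg%03d", seq_len(nr)),
                           sprintf("s%02d", seq_len(nc))))
}

sample_meta <- function(ids, dataset = "D1", sex = NULL,
                        condition = "normal", tumor_type = NA) {
    if (is.null(sex)) sex <- rep(c("female", "male"),
                                 length.out = length(ids))
    data.frame(sample_id = ids, dataset_id = dataset, sex = sex,
               condition = condition,
               tumor_type = if (all(condition == "normal"))
                   NA_character_ else tumor_type,
               stringsAsFactors = FALSE)
}

me_beta <- function(values, ...) {
    MethylationExperiment(values, "beta",
                          sample_meta(colnames(values), ...))
}

me_m <- function(values, ...) {
    MethylationExperiment(values, "M",
                          sample_meta(colnames(values), ...))
}

census_df <- function() {
    data.frame(gene_symbol = c("ONC1", "ONC2", "TSG1", "TSG2", "AMB1"),
               role = c("oncogene", "oncogene", "tsg", "tsg",
                        "ambiguous"),
               tier = 1L, stringsAsFactors = FALSE)
}

# independent step-up oracle for the BH procedure
bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m))
        adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[o] <- adj
    out
}

write_tsv_matrix <- function(v, path) {
    d <- cbind(feature_id = rownames(v), as.data.frame(v))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
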