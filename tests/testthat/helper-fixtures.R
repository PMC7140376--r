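# Shared fixtures: everything is generated in code at test time.

# small expression TSV on disk; returns the path
write_expr_tsv <- function(values, path = tempfile(fileext = ".tsv"),
                           transpose = FALSE) {
  df <- if (transpose) {
    data.frame(sample_id = colnames(values), t(values), check.names = FALSE)
  } else {
    data.frame(gene_id = rownames(values), values, check.names = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# deterministic 3-gene x 2-sample matrix used by the io round-trip tests
tiny_expr <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  m
}

write_clin_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gmt_lines <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# samples-x-genes Gaussian blobs with unit-norm rows: a stand-in for
# hypersphere pathway vectors with planted cluster structure
blob_vectors <- function(n_per, centers_shift = 4, n_genes = 10, sd = 1,
                         seed = 1) {
  set.seed(seed)
  k <- length(n_per)
  lab <- rep(seq_len(k), n_per)
  centers <- matrix(0, k, n_genes)
  for (c in seq_len(k))
    centers[c, ((c - 1) %% n_genes) + seq(1, n_genes / 2)] <- centers_shift
  v <- centers[lab, ] + matrix(rnorm(sum(n_per) * n_genes, sd = sd),
                               sum(n_per), n_genes)
  v <- abs(v)
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- sprintf("S%04d", seq_len(nrow(v)))
  list(vectors = v, labels = lab)
}

# planted Gaussian blobs directly in embedding space (for gmm_fit/select_k)
blob_coords <- function(n_per, sep = 10, d = 3, seed = 1) {
  set.seed(seed)
  k <- length(n_per)
  lab <- rep(seq_len(k), n_per)
  centers <- matrix(0, k, d)
  for (c in seq_len(k)) centers[c, ] <- (c - 1) * sep / sqrt(d)
  co <- centers[lab, , drop = FALSE] + matrix(rnorm(sum(n_per) * d),
                                              sum(n_per), d)
  rownames(co) <- sprintf("S%04d", seq_len(nrow(co)))
  list(coords = co, labels = lab)
}

# adjusted Rand index between two labelings (mclust's implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# replicate of a reference spec with a different cohort seed
respec <- function(name, seed) {
  sp <- reference_specs()[[name]]
  sp$seed <- as.integer(seed)
  sp
}

# truth labels aligned to a fit's analyzed samples
aligned_truth <- function(cohort, fit, source) {
  cohort$truth$labels[[source]][match(fit$assignment$sample_ids,
                                      cohort$clinical$sample_id)]
}

# cluster with the largest effective median survival (the "favorable" one)
best_median_cluster <- function(fit) {
  vals <- vapply(fit$medians, function(m)
    if (m$reached) m$value_days else m$lower_bound_days, numeric(1))
  as.integer(names(which.max(vals)))
}

# minimal strat_fit stub for error-path tests (selection-size checks run
# before any computation touches the data)
stub_fit <- function(labels, k = max(labels)) {
  ids <- sprintf("S%04d", seq_along(labels))
  structure(list(pathway = "STUB",
                 assignment = structure(list(sample_ids = ids,
                                             labels = as.integer(labels),
                                             k = as.integer(k)),
                                        class = "cluster_assignment"),
                 provenance = list(list(type = "stratify", pathway = "STUB",
                                        seed = 1L, k = as.integer(k)))),
            class = "strat_fit")
}
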