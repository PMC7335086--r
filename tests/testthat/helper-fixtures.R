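# Shared fixture builders. Everything is generated in code; no data files.

# Small genes-by-samples matrix with ids.
toy_matrix <- function(n_genes = 20, n_samples = 10, seed = 1, mean = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * n_samples, mean, 1), n_genes, n_samples)
  rownames(X) <- sprintf("g%03d", seq_len(n_genes))
  colnames(X) <- sprintf("s%03d", seq_len(n_samples))
  X
}

# Perfect block consensus-index matrix: within = 100, between = 0.
perfect_index <- function(cluster_sizes) {
  labels <- rep(seq_along(cluster_sizes), cluster_sizes)
  M <- outer(labels, labels, function(a, b) ifelse(a == b, 100L, 0L))
  n <- sum(cluster_sizes)
  dimnames(M) <- list(sprintf("s%03d", 1:n), sprintf("s%03d", 1:n))
  M
}

# Wrap an index matrix as an rcc_consensus object (unit co_sample).
as_consensus <- function(index, k, repeats = 100) {
  structure(list(k = as.integer(k), index = index,
                 co_cluster = index, co_sample = matrix(repeats, nrow(index),
                                                        ncol(index)),
                 labels = consensus_labels(index, k),
                 setting = list(p_item = 1, p_feature = 1, repeats = repeats,
                                seed = 1)),
            class = "rcc_consensus")
}

# Two well-separated sample clouds: genes x samples, first `n1` samples high.
separable_matrix <- function(n1 = 10, n2 = 10, n_genes = 40, gap = 50,
                             seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * (n1 + n2)), n_genes, n1 + n2)
  X[, seq_len(n1)] <- X[, seq_len(n1)] + gap
  rownames(X) <- sprintf("g%03d", seq_len(n_genes))
  colnames(X) <- sprintf("s%03d", seq_len(n1 + n2))
  X
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Configuration files are headerless parameter,value pairs.
write_config_fixture <- function(keys, vals, path = tempfile(fileext = ".csv")) {
  writeLines(paste(keys, vals, sep = ","), path)
  path
}
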