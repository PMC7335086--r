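#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by expression within the sample (ties
#' averaged) and walked in decreasing order. Gene-set members advance a
#' weighted running sum (weight = rank value raised to `exponent`,
#' normalized over the set), non-members advance a uniform penalty
#' `1/(G - m)`; the enrichment score is the sum of the running-sum
#' differences over all positions (the integrated form). Genes of a set
#' absent from the matrix are dropped with a warning.
#'
#' @param X Genes-by-samples log2 matrix.
#' @param gene_sets Named list of character vectors of gene ids.
#' @param exponent Rank weighting exponent (default 0.25).
#' @return data.frame with columns `sample_id`, `gene_set_name`,
#'   `enrichment_score`.
#' @export
ssgsea_scores <- function(X, gene_sets, exponent = 0.25) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1,
            !is.null(names(gene_sets)))
  G <- nrow(X)
  sets <- lapply(names(gene_sets), function(nm) {
    present <- intersect(gene_sets[[nm]], rownames(X))
    dropped <- setdiff(gene_sets[[nm]], rownames(X))
    if (length(dropped))
      warning(sprintf("gene set '%s': %d gene(s) absent from the matrix",
                      nm, length(dropped)))
    if (length(present) == 0)
      stop(sprintf("gene set '%s' has no genes in the matrix", nm))
    if (length(present) >= G)
      stop(sprintf("gene set '%s' covers every gene; no background left", nm))
    present
  })
  names(sets) <- names(gene_sets)
  rows <- vector("list", ncol(X) * length(sets)); idx <- 0
  for (s in seq_len(ncol(X))) {
    expr <- X[, s]
    rk <- rank(expr)                 # rank value: highest expression = G
    ord <- order(expr, decreasing = TRUE)
    for (nm in names(sets)) {
      member <- rownames(X) %in% sets[[nm]]
      m <- sum(member)
      w <- (rk^exponent) * member
      step_in <- cumsum(w[ord]) / sum(w)
      step_out <- cumsum(!member[ord]) / (G - m)
      es <- sum(step_in - step_out)
      idx <- idx + 1
      rows[[idx]] <- data.frame(sample_id = colnames(X)[s],
                                gene_set_name = nm,
                                enrichment_score = es,
                                stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Reshape ssGSEA scores to a sets-by-samples matrix
#' @param scores Output of [ssgsea_scores()].
#' @param zscore z-score each gene set across samples (for heatmaps).
#' @return Numeric matrix (gene sets x samples).
#' @export
ssgsea_matrix <- function(scores, zscore = FALSE) {
  sets <- unique(scores$gene_set_name)
  samples <- unique(scores$sample_id)
  M <- matrix(NA_real_, length(sets), length(samples),
              dimnames = list(sets, samples))
  M[cbind(match(scores$gene_set_name, sets),
          match(scores$sample_id, samples))] <- scores$enrichment_score
  if (zscore) M <- t(scale(t(M)))
  M
}

#' Read a gene-set CSV
#'
#' Accepts either long format (columns `gene_set`, `gene_id`) or wide
#' format (first column = set name, second = comma-separated gene ids).
#'
#' @param path Path to the CSV file.
#' @return Named list of character vectors.
#' @export
read_gene_sets_csv <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (all(c("gene_set", "gene_id") %in% names(df))) {
    return(split(as.character(df$gene_id), df$gene_set))
  }
  sets <- lapply(seq_len(nrow(df)), function(i)
    trimws(strsplit(as.character(df[i, 2]), ",")[[1]]))
  names(sets) <- as.character(df[[1]])
  sets
}
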