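#' Select the most variant genes for a node
#'
#' Genes are ranked by sample variance (n-1 denominator) across the current
#' sample subset, descending, with ties broken by gene id for
#' reproducibility. The top `ceiling(pct/100 * n_genes)` genes are kept;
#' for bulk data the count is raised to `bulk_min_features` (500 by
#' default, or all genes when fewer exist). Zero-variance genes are never
#' selected.
#'
#' @param X Numeric genes-by-samples matrix (log2 scale).
#' @param pct Percentage of genes to keep, in (0, 100].
#' @param data_type `"bulk"` or `"single-cell"`; the feature floor applies
#'   to bulk only.
#' @param bulk_min_features Feature floor for bulk data (default 500).
#' @return An object of class `rcc_features`: list with
#'   `selected_gene_ids`, `variance` (named, for the selected genes),
#'   `pct_used`, and `floor_applied`.
#' @export
select_variant_features <- function(X, pct, data_type = c("bulk", "single-cell"),
                                    bulk_min_features = 500) {
  data_type <- match.arg(data_type)
  if (!is.numeric(pct) || length(pct) != 1 || pct <= 0 || pct > 100)
    stop("'pct' must be in (0, 100]")
  v <- row_vars(X)
  nz <- v > 0
  if (sum(nz) < 2) stop("fewer than 2 genes with nonzero variance")
  n_target <- ceiling(pct / 100 * nrow(X))
  floor_applied <- FALSE
  if (data_type == "bulk" && n_target < bulk_min_features) {
    n_target <- min(bulk_min_features, nrow(X))
    floor_applied <- TRUE
  }
  ids <- rownames(X)[nz]
  vv <- v[nz]
  ord <- order(-vv, ids)
  n_sel <- min(n_target, length(ids))
  sel <- ids[ord][seq_len(n_sel)]
  structure(list(selected_gene_ids = sel,
                 variance = stats::setNames(vv[ord][seq_len(n_sel)], sel),
                 pct_used = pct,
                 floor_applied = floor_applied),
            class = "rcc_features")
}

# Row variances with the sample (n-1) convention, without apply() overhead.
row_vars <- function(X) {
  n <- ncol(X)
  mu <- rowMeans(X)
  (rowSums(X * X) - n * mu * mu) / (n - 1)
}

#' z-score each gene (row) of a matrix
#'
#' Centers each row to mean 0 and scales to standard deviation 1 (sample,
#' n-1 convention). Rows with zero variance are an error: filter them out
#' first with [select_variant_features()].
#'
#' @param X Numeric genes-by-samples matrix.
#' @return Matrix of the same shape with z-scored rows.
#' @export
zscore_rows <- function(X) {
  sds <- sqrt(row_vars(X))
  if (any(sds == 0 | !is.finite(sds)))
    stop("zero-variance gene(s) cannot be z-scored: ",
         paste(utils::head(rownames(X)[sds == 0 | !is.finite(sds)], 5),
               collapse = ", "))
  (X - rowMeans(X)) / sds
}

#' Restrict a matrix to a user-supplied gene list
#'
#' Typical use: keep protein-coding genes for single-cell data before
#' feature selection. Gene ids absent from the matrix are ignored.
#'
#' @param X Numeric genes-by-samples matrix.
#' @param gene_ids Character vector of gene ids to keep.
#' @return The row-subset matrix.
#' @export
filter_genes <- function(X, gene_ids) {
  keep <- intersect(rownames(X), gene_ids)
  if (length(keep) < 2)
    stop("fewer than 2 genes remain after applying the gene list filter")
  X[keep, , drop = FALSE]
}
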