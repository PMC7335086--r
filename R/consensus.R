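#' The eight consensus process settings
#'
#' The consensus engine is run eight times per node, once per cell of the
#' item/feature sampling grid: `p_item` in {0.6, 0.7, 0.8, 0.9} crossed
#' with `p_feature` in {0.8, 1.0}. Each setting carries its own RNG seed so
#' the eight processes are independent and the whole set is reproducible
#' from one top-level seed.
#'
#' @param repeats Consensus repeats per setting (default 100).
#' @param seed Optional integer; when given, the eight per-setting seeds are
#'   derived reproducibly from it. When `NULL`, they are drawn from the
#'   current RNG stream.
#' @return A data.frame with columns `p_item`, `p_feature`, `repeats`,
#'   `seed` (8 rows).
#' @export
parameter_grid <- function(repeats = 100, seed = NULL) {
  grid <- expand.grid(p_feature = c(0.8, 1.0), p_item = c(0.6, 0.7, 0.8, 0.9),
                      KEEP.OUT.ATTRS = FALSE)[, c("p_item", "p_feature")]
  draw <- function() sample.int(.Machine$integer.max - 1L, nrow(grid))
  seeds <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(process = seq_len(nrow(grid)), grid,
             repeats = as.integer(repeats), seed = seeds)
}

#' k-means labels for the columns of a z-scored matrix
#'
#' Thin wrapper over [stats::kmeans()] (Hartigan-Wong, Euclidean): samples
#' (columns) are the clustered objects, the best of `restarts` random
#' initializations by within-cluster sum of squares is kept.
#'
#' @param Z z-scored genes-by-samples matrix.
#' @param k Number of clusters (2 <= k <= number of samples).
#' @param restarts Random restarts (default 10).
#' @param seed Optional seed for reproducibility.
#' @return Integer vector of labels in 1..k, named by sample id.
#' @export
kmeans_labels <- function(Z, k, restarts = 10, seed = NULL) {
  n <- ncol(Z)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  if (k < 1) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (k == n) return(stats::setNames(seq_len(n), colnames(Z))) # WCSS = 0
  fit <- stats::kmeans(t(Z), centers = k, nstart = restarts,
                       iter.max = 1000, algorithm = "Hartigan-Wong")
  stats::setNames(as.integer(fit$cluster), colnames(Z))
}

#' Run one consensus process at one k
#'
#' Repeatedly draws `ceiling(p_item * N)` samples and
#' `ceiling(p_feature * G)` genes without replacement, clusters the
#' subsample with k-means, and accumulates, for every sample pair, the
#' number of repeats in which both were drawn (`co_sample`) and in which
#' they were assigned the same cluster (`co_cluster`). The consensus index
#' is `round(100 * co_cluster / co_sample)` (0 where a pair was never drawn
#' together). Consensus labels for this k are obtained by average-linkage
#' hierarchical clustering of `1 - index/100` cut at k.
#'
#' @param Z z-scored genes-by-samples matrix.
#' @param k Number of clusters (>= 2).
#' @param setting One row of [parameter_grid()] (or a list with `p_item`,
#'   `p_feature`, `repeats`, `seed`).
#' @param restarts,iter_max k-means restarts and iteration cap per repeat.
#' @param return_draws Keep the per-repeat sample draws (for diagnostics
#'   and replay checks; memory-heavy for large runs).
#' @return An object of class `rcc_consensus`: list with `k`, `index`
#'   (N x N integer 0--100), `co_cluster`, `co_sample`, `labels`, and
#'   `setting`.
#' @export
run_consensus <- function(Z, k, setting, restarts = 1, iter_max = 50,
                          return_draws = FALSE) {
  res <- consensus_multi(Z, k, setting, restarts, iter_max, return_draws)
  res[[1]]
}

# All ks in one pass: each repeat draws one item/feature subsample and
# clusters it at every k, so co_sample is shared across ks within a process.
consensus_multi <- function(Z, ks, setting, restarts = 1, iter_max = 50,
                            return_draws = FALSE) {
  stopifnot(all(ks >= 2))
  if (any(ks > ncol(Z)))
    stop("k exceeds the number of samples in the node")
  set.seed(setting$seed)
  eng <- .consensus_engine(t(Z), as.integer(ks), setting$p_item,
                           setting$p_feature, as.integer(setting$repeats),
                           as.integer(iter_max), as.integer(restarts),
                           isTRUE(return_draws))
  ids <- colnames(Z)
  out <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    cc <- eng$co_cluster[[i]]
    cs <- eng$co_sample
    index <- matrix(0L, nrow(cs), ncol(cs))
    pos <- cs > 0
    index[pos] <- as.integer(round(100 * cc[pos] / cs[pos]))
    dimnames(index) <- dimnames(cc) <- dimnames(cs) <- list(ids, ids)
    obj <- list(k = ks[i], index = index, co_cluster = cc, co_sample = cs,
                labels = consensus_labels(index, ks[i]),
                setting = as.list(setting))
    if (isTRUE(return_draws))
      obj$draws <- lapply(eng$draws, function(d) ids[d])
    class(obj) <- "rcc_consensus"
    out[[i]] <- obj
  }
  names(out) <- paste0("k", ks)
  out
}

#' Consensus cluster assignment from an index matrix
#'
#' Average-linkage hierarchical clustering of the consensus dissimilarity
#' `1 - index/100`, cut at k.
#'
#' @param index N x N consensus index matrix (0--100 scale).
#' @param k Number of clusters.
#' @return Integer labels in 1..k, named by sample id.
#' @export
consensus_labels <- function(index, k) {
  d <- stats::as.dist(1 - index / 100)
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' @export
print.rcc_consensus <- function(x, ...) {
  cat(sprintf("Consensus matrix: %d samples, k = %d, pItem = %.1f, pFeature = %.1f, %d repeats\n",
              nrow(x$index), x$k, x$setting$p_item, x$setting$p_feature,
              x$setting$repeats))
  invisible(x)
}
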