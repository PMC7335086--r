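#' Run the full recursive consensus clustering
#'
#' Depth-first divisive clustering: at each node the pipeline re-selects
#' the most variant genes among the node's own samples, z-scales them, runs
#' the eight consensus processes for k = 2..maxK, votes the optimal k, and
#' either splits the node into that many children (recursing on each) or
#' marks it terminal. Termination: fewer than `min_samples` samples, or a
#' zero vote (no k satisfies the criteria in any process). Per-level
#' cluster indices are concatenated into dotted final labels.
#'
#' @param X Genes-by-samples log2 expression matrix.
#' @param config An `rcc_config`. When `config$seed` is set the whole run
#'   is reproducible. When `config$gene_list` names a file, the matrix is
#'   restricted to those genes first (e.g. protein-coding for single-cell
#'   data). When `config$cutoff_level` is set, [apply_cutoff()] is applied
#'   to the finished tree.
#' @param verbose Print one line per node (level, path, size, vote).
#' @return Object of class `rcc_tree`: list with `root` (nested
#'   `rcc_node`s), `final` (named dotted labels), `depth`, `sample_ids`,
#'   `config`.
#' @export
rcc_run <- function(X, config, verbose = FALSE) {
  validate_expression(X)
  stopifnot(inherits(config, "rcc_config"))
  if (!is.na(config$gene_list) && is.character(config$gene_list))
    X <- filter_genes(X, read_gene_list(config$gene_list))
  cfg <- resolve_config(config, ncol(X))
  if (!is.na(cfg$seed)) set.seed(cfg$seed)
  root <- build_node(X, colnames(X), cfg, level = 0L, path = integer(0),
                     verbose = verbose)
  tree <- new_tree(root, colnames(X), cfg)
  if (!is.na(cfg$cutoff_level)) tree <- apply_cutoff(tree, cfg$cutoff_level)
  tree
}

new_tree <- function(root, sample_ids, config) {
  tree <- structure(list(root = root, sample_ids = sample_ids,
                         config = config),
                    class = "rcc_tree")
  tree$final <- final_labels(tree)
  tree$depth <- tree_depth(tree)
  tree
}

build_node <- function(X, ids, cfg, level, path, verbose) {
  node <- list(level = level,
               path_label = paste(path, collapse = "."),
               sample_ids = ids, n = length(ids),
               optimal_k = 0L, termination_reason = "none",
               children = list(), kselect = NULL)
  class(node) <- "rcc_node"
  if (length(ids) < cfg$min_samples) {
    node$termination_reason <- "too_few_samples"
    if (verbose) node_log(node, "too_few_samples")
    return(node)
  }
  sel <- rcc_select_k(X[, ids, drop = FALSE], cfg)
  sel$consensus <- NULL  # drop the large matrices; diagnostics keep the stats
  node$kselect <- sel
  if (sel$optimal_k == 0L) {
    node$termination_reason <- "k_zero"
    if (verbose) node_log(node, "k_zero")
    return(node)
  }
  node$optimal_k <- sel$optimal_k
  if (verbose) node_log(node, paste0("split k=", sel$optimal_k))
  labels <- sel$labels[ids]
  # order child clusters by size descending, ties by smallest member id
  sizes <- table(labels)
  min_id <- vapply(names(sizes), function(l) min(ids[labels == l]), character(1))
  ord <- names(sizes)[order(-as.integer(sizes), min_id)]
  node$children <- lapply(seq_along(ord), function(i) {
    child_ids <- ids[labels == ord[i]]
    build_node(X, child_ids, cfg, level + 1L, c(path, i), verbose)
  })
  node
}

node_log <- function(node, what) {
  message(sprintf("level %d  node [%s]  n=%d  %s", node$level,
                  if (nzchar(node$path_label)) node$path_label else "root",
                  node$n, what))
}

#' Decide whether a node terminates
#'
#' `too_few_samples` when the node has fewer than `min_samples` samples
#' (strict: a node of exactly `min_samples` is still clustered); `k_zero`
#' when a completed vote returned 0; `none` otherwise.
#'
#' @param node A list with at least `n` (sample count) and optionally
#'   `optimal_k` (the completed vote; `NULL` if not yet voted).
#' @param config An `rcc_config`.
#' @return One of `"too_few_samples"`, `"k_zero"`, `"none"`.
#' @export
should_terminate <- function(node, config) {
  if (node$n < config$min_samples) return("too_few_samples")
  if (!is.null(node$optimal_k) && identical(as.integer(node$optimal_k), 0L))
    return("k_zero")
  "none"
}

#' Final concatenated labels of a tree
#'
#' Each sample's label is the dot-joined sequence of its per-level cluster
#' indices down to its leaf. Cluster indices at each level are 1..k ordered
#' by cluster size descending (ties by smallest member id).
#'
#' @param tree An `rcc_tree`.
#' @return Named character vector (names = sample ids), in the original
#'   sample order.
#' @export
final_labels <- function(tree) {
  stopifnot(inherits(tree, "rcc_tree"))
  out <- character(0)
  walk <- function(node) {
    if (length(node$children) == 0) {
      lab <- if (nzchar(node$path_label)) node$path_label else "1"
      out[node$sample_ids] <<- lab
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  out[tree$sample_ids]
}

tree_depth <- function(tree) {
  walk <- function(node) {
    if (length(node$children) == 0) return(node$level)
    max(vapply(node$children, walk, integer(1)))
  }
  max(1L, walk(tree$root))
}

#' Collect the leaves of a tree
#' @param tree An `rcc_tree`.
#' @return List of leaf `rcc_node`s in depth-first order.
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0) out[[length(out) + 1]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' Per-level assignments of every sample
#'
#' @param tree An `rcc_tree`.
#' @return Character matrix (samples x levels) of dotted labels at each
#'   level; `NA` where a sample's branch terminated above that level.
#' @export
assignments_by_level <- function(tree) {
  depth <- tree_depth(tree)
  out <- matrix(NA_character_, length(tree$sample_ids), depth,
                dimnames = list(tree$sample_ids, paste0("level", seq_len(depth))))
  parts <- strsplit(final_labels(tree), ".", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    for (l in seq_len(min(depth, length(p))))
      out[i, l] <- paste(p[seq_len(l)], collapse = ".")
  }
  out
}

#' Truncate a tree at a recursion level
#'
#' Nodes deeper than `level` are removed; internal nodes at `level` become
#' leaves (termination reason `"cutoff"`) and final labels are recomputed.
#' Cutting at or beyond the tree depth returns the tree unchanged.
#'
#' @param tree An `rcc_tree`.
#' @param level Maximum depth to keep (>= 1).
#' @return The truncated `rcc_tree`.
#' @export
apply_cutoff <- function(tree, level) {
  stopifnot(inherits(tree, "rcc_tree"), level >= 1)
  prune <- function(node) {
    if (node$level >= level && length(node$children) > 0) {
      node$children <- list()
      node$termination_reason <- "cutoff"
      node$optimal_k <- 0L
    } else if (length(node$children) > 0) {
      node$children <- lapply(node$children, prune)
    }
    node
  }
  new_tree(prune(tree$root), tree$sample_ids, tree$config)
}

#' @export
print.rcc_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  cat(sprintf("Recursive consensus clustering tree: %d samples, depth %d, %d final clusters\n",
              length(x$sample_ids), x$depth, length(leaves)))
  tab <- table(x$final)
  cat("Cluster sizes:\n")
  print(tab)
  invisible(x)
}

#' Per-node summary of a run
#' @param tree An `rcc_tree`.
#' @return data.frame with one row per node: level, path, n, optimal k,
#'   termination reason.
#' @export
tree_summary <- function(tree) {
  rows <- list()
  walk <- function(node) {
    rows[[length(rows) + 1]] <<- data.frame(
      level = node$level,
      path = if (nzchar(node$path_label)) node$path_label else "root",
      n = node$n, optimal_k = node$optimal_k,
      termination = node$termination_reason, stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  do.call(rbind, rows)
}
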