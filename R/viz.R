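# Figure outputs. Every plot writes its underlying numeric matrix as a CSV
# sidecar next to the PDF so results can be checked on data, not pixels.

sidecar_path <- function(path, suffix = "") {
  sub("\\.pdf$", paste0(suffix, ".csv"), path)
}

white_red <- function(n = 100) grDevices::colorRampPalette(c("white", "red"))(n)

#' Tracking plot of a recursive clustering
#'
#' Columns are samples, grouped by final cluster. Three stacked panels:
#' (i) the marker panel - one row per recursion level, each cell colored
#' white-to-red by the number of marker genes of the sample's cluster at
#' that level, grey where the sample's branch was not subdivided to that
#' level; (ii) the level panel - cluster membership per level;
#' (iii) the annotation panel - one row per sample attribute.
#'
#' @param tree An `rcc_tree`.
#' @param markers Marker table from [tree_markers()] (may be empty).
#' @param annotation Optional data.frame of categorical attributes
#'   (rownames = sample ids).
#' @param path Output PDF path; a CSV sidecar with the per-sample,
#'   per-level assignments and marker counts is written alongside.
#' @return Invisibly, the underlying model (sample order, marker-count
#'   matrix, level assignments).
#' @export
tracking_plot <- function(tree, markers, annotation = NULL, path) {
  stopifnot(inherits(tree, "rcc_tree"))
  lv <- assignments_by_level(tree)
  depth <- ncol(lv)
  final <- final_labels(tree)
  ord <- order(final, names(final))
  samples <- tree$sample_ids[ord]
  # marker counts per (level, cluster label)
  mcount <- matrix(NA_real_, depth, length(samples),
                   dimnames = list(paste0("level", seq_len(depth)), samples))
  for (l in seq_len(depth)) {
    labs <- lv[samples, l]
    counts <- if (nrow(markers)) table(markers$cluster_label[markers$level == l]) else table(character(0))
    mcount[l, ] <- ifelse(is.na(labs), NA,
                          as.numeric(counts[labs]))
    mcount[l, !is.na(labs) & is.na(mcount[l, ])] <- 0
  }
  model <- list(samples = samples, marker_counts = mcount,
                levels = t(lv[samples, , drop = FALSE]),
                final = final[samples], annotation = annotation)
  side <- data.frame(sample = samples, t(mcount),
                     lv[samples, , drop = FALSE], final = final[samples],
                     check.names = FALSE)
  colnames(side) <- c("sample", paste0("markers_level", seq_len(depth)),
                      paste0("level", seq_len(depth)), "final")
  utils::write.csv(side, sidecar_path(path), row.names = FALSE)

  n_ann <- if (!is.null(annotation)) ncol(annotation) else 0
  grDevices::pdf(path, width = 9, height = 2 + 0.45 * (2 * depth + n_ann))
  on.exit(grDevices::dev.off(), add = TRUE)
  nrows <- 2 * depth + max(n_ann, 1)
  old <- graphics::par(mar = c(0.3, 8, 0.3, 1), oma = c(2, 0, 2, 0))
  on.exit(graphics::par(old), add = TRUE)
  graphics::layout(matrix(seq_len(nrows), ncol = 1))
  pal <- white_red(100)
  mx <- max(1, mcount, na.rm = TRUE)
  for (l in seq_len(depth)) {   # marker panel: grey = not subdivided
    v <- mcount[l, ]
    cols <- ifelse(is.na(v), "grey70", pal[pmax(1, ceiling(99 * v / mx) + 1)])
    strip_plot(cols, paste0("markers L", l))
  }
  for (l in seq_len(depth)) {   # level panel
    labs <- lv[samples, l]
    u <- sort(unique(labs[!is.na(labs)]))
    qual <- grDevices::colorRampPalette(
      c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e", "#e6ab02"))(max(2, length(u)))
    cols <- ifelse(is.na(labs), "grey70", qual[match(labs, u)])
    strip_plot(cols, paste0("level ", l))
  }
  if (n_ann > 0) {
    for (a in seq_len(n_ann)) {
      vals <- as.character(annotation[samples, a])
      u <- sort(unique(vals))
      qual <- grDevices::colorRampPalette(
        c("#a6cee3", "#1f78b4", "#b2df8a", "#33a02c", "#fb9a99", "#e31a1c"))(max(2, length(u)))
      strip_plot(qual[match(vals, u)], colnames(annotation)[a])
    }
  } else {
    strip_plot(rep("white", length(samples)), "")
  }
  graphics::mtext("samples (grouped by final cluster)", side = 1, outer = TRUE)
  graphics::mtext("Cluster tracking", side = 3, outer = TRUE, font = 2)
  invisible(model)
}

strip_plot <- function(cols, label) {
  n <- length(cols)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, n), ylim = c(0, 1), xaxs = "i", yaxs = "i")
  graphics::rect((seq_len(n) - 1), 0, seq_len(n), 1, col = cols, border = NA)
  graphics::mtext(label, side = 2, las = 2, cex = 0.6, line = 0.5)
}

#' Cluster annotation plot
#'
#' For each attribute, the matrix of proportions P(attribute value |
#' cluster): rows are clusters, columns are attribute values, each row sums
#' to 1, rendered white (no overlap) to red (all of the cluster).
#'
#' @param labels Cluster labels per sample (named).
#' @param annotation data.frame of categorical attributes (rownames =
#'   sample ids).
#' @param path Output PDF path; the proportion matrices are written to a
#'   long-format CSV sidecar.
#' @return Invisibly, a named list of proportion matrices (one per
#'   attribute).
#' @export
cluster_annotation_plot <- function(labels, annotation, path) {
  if (is.null(annotation) || ncol(annotation) == 0)
    stop("annotation is required for the cluster annotation plot")
  ids <- names(labels)
  stopifnot(!is.null(ids), all(ids %in% rownames(annotation)))
  mats <- list()
  long <- list()
  for (a in colnames(annotation)) {
    tab <- table(labels, as.character(annotation[ids, a]))
    P <- sweep(tab, 1, pmax(1, rowSums(tab)), "/")
    mats[[a]] <- as.matrix(P)
    long[[a]] <- data.frame(attribute = a,
                            cluster = rep(rownames(P), ncol(P)),
                            value = rep(colnames(P), each = nrow(P)),
                            proportion = as.vector(as.matrix(P)))
  }
  utils::write.csv(do.call(rbind, long), sidecar_path(path), row.names = FALSE)
  grDevices::pdf(path, width = 7, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (a in names(mats)) {
    P <- mats[[a]]
    graphics::image(seq_len(ncol(P)), seq_len(nrow(P)), t(P)[, rev(seq_len(nrow(P))), drop = FALSE],
                    zlim = c(0, 1), col = white_red(100), axes = FALSE,
                    xlab = "", ylab = "", main = paste("Attribute:", a))
    graphics::axis(1, seq_len(ncol(P)), colnames(P), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(nrow(P)), rev(rownames(P)), las = 2, cex.axis = 0.7)
    graphics::box()
  }
  invisible(mats)
}

#' Marker-gene heatmap
#'
#' Rows are marker genes grouped by owning cluster, columns are samples
#' grouped by cluster; values are z-scored per gene. A cluster annotation
#' bar marks the column groups.
#'
#' @param X Genes-by-samples log2 matrix.
#' @param markers Marker table from [find_markers()]/[tree_markers()].
#' @param labels Cluster labels per sample (named).
#' @param path Output PDF path; the plotted matrix goes to a CSV sidecar.
#' @return Invisibly, the z-scored matrix (or `NULL` when no markers).
#' @export
gene_marker_heatmap <- function(X, markers, labels, path) {
  if (nrow(markers) == 0) {
    grDevices::pdf(path, width = 6, height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot.new()
    graphics::text(0.5, 0.5, "No marker genes at any level")
    utils::write.csv(data.frame(), sidecar_path(path), row.names = FALSE)
    return(invisible(NULL))
  }
  mk <- markers[order(markers$cluster_label, markers$fdr), ]
  mk <- mk[!duplicated(mk$gene_id), ]
  ids <- names(labels)
  ord <- ids[order(as.character(labels), ids)]
  M <- zscore_rows(X[mk$gene_id, ord, drop = FALSE])
  utils::write.csv(data.frame(gene_id = rownames(M),
                              cluster_label = mk$cluster_label, M,
                              check.names = FALSE),
                   sidecar_path(path), row.names = FALSE)
  ann_col <- data.frame(cluster = as.character(labels)[match(ord, ids)],
                        row.names = ord)
  pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                     show_colnames = FALSE,
                     show_rownames = nrow(M) <= 60,
                     annotation_col = ann_col, filename = path,
                     main = "Cluster marker genes (z-scored)")
  invisible(M)
}

#' Consensus-of-runs heatmap
#'
#' Given final labels from repeated seeded runs over the same samples, the
#' N x N matrix of the fraction of runs in which each sample pair shares a
#' final cluster (symmetric, unit diagonal).
#'
#' @param label_sets List (length >= 2) of named label vectors over
#'   identical samples.
#' @param path Output PDF path; the matrix goes to a CSV sidecar.
#' @return Invisibly, the pair-fraction matrix.
#' @export
runs_consensus_heatmap <- function(label_sets, path) {
  stopifnot(length(label_sets) >= 2)
  ids <- sort(names(label_sets[[1]]))
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (ls in label_sets) {
    if (!identical(sort(names(ls)), ids))
      stop("runs cover different sample sets")
    same <- outer(ls[ids], ls[ids], "==")
    M <- M + same
  }
  M <- M / length(label_sets)
  utils::write.csv(data.frame(sample = rownames(M), M, check.names = FALSE),
                   sidecar_path(path), row.names = FALSE)
  pheatmap::pheatmap(M, color = white_red(100), breaks = seq(0, 1, length.out = 101),
                     show_rownames = FALSE, show_colnames = FALSE,
                     filename = path, main = "Consensus of repeated runs")
  invisible(M)
}

#' ssGSEA heatmap
#'
#' Gene sets by samples, scores z-scored per set, columns grouped by
#' cluster.
#'
#' @param scores Output of [ssgsea_scores()].
#' @param labels Cluster labels per sample (named).
#' @param path Output PDF path; the plotted matrix goes to a CSV sidecar.
#' @return Invisibly, the plotted matrix.
#' @export
ssgsea_plot <- function(scores, labels, path) {
  M <- ssgsea_matrix(scores, zscore = TRUE)
  ids <- names(labels)
  ord <- ids[order(as.character(labels), ids)]
  M <- M[, ord, drop = FALSE]
  utils::write.csv(data.frame(gene_set = rownames(M), M, check.names = FALSE),
                   sidecar_path(path), row.names = FALSE)
  ann_col <- data.frame(cluster = as.character(labels)[match(ord, ids)],
                        row.names = ord)
  pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                     show_colnames = FALSE, annotation_col = ann_col,
                     filename = path,
                     main = "ssGSEA enrichment (z-scored per set)")
  invisible(M)
}
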