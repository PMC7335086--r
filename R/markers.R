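#' Marker genes per cluster
#'
#' One-vs-rest Wilcoxon rank-sum test per gene per cluster on the log2
#' (not z-scored) matrix, BH-corrected within each cluster comparison.
#' Reported markers satisfy `fdr < 0.01` and log2 fold change (difference
#' of means on the log2 scale) `> 1` by default, sorted by adjusted p then
#' fold change.
#'
#' @param X Genes-by-samples log2 matrix.
#' @param labels Cluster labels over the columns of `X` (>= 2 clusters).
#' @param level Recursion level tag carried into the output (default `NA`).
#' @param fdr BH-adjusted p threshold (default 0.01).
#' @param lfc log2 fold-change threshold (default 1).
#' @return data.frame with columns `gene_id`, `cluster_label`, `level`,
#'   `log2_fold_change`, `fdr`.
#' @export
find_markers <- function(X, labels, level = NA_integer_, fdr = 0.01, lfc = 1.0) {
  cl <- sort(unique(as.character(labels)))
  if (length(cl) < 2) stop("marker detection needs at least 2 clusters")
  rk <- rank_matrix(X)
  out <- list()
  for (c in cl) {
    in_idx <- as.character(labels) == c
    if (sum(in_idx) < 2 || sum(!in_idx) < 2) next
    rs <- ranksum_rows(X, in_idx, rk)
    padj <- stats::p.adjust(rs$p, method = "BH")
    keep <- padj < fdr & rs$delta > lfc
    if (any(keep)) {
      out[[c]] <- data.frame(gene_id = rownames(X)[keep],
                             cluster_label = c,
                             level = level,
                             log2_fold_change = rs$delta[keep],
                             fdr = padj[keep],
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), cluster_label = character(0),
                      level = integer(0), log2_fold_change = numeric(0),
                      fdr = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$fdr, -res$log2_fold_change), ]
  rownames(res) <- NULL
  res
}

#' Marker genes at every level of a tree
#'
#' At each internal node, markers distinguish its children from one another
#' (one-vs-rest among the node's own samples), so level-l markers are the
#' genes newly separating level-l clusters within their parent.
#'
#' @param X Genes-by-samples log2 matrix (all samples of the run).
#' @param tree An `rcc_tree`.
#' @param fdr,lfc Thresholds as in [find_markers()].
#' @return data.frame as in [find_markers()] with `cluster_label` holding
#'   the dotted child label.
#' @export
tree_markers <- function(X, tree, fdr = 0.01, lfc = 1.0) {
  out <- list()
  walk <- function(node) {
    if (length(node$children) >= 2) {
      ids <- node$sample_ids
      labs <- rep(NA_character_, length(ids)); names(labs) <- ids
      for (ch in node$children) labs[ch$sample_ids] <- ch$path_label
      mk <- find_markers(X[, ids, drop = FALSE], labs,
                         level = node$level + 1L, fdr = fdr, lfc = lfc)
      if (nrow(mk)) out[[length(out) + 1]] <<- mk
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), cluster_label = character(0),
                      level = integer(0), log2_fold_change = numeric(0),
                      fdr = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher cluster-attribute enrichment
#'
#' For every (cluster, attribute value) pair, a two-sided Fisher's exact
#' test on the 2x2 table {in/out of cluster} x {has/lacks the value}. Both
#' raw and BH-adjusted p-values are reported.
#'
#' @param labels Cluster labels per sample (>= 2 clusters).
#' @param annotation Character/factor vector of one categorical attribute,
#'   aligned with `labels`.
#' @return data.frame with columns `cluster_label`, `attribute_value`,
#'   `count_in`, `count_out`, `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
fisher_enrichment <- function(labels, annotation) {
  stopifnot(length(labels) == length(annotation))
  labels <- as.character(labels); annotation <- as.character(annotation)
  if (length(unique(labels)) < 2) stop("enrichment needs at least 2 clusters")
  if (length(unique(annotation)) < 2)
    stop("attribute has a single level; nothing to test")
  rows <- list()
  for (cl in sort(unique(labels))) {
    for (v in sort(unique(annotation))) {
      a <- sum(labels == cl & annotation == v)
      b <- sum(labels == cl & annotation != v)
      c2 <- sum(labels != cl & annotation == v)
      d <- sum(labels != cl & annotation != v)
      ft <- stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        cluster_label = cl, attribute_value = v,
        count_in = a, count_out = c2,
        odds_ratio = unname(ft$estimate), p_value = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Adjusted Rand index between two partitions
#'
#' Standard permutation-model chance-corrected agreement from the
#' contingency table; 1 for identical partitions (up to relabeling), about
#' 0 for independent ones.
#'
#' @param a,b Two label vectors over the same samples.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' Kaplan-Meier comparison of cluster survival
#'
#' Kaplan-Meier estimate per cluster, overall log-rank test across
#' clusters, and pairwise log-rank p-values. Optionally writes a survival
#' plot (PDF).
#'
#' @param labels Cluster labels per sample.
#' @param surv data.frame with columns `time` (> 0) and `event`
#'   (1 = event, 0 = censored), one row per sample in the order of
#'   `labels`.
#' @param path Optional PDF path for the plot.
#' @return List with `fit` (the [survival::survfit] object), `overall_p`
#'   (log-rank), and `pairwise` (data.frame with `cluster1`, `cluster2`,
#'   `p_value`).
#' @export
cluster_survival <- function(labels, surv, path = NULL) {
  stopifnot(is.data.frame(surv), all(c("time", "event") %in% names(surv)),
            nrow(surv) == length(labels))
  cluster <- factor(labels)
  ev_per <- tapply(surv$event, cluster, sum)
  if (length(levels(cluster)) < 2) stop("survival comparison needs >= 2 clusters")
  if (any(ev_per < 2))
    stop("every cluster needs at least 2 observed events; offending: ",
         paste(names(ev_per)[ev_per < 2], collapse = ", "))
  df <- data.frame(time = surv$time, event = surv$event, cluster = cluster)
  fit <- survival::survfit(survival::Surv(time, event) ~ cluster, data = df)
  sd_all <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = df)
  overall_p <- stats::pchisq(sd_all$chisq, df = length(levels(cluster)) - 1,
                             lower.tail = FALSE)
  lv <- levels(cluster)
  pw <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    sub <- df[df$cluster %in% lv[c(i, j)], ]
    sub$cluster <- droplevels(sub$cluster)
    sd <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = sub)
    pw[[length(pw) + 1]] <- data.frame(
      cluster1 = lv[i], cluster2 = lv[j],
      p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  pairwise <- do.call(rbind, pw)
  if (!is.null(path)) {
    grDevices::pdf(path, width = 7, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(fit, col = seq_along(lv), lwd = 2, xlab = "Time",
         ylab = "Survival probability",
         main = sprintf("Kaplan-Meier by cluster (log-rank p = %.3g)",
                        overall_p))
    graphics::legend("topright", legend = lv, col = seq_along(lv), lwd = 2,
                     bty = "n")
  }
  list(fit = fit, overall_p = overall_p, pairwise = pairwise)
}

#' ARI of repeated runs against a reference run
#'
#' The cross-run stability protocol: given final labels from several
#' seeded runs over the same samples, compute the adjusted Rand index of
#' every run against one reference run (by default a randomly chosen one).
#'
#' @param label_sets List of named label vectors over identical samples.
#' @param reference Index of the reference run; `NULL` picks one at random.
#' @return List with `reference` (index) and `ari` (numeric vector, one
#'   entry per run; the reference's own entry is 1).
#' @export
runs_ari <- function(label_sets, reference = NULL) {
  stopifnot(length(label_sets) >= 2)
  ids <- names(label_sets[[1]])
  for (ls in label_sets)
    if (!identical(sort(names(ls)), sort(ids)))
      stop("runs cover different sample sets")
  if (is.null(reference)) reference <- sample.int(length(label_sets), 1)
  ref <- label_sets[[reference]][ids]
  ari <- vapply(label_sets, function(ls) adjusted_rand_index(ls[ids], ref),
                numeric(1))
  list(reference = reference, ari = ari)
}
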