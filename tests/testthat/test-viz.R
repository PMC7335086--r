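# Plot functions are checked through their CSV sidecars and returned
# matrices; PDFs are smoke-tested for existence only.

make_tree_fixture <- function() {
  df <- data.frame(sample = sprintf("s%02d", 1:12),
                   final = c(rep("1", 6), rep("2.1", 3), rep("2.2", 3)))
  tree_from_cluster_info(df)
}

test_that("tracking plot model shares one sample order across panels", {
  tree <- make_tree_fixture()
  X <- toy_matrix(60, 12, seed = 20)
  colnames(X) <- tree$sample_ids
  X[1:10, 1:6] <- X[1:10, 1:6] + 4        # markers for cluster 1
  mk <- tree_markers(X, tree)
  ann <- data.frame(group = rep(c("u", "v"), 6),
                    row.names = tree$sample_ids)
  path <- tempfile(fileext = ".pdf")
  model <- tracking_plot(tree, mk, ann, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  side <- utils::read.csv(sub("pdf$", "csv", path))
  expect_equal(nrow(side), 12)
  expect_equal(nrow(model$marker_counts), tree$depth)  # one row per level
  # grey sentinel: cluster 1 is not subdivided, so level-2 marker count is NA
  s_in_1 <- model$samples[model$final == "1"]
  expect_true(all(is.na(model$marker_counts[2, s_in_1])))
  expect_false(anyNA(model$marker_counts[1, ]))
  # panels share the order
  expect_identical(colnames(model$marker_counts), model$samples)
  expect_identical(colnames(model$levels), model$samples)
  # re-render determinism
  model2 <- tracking_plot(tree, mk, ann, tempfile(fileext = ".pdf"))
  expect_identical(model$samples, model2$samples)
})

test_that("annotation plot proportions are normalized per cluster", {
  labels <- stats::setNames(rep(c("1", "2"), each = 10), sprintf("s%d", 1:20))
  ann <- data.frame(tissue = rep(c("a", "b"), 10),
                    row.names = names(labels))
  path <- tempfile(fileext = ".pdf")
  mats <- cluster_annotation_plot(labels, ann, path)
  P <- mats$tissue
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  expect_true(file.exists(sub("pdf$", "csv", path)))

  # clusters identical to the attribute -> permutation matrix
  ann2 <- data.frame(tissue = unname(labels), row.names = names(labels))
  mats2 <- cluster_annotation_plot(labels, ann2, tempfile(fileext = ".pdf"))
  expect_equal(sort(as.vector(mats2$tissue)), c(0, 0, 1, 1))

  expect_error(cluster_annotation_plot(labels, NULL, path), "required")
})

test_that("marker heatmap groups rows and columns by cluster", {
  sim <- simulate_flat(group_sizes = c(15, 15), n_genes = 200,
                       markers_per_group = 10, seed = 21)
  mk <- find_markers(sim$X, sim$labels, level = 1)
  path <- tempfile(fileext = ".pdf")
  M <- gene_marker_heatmap(sim$X, mk, sim$labels, path)
  expect_true(file.exists(path))
  side <- utils::read.csv(sub("pdf$", "csv", path), check.names = FALSE)
  expect_true(all(c("gene_id", "cluster_label") %in% names(side)))
  # rows grouped contiguously per owning cluster
  expect_false(is.unsorted(side$cluster_label))
  # columns grouped per cluster
  expect_false(is.unsorted(as.character(sim$labels[colnames(M)])))

  # empty marker list: notice plot, empty sidecar, NULL matrix
  empty <- find_markers(sim$X, sim$labels)[0, ]
  p2 <- tempfile(fileext = ".pdf")
  expect_null(gene_marker_heatmap(sim$X, empty, sim$labels, p2))
  expect_true(file.exists(p2))
})

test_that("consensus-of-runs matrix matches a direct recount", {
  ids <- sprintf("s%d", 1:6)
  runs <- list(stats::setNames(c(1, 1, 1, 2, 2, 2), ids),
               stats::setNames(c(1, 1, 2, 2, 2, 2), ids),
               stats::setNames(c(2, 2, 2, 1, 1, 1), ids))
  path <- tempfile(fileext = ".pdf")
  M <- runs_consensus_heatmap(runs, path)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    frac <- mean(vapply(runs, function(r)
      r[ids[i]] == r[ids[j]], logical(1)))
    expect_equal(M[ids[i], ids[j]], frac)
  }
  # identical runs -> 0/1 block matrix
  M2 <- runs_consensus_heatmap(runs[c(1, 3)], tempfile(fileext = ".pdf"))
  expect_true(all(M2 %in% c(0, 1)))
  bad <- list(runs[[1]], stats::setNames(rep(1, 6), sprintf("t%d", 1:6)))
  expect_error(runs_consensus_heatmap(bad, path), "different sample sets")
})

test_that("ssGSEA heatmap writes a z-scored sets-by-samples sidecar", {
  X <- toy_matrix(40, 10, seed = 22)
  sets <- list(s1 = rownames(X)[1:10], s2 = rownames(X)[11:20])
  sc <- ssgsea_scores(X, sets)
  labels <- stats::setNames(rep(c("1", "2"), each = 5), colnames(X))
  path <- tempfile(fileext = ".pdf")
  M <- ssgsea_plot(sc, labels, path)
  expect_equal(dim(M), c(2, 10))
  expect_true(all(abs(rowMeans(M)) < 1e-10))
  expect_true(file.exists(sub("pdf$", "csv", path)))
})
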