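test_that("marker detection has power at the stated effect size", {
  hits <- vapply(1:10, function(s) {
    X <- toy_matrix(200, 60, seed = 600 + s)
    X[1:50, 1:30] <- X[1:50, 1:30] + 3    # 50 genes, +3 log2 in cluster A
    labels <- rep(c("A", "B"), each = 30)
    mk <- find_markers(X, labels)
    sum(mk$cluster_label == "A" & mk$gene_id %in% sprintf("g%03d", 1:50))
  }, numeric(1))
  expect_true(all(hits >= 45))
})

test_that("permuted labels on homogeneous data give (almost) no markers", {
  n_mk <- vapply(1:20, function(s) {
    X <- toy_matrix(100, 40, seed = 700 + s)
    labels <- sample(rep(1:2, each = 20))
    nrow(find_markers(X, labels))
  }, numeric(1))
  expect_lte(mean(n_mk > 0), 0.05)
  expect_lte(sum(n_mk) / (20 * 100), 0.01)
})

test_that("fold-change threshold excludes small shifts regardless of p", {
  X <- toy_matrix(50, 200, seed = 8)
  X[1, 1:100] <- X[1, 1:100] + 0.5  # significant but below lfc = 1
  labels <- rep(1:2, each = 100)
  mk <- find_markers(X, labels)
  expect_false("g001" %in% mk$gene_id)
  mk_loose <- find_markers(X, labels, lfc = 0.2)
  expect_true("g001" %in% mk_loose$gene_id)
})

test_that("markers are cluster-specific for disjoint effects", {
  sim <- simulate_flat(group_sizes = c(30, 30, 30), n_genes = 300,
                       markers_per_group = 20, seed = 9)
  mk <- find_markers(sim$X, sim$labels)
  expect_equal(anyDuplicated(mk$gene_id), 0)
  expect_invariants <- all(c("gene_id", "cluster_label", "level",
                             "log2_fold_change", "fdr") %in% names(mk))
  expect_true(expect_invariants)
  expect_true(all(mk$fdr < 0.01 & mk$log2_fold_change > 1))
})

test_that("ssGSEA scores match a step-by-step oracle and order sensibly", {
  X <- toy_matrix(20, 5, seed = 10)
  sets <- list(top = character(0), bottom = character(0))
  # per-sample ordering property: top-m set beats bottom-m set
  for (s in seq_len(ncol(X))) {
    ord <- order(X[, s], decreasing = TRUE)
    top <- rownames(X)[ord[1:5]]
    bottom <- rownames(X)[ord[16:20]]
    sc <- ssgsea_scores(X[, s, drop = FALSE],
                        list(top = top, bottom = bottom))
    expect_gt(sc$enrichment_score[sc$gene_set_name == "top"],
              sc$enrichment_score[sc$gene_set_name == "bottom"])
  }

  # independent direct implementation of the running-sum statistic
  oracle_es <- function(expr, set, alpha = 0.25) {
    G <- length(expr)
    rk <- rank(expr)
    ord <- order(expr, decreasing = TRUE)
    member <- names(expr) %in% set
    w <- rk^alpha
    pin <- 0; pout <- 0; es <- 0
    sum_w <- sum(w[member])
    for (g in ord) {
      if (member[g]) pin <- pin + w[g] / sum_w
      else pout <- pout + 1 / (G - sum(member))
      es <- es + (pin - pout)
    }
    as.numeric(es)
  }
  set <- c("g003", "g007", "g011", "g015")
  sc <- ssgsea_scores(X, list(myset = set))
  for (s in seq_len(ncol(X))) {
    expr <- stats::setNames(X[, s], rownames(X))
    expect_equal(sc$enrichment_score[sc$sample_id == colnames(X)[s]],
                 oracle_es(expr, set), tolerance = 1e-10)
  }

  # absent genes are dropped with a warning; empty sets are an error
  expect_warning(ssgsea_scores(X, list(a = c("g001", "nope", "g002"))),
                 "absent")
  expect_error(suppressWarnings(ssgsea_scores(X, list(a = "nope"))),
               "no genes")
})

test_that("singleton-set score increases with the gene's rank", {
  X <- toy_matrix(30, 2, seed = 11)
  X["g005", 1] <- max(X[, 1]) + 1  # top rank in sample 1
  X["g005", 2] <- min(X[, 2]) - 1  # bottom rank in sample 2
  X[X < 0] <- 0
  sc <- ssgsea_scores(X, list(s = "g005"))
  expect_gt(sc$enrichment_score[sc$sample_id == "s001"],
            sc$enrichment_score[sc$sample_id == "s002"])
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # 2x2 table (8,2;1,9): p from direct tail enumeration
  labels <- rep(c("c1", "c2"), c(10, 10))
  attr_val <- c(rep("x", 8), rep("y", 2), "x", rep("y", 9))
  fe <- fisher_enrichment(labels, attr_val)
  row <- fe[fe$cluster_label == "c1" & fe$attribute_value == "x", ]
  # enumeration oracle: sum P(tables) <= P(observed) over all tables with
  # the same margins (row total 10, column total 9, n 20)
  p_obs <- dhyper(8, 9, 11, 10)
  p_enum <- sum(vapply(0:9, function(a) {
    p <- dhyper(a, 9, 11, 10)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
  expect_equal(row$p_value, p_enum, tolerance = 1e-9)
  expect_equal(row$count_in, 8)
  expect_equal(row$count_out, 1)

  # perfect association: tiny p
  lab2 <- rep(c("c1", "c2"), each = 15)
  expect_lt(min(fisher_enrichment(lab2, lab2)$p_value), 1e-6)
  expect_error(fisher_enrichment(lab2, rep("only", 30)), "single level")
})

test_that("Fisher p-values are roughly uniform under independence", {
  prop_small <- vapply(1:40, function(s) {
    set.seed(900 + s)
    labels <- sample(rep(1:3, each = 20))
    attr_val <- sample(rep(c("x", "y"), each = 30))
    fe <- fisher_enrichment(labels, attr_val)
    mean(fe$p_value < 0.05)
  }, numeric(1))
  expect_lte(mean(prop_small), 0.07)
})

test_that("ARI matches an independent implementation and is well-behaved", {
  expect_equal(adjusted_rand_index(rep(1:3, 5), rep(1:3, 5)), 1)
  a <- rep(1:4, each = 5)
  perm <- sample(a)
  expect_equal(adjusted_rand_index(a, perm), adjusted_rand_index(perm, a))
  # chance-corrected limit: singletons vs one block
  expect_equal(adjusted_rand_index(1:10, rep(1, 10)), 0)
  # relabeling invariance
  expect_equal(adjusted_rand_index(a, c(2, 1, 4, 3)[a]), 1)
  # independent contingency-table implementation (mclust)
  set.seed(12)
  for (i in 1:5) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:5, 1:6), "length")
})

test_that("log-rank comparison is calibrated and powered", {
  # identical survival in both clusters -> p near 1
  surv <- data.frame(time = rep(c(1, 2, 3, 4, 5), 4),
                     event = rep(1L, 20))
  labels <- rep(1:2, each = 10)
  res <- cluster_survival(labels, surv)
  expect_gt(res$overall_p, 0.9)

  # 4x hazard ratio, n = 100 per arm: p < 0.01 in nearly all seeds
  hits <- vapply(1:20, function(s) {
    labels <- rep(c("a", "b"), each = 100)
    sv <- simulate_survival(labels, c(a = 1, b = 4), censor_rate = 0.1,
                            seed = 1000 + s)
    cluster_survival(labels, sv[, c("time", "event")])$overall_p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # KM estimator: non-increasing step function starting at 1
  fit <- res$fit
  expect_true(all(fit$surv <= 1 + 1e-12))
  for (stratum in seq_along(fit$strata)) {
    idx <- (cumsum(c(0, fit$strata))[stratum] + 1):cumsum(fit$strata)[stratum]
    expect_true(all(diff(fit$surv[idx]) <= 1e-12))
  }
  expect_error(cluster_survival(rep(1:2, each = 5),
                                data.frame(time = rep(1, 10),
                                           event = rep(0L, 10))),
               "events")
})

test_that("cross-run ARI helper validates inputs and scores identity", {
  l1 <- stats::setNames(rep(1:2, each = 5), sprintf("s%d", 1:10))
  l2 <- stats::setNames(c(rep(2, 5), rep(1, 5)), sprintf("s%d", 1:10))
  set.seed(1)
  res <- runs_ari(list(l1, l2, l1))
  expect_true(all(res$ari == 1))  # all three are the same partition
  bad <- stats::setNames(rep(1, 10), sprintf("t%d", 1:10))
  expect_error(runs_ari(list(l1, bad)), "different sample sets")
})
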