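test_that("maxK follows min(10, n/10)", {
  expect_equal(compute_maxK(300), 10L)
  expect_equal(compute_maxK(98), 9L)
  expect_equal(compute_maxK(25), 2L)
  expect_lt(compute_maxK(19), 2L)  # signals "cannot cluster"
})

test_that("CDF matches brute-force pair enumeration", {
  # degenerate: all off-diagonal zero -> CDF = 1 everywhere
  M0 <- perfect_index(c(4))
  M0[upper.tri(M0)] <- 0; M0[lower.tri(M0)] <- 0
  expect_true(all(compute_cdf(M0)$values == 1))

  # two perfect clusters of 2: CDF = 4/6 below 100
  M <- perfect_index(c(2, 2))
  cdf <- compute_cdf(M)
  expect_equal(cdf$values[1:100], rep(4 / 6, 100))
  expect_equal(cdf$values[101], 1)
  expect_equal(cdf$n_pairs, 6)

  # random symmetric matrices vs brute force, N up to 20
  for (trial in 1:10) {
    set.seed(trial)
    n <- sample(2:20, 1)
    M <- matrix(0L, n, n)
    M[upper.tri(M)] <- sample(0:100, n * (n - 1) / 2, replace = TRUE)
    M <- M + t(M); diag(M) <- 100L
    cdf <- compute_cdf(M)
    pairs <- M[upper.tri(M)]
    for (c in c(0, 1, 17, 50, 99, 100))
      expect_equal(cdf$values[c + 1], mean(pairs <= c))
    expect_true(all(diff(cdf$values) >= 0))   # monotone
    expect_equal(cdf$values[101], 1)
  }
})

test_that("perfect CDF value equals the between-cluster pair fraction", {
  expect_equal(perfect_cdf_value(10), 0)       # one cluster
  expect_equal(perfect_cdf_value(rep(1, 7)), 1) # all singletons
  expect_equal(perfect_cdf_value(c(3, 3)), 1 - 6 / 15)
  # enumeration oracle
  for (trial in 1:10) {
    set.seed(100 + trial)
    sizes <- sample(1:6, sample(2:4, 1), replace = TRUE)
    labels <- rep(seq_along(sizes), sizes)
    n <- length(labels)
    between <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      between <- between + (labels[i] != labels[j])
    expect_equal(perfect_cdf_value(sizes), between / (n * (n - 1) / 2))
  }
})

test_that("a perfect consensus matrix yields the full-span zero-slope line", {
  for (sizes in list(c(5, 5), c(20, 20, 20), c(7, 3, 2))) {
    M <- perfect_index(sizes)
    line <- fit_trim_line(compute_cdf(M), perfect_cdf_value(sizes))
    expect_true(line$valid)
    expect_equal(line$c_start, 0)
    expect_equal(line$c_end, 99)
    expect_equal(line$length, 99)
    expect_equal(line$slope_deg, 0)
  }
})

test_that("line fitting is invalid when the band holds fewer than 2 points", {
  # a steep staircase CDF: plateau value never approached within +-0.5
  M <- perfect_index(c(4, 4))
  curve <- compute_cdf(M)
  line <- fit_trim_line(curve, cdfp = 0.2)  # wrong plateau, band ~empty
  expect_false(line$valid)
})

test_that("trimming matches an exhaustive low-end trim oracle", {
  # perfect plateau perturbed at low c: steps push early CDF values up
  sizes <- c(30, 30)
  cdfp <- perfect_cdf_value(sizes)
  values <- rep(cdfp, 101); values[101] <- 1
  set.seed(5)
  bump <- seq(0.004, 0, length.out = 20)
  values[1:20] <- cdfp + bump   # within the +-0.5 (0-100 scale) band but sloped
  curve <- structure(list(values = values, n_pairs = 100), class = "rcc_cdf")

  min_slope <- 0.05; min_len <- 30
  got <- fit_trim_line(curve, cdfp, min_slope, min_len)

  # oracle: try every trailing-trim amount, keep the longest line passing
  y <- 100 * values[1:100]; cs <- 0:99
  band <- which(abs(y - 100 * cdfp) <= 0.5)
  best <- NULL
  for (drop in 0:(length(band) - 2)) {
    idx <- band[(drop + 1):length(band)]
    cm <- cs[idx] - mean(cs[idx])
    slope <- sum(cm * (y[idx] - mean(y[idx]))) / sum(cm^2)
    if (atan(abs(slope)) * 180 / pi <= min_slope) {
      best <- range(cs[idx]); break
    }
  }
  expect_true(got$valid)
  expect_equal(got$c_start, best[1])
  expect_equal(got$c_end, best[2])
  expect_lte(got$slope_deg, min_slope)
})

test_that("intra/inter statistics match brute-force pair means", {
  M <- perfect_index(c(3, 3))
  labels <- rep(1:2, each = 3)
  expect_equal(intra_cluster_stability(M, labels), 1)
  expect_equal(inter_cluster_overlap(M, labels), 0)

  # mixed 6-sample matrix vs brute force
  set.seed(9)
  A <- matrix(0L, 6, 6)
  A[upper.tri(A)] <- sample(0:100, 15)
  A <- A + t(A); diag(A) <- 100L
  lab <- c(1, 1, 2, 2, 2, 3)
  wi <- c(); bt <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    if (lab[i] == lab[j]) wi <- c(wi, A[i, j]) else bt <- c(bt, A[i, j])
  }
  expect_equal(intra_cluster_stability(A, lab), mean(wi) / 100)
  expect_equal(inter_cluster_overlap(A, lab), mean(bt) / 100)

  # all singletons: no within pairs -> stability 1 by convention
  expect_equal(intra_cluster_stability(A, 1:6), 1)
  expect_error(inter_cluster_overlap(A, rep(1, 6)), "2 clusters")
})

test_that("the DE validity filter controls false positives and has power", {
  # null: random labels on homogeneous data
  fracs <- vapply(1:20, function(s) {
    X <- toy_matrix(100, 60, seed = 400 + s)
    labels <- sample(rep(1:2, each = 30))
    de_gene_fraction(X, labels, fdr = 0.01)
  }, numeric(1))
  expect_lt(mean(fracs), 0.01)

  # power: 30% of genes shifted +3 in cluster 1, n = 30 per cluster
  fracs2 <- vapply(1:20, function(s) {
    X <- toy_matrix(100, 60, seed = 500 + s)
    X[1:30, 1:30] <- X[1:30, 1:30] + 3
    de_gene_fraction(X, rep(1:2, each = 30), fdr = 0.01)
  }, numeric(1))
  expect_true(all(fracs2 >= 0.25))

  # identical expression for all samples: nothing is differential
  Xc <- matrix(5, 10, 20, dimnames = list(sprintf("g%d", 1:10),
                                          sprintf("s%d", 1:20)))
  expect_equal(de_gene_fraction(Xc, rep(1:2, each = 10)), 0)
  expect_error(de_gene_fraction(Xc, rep(1, 20)), "2 clusters")
})

test_that("vectorized rank-sum matches wilcox.test", {
  X <- toy_matrix(40, 25, seed = 77)
  X[5, ] <- round(X[5, ])  # introduce ties
  in_idx <- c(rep(TRUE, 10), rep(FALSE, 15))
  rs <- rcclust:::ranksum_rows(X, in_idx)
  for (g in c(1, 5, 17, 40)) {
    w <- wilcox.test(X[g, in_idx], X[g, !in_idx], exact = FALSE,
                     correct = TRUE)
    expect_equal(rs$p[g], w$p.value, tolerance = 1e-10)
  }
})

test_that("criteria a-e and weights behave as specified", {
  cfg <- rcc_config("bulk", min_de_pct = 10)
  M <- perfect_index(c(20, 20))
  cm <- as_consensus(M, 2)
  # strong DE: half the genes upregulated in cluster 1
  X <- toy_matrix(40, 40, seed = 13)
  X[1:20, 1:20] <- X[1:20, 1:20] + 4
  ev <- evaluate_k(cm, cm$labels, X, cfg)
  expect_true(all(ev$passes))
  expect_equal(ev$weight, 2L)  # slope 0 <= 5 and length 99 >= 40

  # no DE signal: a-d pass, e fails, weight 0
  Xn <- toy_matrix(40, 40, seed = 14)
  ev2 <- evaluate_k(cm, cm$labels, Xn, cfg)
  expect_true(all(ev2$passes[c("a", "b", "c", "d")]))
  expect_false(ev2$passes["e"][[1]])
  expect_equal(ev2$weight, 0L)
})

test_that("best-k selection and the vote follow the worked example", {
  mk_eval <- function(k, weight, pass = TRUE) {
    structure(list(k = as.integer(k), weight = as.integer(weight),
                   passes = c(a = pass, b = pass, c = pass, d = pass,
                              e = pass)),
              class = "rcc_keval")
  }
  # k = 2..5 pass a-e; weights narrow the best set to {3,4,5}
  evals <- list(mk_eval(2, 0), mk_eval(3, 2), mk_eval(4, 2), mk_eval(5, 2),
                mk_eval(6, 0, pass = FALSE))
  expect_equal(best_k_for_process(evals), c(3L, 4L, 5L))
  expect_equal(best_k_for_process(list(mk_eval(2, 0, FALSE))), integer(0))
  expect_equal(best_k_for_process(list(mk_eval(4, 1))), 4L)

  expect_equal(vote_optimal_k(list(4L, 4L, c(3L, 4L), c(4L, 5L), 4L, 4L,
                                   integer(0), 4L)), 4L)
  expect_equal(vote_optimal_k(rep(list(integer(0)), 8)), 0L)
  expect_equal(vote_optimal_k(list(3L, 4L)), 3L)  # tie -> smaller k
})

test_that("raising the line-length threshold can only shrink the passing set", {
  cfg_loose <- rcc_config("bulk", min_de_pct = 10, min_line_length = 30)
  cfg_tight <- rcc_config("bulk", min_de_pct = 10, min_line_length = 60)
  set.seed(15)
  X <- toy_matrix(40, 40, seed = 15)
  X[1:20, 1:20] <- X[1:20, 1:20] + 4
  Z <- zscore_rows(X)
  for (k in 2:4) {
    cm <- run_consensus(Z, k, list(p_item = 0.7, p_feature = 0.8,
                                   repeats = 50, seed = 20 + k))
    ev_loose <- evaluate_k(cm, cm$labels, X, cfg_loose)
    ev_tight <- evaluate_k(cm, cm$labels, X, cfg_tight)
    if (all(ev_tight$passes)) expect_true(all(ev_loose$passes))
  }
})
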