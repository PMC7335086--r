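#' Maximum number of clusters to evaluate at a node
#'
#' `min(10, floor(n/10))`. Values below 2 mean the node cannot be
#' clustered.
#'
#' @param n_samples Number of samples at the node.
#' @return Integer maxK.
#' @export
compute_maxK <- function(n_samples) {
  stopifnot(n_samples >= 1)
  as.integer(min(10, floor(n_samples / 10)))
}

#' Empirical CDF of a consensus matrix
#'
#' For every integer consensus index c in 0..100, the fraction of unordered
#' off-diagonal sample pairs whose index is <= c.
#'
#' @param index N x N consensus index matrix (0--100), or an
#'   `rcc_consensus` object.
#' @return Object of class `rcc_cdf`: list with `values` (length 101,
#'   positions 1..101 = c 0..100) and `n_pairs`.
#' @export
compute_cdf <- function(index) {
  if (inherits(index, "rcc_consensus")) index <- index$index
  n <- nrow(index)
  stopifnot(n >= 2)
  vals <- index[upper.tri(index)]
  counts <- tabulate(as.integer(round(vals)) + 1L, nbins = 101L)
  structure(list(values = cumsum(counts) / length(vals),
                 n_pairs = length(vals)),
            class = "rcc_cdf")
}

#' CDF plateau value of a perfect clustering
#'
#' With every within-cluster pair at consensus 100 and every between-pair
#' at 0, the CDF equals the fraction of between-cluster pairs for all
#' c in 0..99: `1 - sum(Ni*(Ni-1)/2) / (N*(N-1)/2)`.
#'
#' @param cluster_sizes Integer vector of cluster sizes.
#' @return The plateau fraction in [0, 1].
#' @export
perfect_cdf_value <- function(cluster_sizes) {
  N <- sum(cluster_sizes)
  stopifnot(N >= 2)
  1 - sum(cluster_sizes * (cluster_sizes - 1) / 2) / (N * (N - 1) / 2)
}

#' Fit and trim the CDF plateau line
#'
#' Works on the symmetric 0--100 scale (x = consensus index c in 0..99,
#' y = 100 * CDF(c)) so that the degree thresholds are meaningful. All
#' points with |y - 100*cdfp| <= 0.5 form the initial band; a least-squares
#' line is fitted and, while its absolute slope exceeds
#' `min_slope_deg`, points are dropped from the low-c end (the unstable
#' rising part of the curve) and the line refitted, stopping when the slope
#' passes or the remaining length falls below `min_line_length`. The fit is
#' invalid when the band holds fewer than 2 points or trimming exhausts the
#' length.
#'
#' @param curve An `rcc_cdf` from [compute_cdf()].
#' @param cdfp Perfect-CDF plateau value from [perfect_cdf_value()].
#' @param min_slope_deg Slope threshold in degrees (default 10).
#' @param min_line_length Minimum line length in consensus-index units
#'   (default 30).
#' @return Object of class `rcc_line`: list with `slope_deg`, `length`,
#'   `c_start`, `c_end`, `n_points`, `valid`.
#' @export
fit_trim_line <- function(curve, cdfp, min_slope_deg = 10,
                          min_line_length = 30) {
  stopifnot(inherits(curve, "rcc_cdf"), cdfp >= 0, cdfp <= 1)
  y_all <- 100 * curve$values[1:100]   # c = 0..99
  c_all <- 0:99
  keep <- which(abs(y_all - 100 * cdfp) <= 0.5)
  invalid <- structure(list(slope_deg = NA_real_, length = 0,
                            c_start = NA_integer_, c_end = NA_integer_,
                            n_points = length(keep), valid = FALSE),
                       class = "rcc_line")
  if (length(keep) < 2) return(invalid)
  cc <- c_all[keep]; yy <- y_all[keep]
  slope_of <- function(cc, yy) {
    cm <- cc - mean(cc)
    sum(cm * (yy - mean(yy))) / sum(cm * cm)
  }
  repeat {
    slope_deg <- atan(abs(slope_of(cc, yy))) * 180 / pi
    len <- cc[length(cc)] - cc[1]
    if (slope_deg <= min_slope_deg) break
    if (len < min_line_length || length(cc) <= 2) break
    cc <- cc[-1]; yy <- yy[-1]  # trim the low-c end
  }
  len <- cc[length(cc)] - cc[1]
  if (length(cc) < 2 || len < min_line_length && slope_deg > min_slope_deg)
    return(invalid)
  structure(list(slope_deg = slope_deg, length = len,
                 c_start = cc[1], c_end = cc[length(cc)],
                 n_points = length(cc), valid = TRUE),
            class = "rcc_line")
}

#' Mean within-cluster consensus
#'
#' Mean of index/100 over all unordered within-cluster off-diagonal pairs;
#' 1 when the clustering has no within pairs (all singletons).
#'
#' @param index Consensus index matrix (0--100) or `rcc_consensus`.
#' @param labels Cluster labels over the samples.
#' @return Fraction in [0, 1].
#' @export
intra_cluster_stability <- function(index, labels) {
  if (inherits(index, "rcc_consensus")) index <- index$index
  same <- outer(labels, labels, "==") & upper.tri(index)
  if (!any(same)) return(1.0)
  mean(index[same]) / 100
}

#' Mean between-cluster consensus
#'
#' Mean of index/100 over all between-cluster pairs. Requires at least two
#' clusters.
#'
#' @inheritParams intra_cluster_stability
#' @return Fraction in [0, 1].
#' @export
inter_cluster_overlap <- function(index, labels) {
  if (inherits(index, "rcc_consensus")) index <- index$index
  if (length(unique(labels)) < 2)
    stop("inter-cluster overlap needs at least 2 clusters")
  diff <- outer(labels, labels, "!=") & upper.tri(index)
  mean(index[diff]) / 100
}

#' Fraction of genes upregulated in at least one cluster
#'
#' The differential-expression validity filter: for each cluster (with at
#' least 2 samples), every gene is tested one-vs-rest with a Wilcoxon
#' rank-sum test, BH-corrected within the comparison; a gene counts when it
#' is significant at `fdr` and upregulated (positive mean difference) in at
#' least one cluster. The fraction is over all genes in `X`.
#'
#' @param X Genes-by-samples matrix on the log2 scale (the node's selected
#'   features, not z-scored).
#' @param labels Cluster labels over the columns of `X`.
#' @param fdr BH-adjusted significance threshold (default 0.01).
#' @return Fraction in [0, 1].
#' @export
de_gene_fraction <- function(X, labels, fdr = 0.01) {
  de_gene_fraction2(X, labels, fdr)
}

#' Evaluate one candidate k against the acceptance criteria
#'
#' Criteria: (a) line length > `min_line_length`; (b) line slope <
#' `min_slope_deg`; (c) intra-cluster stability > `intra_stability_min`;
#' (d) inter-cluster overlap < `inter_overlap_max`; (e) upregulated-gene
#' fraction > `min_de_pct`/100. A k passing a--e earns one weight point for
#' slope <= `weight_slope_deg` and one for length >= `weight_line_length`;
#' otherwise its weight is 0.
#'
#' @param cm `rcc_consensus` object for this k.
#' @param labels Consensus labels at this k (defaults to `cm$labels`).
#' @param X_subset Node's selected-feature log2 matrix for the DE filter.
#' @param config `rcc_config` with resolved `min_de_pct`.
#' @param rk Optional precomputed rank structure for `X_subset` (internal
#'   speed-up when many ks share the matrix).
#' @return Object of class `rcc_keval`: list with `k`, `line`,
#'   `intra_stability`, `inter_overlap`, `de_fraction`, `passes` (named
#'   logical a..e), and `weight`.
#' @export
evaluate_k <- function(cm, labels = cm$labels, X_subset, config, rk = NULL) {
  stopifnot(inherits(cm, "rcc_consensus"))
  if (is.na(config$min_de_pct))
    stop("config$min_de_pct is unresolved; set it or use rcc_run()/rcc_select_k()")
  curve <- compute_cdf(cm)
  cdfp <- perfect_cdf_value(as.integer(table(labels)))
  line <- fit_trim_line(curve, cdfp, config$min_slope_deg,
                        config$min_line_length)
  intra <- intra_cluster_stability(cm, labels)
  inter <- inter_cluster_overlap(cm, labels)
  de <- de_gene_fraction2(X_subset, labels, config$marker_fdr, rk)
  passes <- c(
    a = isTRUE(line$valid) && line$length > config$min_line_length,
    b = isTRUE(line$valid) && line$slope_deg < config$min_slope_deg,
    c = intra > config$intra_stability_min,
    d = inter < config$inter_overlap_max,
    e = de > config$min_de_pct / 100
  )
  weight <- 0L
  if (all(passes)) {
    weight <- as.integer(line$slope_deg <= config$weight_slope_deg) +
      as.integer(line$length >= config$weight_line_length)
  }
  structure(list(k = cm$k, line = line, intra_stability = intra,
                 inter_overlap = inter, de_fraction = de,
                 passes = passes, weight = weight),
            class = "rcc_keval")
}

# de_gene_fraction with an optional shared rank structure.
de_gene_fraction2 <- function(X, labels, fdr, rk = NULL) {
  cl <- unique(labels)
  if (length(cl) < 2) stop("differential expression needs at least 2 clusters")
  if (is.null(rk)) rk <- rank_matrix(X)
  hit <- rep(FALSE, nrow(X))
  for (c in cl) {
    in_idx <- labels == c
    if (sum(in_idx) < 2 || sum(!in_idx) < 1) next
    rs <- ranksum_rows(X, in_idx, rk)
    padj <- stats::p.adjust(rs$p, method = "BH")
    hit <- hit | (padj < fdr & rs$delta > 0)
  }
  sum(hit) / nrow(X)
}

#' Best k set of one consensus process
#'
#' Among the ks passing criteria a--e, returns all achieving the maximum
#' weight; the empty set when none pass.
#'
#' @param evals List of `rcc_keval` objects (k = 2..maxK).
#' @return Integer vector of best ks (possibly empty).
#' @export
best_k_for_process <- function(evals) {
  pass <- vapply(evals, function(e) all(e$passes), logical(1))
  if (!any(pass)) return(integer(0))
  ks <- vapply(evals, function(e) e$k, integer(1))[pass]
  ws <- vapply(evals, function(e) e$weight, integer(1))[pass]
  sort(ks[ws == max(ws)])
}

#' Vote the optimal k across processes
#'
#' Pools the best-k sets of all processes and returns the most frequent
#' value; frequency ties break toward the smaller (coarser) k; 0 when every
#' set is empty, signalling termination.
#'
#' @param per_process List of integer vectors (one best-k set per process).
#' @return Integer optimal k (0 = none).
#' @export
vote_optimal_k <- function(per_process) {
  pool <- unlist(per_process)
  if (length(pool) == 0) return(0L)
  tab <- table(pool)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Select the optimal k for one node
#'
#' The per-node pipeline: feature selection on the node's samples,
#' z-scaling, eight consensus processes at k = 2..maxK, evaluation of every
#' (process, k) against criteria a--e with weights, the per-process best-k
#' sets, and the frequency vote. Also picks the partition that realizes the
#' voted k: among processes whose best set contains it, the one with the
#' longest (then flattest) line.
#'
#' @param X Genes-by-samples log2 matrix (the node's samples).
#' @param config An `rcc_config`. `min_de_pct = NA` is resolved from
#'   `ncol(X)` (20 above 1000 samples, else 10).
#' @param grid Optional precomputed [parameter_grid()]; by default one is
#'   drawn from the current RNG stream.
#' @return Object of class `rcc_kselect`: list with `optimal_k`, `labels`
#'   (named, for the voted k; `NULL` when optimal_k = 0), `chosen_process`,
#'   `best_sets`, `evaluations` (long data.frame over process x k),
#'   `features`, `maxK`, and `consensus` (the chosen `rcc_consensus`).
#' @export
rcc_select_k <- function(X, config, grid = NULL) {
  validate_expression(X)
  n <- ncol(X)
  cfg <- resolve_config(config, n)
  maxK <- compute_maxK(n)
  if (maxK < 2) {
    return(structure(list(optimal_k = 0L, labels = NULL,
                          chosen_process = NA_integer_, best_sets = list(),
                          evaluations = NULL, features = NULL, maxK = maxK,
                          consensus = NULL),
                     class = "rcc_kselect"))
  }
  feats <- select_variant_features(X, cfg$variant_gene_pct, cfg$data_type,
                                   cfg$bulk_min_features)
  Xs <- X[feats$selected_gene_ids, , drop = FALSE]
  Z <- zscore_rows(Xs)
  if (is.null(grid)) grid <- parameter_grid(cfg$repeats_per_process)
  rk <- rank_matrix(Xs)
  ks <- 2:maxK
  best_sets <- vector("list", nrow(grid))
  eval_rows <- list()
  all_evals <- vector("list", nrow(grid))
  consensus_store <- vector("list", nrow(grid))
  for (p in seq_len(nrow(grid))) {
    cms <- consensus_multi(Z, ks, grid[p, ], cfg$kmeans_restarts,
                           cfg$kmeans_iter_max)
    evs <- lapply(cms, evaluate_k, X_subset = Xs, config = cfg, rk = rk)
    all_evals[[p]] <- evs
    consensus_store[[p]] <- cms
    best_sets[[p]] <- best_k_for_process(evs)
    eval_rows[[p]] <- do.call(rbind, lapply(evs, function(e) {
      data.frame(process = p, k = e$k,
                 line_length = e$line$length, slope_deg = e$line$slope_deg,
                 intra_stability = e$intra_stability,
                 inter_overlap = e$inter_overlap,
                 de_fraction = e$de_fraction,
                 pass = all(e$passes), weight = e$weight)
    }))
  }
  evaluations <- do.call(rbind, eval_rows)
  rownames(evaluations) <- NULL
  opt <- vote_optimal_k(best_sets)
  labels <- NULL; chosen <- NA_integer_; chosen_cm <- NULL
  if (opt > 0) {
    cand <- which(vapply(best_sets, function(s) opt %in% s, logical(1)))
    score <- vapply(cand, function(p) {
      e <- all_evals[[p]][[paste0("k", opt)]]
      e$line$length * 1000 - e$line$slope_deg  # longest, then flattest
    }, numeric(1))
    chosen <- cand[which.max(score)]
    chosen_cm <- consensus_store[[chosen]][[paste0("k", opt)]]
    labels <- chosen_cm$labels
  }
  structure(list(optimal_k = as.integer(opt), labels = labels,
                 chosen_process = chosen, best_sets = best_sets,
                 evaluations = evaluations, features = feats, maxK = maxK,
                 consensus = chosen_cm),
            class = "rcc_kselect")
}

# Fill in data-dependent defaults (the DE percentage depends on dataset size).
resolve_config <- function(config, n_samples) {
  stopifnot(inherits(config, "rcc_config"))
  if (is.na(config$min_de_pct))
    config$min_de_pct <- if (n_samples > 1000) 20 else 10
  config
}

#' @export
print.rcc_kselect <- function(x, ...) {
  cat("Optimal k:", x$optimal_k, "\n")
  cat("Best-k sets per process:",
      paste(vapply(x$best_sets, function(s)
        if (length(s)) paste0("{", paste(s, collapse = ","), "}") else "{}",
        character(1)), collapse = " "), "\n")
  invisible(x)
}
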