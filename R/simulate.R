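#' Simulate a flat group-structured expression matrix
#'
#' Generates a genes-by-samples log2-scale matrix with known group
#' structure: every gene has a constant baseline drawn from
#' Normal(`baseline_mean`, `baseline_sd`), each group owns a disjoint block
#' of `markers_per_group` genes shifted up by `effect_log2` in that group,
#' and i.i.d. Normal(0, `noise_sd`) noise is added everywhere. Defaults
#' give five equal, well-separated groups at a scale suitable for
#' minute-level validation runs. `group_sizes = c(100, 60, 40, 30, 20)`
#' reproduces the unequal-proportions design.
#'
#' @param group_sizes Integer vector of group sizes (each >= 2).
#' @param n_genes Total number of genes (default 2000).
#' @param markers_per_group Marker genes per group (default 40);
#'   `markers_per_group * n_groups` must not exceed `n_genes`. 0 gives a
#'   structureless (homogeneous) matrix.
#' @param effect_log2 Upregulation of a group's markers in that group, on
#'   the log2 scale (default 3).
#' @param noise_sd Within-group standard deviation (default 1).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution
#'   (defaults 5 and 1).
#' @param dropout_threshold Optional: values below this are set to 0,
#'   mimicking dropout in sparse single-cell data. `NULL` disables.
#' @param seed Optional seed; the generator is a pure function of
#'   (arguments, seed).
#' @return List with `X` (matrix with gene/sample ids) and `labels`
#'   (named integer group labels).
#' @export
simulate_flat <- function(group_sizes = rep(50, 5), n_genes = 2000,
                          markers_per_group = 40, effect_log2 = 3,
                          noise_sd = 1, baseline_mean = 5, baseline_sd = 1,
                          dropout_threshold = NULL, seed = NULL) {
  stopifnot(all(group_sizes >= 2), n_genes >= 2, markers_per_group >= 0,
            effect_log2 >= 0, noise_sd > 0)
  n_groups <- length(group_sizes)
  if (markers_per_group * n_groups > n_genes)
    stop("marker blocks exceed the number of genes")
  if (!is.null(seed)) set.seed(seed)
  N <- sum(group_sizes)
  labels <- rep(seq_len(n_groups), group_sizes)
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  X <- matrix(stats::rnorm(n_genes * N, 0, noise_sd), n_genes, N) + baseline
  if (markers_per_group > 0 && effect_log2 > 0) {
    for (g in seq_len(n_groups)) {
      rows <- ((g - 1) * markers_per_group + 1):(g * markers_per_group)
      X[rows, labels == g] <- X[rows, labels == g] + effect_log2
    }
  }
  X[X < 0] <- 0  # log2(x+1) values are non-negative
  if (!is.null(dropout_threshold)) X[X < dropout_threshold] <- 0
  rownames(X) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(X) <- sprintf("sample%03d", seq_len(N))
  list(X = X, labels = stats::setNames(labels, colnames(X)))
}

#' Simulate a nested (hierarchical) group structure
#'
#' Two layers of structure: super-groups separated by large-effect marker
#' blocks, and sub-groups within each super-group separated by disjoint
#' smaller-effect blocks. Because super-group markers dominate global
#' variance, top-variance feature selection over all samples sees mostly
#' the super-group split; re-selecting features inside a super-group (where
#' its own markers are flat) is what exposes the sub-groups - the behavior
#' the recursion exploits. Default effects 8 and 2 (4:1 ratio).
#'
#' @param subgroup_sizes List of integer vectors: one vector per
#'   super-group giving its sub-group sizes, e.g.
#'   `list(c(60, 60), c(40, 40, 40))`.
#' @param n_genes Total genes (default 2000).
#' @param markers_per_group Genes per marker block (default 40); blocks for
#'   super-groups and all sub-groups are disjoint.
#' @param effect_super,effect_sub log2 shifts of the super- and sub-group
#'   blocks (defaults 8 and 2).
#' @param noise_sd,baseline_mean,baseline_sd As in [simulate_flat()].
#' @param seed Optional seed.
#' @return List with `X`, `labels_super` (level-1 truth), `labels_leaf`
#'   (finest truth, `"super.sub"` strings), both named by sample.
#' @export
simulate_nested <- function(subgroup_sizes = list(c(60, 60), c(40, 40, 40)),
                            n_genes = 2000, markers_per_group = 40,
                            effect_super = 8, effect_sub = 2,
                            noise_sd = 1, baseline_mean = 5, baseline_sd = 1,
                            seed = NULL) {
  stopifnot(is.list(subgroup_sizes), length(subgroup_sizes) >= 2,
            effect_super > 0, effect_sub > 0)
  n_super <- length(subgroup_sizes)
  n_sub_total <- sum(lengths(subgroup_sizes))
  n_blocks <- n_super + n_sub_total
  if (n_blocks * markers_per_group > n_genes)
    stop("marker blocks exceed the number of genes (overlapping allocation)")
  if (!is.null(seed)) set.seed(seed)
  super_sizes <- vapply(subgroup_sizes, sum, numeric(1))
  N <- sum(super_sizes)
  labels_super <- rep(seq_len(n_super), super_sizes)
  labels_leaf <- unlist(lapply(seq_len(n_super), function(s)
    rep(paste0(s, ".", seq_along(subgroup_sizes[[s]])), subgroup_sizes[[s]])))
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  X <- matrix(stats::rnorm(n_genes * N, 0, noise_sd), n_genes, N) + baseline
  block <- function(i) ((i - 1) * markers_per_group + 1):(i * markers_per_group)
  bi <- 0
  for (s in seq_len(n_super)) {
    bi <- bi + 1
    X[block(bi), labels_super == s] <- X[block(bi), labels_super == s] + effect_super
  }
  for (s in seq_len(n_super)) {
    for (u in seq_along(subgroup_sizes[[s]])) {
      bi <- bi + 1
      sel <- labels_leaf == paste0(s, ".", u)
      X[block(bi), sel] <- X[block(bi), sel] + effect_sub
    }
  }
  X[X < 0] <- 0
  rownames(X) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(X) <- sprintf("sample%03d", seq_len(N))
  list(X = X,
       labels_super = stats::setNames(labels_super, colnames(X)),
       labels_leaf = stats::setNames(labels_leaf, colnames(X)))
}

#' Simulate per-cluster exponential survival
#'
#' Event times are exponential with per-cluster hazard
#' `baseline_hazard * hazard_ratios[cluster]`; censoring times are
#' independent exponentials with rate chosen so the expected censored
#' fraction equals `censor_rate` in every cluster.
#'
#' @param labels Cluster labels per sample.
#' @param hazard_ratios Named (by cluster) or positional numeric vector of
#'   hazard multipliers, one per cluster, all > 0.
#' @param censor_rate Expected fraction censored, in [0, 1) (default 0.2).
#' @param baseline_hazard Baseline event rate (default 0.1).
#' @param seed Optional seed.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(labels, hazard_ratios, censor_rate = 0.2,
                              baseline_hazard = 0.1, seed = NULL) {
  cl <- sort(unique(as.character(labels)))
  if (is.null(names(hazard_ratios))) {
    stopifnot(length(hazard_ratios) == length(cl))
    names(hazard_ratios) <- cl
  }
  if (any(hazard_ratios <= 0)) stop("hazard ratios must be positive")
  stopifnot(censor_rate >= 0, censor_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  lam <- baseline_hazard * hazard_ratios[as.character(labels)]
  t_event <- stats::rexp(n, rate = lam)
  if (censor_rate > 0) {
    mu <- lam * censor_rate / (1 - censor_rate) # P(censor) = mu/(lam+mu)
    t_cens <- stats::rexp(n, rate = mu)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  ids <- if (!is.null(names(labels))) names(labels) else
    sprintf("sample%03d", seq_len(n))
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Write a simulated fixture to CSV files
#'
#' Writes the expression matrix in the same dialect [read_expression_csv()]
#' reads, plus a truth-label table.
#'
#' @param sim Output of [simulate_flat()] or [simulate_nested()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xpath <- file.path(dir, paste0(prefix, "_expression.csv"))
  df <- data.frame(gene_id = rownames(sim$X), sim$X, check.names = FALSE)
  utils::write.csv(df, xpath, row.names = FALSE, quote = FALSE)
  labs <- if (!is.null(sim$labels)) {
    data.frame(sample = names(sim$labels), label = sim$labels)
  } else {
    data.frame(sample = names(sim$labels_leaf),
               label_super = sim$labels_super, label_leaf = sim$labels_leaf)
  }
  lpath <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(labs, lpath, row.names = FALSE, quote = FALSE)
  invisible(c(expression = xpath, truth = lpath))
}
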