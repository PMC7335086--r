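#' Construct a clustering configuration
#'
#' Holds every tunable parameter of the recursive consensus clustering
#' pipeline, with the published defaults. All thresholds must be strictly
#' positive.
#'
#' @param data_type `"bulk"` or `"single-cell"`. Controls the default
#'   percentage of variant genes and whether the 500-gene feature floor is
#'   applied.
#' @param min_slope_deg Maximum slope (degrees) a trimmed CDF line may have
#'   for a k to be accepted. Default 10; recommended range 5--15.
#' @param min_samples Minimum node size for clustering to be attempted.
#'   Nodes with fewer samples become leaves. Default 20.
#' @param min_line_length Minimum CDF line length, on the 0--100 consensus
#'   index scale. A perfect clustering has line length 99. Default 30;
#'   recommended range 30--60.
#' @param variant_gene_pct Percentage of top-variance genes selected at each
#'   node. Defaults to 3 for bulk and 1 for single-cell data.
#' @param min_de_pct Minimum percentage of tested genes that must be
#'   significantly upregulated in at least one cluster for a k to count as
#'   biologically valid. `NA` (default) resolves at run time to 20 when the
#'   dataset has more than 1000 samples and 10 otherwise.
#' @param annotation_file,expression_matrix,gene_list,output_dir Optional
#'   file-system paths used by the command-line workflow; `NA` means absent.
#' @param seed Integer seed making the whole run reproducible; `NA` leaves
#'   the R RNG untouched.
#' @param repeats_per_process Consensus repeats per process. Default 100.
#' @param n_processes Number of consensus processes (the item/feature
#'   sampling grid has eight cells). Default 8.
#' @param weight_slope_deg,weight_line_length Thresholds for the tie-break
#'   weights: a passing k earns one weight point for slope <= 5 degrees and
#'   one for line length >= 40.
#' @param intra_stability_min Minimum mean within-cluster consensus
#'   (fraction). Default 0.8.
#' @param inter_overlap_max Maximum mean between-cluster consensus
#'   (fraction). Default 0.2.
#' @param marker_fdr,marker_lfc Marker-gene thresholds: BH-adjusted p below
#'   `marker_fdr` (default 0.01) and log2 fold change above `marker_lfc`
#'   (default 1).
#' @param bulk_min_features Feature floor for bulk data. Default 500.
#' @param cutoff_level Optional maximum recursion depth applied after the
#'   run (see [apply_cutoff()]); `NA` means unlimited.
#' @param kmeans_restarts Random restarts per k-means call inside the
#'   consensus engine. Default 1 (k-means++ seeding makes single starts
#'   reliable; the 100 subsampled repeats provide the averaging).
#' @param kmeans_iter_max Iteration cap per k-means call. Default 50 with
#'   early stopping on a stable assignment.
#' @return An object of class `rcc_config` (a named list).
#' @seealso [read_config_csv()] to build one from a two-column CSV.
#' @export
rcc_config <- function(data_type,
                       min_slope_deg = 10,
                       min_samples = 20,
                       min_line_length = 30,
                       variant_gene_pct = NULL,
                       min_de_pct = NA,
                       annotation_file = NA,
                       expression_matrix = NA,
                       gene_list = NA,
                       output_dir = ".",
                       seed = NA,
                       repeats_per_process = 100,
                       n_processes = 8,
                       weight_slope_deg = 5,
                       weight_line_length = 40,
                       intra_stability_min = 0.8,
                       inter_overlap_max = 0.2,
                       marker_fdr = 0.01,
                       marker_lfc = 1.0,
                       bulk_min_features = 500,
                       cutoff_level = NA,
                       kmeans_restarts = 1,
                       kmeans_iter_max = 50) {
  if (missing(data_type)) stop("config: 'data_type' is required")
  data_type <- match.arg(data_type, c("bulk", "single-cell"))
  if (is.null(variant_gene_pct)) {
    variant_gene_pct <- if (data_type == "bulk") 3 else 1
  }
  cfg <- list(
    data_type = data_type,
    min_slope_deg = as.numeric(min_slope_deg),
    min_samples = as.integer(min_samples),
    min_line_length = as.numeric(min_line_length),
    variant_gene_pct = as.numeric(variant_gene_pct),
    min_de_pct = if (is.na(min_de_pct)) NA_real_ else as.numeric(min_de_pct),
    annotation_file = annotation_file,
    expression_matrix = expression_matrix,
    gene_list = gene_list,
    output_dir = output_dir,
    seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
    repeats_per_process = as.integer(repeats_per_process),
    n_processes = as.integer(n_processes),
    weight_slope_deg = as.numeric(weight_slope_deg),
    weight_line_length = as.numeric(weight_line_length),
    intra_stability_min = as.numeric(intra_stability_min),
    inter_overlap_max = as.numeric(inter_overlap_max),
    marker_fdr = as.numeric(marker_fdr),
    marker_lfc = as.numeric(marker_lfc),
    bulk_min_features = as.integer(bulk_min_features),
    cutoff_level = if (is.na(cutoff_level)) NA_integer_ else as.integer(cutoff_level),
    kmeans_restarts = as.integer(kmeans_restarts),
    kmeans_iter_max = as.integer(kmeans_iter_max)
  )
  class(cfg) <- "rcc_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("min_slope_deg", "min_line_length", "variant_gene_pct",
           "repeats_per_process", "n_processes", "weight_slope_deg",
           "weight_line_length", "intra_stability_min", "inter_overlap_max",
           "marker_fdr", "marker_lfc", "bulk_min_features",
           "kmeans_restarts", "kmeans_iter_max")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop(sprintf("config: '%s' must be a single strictly positive number", p))
  }
  if (cfg$variant_gene_pct > 100)
    stop("config: 'variant_gene_pct' must be in (0, 100]")
  if (is.na(cfg$min_samples) || cfg$min_samples < 4)
    stop("config: 'min_samples' must be >= 4")
  if (!is.na(cfg$min_de_pct) && (cfg$min_de_pct <= 0 || cfg$min_de_pct > 100))
    stop("config: 'min_de_pct' must be in (0, 100]")
  if (!is.na(cfg$cutoff_level) && cfg$cutoff_level < 1)
    stop("config: 'cutoff_level' must be >= 1")
  invisible(cfg)
}

#' @export
print.rcc_config <- function(x, ...) {
  cat("Recursive consensus clustering configuration (", x$data_type, ")\n",
      sep = "")
  keys <- setdiff(names(x), "data_type")
  for (k in keys) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Map from config-file keys (case-insensitive) to rcc_config arguments.
config_key_map <- function() {
  c(expression_matrix = "expression_matrix",
    annotation_file = "annotation_file",
    data_type = "data_type",
    min_slope_deg = "min_slope_deg",
    min_samples = "min_samples",
    min_line_length = "min_line_length",
    variant_gene_pct = "variant_gene_pct",
    min_de_pct = "min_de_pct",
    gene_list = "gene_list",
    output_dir = "output_dir",
    seed = "seed",
    repeats_per_process = "repeats_per_process",
    n_processes = "n_processes",
    weight_slope_deg = "weight_slope_deg",
    weight_line_length = "weight_line_length",
    intra_stability_min = "intra_stability_min",
    inter_overlap_max = "inter_overlap_max",
    marker_fdr = "marker_fdr",
    marker_lfc = "marker_lfc",
    bulk_min_features = "bulk_min_features",
    cutoff_level = "cutoff_level",
    kmeans_restarts = "kmeans_restarts",
    kmeans_iter_max = "kmeans_iter_max")
}

#' Read a configuration CSV
#'
#' The file has two columns: parameter name and value (no header required;
#' a `parameter,value` header row is tolerated). Keys are case-insensitive
#' and whitespace-trimmed; unknown keys are an error. A value of `"NA"` for
#' an optional path (e.g. the annotation file) means absent. Parameters not
#' present in the file take their defaults; `data_type` is required.
#'
#' @param path Path to the CSV file.
#' @param ... Overrides applied on top of the file (same names as
#'   [rcc_config()] arguments).
#' @return An `rcc_config` object.
#' @export
read_config_csv <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  if (ncol(raw) < 2) stop("config file must have two columns (parameter,value)")
  keys <- trimws(tolower(as.character(raw[[1]])))
  vals <- trimws(as.character(raw[[2]]))
  hdr <- keys %in% c("parameter", "param", "name")
  keys <- keys[!hdr]; vals <- vals[!hdr]
  map <- config_key_map()
  unknown <- setdiff(keys, names(map))
  if (length(unknown))
    stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated configuration parameter(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  args <- list()
  char_keys <- c("expression_matrix", "annotation_file", "gene_list",
                 "output_dir", "data_type")
  for (i in seq_along(keys)) {
    key <- map[[keys[i]]]; val <- vals[i]
    if (key %in% char_keys) {
      args[[key]] <- if (identical(toupper(val), "NA")) NA else val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (identical(toupper(val), "NA")) num <- NA
      else if (is.na(num))
        stop(sprintf("config: value '%s' for '%s' is not numeric", val, key))
      args[[key]] <- num
    }
  }
  overrides <- list(...)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  if (is.null(args$data_type)) stop("config: 'data_type' is required")
  do.call(rcc_config, args)
}

#' Read a genes-by-samples expression CSV
#'
#' The first column holds gene identifiers and the header row holds sample
#' identifiers. Values are expected to be normalized and log2(x+1)
#' transformed upstream; the loader validates finiteness only and warns
#' (without transforming) when values look like they are not on a log2
#' scale (negative or above 50).
#'
#' @param path Path to the CSV file.
#' @return A numeric matrix (genes x samples) with unique row and column
#'   names.
#' @export
read_expression_csv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("expression matrix is empty: ", path)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  samples <- colnames(vals)
  if (anyDuplicated(samples))
    stop("duplicated sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric value in column '%s', row '%s'",
                   samples[j], genes[if (is.na(bad)) 1 else bad]))
    }
  }
  X <- as.matrix(vals)
  rownames(X) <- genes
  validate_expression(X)
  X
}

validate_expression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("expression data must be a numeric matrix")
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("expression matrix needs gene and sample identifiers")
  if (anyDuplicated(rownames(X))) stop("duplicated gene id(s)")
  if (anyDuplicated(colnames(X))) stop("duplicated sample id(s)")
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-finite value at gene '%s', sample '%s'",
                 rownames(X)[bad[1]], colnames(X)[bad[2]]))
  }
  if (any(X < 0) || any(X > 50))
    warning("values outside [0, 50]: input may not be log2(x+1)-transformed")
  invisible(X)
}

#' Read a sample annotation CSV
#'
#' First column = sample id; remaining columns = categorical attributes.
#' Samples present in the expression matrix but absent here are retained
#' with attribute value `"NA"` downstream.
#'
#' @param path Path to the CSV file.
#' @param sample_ids Optional character vector of expected sample ids; every
#'   annotated id must be among them.
#' @return A data.frame with rownames = sample ids and character columns.
#' @export
read_annotation_csv <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation file needs a sample column plus attributes")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample id(s) in annotation")
  ann <- df[, -1, drop = FALSE]
  ann[] <- lapply(ann, as.character)
  rownames(ann) <- ids
  if (!is.null(sample_ids)) {
    extra <- setdiff(ids, sample_ids)
    if (length(extra))
      stop("annotated sample(s) not in expression matrix: ",
           paste(utils::head(extra, 5), collapse = ", "))
    missing <- setdiff(sample_ids, ids)
    if (length(missing)) {
      pad <- as.data.frame(matrix("NA", length(missing), ncol(ann)),
                           stringsAsFactors = FALSE)
      colnames(pad) <- colnames(ann); rownames(pad) <- missing
      ann <- rbind(ann, pad)[sample_ids, , drop = FALSE]
    } else {
      ann <- ann[sample_ids, , drop = FALSE]
    }
  }
  ann
}

#' Read an optional gene-list filter file (one gene id per line)
#' @param path Path to a text file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' Write the per-sample cluster information table
#'
#' One row per sample: its dotted cluster label at every recursion level
#' (blank where the sample's branch terminated earlier) and the final
#' concatenated label.
#'
#' @param tree A completed `rcc_tree` from [rcc_run()].
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_cluster_info <- function(tree, path) {
  df <- cluster_info_table(tree)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write cluster information to: ", path)
  invisible(df)
}

#' Tabulate per-level cluster assignments of a tree
#' @param tree An `rcc_tree`.
#' @return data.frame with columns `sample`, `level1..levelL`, `final`.
#' @export
cluster_info_table <- function(tree) {
  stopifnot(inherits(tree, "rcc_tree"))
  final <- final_labels(tree)
  depth <- max(1L, tree_depth(tree))
  lv <- matrix("", length(final), depth)
  parts <- strsplit(final, ".", fixed = TRUE)
  for (i in seq_along(final)) {
    p <- parts[[i]]
    for (l in seq_len(min(depth, length(p))))
      lv[i, l] <- paste(p[seq_len(l)], collapse = ".")
  }
  df <- data.frame(sample = names(final), lv, final = unname(final),
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample", paste0("level", seq_len(depth)), "final")
  df
}

#' Re-read a cluster information CSV
#' @param path Path written by [write_cluster_info()].
#' @return Named character vector of final labels (names = sample ids).
#' @export
read_cluster_info <- function(path) {
  if (!file.exists(path)) stop("cluster info file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  stats::setNames(as.character(df$final), df$sample)
}
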