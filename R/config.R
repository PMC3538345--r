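#' Analysis configuration
#'
#' Bundle of every tunable constant the pipeline uses. Defaults are the
#' published analysis settings: the clustering shortlist regime
#' (|log2 FC| > 0.5, adjusted P < 0.01, significant in at least five
#' experiments), the overlap-network regime (|log2 FC| > 0.3, adjusted
#' P < 0.01, nodes with fewer than five edges pruned), the percent-overlap
#' selection (at least 50 significant genes), the COSA-style scaling factor
#' lambda = 0.6, the 2 kb TSS window for ChIP direct targets, and the
#' 12-bin / center-bin-7 flow-cytometry size binning with KS alpha 0.01.
#'
#' @param lfc_threshold_cluster absolute log2 fold-change threshold for the
#'   clustering shortlist (strict inequality).
#' @param lfc_threshold_overlap absolute log2 fold-change threshold for the
#'   overlap-network significant sets (strict inequality).
#' @param adj_p_threshold Benjamini-Hochberg adjusted P threshold (strict).
#' @param min_experiments minimum number of experiments a gene must be
#'   significant in to enter the shortlist / overlap universe (inclusive).
#' @param min_sig_genes_percent_overlap minimum significant-set size for an
#'   experiment to enter the percent-overlap clustering (inclusive).
#' @param min_node_degree minimum node degree retained in the overlap
#'   network; lower-degree nodes are removed iteratively.
#' @param cosa_lambda attribute-weight scaling factor of the COSA-style
#'   clustering.
#' @param tss_window half-width in bp of the symmetric window around a TSS
#'   used to call ChIP direct targets.
#' @param n_size_bins number of cell-size (FSC-A) bins for the flow analysis.
#' @param center_bin 1-based index of the reference bin for the KS tests.
#' @param ks_alpha significance level for per-bin KS tests (strict).
#' @param n_permutations number of batch-restricted permutations for the
#'   phenotype-correlation null.
#' @param expected_false_hits calibration budget of the permutation cutoff:
#'   expected number of genes passing per phenotype under the null. Kept
#'   strictly below one so that "less than one correlated gene by random"
#'   holds with margin rather than at the boundary.
#' @param peak_p_threshold significance threshold for ChIP-seq peaks
#'   (strict) when classifying TSS-window direct targets.
#' @param uncoupled_max_significant maximum number of significantly
#'   regulated genes an experiment may have and still be called uncoupled.
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$cosa_lambda
#' @export
analysis_config <- function(lfc_threshold_cluster = 0.5,
                            lfc_threshold_overlap = 0.3,
                            adj_p_threshold = 0.01,
                            min_experiments = 5L,
                            min_sig_genes_percent_overlap = 50L,
                            min_node_degree = 5L,
                            cosa_lambda = 0.6,
                            tss_window = 2000L,
                            n_size_bins = 12L,
                            center_bin = 7L,
                            ks_alpha = 0.01,
                            n_permutations = 1000L,
                            expected_false_hits = 0.5,
                            peak_p_threshold = 0.01,
                            uncoupled_max_significant = 100L,
                            rng_seed = 1L) {
  cfg <- list(
    lfc_threshold_cluster = as.numeric(lfc_threshold_cluster),
    lfc_threshold_overlap = as.numeric(lfc_threshold_overlap),
    adj_p_threshold = as.numeric(adj_p_threshold),
    min_experiments = as.integer(min_experiments),
    min_sig_genes_percent_overlap = as.integer(min_sig_genes_percent_overlap),
    min_node_degree = as.integer(min_node_degree),
    cosa_lambda = as.numeric(cosa_lambda),
    tss_window = as.integer(tss_window),
    n_size_bins = as.integer(n_size_bins),
    center_bin = as.integer(center_bin),
    ks_alpha = as.numeric(ks_alpha),
    n_permutations = as.integer(n_permutations),
    expected_false_hits = as.numeric(expected_false_hits),
    peak_p_threshold = as.numeric(peak_p_threshold),
    uncoupled_max_significant = as.integer(uncoupled_max_significant),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (cfg$lfc_threshold_cluster <= 0 || cfg$lfc_threshold_overlap <= 0)
    stop("log fold-change thresholds must be > 0")
  for (f in c("adj_p_threshold", "ks_alpha", "peak_p_threshold")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop(sprintf("%s must lie in (0, 1)", f))
  }
  if (cfg$min_experiments < 1L) stop("min_experiments must be >= 1")
  if (cfg$min_node_degree < 0L) stop("min_node_degree must be >= 0")
  if (cfg$cosa_lambda <= 0) stop("cosa_lambda must be > 0")
  if (cfg$tss_window <= 0L) stop("tss_window must be > 0")
  if (cfg$n_size_bins < 3L) stop("n_size_bins must be >= 3")
  if (cfg$center_bin < 1L || cfg$center_bin > cfg$n_size_bins)
    stop("center_bin must lie in 1..n_size_bins")
  if (cfg$n_permutations < 0L) stop("n_permutations must be >= 0")
  if (cfg$expected_false_hits <= 0 || cfg$expected_false_hits >= 1)
    stop("expected_false_hits must lie in (0, 1)")
  invisible(cfg)
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path path to a YAML file of `analysis_config()` fields.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to a YAML file
#'
#' @param cfg an `analysis_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  shortlist regime: |logFC| > %.2f, adj P < %.3g, >= %d experiments\n",
              x$lfc_threshold_cluster, x$adj_p_threshold, x$min_experiments))
  cat(sprintf("  overlap regime:   |logFC| > %.2f, adj P < %.3g, min degree %d\n",
              x$lfc_threshold_overlap, x$adj_p_threshold, x$min_node_degree))
  cat(sprintf("  clustering: lambda = %.2f; percent-overlap min set %d\n",
              x$cosa_lambda, x$min_sig_genes_percent_overlap))
  cat(sprintf("  TSS window: +/- %d bp (peak P < %.3g)\n",
              x$tss_window, x$peak_p_threshold))
  cat(sprintf("  flow: %d size bins, center %d, KS alpha %.3g\n",
              x$n_size_bins, x$center_bin, x$ks_alpha))
  cat(sprintf("  permutations: %d (expected false hits %.2f), seed %d\n",
              x$n_permutations, x$expected_false_hits, x$rng_seed))
  invisible(x)
}
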