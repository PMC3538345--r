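#' Expected overlap of two random gene sets
#'
#' Hypergeometric mean: drawing sets of the given sizes uniformly from the
#' universe, the expected intersection is `size_a * size_b / universe`.
#'
#' @param size_a,size_b set sizes.
#' @param universe universe size (> 0).
#' @return Expected overlap (real-valued).
#' @export
expected_overlap <- function(size_a, size_b, universe) {
  if (universe <= 0) stop("universe size must be positive")
  if (size_a > universe || size_b > universe)
    stop("set sizes cannot exceed the universe")
  size_a * size_b / universe
}

empty_edge_table <- function() {
  data.frame(experiment_a = character(), experiment_b = character(),
             sign = integer(), observed = integer(), expected = numeric(),
             weight = numeric(), tie = logical(), stringsAsFactors = FALSE)
}

#' Signed excess-over-random overlap of two significant sets
#'
#' Counts shared genes moving in the same and in the opposite direction;
#' the direction with the larger overlap determines the edge sign
#' (+1 same effect on same genes, -1 opposite effect on same genes) and the
#' observed count. The weight rescales the observed count linearly between
#' the random expectation (`|A|*|B|/universe`) and the maximum possible
#' overlap (`min(|A|, |B|)`), clipped to `[0, 1]`: 0 means less than or
#' equal to random overlap, 1 means complete overlap.
#'
#' @param set_a,set_b named sign vectors (+1/-1 per gene), as produced by
#'   [significant_sets()], already restricted to the universe.
#' @param universe character vector of universe genes, or its size.
#' @return One-row data frame: `sign`, `observed`, `expected`, `weight`,
#'   `tie` (direction counts equal).
#' @export
signed_overlap_weight <- function(set_a, set_b, universe) {
  n_universe <- if (is.character(universe)) length(universe) else universe
  if (n_universe <= 0) stop("empty universe")
  if (is.character(universe)) {
    set_a <- set_a[names(set_a) %in% universe]
    set_b <- set_b[names(set_b) %in% universe]
  }
  shared <- intersect(names(set_a), names(set_b))
  same <- sum(set_a[shared] == set_b[shared])
  opp <- length(shared) - same
  tie <- same == opp && length(shared) > 0
  sign <- if (same >= opp) 1L else -1L  # ties resolve to +1 by convention
  observed <- max(same, opp)
  expected <- expected_overlap(length(set_a), length(set_b), n_universe)
  max_possible <- min(length(set_a), length(set_b))
  weight <- if (max_possible > expected) {
    min(1, max(0, (observed - expected) / (max_possible - expected)))
  } else {
    0
  }
  data.frame(sign = sign, observed = as.integer(observed),
             expected = expected, weight = weight, tie = tie)
}

#' Build the signed target-overlap network
#'
#' The universe is the set of genes significantly regulated in at least
#' `min_experiments` experiments; each experiment's significant set is
#' restricted to it. All pairwise edges with positive excess-overlap weight
#' are created, and nodes with fewer than `min_node_degree` adjacent edges
#' are removed iteratively (degrees re-checked after every removal round)
#' with the removals logged.
#'
#' @param sets a `significant_sets` list (overlap regime).
#' @param config an [analysis_config()].
#' @param universe optional explicit gene universe; by default derived from
#'   the `min_experiments` rule.
#' @return An `overlap_network`: `nodes` (experiment, degree,
#'   n_significant), `edges`, `universe_size`, `pruning_log`.
#' @export
build_network <- function(sets, config = analysis_config(),
                          universe = NULL) {
  if (is.null(universe))
    universe <- shortlist_genes(sets, config$min_experiments)
  restricted <- lapply(sets, function(s) s[names(s) %in% universe])
  exps <- names(sets)
  edges <- empty_edge_table()
  if (length(exps) >= 2 && length(universe) > 0) {
    pairs <- utils::combn(exps, 2)
    rows <- vector("list", ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      w <- signed_overlap_weight(restricted[[a]], restricted[[b]],
                                 length(universe))
      if (w$weight > 0)
        rows[[k]] <- cbind(data.frame(experiment_a = a, experiment_b = b,
                                      stringsAsFactors = FALSE), w)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) > 0) edges <- do.call(rbind, rows)
  }

  # iterative degree pruning to a fixed point
  active <- exps
  pruning_log <- character()
  repeat {
    deg <- stats::setNames(rep(0L, length(active)), active)
    keep_e <- edges$experiment_a %in% active & edges$experiment_b %in% active
    tab <- table(c(edges$experiment_a[keep_e], edges$experiment_b[keep_e]))
    deg[names(tab)] <- as.integer(tab)
    drop <- names(deg)[deg < config$min_node_degree]
    if (length(drop) == 0) break
    pruning_log <- c(pruning_log, drop)
    active <- setdiff(active, drop)
    if (length(active) == 0) break
  }
  edges <- edges[edges$experiment_a %in% active &
                   edges$experiment_b %in% active, , drop = FALSE]
  rownames(edges) <- NULL
  deg <- stats::setNames(rep(0L, length(active)), active)
  tab <- table(c(edges$experiment_a, edges$experiment_b))
  deg[names(tab)] <- as.integer(tab)
  nodes <- data.frame(
    experiment = active,
    degree = unname(deg[active]),
    n_significant = vapply(restricted[active], length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 universe_size = length(universe),
                 pruning_log = pruning_log),
            class = "overlap_network")
}

#' @export
print.overlap_network <- function(x, ...) {
  cat(sprintf("Overlap network: %d nodes, %d edges (universe %s genes, %d pruned)\n",
              nrow(x$nodes), nrow(x$edges),
              ifelse(is.na(x$universe_size), "?", x$universe_size),
              length(x$pruning_log)))
  if (nrow(x$edges) > 0)
    cat(sprintf("  %d positive / %d negative edges; mean weight %.3f\n",
                sum(x$edges$sign > 0), sum(x$edges$sign < 0),
                mean(x$edges$weight)))
  invisible(x)
}

#' Directional percent-overlap clustering of experiments
#'
#' Experiments with at least `min_sig_genes_percent_overlap` significant
#' genes are pairwise compared; `M[a, b] = |A intersect B| / |A|`
#' (direction-sensitive, hence asymmetric). Rows are hierarchically
#' clustered with the cosine angle distance and average linkage.
#'
#' @param sets a `significant_sets` list.
#' @param config an [analysis_config()].
#' @return A list: `percent_matrix`, `dendrogram` (an `hclust`),
#'   `experiments`.
#' @export
percent_overlap_clustering <- function(sets, config = analysis_config()) {
  sizes <- vapply(sets, length, integer(1))
  keep <- names(sets)[sizes >= config$min_sig_genes_percent_overlap]
  if (length(keep) < 2)
    stop("fewer than 2 experiments with >= ",
         config$min_sig_genes_percent_overlap, " significant genes")
  gl <- lapply(sets[keep], names)
  n <- length(keep)
  m <- matrix(0, n, n, dimnames = list(keep, keep))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(gl[[i]], gl[[j]])) / length(gl[[i]])
    }
  }
  d <- cosine_distance(m)
  hc <- stats::hclust(d, method = "average")
  list(percent_matrix = m, dendrogram = hc, experiments = keep)
}

#' Upper-tail hypergeometric enrichment
#'
#' Probability of an overlap at least as large as observed when drawing
#' `|target|` genes uniformly from the universe containing `|annotation|`
#' annotated genes.
#'
#' @param target_set,annotation_set character gene vectors, subsets of the
#'   universe.
#' @param universe character vector of universe genes.
#' @return The upper-tail p value.
#' @export
hypergeometric_enrichment <- function(target_set, annotation_set, universe) {
  if (length(universe) == 0) stop("empty universe")
  target_set <- unique(target_set)
  annotation_set <- unique(annotation_set)
  if (!all(target_set %in% universe) || !all(annotation_set %in% universe))
    stop("target and annotation sets must be subsets of the universe")
  k <- length(intersect(target_set, annotation_set))
  stats::phyper(k - 1, length(annotation_set),
                length(universe) - length(annotation_set),
                length(target_set), lower.tail = FALSE)
}

#' ChIP direct targets: significant peaks near transcription start sites
#'
#' A gene is classified as a direct target when at least one peak with
#' `pvalue < peak_p_threshold` overlaps the half-open window
#' `[TSS - w, TSS + w)` around its transcription start site (0-based
#' coordinates, strand ignored).
#'
#' @param peaks `GRanges` of peak intervals with a `pvalue` column (from
#'   [read_peaks_bed()]).
#' @param tss TSS table (from [read_tss_table()]): `gene`, `chrom`,
#'   `position` (0-based), optional `strand`.
#' @param config an [analysis_config()] supplying `tss_window` and
#'   `peak_p_threshold`.
#' @return Character vector of direct-target genes.
#' @export
chip_tss_targets <- function(peaks, tss, config = analysis_config()) {
  if (length(peaks) == 0 || nrow(tss) == 0) return(character(0))
  if (is.null(peaks$pvalue))
    stop("peaks must carry a 'pvalue' metadata column")
  sig <- peaks[!is.na(peaks$pvalue) & peaks$pvalue < config$peak_p_threshold]
  if (length(sig) == 0) return(character(0))
  w <- config$tss_window
  # 0-based half-open [pos - w, pos + w) -> 1-based closed [pos - w + 1, pos + w]
  windows <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$position - w + 1L,
                              end = tss$position + w)
  )
  # TSS chromosomes absent from the peak set simply produce no hits
  hits <- suppressWarnings(GenomicRanges::findOverlaps(windows, sig))
  sort(unique(tss$gene[unique(S4Vectors::queryHits(hits))]))
}
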