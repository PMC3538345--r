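#' Spearman correlation of gene expression with a phenotype
#'
#' Rank correlation (average ranks on ties) of each gene's logFC profile
#' across experiments with a phenotype vector. Genes with constant profiles
#' return `NA`.
#'
#' @param logfc genes x experiments logFC matrix.
#' @param phenotype named numeric vector, one value per experiment.
#' @param restrict optional character vector of experiments to use (e.g.
#'   those with increased G1 versus batch controls).
#' @param min_experiments minimum experiments after restriction.
#' @return Named vector of Spearman rho per gene.
#' @export
spearman_phenotype_correlation <- function(logfc, phenotype,
                                           restrict = NULL,
                                           min_experiments = 5L) {
  stopifnot(!is.null(colnames(logfc)), !is.null(names(phenotype)))
  keep <- intersect(colnames(logfc), names(phenotype))
  if (!is.null(restrict)) keep <- intersect(keep, restrict)
  if (length(keep) < min_experiments)
    stop("fewer than ", min_experiments,
         " experiments remain after restriction")
  suppressWarnings(
    rho <- stats::cor(t(logfc[, keep, drop = FALSE]), phenotype[keep],
                      method = "spearman")[, 1]
  )
  rho
}

# standardized average ranks along each row
.std_ranks <- function(x) {
  r <- t(apply(x, 1, rank, ties.method = "average"))
  ctr <- r - rowMeans(r)
  sdv <- sqrt(rowSums(ctr^2) / (ncol(x) - 1))
  ctr / ifelse(sdv == 0, NA_real_, sdv)
}

# within-batch permutation indices: a matrix n x n_perm of experiment
# indices, each column permuting experiments within their batch only
batch_permutation_indices <- function(batch, n_perm, seed) {
  set.seed(seed)
  n <- length(batch)
  singles <- names(table(batch))[table(batch) == 1]
  if (length(singles) > 0)
    warning("batch(es) of size 1 left unshuffled: ",
            paste(singles, collapse = ", "))
  idx <- matrix(seq_len(n), n, n_perm)
  for (k in seq_len(n_perm)) {
    for (b in unique(batch)) {
      w <- which(batch == b)
      if (length(w) > 1) idx[w, k] <- w[sample.int(length(w))]
    }
  }
  idx
}

#' Batch-restricted permutation null for phenotype correlations
#'
#' Permutes the phenotype among experiments within each batch, recomputes
#' all gene correlations per permutation, and calibrates a rho cutoff such
#' that the mean number of genes exceeding it across permutations stays at
#' the configured expected-false-hit budget (strictly below one passing
#' gene per phenotype expected by random). Per-gene empirical p values
#' (add-one smoothed) and family-wise p values (against the per-permutation
#' maximum) are both reported.
#'
#' @param logfc genes x experiments logFC matrix (already restricted).
#' @param phenotype named phenotype vector aligned with `logfc` columns.
#' @param batch named batch labels per experiment.
#' @param n_permutations number of permutations (>= 100 recommended).
#' @param seed RNG seed (used only when `perm_idx` is not supplied).
#' @param expected_false_hits calibration budget, in genes per phenotype.
#' @param perm_idx optional precomputed permutation index matrix from
#'   `batch_permutation_indices` (lets several phenotypes share the same
#'   joint permutations).
#' @return A list: `rho` (observed), `empirical_p`, `familywise_p`,
#'   `rho_cutoff`, `passed`, `n_permutations`.
#' @export
batch_permutation_cutoff <- function(logfc, phenotype, batch,
                                     n_permutations = 1000L, seed = 1L,
                                     expected_false_hits = 0.5,
                                     perm_idx = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  exps <- colnames(logfc)
  stopifnot(all(exps %in% names(phenotype)), all(exps %in% names(batch)))
  y <- phenotype[exps]
  b <- batch[exps]
  n <- length(exps)

  rr <- .std_ranks(logfc)               # genes x n
  yr <- rank(y, ties.method = "average")
  yr <- (yr - mean(yr)) / sqrt(sum((yr - mean(yr))^2) / (n - 1))
  rho_obs <- as.vector(rr %*% yr) / (n - 1)
  names(rho_obs) <- rownames(logfc)

  if (is.null(perm_idx))
    perm_idx <- batch_permutation_indices(b, n_permutations, seed)
  yperm <- matrix(yr[perm_idx], n, n_permutations)
  rho_perm <- (rr %*% yperm) / (n - 1)  # genes x perms

  a_obs <- abs(rho_obs)
  a_perm <- abs(rho_perm)
  cnt <- rowSums(a_perm >= a_obs)
  cnt[is.na(a_obs)] <- n_permutations
  empirical_p <- (1 + cnt) / (n_permutations + 1)
  maxes <- apply(a_perm, 2, max, na.rm = TRUE)
  fw_cnt <- vapply(a_obs, function(v) sum(maxes >= v), numeric(1))
  familywise_p <- (1 + fw_cnt) / (n_permutations + 1)

  m <- max(1L, floor(expected_false_hits * n_permutations))
  pooled <- sort(a_perm[is.finite(a_perm)], decreasing = TRUE)
  rho_cutoff <- pooled[min(m, length(pooled))]
  passed <- !is.na(a_obs) & a_obs > rho_cutoff

  list(rho = rho_obs, empirical_p = empirical_p,
       familywise_p = familywise_p, rho_cutoff = rho_cutoff,
       passed = passed, n_permutations = n_permutations)
}

# per-experiment phenotype summaries and deltas versus batch controls
phenotype_deltas <- function(pheno) {
  stopifnot(all(c("experiment_id", "batch", "g1_frac", "is_control") %in%
                  colnames(pheno)))
  ctrl <- pheno[pheno$is_control, , drop = FALSE]
  ctrl_g1 <- tapply(ctrl$g1_frac, ctrl$batch, mean)
  trt <- pheno[!pheno$is_control, , drop = FALSE]
  agg <- stats::aggregate(
    trt[, intersect(c("g1_frac", "s_frac", "g2_frac", "g1_size", "g2_size"),
                    colnames(trt))],
    by = list(experiment_id = trt$experiment_id, batch = trt$batch), mean)
  agg$delta_g1 <- agg$g1_frac - ctrl_g1[agg$batch]
  agg
}

#' Correlate gene expression with FACS phenotypes
#'
#' Driver for the phenotype-correlation analysis: summarizes phenotypes per
#' experiment, restricts to experiments whose G1 fraction increased versus
#' their batch controls, and runs the batch-restricted permutation null for
#' every phenotype. Whole phenotype records are permuted jointly, so
#' cross-phenotype correlations are preserved under the null.
#'
#' @param de a `de_table` (its logFC matrix is used), or a logFC matrix.
#' @param pheno a `phenotype_table` with control rows.
#' @param config an [analysis_config()].
#' @param seed RNG seed for the permutations.
#' @param phenotypes phenotype columns to analyze.
#' @param restrict_g1_increase restrict to experiments with `delta_g1 > 0`.
#' @return A `phenotype_correlation` list: `results` (long data frame of
#'   gene x phenotype rho, empirical and family-wise p, passed flag),
#'   `cutoffs` per phenotype, `experiments_used`, `n_permutations`.
#' @export
correlate_phenotypes <- function(de, pheno, config = analysis_config(),
                                 seed = 1L,
                                 phenotypes = c("g1_frac", "g2_frac",
                                                "g1_size", "g2_size"),
                                 restrict_g1_increase = TRUE) {
  logfc <- if (inherits(de, "de_table")) attr(de, "logfc_matrix") else de
  if (config$n_permutations < 1) stop("n_permutations must be >= 1")
  agg <- phenotype_deltas(pheno)
  keep <- agg$experiment_id[!restrict_g1_increase | agg$delta_g1 > 0]
  keep <- intersect(colnames(logfc), keep)
  if (length(keep) < 5)
    stop("fewer than 5 experiments remain after the G1-increase restriction")
  sub <- logfc[, keep, drop = FALSE]
  batch <- stats::setNames(agg$batch, agg$experiment_id)[keep]
  perm_idx <- batch_permutation_indices(batch, config$n_permutations, seed)

  rows <- list()
  cutoffs <- stats::setNames(numeric(length(phenotypes)), phenotypes)
  for (ph in phenotypes) {
    y <- stats::setNames(agg[[ph]], agg$experiment_id)[keep]
    res <- batch_permutation_cutoff(sub, y, batch,
                                    n_permutations = config$n_permutations,
                                    expected_false_hits = config$expected_false_hits,
                                    perm_idx = perm_idx)
    cutoffs[ph] <- res$rho_cutoff
    rows[[ph]] <- data.frame(gene = names(res$rho), phenotype = ph,
                             rho = unname(res$rho),
                             empirical_p = unname(res$empirical_p),
                             familywise_p = unname(res$familywise_p),
                             passed = unname(res$passed),
                             stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 cutoffs = cutoffs, experiments_used = keep,
                 n_permutations = config$n_permutations),
            class = "phenotype_correlation")
}

#' @export
print.phenotype_correlation <- function(x, ...) {
  cat(sprintf("Phenotype correlation on %d experiments, %d permutations\n",
              length(x$experiments_used), x$n_permutations))
  hits <- table(x$results$phenotype[x$results$passed])
  for (ph in names(x$cutoffs))
    cat(sprintf("  %s: rho cutoff %.3f, %d gene(s) passing\n", ph,
                x$cutoffs[ph],
                if (ph %in% names(hits)) hits[[ph]] else 0L))
  invisible(x)
}

#' Transcription / cell-cycle uncoupling analysis
#'
#' For every experiment, the total transcriptional effect is the Manhattan
#' distance of its logFC profile from zero, restricted to the clustering
#' shortlist (the GFP control profile is 0 by construction of the
#' contrasts). An experiment is flagged uncoupled when its G1 increase is
#' in the top decile of positive G1 shifts while its significant-gene count
#' stays at or below the configured cap. The overall Pearson correlation
#' between G1 shift and total effect is reported.
#'
#' @param de a `de_table`.
#' @param sets `significant_sets` in the overlap regime (0.3 / 0.01).
#' @param pheno a `phenotype_table` with control rows.
#' @param shortlist character vector of shortlist genes (from
#'   [shortlist_genes()] in the 0.5 / 0.01 regime).
#' @param config an [analysis_config()].
#' @return An `uncoupling` list: `records` (experiment, total_effect,
#'   delta_g1, n_significant, uncoupled_flag), `r` (Pearson), `g1_q90`.
#' @export
uncoupling_metrics <- function(de, sets, pheno, shortlist,
                               config = analysis_config()) {
  if (length(shortlist) == 0) stop("empty shortlist")
  logfc <- attr(de, "logfc_matrix")
  shortlist <- intersect(shortlist, rownames(logfc))
  if (length(shortlist) == 0) stop("shortlist genes absent from the matrix")
  total_effect <- colSums(abs(logfc[shortlist, , drop = FALSE]))
  agg <- phenotype_deltas(pheno)
  exps <- intersect(colnames(logfc), agg$experiment_id)
  delta_g1 <- stats::setNames(agg$delta_g1, agg$experiment_id)[exps]
  n_sig <- vapply(sets[exps], length, integer(1))
  pos <- delta_g1[delta_g1 > 0]
  q90 <- if (length(pos) > 0) stats::quantile(pos, 0.9, names = FALSE) else Inf
  flag <- delta_g1 >= q90 & n_sig <= config$uncoupled_max_significant
  records <- data.frame(experiment_id = exps,
                        total_effect = unname(total_effect[exps]),
                        delta_g1 = unname(delta_g1),
                        n_significant = unname(n_sig),
                        uncoupled_flag = unname(flag),
                        stringsAsFactors = FALSE)
  r <- if (nrow(records) >= 3) {
    suppressWarnings(stats::cor(records$delta_g1, records$total_effect,
                                method = "pearson"))
  } else {
    NA_real_
  }
  structure(list(records = records, r = r, g1_q90 = q90),
            class = "uncoupling")
}

#' @export
print.uncoupling <- function(x, ...) {
  cat(sprintf("Uncoupling analysis: %d experiments, r = %.3f, %d flagged\n",
              nrow(x$records), x$r, sum(x$records$uncoupled_flag)))
  invisible(x)
}

#' Fraction of one significant set shared with another
#'
#' @param set_a,set_b named sign vectors or character gene vectors.
#' @return `|A intersect B| / |A|`.
#' @export
set_sharing_fraction <- function(set_a, set_b) {
  a <- if (is.character(set_a)) set_a else names(set_a)
  b <- if (is.character(set_b)) set_b else names(set_b)
  if (length(a) == 0) stop("set A is empty")
  length(intersect(a, b)) / length(a)
}
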