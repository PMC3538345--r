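#' Quantile-normalize an expression matrix
#'
#' Forces every column to share the identical sorted value vector (the
#' per-rank across-column mean); ties within a column receive the mean of
#' their rank-range values. Delegates to limma's quantile normalization.
#'
#' @param mat numeric matrix (genes x samples), at least 2 columns.
#' @return The normalized matrix with dimnames preserved.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (anyNA(mat)) stop("quantile_normalize: matrix contains missing values")
  if (ncol(mat) < 2) {
    warning("single-column matrix returned unchanged")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Batch-matched knockdown contrasts
#'
#' For every experiment, the log fold change is the mean of its treated
#' replicates minus the mean of the GFP control samples of the same batch.
#' The residual variance is pooled per gene over all replicate groups of
#' the batch (controls form one group, each experiment another), so
#' singlicate experiments inherit residual degrees of freedom from the
#' replicated groups in their batch.
#'
#' @param exprs log2 expression matrix (genes x samples).
#' @param sheet matching `sample_sheet`.
#' @return A `batch_contrasts` list: `logfc` (genes x experiments),
#'   `s2` (genes x batches pooled residual variances), `df` (per batch),
#'   `se_scale` (per experiment, `1/n_treated + 1/n_control`),
#'   `experiments` (design table).
#' @export
fit_batch_contrasts <- function(exprs, sheet) {
  check_samples_match(exprs, sheet)
  exprs <- exprs[, sheet$sample_id, drop = FALSE]
  key <- ifelse(sheet$is_control, paste0("CTRL.", sheet$batch),
                paste(sheet$batch, sheet$target_gene, sep = "."))
  # experiment id = kd_<target>, batch-suffixed if a target recurs
  exp_key <- unique(key[!sheet$is_control])
  tg <- sub("^[^.]+\\.", "", exp_key)
  bt <- sub("\\..*$", "", exp_key)
  exp_id <- paste0("kd_", tg)
  if (anyDuplicated(exp_id))
    exp_id <- ifelse(tg %in% tg[duplicated(exp_id) | duplicated(exp_id, fromLast = TRUE)],
                     paste0("kd_", tg, ".", bt), exp_id)
  names(exp_id) <- exp_key

  batches <- unique(sheet$batch)
  genes <- rownames(exprs)
  logfc <- matrix(NA_real_, length(genes), length(exp_id),
                  dimnames = list(genes, unname(exp_id)))
  s2 <- matrix(NA_real_, length(genes), length(batches),
               dimnames = list(genes, batches))
  df <- stats::setNames(numeric(length(batches)), batches)
  se_scale <- stats::setNames(numeric(length(exp_id)), unname(exp_id))
  n_treated <- se_scale

  for (b in batches) {
    in_b <- sheet$batch == b
    groups <- key[in_b]
    xb <- exprs[, in_b, drop = FALSE]
    glev <- unique(groups)
    n_b <- sum(in_b)
    dfb <- n_b - length(glev)
    if (dfb < 1)
      stop("batch '", b, "' has no residual degrees of freedom ",
           "(need replication in controls or treatments)")
    ind <- outer(groups, glev, "==") + 0
    counts <- colSums(ind)
    gmeans <- xb %*% sweep(ind, 2, counts, "/")  # genes x groups
    colnames(gmeans) <- glev
    rss <- rowSums(xb^2) - as.vector(gmeans^2 %*% counts)
    s2[, b] <- pmax(rss, 0) / dfb
    df[b] <- dfb
    ctrl_key <- paste0("CTRL.", b)
    n_ctrl <- counts[match(ctrl_key, glev)]
    for (gk in setdiff(glev, ctrl_key)) {
      e <- exp_id[[gk]]
      logfc[, e] <- gmeans[, gk] - gmeans[, ctrl_key]
      nt <- counts[match(gk, glev)]
      se_scale[e] <- 1 / nt + 1 / n_ctrl
      n_treated[e] <- nt
    }
  }
  experiments <- data.frame(
    experiment_id = unname(exp_id), batch = bt, target_gene = tg,
    n_treated = n_treated[unname(exp_id)], stringsAsFactors = FALSE)
  structure(list(logfc = logfc, s2 = s2, df = df, se_scale = se_scale,
                 experiments = experiments),
            class = "batch_contrasts")
}

# Newton solve of trigamma(x) = y, vectorized (used by the scaled-F
# method-of-moments fit)
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y >= 1e7] <- 1 / sqrt(y[y >= 1e7])
  out[y <= 1e-6] <- 1 / y[y <= 1e-6]
  todo <- is.na(out) & is.finite(y)
  x <- 0.5 + 1 / y[todo]
  if (any(todo)) {
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[todo] <- x
  }
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits the scaled-F model of sample variances by method of moments on the
#' log scale: prior degrees of freedom `d0` and prior variance `s0_sq` are
#' estimated from the mean and excess variance of
#' `log(s2) - digamma(df/2) + log(df/2)`, and each gene's posterior
#' variance is the df-weighted mix `(d0*s0_sq + df*s2) / (d0 + df)`. When
#' the moment equation has no positive solution `d0` is infinite and all
#' posterior variances equal `s0_sq` (complete shrinkage). When every
#' variance is zero the fit falls back to a floor variance with a flag
#' (downstream t statistics are then effectively ordinary t on planted
#' differences).
#'
#' @param variances vector or matrix of per-gene residual variances.
#' @param df residual degrees of freedom (scalar, or one per column when
#'   `variances` is a matrix, or one per element).
#' @param floor_variance fallback variance used when all variances vanish.
#' @return A `moderated_variance` list: `d0`, `s0_sq`, `s2_post` (same
#'   shape as `variances`), `df_total`, `fallback`.
#' @export
moderate_variances <- function(variances, df, floor_variance = 1e-8) {
  is_mat <- is.matrix(variances)
  v <- as.vector(variances)
  if (is_mat && length(df) == ncol(variances)) {
    dfv <- rep(df, each = nrow(variances))
  } else {
    dfv <- rep_len(df, length(v))
  }
  stopifnot(all(dfv > 0), all(v >= 0))

  if (all(v <= floor_variance)) {
    s2_post <- pmax(v, floor_variance)
    out <- list(d0 = 0, s0_sq = floor_variance, s2_post = s2_post,
                df_total = dfv, fallback = TRUE)
  } else {
    pos <- v > 0
    if (sum(pos) < 50)
      warning("fewer than 50 positive variances; hyperparameters unstable")
    z <- log(v[pos])
    e <- z - digamma(dfv[pos] / 2) + log(dfv[pos] / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(dfv[pos] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
    if (is.finite(d0)) {
      s2_post <- (d0 * s0_sq + dfv * v) / (d0 + dfv)
    } else {
      s2_post <- rep(s0_sq, length(v))
    }
    out <- list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post,
                df_total = d0 + dfv, fallback = FALSE)
  }
  if (is_mat) {
    out$s2_post <- matrix(out$s2_post, nrow(variances), ncol(variances),
                          dimnames = dimnames(variances))
    out$df_total <- matrix(out$df_total, nrow(variances), ncol(variances))
  }
  class(out) <- "moderated_variance"
  out
}

#' Moderated t statistics and two-sided p values
#'
#' `t = logfc / sqrt(s2_post * se_scale)` with `d0 + df` degrees of
#' freedom. At `d0 = 0` the posterior variance equals the sample variance
#' and the statistic reduces to the ordinary t.
#'
#' @param logfc effect estimates.
#' @param s2_post posterior variances aligned with `logfc`.
#' @param df_total total degrees of freedom aligned with `logfc`.
#' @param se_scale variance multiplier of the contrast
#'   (`1/n_treated + 1/n_control`).
#' @return A list with `t` and `p` shaped like `logfc`.
#' @export
moderated_t <- function(logfc, s2_post, df_total, se_scale = 1) {
  se <- sqrt(s2_post * se_scale)
  t <- logfc / se
  t[logfc == 0 & se == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  list(t = t, p = p)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up FDR adjustment (monotone in rank, capped at 1).
#'
#' @param p vector of raw p values in `[0, 1]`.
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Batch-matched moderated differential expression
#'
#' Runs the full DE chain: optional quantile normalization, batch-matched
#' contrasts against in-batch GFP controls, empirical-Bayes variance
#' moderation pooled over all (gene, batch) residual variances, moderated t
#' and per-experiment Benjamini-Hochberg adjustment.
#'
#' @param exprs log2 expression matrix (genes x samples).
#' @param sheet matching `sample_sheet`.
#' @param config an [analysis_config()].
#' @param normalize quantile-normalize before contrasting.
#' @return A `de_table` data frame (`experiment_id`, `gene`, `logfc`, `t`,
#'   `p`, `adj_p`) with the logFC matrix, design table and moderation fit
#'   attached as attributes.
#' @export
run_differential_expression <- function(exprs, sheet,
                                        config = analysis_config(),
                                        normalize = TRUE) {
  if (normalize) exprs <- quantile_normalize(exprs)
  bc <- fit_batch_contrasts(exprs, sheet)
  mv <- moderate_variances(bc$s2, bc$df)
  exp_batch <- stats::setNames(bc$experiments$batch,
                               bc$experiments$experiment_id)
  genes <- rownames(bc$logfc)
  exps <- colnames(bc$logfc)
  s2_post <- mv$s2_post[, exp_batch[exps], drop = FALSE]
  df_total <- if (is.matrix(mv$df_total)) {
    mv$df_total[, match(exp_batch[exps], colnames(bc$s2)), drop = FALSE]
  } else {
    matrix(rep(mv$df_total, length.out = length(genes) * length(exps)),
           length(genes))
  }
  se_scale <- matrix(rep(bc$se_scale[exps], each = length(genes)),
                     length(genes))
  tp <- moderated_t(bc$logfc, s2_post, df_total, se_scale)
  adj <- apply(tp$p, 2, bh_adjust)

  de <- data.frame(
    experiment_id = rep(exps, each = length(genes)),
    gene = rep(genes, times = length(exps)),
    logfc = as.vector(bc$logfc),
    t = as.vector(tp$t),
    p = as.vector(tp$p),
    adj_p = as.vector(adj),
    stringsAsFactors = FALSE
  )
  class(de) <- c("de_table", "data.frame")
  attr(de, "logfc_matrix") <- bc$logfc
  attr(de, "experiments") <- bc$experiments
  attr(de, "moderation") <- list(d0 = mv$d0, s0_sq = mv$s0_sq,
                                 fallback = mv$fallback)
  de
}

#' @export
print.de_table <- function(x, ...) {
  ex <- attr(x, "experiments")
  mod <- attr(x, "moderation")
  cat(sprintf("Differential expression: %d experiments x %d genes\n",
              nrow(ex), nrow(attr(x, "logfc_matrix"))))
  cat(sprintf("  moderation: d0 = %.3g, s0^2 = %.3g%s\n", mod$d0, mod$s0_sq,
              if (isTRUE(mod$fallback)) " (zero-variance fallback)" else ""))
  invisible(x)
}

#' Signed significant-gene sets
#'
#' A gene enters an experiment's set when `|logfc|` exceeds the threshold
#' and the adjusted p value is below the threshold (both strict), signed by
#' the direction of the change.
#'
#' @param de a `de_table` from [run_differential_expression()].
#' @param lfc_threshold absolute log2 fold-change threshold.
#' @param adj_p_threshold adjusted-p threshold.
#' @return A `significant_sets` named list (one per experiment) of named
#'   sign vectors (+1 / -1 per gene), with thresholds attached.
#' @export
significant_sets <- function(de, lfc_threshold, adj_p_threshold) {
  keep <- abs(de$logfc) > lfc_threshold & de$adj_p < adj_p_threshold
  sub <- de[keep, , drop = FALSE]
  exps <- attr(de, "experiments")$experiment_id
  sets <- lapply(stats::setNames(exps, exps), function(e) {
    rows <- sub[sub$experiment_id == e, , drop = FALSE]
    stats::setNames(ifelse(rows$logfc > 0, 1L, -1L), rows$gene)
  })
  structure(sets, class = "significant_sets",
            lfc_threshold = lfc_threshold, adj_p_threshold = adj_p_threshold)
}

#' Rank of the intended target among down-regulated genes
#'
#' Self-knockdown QC: the target gene's rank when the experiment's genes
#' are ordered by ascending log fold change. Experiments whose target is
#' absent from the matrix return `NA` (not an error), mirroring probes
#' missing from an array.
#'
#' @param de a `de_table`.
#' @param experiment_id experiment to check.
#' @param top_percent flag threshold on the percentile (default 0.01, the
#'   "top 1 percent of down-regulated genes" rule).
#' @return A list: `target`, `rank`, `percentile`, `flagged`.
#' @export
self_knockdown_rank <- function(de, experiment_id, top_percent = 0.01) {
  ex <- attr(de, "experiments")
  i <- match(experiment_id, ex$experiment_id)
  if (is.na(i)) stop("unknown experiment: ", experiment_id)
  target <- ex$target_gene[i]
  lfc <- attr(de, "logfc_matrix")[, experiment_id]
  if (!target %in% names(lfc))
    return(list(target = target, rank = NA_integer_,
                percentile = NA_real_, flagged = NA))
  r <- rank(lfc, ties.method = "min")[[target]]
  pct <- r / length(lfc)
  list(target = target, rank = as.integer(r), percentile = pct,
       flagged = pct <= top_percent)
}

#' Shortlist genes significant in several experiments
#'
#' @param sets a `significant_sets` list.
#' @param min_experiments minimum number of experiments (inclusive, "in at
#'   least five experiments").
#' @return Character vector of gene ids.
#' @export
shortlist_genes <- function(sets, min_experiments) {
  counts <- table(unlist(lapply(sets, names), use.names = FALSE))
  sort(names(counts)[counts >= min_experiments])
}
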