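cosine_distance <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0))
    stop("cosine distance undefined for all-zero rows")
  sim <- tcrossprod(mat / norms)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  stats::as.dist(1 - sim)
}

#' Pairwise row distances
#'
#' Euclidean and Manhattan via [stats::dist()]; cosine distance is
#' `1 - cos(angle)` between rows (scale-invariant).
#'
#' @param mat numeric matrix, rows are the objects.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"cosine"`.
#' @return A `dist` object.
#' @export
pairwise_distances <- function(mat,
                               metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  if (anyNA(mat) || any(!is.finite(mat)))
    stop("distance input must be finite")
  switch(metric,
         euclidean = stats::dist(mat, method = "euclidean"),
         manhattan = stats::dist(mat, method = "manhattan"),
         cosine = cosine_distance(mat))
}

#' Agglomerative hierarchical clustering
#'
#' Thin wrapper around [stats::hclust()]; average linkage is the pipeline
#' default.
#'
#' @param d a `dist` object.
#' @param linkage linkage criterion.
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  stopifnot(inherits(d, "dist"))
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into clusters
#'
#' @param tree an `hclust`.
#' @param k number of clusters, or
#' @param h cut height (one of the two must be given).
#' @return Integer cluster labels named by object.
#' @export
cut_clusters <- function(tree, k = NULL, h = NULL) {
  if (is.null(k) && is.null(h)) stop("supply k or h")
  n <- length(tree$order)
  if (!is.null(k) && k > n) stop("k exceeds the number of objects")
  stats::cutree(tree, k = k, h = h)
}

#' Per-cluster attribute weights of the COSA-style distance
#'
#' For each cluster and experiment the dispersion `s_ke` is the mean
#' absolute deviation of the cluster's members from their mean on that
#' experiment; weights are `exp(-s_ke / lambda)` normalized to sum to one
#' over experiments, so tightly co-regulated experiments dominate the
#' cluster's distance.
#'
#' @param mat genes x experiments logFC matrix.
#' @param labels integer cluster labels (one per row of `mat`).
#' @param lambda scaling factor (> 0).
#' @return Matrix of weights, clusters x experiments, rows summing to 1.
#' @export
cosa_lite_weights <- function(mat, labels, lambda) {
  stopifnot(lambda > 0, length(labels) == nrow(mat))
  lev <- sort(unique(labels))
  w <- matrix(NA_real_, length(lev), ncol(mat),
              dimnames = list(as.character(lev), colnames(mat)))
  for (i in seq_along(lev)) {
    rows <- mat[labels == lev[i], , drop = FALSE]
    ctr <- colMeans(rows)
    s <- colMeans(abs(sweep(rows, 2, ctr)))
    ew <- exp(-s / lambda)
    w[i, ] <- ew / sum(ew)
  }
  w
}

#' Attribute-weighted Manhattan distances
#'
#' `D_ij = sum_e max(w_(k(i), e), w_(k(j), e)) * |x_ie - x_je|`, combining
#' the attribute weights of the clusters containing the two objects by the
#' elementwise maximum. With uniform weights this reduces to the plain
#' Manhattan distance divided by the number of experiments.
#'
#' @param mat genes x experiments matrix.
#' @param weights cluster x experiment weight matrix
#'   (from [cosa_lite_weights()]).
#' @param labels integer cluster labels per row of `mat`.
#' @return A `dist` object.
#' @export
cosa_lite_distance <- function(mat, weights, labels) {
  n <- nrow(mat)
  lab_chr <- as.character(labels)
  wrow <- weights[lab_chr, , drop = FALSE]  # n x p, weight of each row's cluster
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    wmax <- pmax(matrix(wrow[i, ], length(js), ncol(mat), byrow = TRUE),
                 wrow[js, , drop = FALSE])
    diffs <- abs(sweep(mat[js, , drop = FALSE], 2, mat[i, ]))
    d[i, js] <- d[js, i] <- rowSums(wmax * diffs)
  }
  dimnames(d) <- list(rownames(mat), rownames(mat))
  stats::as.dist(d)
}

#' Simplified COSA-style attribute-weighted clustering
#'
#' Iterates clustering and attribute weighting: initial labels come from
#' unweighted Manhattan average-linkage clustering; each round recomputes
#' per-cluster attribute weights ([cosa_lite_weights()]), the weighted
#' distance ([cosa_lite_distance()]), and the clustering, until the
#' partition stops changing or `max_iter` is reached. This keeps only the
#' lambda-controlled attribute weighting of the full COSA algorithm and is
#' deliberately a lightweight variant; results are validated against
#' planted truth, not against any external implementation.
#'
#' @param mat genes x experiments logFC matrix.
#' @param k number of clusters.
#' @param lambda scaling factor (> 0); large lambda approaches plain
#'   Manhattan clustering.
#' @param max_iter maximum weight/cluster iterations.
#' @param tol fraction of labels allowed to change at convergence.
#' @return A `cosa_lite` list: `labels`, `weights`, `tree` (final
#'   `hclust`), `iterations`, `converged`.
#' @export
cosa_lite <- function(mat, k, lambda = 0.6, max_iter = 20L, tol = 0) {
  stopifnot(lambda > 0, k >= 1)
  d0 <- pairwise_distances(mat, "manhattan")
  tree <- hierarchical_cluster(d0, "average")
  labels <- cut_clusters(tree, k = k)
  converged <- FALSE
  iter <- 0L
  weights <- cosa_lite_weights(mat, labels, lambda)
  for (iter in seq_len(max_iter)) {
    weights <- cosa_lite_weights(mat, labels, lambda)
    d <- cosa_lite_distance(mat, weights, labels)
    tree <- hierarchical_cluster(d, "average")
    new_labels <- cut_clusters(tree, k = k)
    changed <- !same_partition(labels, new_labels)
    frac_changed <- mean(partition_disagreement(labels, new_labels))
    labels <- new_labels
    if (!changed || frac_changed <= tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(labels = labels, weights = weights, tree = tree,
                 iterations = iter, converged = converged),
            class = "cosa_lite")
}

# TRUE when two label vectors induce the same partition
same_partition <- function(a, b) {
  identical(unname(match(a, unique(a))), unname(match(b, unique(b))))
}

# per-object indicator of membership change after best-effort label matching
partition_disagreement <- function(a, b) {
  ca <- match(a, unique(a))
  cb <- match(b, unique(b))
  ca != cb
}

#' Extract gene clusters from a clustering result
#'
#' @param x an `hclust` tree or a `cosa_lite` result.
#' @param k,h cut parameters (ignored for `cosa_lite`, whose labels are
#'   final).
#' @return A `gene_cluster_set`: named list mapping cluster id to gene
#'   vector.
#' @export
extract_gene_clusters <- function(x, k = NULL, h = NULL) {
  labels <- if (inherits(x, "cosa_lite")) {
    x$labels
  } else if (inherits(x, "hclust")) {
    cut_clusters(x, k = k, h = h)
  } else {
    stop("x must be an hclust or cosa_lite object")
  }
  out <- split(names(labels), labels)
  names(out) <- paste0("cluster", names(out))
  structure(out, class = "gene_cluster_set")
}

#' Annotate clusters by hypergeometric enrichment
#'
#' @param clusters a `gene_cluster_set`.
#' @param annotations named list of annotation gene vectors (user-supplied;
#'   no ontology is bundled). Genes outside the universe are dropped with a
#'   warning.
#' @param universe character vector of universe genes.
#' @return Data frame: `cluster`, `annotation`, `overlap`, `cluster_size`,
#'   `annotation_size`, `p`.
#' @export
annotate_clusters <- function(clusters, annotations, universe) {
  rows <- list()
  for (cl in names(clusters)) {
    genes <- intersect(clusters[[cl]], universe)
    if (length(genes) == 0) {
      warning("cluster ", cl, " has no genes in the universe; skipped")
      next
    }
    for (an in names(annotations)) {
      ann <- annotations[[an]]
      outside <- setdiff(ann, universe)
      if (length(outside) > 0) {
        warning(length(outside), " annotation gene(s) of '", an,
                "' outside the universe dropped")
        ann <- intersect(ann, universe)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, annotation = an,
        overlap = length(intersect(genes, ann)),
        cluster_size = length(genes), annotation_size = length(ann),
        p = hypergeometric_enrichment(genes, ann, universe),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(cluster = character(), annotation = character(),
                      overlap = integer(), cluster_size = integer(),
                      annotation_size = integer(), p = numeric()))
  do.call(rbind, rows)
}
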