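#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample identifiers, gene identifiers in the first
#' column, and a fully numeric body (log2 scale after normalization).
#' Duplicated gene or sample identifiers and missing or non-numeric cells
#' are rejected.
#'
#' @param path path to a tab-separated matrix.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression matrix needs a gene column plus >= 1 sample column")
  genes <- df[[1]]
  samples <- colnames(df)[-1]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0)
    stop("duplicated gene id(s) in expression matrix: ",
         paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0)
    stop("duplicated sample id(s) in expression matrix: ",
         paste(dup_s, collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing cell at gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, samples)
  num
}

#' Write a log2 expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; values are written at full
#' precision so a write/read round trip is lossless.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), is.numeric(mat),
            !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sheet must carry columns `sample_id`, `batch`, `target_gene`,
#' `is_control` (and optionally `replicate_index`). Each batch must contain
#' at least one control sample (the GFP knockdowns that anchor the
#' batch-matched contrasts); controls carry target `NONE`.
#'
#' @param path path to a tab-separated sample sheet.
#' @return A `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_sample_sheet(df)
}

#' Construct a validated sample sheet from a data frame
#'
#' @param df data frame with columns `sample_id`, `batch`, `target_gene`,
#'   `is_control`, optional `replicate_index`.
#' @return A `sample_sheet` data frame.
#' @export
as_sample_sheet <- function(df) {
  need <- c("sample_id", "batch", "target_gene", "is_control")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$batch <- as.character(df$batch)
  df$target_gene <- as.character(df$target_gene)
  df$is_control <- as.logical(df$is_control)
  if (anyNA(df$is_control)) stop("is_control must be logical (TRUE/FALSE)")
  if (is.null(df$replicate_index)) df$replicate_index <- 1L
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0)
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  ctl_per_batch <- tapply(df$is_control, df$batch, sum)
  no_ctl <- names(ctl_per_batch)[ctl_per_batch == 0]
  if (length(no_ctl) > 0)
    stop("batch(es) without any control sample: ",
         paste(no_ctl, collapse = ", "))
  bad_target <- !df$is_control &
    (is.na(df$target_gene) | df$target_gene %in% c("", "NONE"))
  if (any(bad_target))
    stop("non-control sample(s) without a target gene: ",
         paste(df$sample_id[bad_target], collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet to TSV
#'
#' @param sheet a `sample_sheet` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check that a matrix and sample sheet describe the same samples
#'
#' @param mat expression matrix (samples in columns).
#' @param sheet a `sample_sheet`.
#' @return Invisibly `TRUE`; errors listing the offending ids otherwise.
#' @export
check_samples_match <- function(mat, sheet) {
  only_mat <- setdiff(colnames(mat), sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, colnames(mat))
  if (length(only_mat) > 0 || length(only_sheet) > 0)
    stop("sample ids do not match; only in matrix: [",
         paste(only_mat, collapse = ", "), "]; only in sheet: [",
         paste(only_sheet, collapse = ", "), "]")
  invisible(TRUE)
}

#' Read ChIP-seq peak intervals from BED
#'
#' BED coordinates are 0-based half-open on disk; the returned `GRanges` is
#' 1-based closed as usual for Bioconductor containers. A 5th column, when
#' present, is kept as the peak significance (`pvalue`).
#'
#' @param path path to a BED4/BED5 file.
#' @return A `GRanges` with an optional `pvalue` metadata column.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad) > 0)
    stop("malformed coordinate on BED line ", bad[1])
  rev <- which(starts >= ends)
  if (length(rev) > 0)
    stop("BED line ", rev[1], ": start >= end (intervals are half-open)")
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$score)) {
    gr$pvalue <- as.numeric(gr$score)
    gr$score <- NULL
  }
  gr
}

#' Read a TSS table
#'
#' Tab-separated columns `gene`, `chrom`, `position`, `strand`; positions
#' are 0-based, matching the BED convention for the peak intervals.
#'
#' @param path path to the TSS table.
#' @return A data frame with one row per gene.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "position")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("TSS table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$strand)) df$strand <- "*"
  df$position <- as.integer(df$position)
  if (anyNA(df$position)) stop("non-integer TSS position")
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0)
    stop("duplicated gene(s) in TSS table: ", paste(dup, collapse = ", "))
  df
}

#' Export an overlap network as GraphML
#'
#' Nodes carry degree and significant-set size; edges carry sign, observed
#' and expected overlap, and the 0-1 excess-overlap weight. Re-importing
#' with [read_network_graphml()] yields an isomorphic graph with identical
#' attributes.
#'
#' @param net an `overlap_network` (see [build_network()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "overlap_network"))
  g <- as_igraph_network(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

as_igraph_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (nrow(edges) > 0) {
    orphan <- setdiff(unique(c(edges$experiment_a, edges$experiment_b)),
                      nodes$experiment)
    if (length(orphan) > 0)
      stop("network has edges naming nodes absent from the node table ",
           "(unpruned metadata): ", paste(orphan, collapse = ", "))
  }
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(nodes) > 0) {
    g <- igraph::set_vertex_attr(g, "name", value = nodes$experiment)
    g <- igraph::set_vertex_attr(g, "degree", value = as.numeric(nodes$degree))
    g <- igraph::set_vertex_attr(g, "n_significant_genes",
                                 value = as.numeric(nodes$n_significant))
  }
  if (nrow(edges) > 0) {
    idx <- rbind(match(edges$experiment_a, nodes$experiment),
                 match(edges$experiment_b, nodes$experiment))
    g <- igraph::add_edges(g, as.vector(idx))
    g <- igraph::set_edge_attr(g, "sign", value = as.numeric(edges$sign))
    g <- igraph::set_edge_attr(g, "observed", value = as.numeric(edges$observed))
    g <- igraph::set_edge_attr(g, "expected", value = edges$expected)
    g <- igraph::set_edge_attr(g, "weight", value = edges$weight)
  }
  g
}

#' Import an overlap network from GraphML
#'
#' @param path a GraphML file written by [write_network_graphml()].
#' @return An `overlap_network` object (without pruning provenance, which
#'   is not serialized).
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  nodes <- data.frame(
    experiment = if (n > 0) igraph::vertex_attr(g, "name") else character(),
    degree = if (n > 0) as.integer(igraph::vertex_attr(g, "degree")) else integer(),
    n_significant = if (n > 0) as.integer(igraph::vertex_attr(g, "n_significant_genes")) else integer(),
    stringsAsFactors = FALSE
  )
  m <- igraph::ecount(g)
  if (m > 0) {
    ends <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(
      experiment_a = ends[, 1], experiment_b = ends[, 2],
      sign = as.integer(igraph::edge_attr(g, "sign")),
      observed = as.integer(igraph::edge_attr(g, "observed")),
      expected = igraph::edge_attr(g, "expected"),
      weight = igraph::edge_attr(g, "weight"),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- empty_edge_table()
  }
  structure(list(nodes = nodes, edges = edges, universe_size = NA_integer_,
                 pruning_log = character()),
            class = "overlap_network")
}
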