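#' Run the full compendium analysis
#'
#' Chains every stage on a matrix + sample sheet (+ optional phenotypes):
#' differential expression, significant sets in both threshold regimes,
#' shortlist, overlap network, COSA-style gene clustering, phenotype
#' correlation and the uncoupling analysis. Results are returned as a list
#' and, when `out_dir` is given, written as TSV/GraphML files.
#'
#' @param exprs log2 expression matrix.
#' @param sheet matching `sample_sheet`.
#' @param pheno optional `phenotype_table`.
#' @param config an [analysis_config()].
#' @param out_dir optional output directory.
#' @param seed RNG seed for the permutation stages.
#' @param k_gene_clusters clusters to extract from the shortlist profile.
#' @return A `compendium_analysis` list with elements `de`, `sets_overlap`,
#'   `sets_cluster`, `shortlist`, `network`, `clustering`, `correlation`,
#'   `uncoupling` (the last two `NULL` without phenotypes).
#' @export
run_pipeline <- function(exprs, sheet, pheno = NULL,
                         config = analysis_config(), out_dir = NULL,
                         seed = config$rng_seed, k_gene_clusters = 4L) {
  check_samples_match(exprs, sheet)
  de <- run_differential_expression(exprs, sheet, config)
  sets_overlap <- significant_sets(de, config$lfc_threshold_overlap,
                                   config$adj_p_threshold)
  sets_cluster <- significant_sets(de, config$lfc_threshold_cluster,
                                   config$adj_p_threshold)
  shortlist <- shortlist_genes(sets_cluster, config$min_experiments)
  network <- build_network(sets_overlap, config)
  clustering <- NULL
  if (length(shortlist) >= max(2L, k_gene_clusters)) {
    profile <- attr(de, "logfc_matrix")[shortlist, , drop = FALSE]
    clustering <- cosa_lite(profile, k = k_gene_clusters,
                            lambda = config$cosa_lambda)
  }
  correlation <- NULL
  uncoupling <- NULL
  if (!is.null(pheno)) {
    correlation <- correlate_phenotypes(de, pheno, config, seed = seed)
    if (length(shortlist) > 0)
      uncoupling <- uncoupling_metrics(de, sets_overlap, pheno, shortlist,
                                       config)
  }
  res <- structure(list(de = de, sets_overlap = sets_overlap,
                        sets_cluster = sets_cluster, shortlist = shortlist,
                        network = network, clustering = clustering,
                        correlation = correlation, uncoupling = uncoupling,
                        config = config),
                   class = "compendium_analysis")
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' @export
print.compendium_analysis <- function(x, ...) {
  ex <- attr(x$de, "experiments")
  cat(sprintf("Compendium analysis: %d experiments, %d shortlist genes\n",
              nrow(ex), length(x$shortlist)))
  print(x$network)
  if (!is.null(x$uncoupling)) print(x$uncoupling)
  invisible(x)
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  utils::write.table(as.data.frame(res$de), path("de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig_long <- do.call(rbind, lapply(names(res$sets_overlap), function(e) {
    s <- res$sets_overlap[[e]]
    if (length(s) == 0) return(NULL)
    data.frame(experiment_id = e, gene = names(s), sign = unname(s),
               stringsAsFactors = FALSE)
  }))
  if (is.null(sig_long))
    sig_long <- data.frame(experiment_id = character(), gene = character(),
                           sign = integer())
  utils::write.table(sig_long, path("significant_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(res$shortlist, path("shortlist_genes.txt"))
  utils::write.table(res$network$edges, path("network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_graphml(res$network, path("network.graphml"))
  if (!is.null(res$clustering)) {
    utils::write.table(
      data.frame(gene = names(res$clustering$labels),
                 cluster = unname(res$clustering$labels)),
      path("gene_clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(res$clustering$weights, path("cosa_weights.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(res$correlation))
    utils::write.table(res$correlation$results,
                       path("phenotype_correlation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$uncoupling))
    utils::write.table(res$uncoupling$records, path("uncoupling.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(res$config, path("config_used.yaml"))
  invisible(out_dir)
}

cli_usage <- function() {
  paste(
    "usage: compendium-cli <subcommand> [--config FILE] [--seed N]",
    "                      [--out-dir DIR] [--matrix FILE] [--sheet FILE]",
    "                      [--pheno FILE] [--flow FILE]",
    "subcommands: simulate | de | overlap | cluster | correlate | flow | all",
    sep = "\n")
}

parse_cli_args <- function(args) {
  if (length(args) == 0) stop(cli_usage(), call. = FALSE)
  sub <- args[1]
  opts <- list(seed = 1L, out_dir = "results", config = NULL,
               matrix = NULL, sheet = NULL, pheno = NULL, flow = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts)) stop("unknown option: ", args[i], call. = FALSE)
    if (i + 1L > length(args)) stop("missing value for --", key, call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts$seed <- as.integer(opts$seed)
  list(subcommand = sub, opts = opts)
}

#' Command-line entry point
#'
#' Drives the pipeline from parsed shell arguments; see
#' `inst/scripts/compendium-cli.R` for the executable wrapper. Runs are
#' deterministic given `--seed`; a log file in the output directory records
#' the configuration and package version.
#'
#' @param args character vector of arguments
#'   (e.g. `c("simulate", "--seed", "1", "--out-dir", "out")`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
compendium_cli <- function(args) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    sub <- parsed$subcommand
    o <- parsed$opts
    cfg <- if (!is.null(o$config)) read_config(o$config) else
      analysis_config(rng_seed = o$seed)
    dir.create(o$out_dir, recursive = TRUE, showWarnings = FALSE)

    load_inputs <- function() {
      if (is.null(o$matrix) || is.null(o$sheet))
        stop("--matrix and --sheet are required for this subcommand")
      list(exprs = read_expression_matrix(o$matrix),
           sheet = read_sample_sheet(o$sheet))
    }

    if (sub == "simulate") {
      sim <- generate_compendium(seed = o$seed)
      write_expression_matrix(sim$exprs, file.path(o$out_dir, "expression.tsv"))
      write_sample_sheet(sim$sheet, file.path(o$out_dir, "sample_sheet.tsv"))
      pheno <- generate_phenotypes(sim$sheet, sim$truth, seed = o$seed)
      utils::write.table(pheno, file.path(o$out_dir, "phenotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (sub %in% c("de", "overlap", "cluster", "all")) {
      inp <- load_inputs()
      pheno <- NULL
      if (!is.null(o$pheno) && sub == "all") {
        pheno <- utils::read.delim(o$pheno, stringsAsFactors = FALSE)
        class(pheno) <- c("phenotype_table", "data.frame")
      }
      if (sub == "all") {
        run_pipeline(inp$exprs, inp$sheet, pheno = pheno, config = cfg,
                     out_dir = o$out_dir, seed = o$seed)
      } else {
        de <- run_differential_expression(inp$exprs, inp$sheet, cfg)
        utils::write.table(as.data.frame(de),
                           file.path(o$out_dir, "de_results.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (sub %in% c("overlap", "cluster")) {
          sets <- significant_sets(de, cfg$lfc_threshold_overlap,
                                   cfg$adj_p_threshold)
          if (sub == "overlap") {
            net <- build_network(sets, cfg)
            utils::write.table(net$edges,
                               file.path(o$out_dir, "network_edges.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            write_network_graphml(net, file.path(o$out_dir, "network.graphml"))
          } else {
            sets_c <- significant_sets(de, cfg$lfc_threshold_cluster,
                                       cfg$adj_p_threshold)
            shortlist <- shortlist_genes(sets_c, cfg$min_experiments)
            if (length(shortlist) < 2) stop("shortlist too small to cluster")
            cl <- cosa_lite(attr(de, "logfc_matrix")[shortlist, , drop = FALSE],
                            k = 4L, lambda = cfg$cosa_lambda)
            utils::write.table(
              data.frame(gene = names(cl$labels), cluster = unname(cl$labels)),
              file.path(o$out_dir, "gene_clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
          }
        }
      }
    } else if (sub == "correlate") {
      inp <- load_inputs()
      if (is.null(o$pheno)) stop("--pheno is required for correlate")
      pheno <- utils::read.delim(o$pheno, stringsAsFactors = FALSE)
      class(pheno) <- c("phenotype_table", "data.frame")
      de <- run_differential_expression(inp$exprs, inp$sheet, cfg)
      corr <- correlate_phenotypes(de, pheno, cfg, seed = o$seed)
      utils::write.table(corr$results,
                         file.path(o$out_dir, "phenotype_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (sub == "flow") {
      if (is.null(o$flow)) stop("--flow is required for the flow subcommand")
      ev <- read_flow_csv(o$flow)
      prof <- flow_size_profile(ev, cfg)
      utils::write.table(as.data.frame(prof),
                         file.path(o$out_dir, "flow_bin_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      stop(cli_usage(), call. = FALSE)
    }

    writeLines(c(sprintf("rnaicompendium %s",
                         as.character(utils::packageVersion("rnaicompendium"))),
                 sprintf("subcommand: %s", sub),
                 sprintf("seed: %d", o$seed),
                 sprintf("config: %s",
                         paste(deparse(unclass(cfg)), collapse = ""))),
               file.path(o$out_dir, "run_log.txt"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
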