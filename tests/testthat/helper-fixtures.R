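# shared fixtures, built in code and cached across test files

.fixtures <- new.env(parent = emptyenv())

# default synthetic compendium (seed 1) with DE results, reused by several
# test files to keep the suite fast
default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- generate_compendium(seed = 1)
    .fixtures$de <- run_differential_expression(.fixtures$sim$exprs,
                                                .fixtures$sim$sheet)
  }
  list(sim = .fixtures$sim, de = .fixtures$de)
}

# tiny two-batch compendium with hand-set values: 3 genes, each batch has
# 2 controls and 1 singlicate experiment plus 1 duplicate experiment
tiny_sheet <- function() {
  as_sample_sheet(data.frame(
    sample_id = c("c1", "c2", "t1a", "t1b", "t2",
                  "d1", "d2", "u1a", "u1b", "u2"),
    batch = rep(c("A", "B"), each = 5),
    target_gene = c("NONE", "NONE", "gene2", "gene2", "gene3",
                    "NONE", "NONE", "gene1", "gene1", "gene2"),
    is_control = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, FALSE, FALSE, FALSE),
    replicate_index = c(1, 2, 1, 2, 1, 1, 2, 1, 2, 1),
    stringsAsFactors = FALSE))
}

tiny_exprs <- function(sheet = tiny_sheet(), seed = 7, sd = 0.1) {
  set.seed(seed)
  genes <- c("gene1", "gene2", "gene3")
  m <- matrix(stats::rnorm(length(genes) * nrow(sheet), 8, sd),
              length(genes), nrow(sheet),
              dimnames = list(genes, sheet$sample_id))
  m
}

# build a de_table skeleton by hand (for threshold-boundary tests)
fake_de_table <- function(df, experiments) {
  class(df) <- c("de_table", "data.frame")
  genes <- unique(df$gene)
  lfc <- matrix(NA_real_, length(genes), nrow(experiments),
                dimnames = list(genes, experiments$experiment_id))
  for (i in seq_len(nrow(df)))
    lfc[df$gene[i], df$experiment_id[i]] <- df$logfc[i]
  attr(df, "logfc_matrix") <- lfc
  attr(df, "experiments") <- experiments
  df
}

# signed set helper: named sign vector
sset <- function(genes, signs = 1L) {
  stats::setNames(rep_len(as.integer(signs), length(genes)), genes)
}

# brute-force upper-tail hypergeometric by enumeration over overlap counts
enum_hyper_tail <- function(k, size_ann, size_univ, size_target) {
  ks <- k:min(size_ann, size_target)
  sum(choose(size_ann, ks) * choose(size_univ - size_ann, size_target - ks)) /
    choose(size_univ, size_target)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

module_labels <- function(truth, genes) {
  m <- truth$module_assignments[genes]
  ifelse(is.na(m), "none", m)
}
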