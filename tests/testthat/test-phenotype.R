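test_that("Spearman correlation matches hand rank computations", {
  lf <- rbind(gA = c(1, 2, 3, 4, 5),
              gB = c(2, 1, 4, 3, 5),
              gC = c(7, 7, 7, 7, 7))
  colnames(lf) <- paste0("e", 1:5)
  y <- setNames(c(10, 20, 30, 40, 50), colnames(lf))
  rho <- spearman_phenotype_correlation(lf, y)
  expect_equal(unname(rho["gA"]), 1.0)
  expect_true(is.na(rho["gC"]))  # constant profile
  # x = (1,2,3,4), y = (2,1,4,3): hand-computed rho = 0.6
  lf4 <- rbind(gA = c(1, 2, 3, 4))
  colnames(lf4) <- paste0("e", 1:4)
  y4 <- setNames(c(2, 1, 4, 3), colnames(lf4))
  expect_equal(unname(spearman_phenotype_correlation(lf4, y4,
                                                     min_experiments = 4)),
               0.6)
  expect_error(
    spearman_phenotype_correlation(lf, y, restrict = paste0("e", 1:4)),
    "fewer than 5")
})

test_that("permutations preserve each batch's phenotype multiset", {
  batch <- setNames(rep(c("A", "B", "C"), times = c(4, 3, 1)),
                    paste0("e", 1:8))
  y <- setNames(c(5, 6, 7, 8, 1, 2, 3, 99), names(batch))
  expect_warning(
    idx <- rnaicompendium:::batch_permutation_indices(batch, 50, seed = 2),
    "size 1")
  for (k in seq_len(ncol(idx))) {
    yk <- y[idx[, k]]
    for (b in unique(batch)) {
      expect_setequal(unname(yk[batch == b]), unname(y[batch == b]))
    }
  }
  # the singleton batch never moves
  expect_true(all(idx[8, ] == 8))
})

test_that("empirical p values are uniform under the null", {
  set.seed(71)
  g <- 400; n <- 36
  lf <- matrix(rnorm(g * n), g, n,
               dimnames = list(paste0("g", 1:g), paste0("e", 1:n)))
  batch <- setNames(rep(paste0("b", 1:6), each = 6), colnames(lf))
  y <- setNames(rnorm(n), colnames(lf))
  res <- batch_permutation_cutoff(lf, y, batch, n_permutations = 1000,
                                  seed = 3)
  ks <- suppressWarnings(stats::ks.test(res$empirical_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the calibrated cutoff admits less than one null gene on average", {
  counts <- vapply(1:3, function(s) {
    set.seed(100 + s)
    g <- 500; n <- 48
    lf <- matrix(rnorm(g * n), g, n,
                 dimnames = list(paste0("g", 1:g), paste0("e", 1:n)))
    batch <- setNames(rep(paste0("b", 1:6), each = 8), colnames(lf))
    y <- setNames(rnorm(n), colnames(lf))
    res <- batch_permutation_cutoff(lf, y, batch, n_permutations = 500,
                                    seed = s)
    sum(res$passed)
  }, numeric(1))
  expect_lt(mean(counts), 1)
})

test_that("a strongly linked gene passes the cutoff reliably", {
  hits <- vapply(1:10, function(s) {
    set.seed(200 + s)
    g <- 500; n <- 48
    lf <- matrix(rnorm(g * n), g, n,
                 dimnames = list(paste0("g", 1:g), paste0("e", 1:n)))
    batch <- setNames(rep(paste0("b", 1:6), each = 8), colnames(lf))
    y <- setNames(rnorm(n), colnames(lf))
    # plant a gene tracking the phenotype at population Spearman ~ 0.9
    lf["g1", ] <- scale(y)[, 1] + rnorm(n, 0, 0.4)
    res <- batch_permutation_cutoff(lf, y, batch, n_permutations = 500,
                                    seed = s)
    res$passed[["g1"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("zero permutations are refused", {
  lf <- matrix(rnorm(50), 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("e", 1:5)))
  batch <- setNames(rep("A", 5), colnames(lf))
  y <- setNames(rnorm(5), colnames(lf))
  expect_error(batch_permutation_cutoff(lf, y, batch, n_permutations = 0),
               ">= 1")
})

test_that("phenotype driver restricts to G1-increased experiments", {
  d <- default_sim()
  ph <- generate_phenotypes(d$sim$sheet, d$sim$truth, seed = 1)
  cfg <- analysis_config(n_permutations = 200L)
  corr <- correlate_phenotypes(d$de, ph, cfg, seed = 1)
  agg <- rnaicompendium:::phenotype_deltas(ph)
  expect_setequal(corr$experiments_used,
                  agg$experiment_id[agg$delta_g1 > 0])
  expect_true(all(corr$results$phenotype %in%
                    c("g1_frac", "g2_frac", "g1_size", "g2_size")))
  expect_true(all(corr$results$rho >= -1 & corr$results$rho <= 1,
                  na.rm = TRUE))
  expect_true(all(corr$results$empirical_p > 0 &
                    corr$results$empirical_p <= 1))
})

test_that("uncoupling metrics flag planted uncoupled experiments only", {
  d <- default_sim()
  ph <- generate_phenotypes(d$sim$sheet, d$sim$truth, seed = 1)
  sets_o <- significant_sets(d$de, 0.3, 0.01)
  shortlist <- shortlist_genes(significant_sets(d$de, 0.5, 0.01), 5)
  unc <- uncoupling_metrics(d$de, sets_o, ph, shortlist)
  flagged <- unc$records$experiment_id[unc$records$uncoupled_flag]
  expect_setequal(flagged, d$sim$truth$uncoupled_experiments)
  expect_true(all(unc$records$total_effect >= 0))
  expect_error(uncoupling_metrics(d$de, sets_o, ph, character(0)),
               "empty shortlist")
})

test_that("a control-like profile has zero total effect", {
  experiments <- data.frame(experiment_id = "e1", batch = "A",
                            target_gene = "g1", n_treated = 1,
                            stringsAsFactors = FALSE)
  de <- fake_de_table(data.frame(
    experiment_id = "e1", gene = paste0("g", 1:5), logfc = 0,
    t = 0, p = 1, adj_p = 1, stringsAsFactors = FALSE), experiments)
  pheno <- data.frame(
    sample_id = c("c1", "t1"), experiment_id = c(NA, "e1"),
    batch = "A", g1_frac = c(0.5, 0.6), s_frac = 0.25,
    g2_frac = c(0.25, 0.15), g1_size = 100, g2_size = 130,
    is_control = c(TRUE, FALSE))
  unc <- uncoupling_metrics(de, list(e1 = sset(character(0))), pheno,
                            paste0("g", 1:5))
  expect_equal(unc$records$total_effect, 0)
})

test_that("set sharing fraction matches hand values", {
  a <- sset(paste0("g", 1:50))
  b <- sset(paste0("g", 19:100))
  expect_equal(set_sharing_fraction(a, b), 32 / 50)  # g19..g50 shared
  expect_equal(set_sharing_fraction(sset(paste0("g", 1:5)),
                                    sset(paste0("g", 1:9))), 1.0)
  expect_equal(set_sharing_fraction(sset("g1"), sset("g2")), 0.0)
  expect_error(set_sharing_fraction(sset(character(0)), sset("g1")), "empty")
})
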