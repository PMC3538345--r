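test_that("quantile normalization equalizes column distributions", {
  # identical columns are a fixed point
  m <- cbind(a = c(1, 5, 3), b = c(1, 5, 3))
  expect_equal(quantile_normalize(m), m)
  # hand-computed rank means
  m2 <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m2)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  # postcondition: identical sorted vectors across columns
  set.seed(9)
  m3 <- matrix(rnorm(500), 100, 5)
  out3 <- quantile_normalize(m3)
  sorted <- apply(out3, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_warning(quantile_normalize(m3[, 1, drop = FALSE]), "single-column")
})

test_that("batch contrasts match hand computations", {
  sheet <- as_sample_sheet(data.frame(
    sample_id = c(paste0("c", 1:4), "t1", "t2"),
    batch = "A",
    target_gene = c(rep("NONE", 4), "gX", "gX"),
    is_control = c(rep(TRUE, 4), FALSE, FALSE)))
  m <- matrix(c(3, 3, 3, 3, 5, 5), 1,
              dimnames = list("gX", sheet$sample_id))
  bc <- fit_batch_contrasts(m, sheet)
  expect_equal(unname(bc$logfc["gX", "kd_gX"]), 2.0)
  expect_equal(unname(bc$s2["gX", "A"]), 0)
  expect_equal(unname(bc$df["A"]), 4)
  expect_equal(unname(bc$se_scale["kd_gX"]), 1 / 2 + 1 / 4)

  sheet2 <- as_sample_sheet(data.frame(
    sample_id = c("c1", "c2", "t1"), batch = "B",
    target_gene = c("NONE", "NONE", "gX"),
    is_control = c(TRUE, TRUE, FALSE)))
  m2 <- matrix(c(1, 3, 4), 1, dimnames = list("gX", sheet2$sample_id))
  bc2 <- fit_batch_contrasts(m2, sheet2)
  expect_equal(unname(bc2$logfc["gX", "kd_gX"]), 2.0)
  expect_equal(unname(bc2$df["B"]), 1)
  expect_equal(unname(bc2$s2["gX", "B"]), 2)  # controls deviate by +/-1

  # equal treated and control values give logfc 0
  m3 <- matrix(rep(7, 3), 1, dimnames = list("gX", sheet2$sample_id))
  expect_equal(unname(fit_batch_contrasts(m3, sheet2)$logfc["gX", "kd_gX"]), 0)
})

test_that("a batch without residual degrees of freedom is refused", {
  sheet <- as_sample_sheet(data.frame(
    sample_id = c("c1", "t1"), batch = "A",
    target_gene = c("NONE", "gX"), is_control = c(TRUE, FALSE)))
  m <- matrix(c(1, 2), 1, dimnames = list("gX", sheet$sample_id))
  expect_error(fit_batch_contrasts(m, sheet), "residual degrees of freedom")
})

test_that("logfc is invariant to per-gene per-batch offsets", {
  sheet <- tiny_sheet()
  m <- tiny_exprs(sheet)
  bc <- fit_batch_contrasts(m, sheet)
  shifted <- m
  set.seed(21)
  for (b in unique(sheet$batch)) {
    ids <- sheet$sample_id[sheet$batch == b]
    shifted[, ids] <- shifted[, ids] + rnorm(nrow(m), 0, 5)
  }
  bc2 <- fit_batch_contrasts(shifted, sheet)
  expect_equal(bc2$logfc, bc$logfc, tolerance = 1e-12)
})

test_that("variance moderation has the right limits and recovers truth", {
  set.seed(31)
  # homogeneous variances: no excess spread, complete shrinkage (d0 = Inf)
  df <- 4
  s2_flat <- rep(1, 200) * rchisq(200, 1e6) / 1e6
  mv_inf <- moderate_variances(s2_flat, df)
  expect_true(is.infinite(mv_inf$d0))
  expect_equal(unname(stats::sd(mv_inf$s2_post)), 0)

  # d0 = 0: posterior variance equals the sample variance, moderated t
  # equals ordinary t to 1e-10
  s2 <- rchisq(100, df) / df
  lfc <- rnorm(100)
  tp <- moderated_t(lfc, s2, df_total = df, se_scale = 0.75)
  expect_equal(tp$t, lfc / sqrt(s2 * 0.75), tolerance = 1e-10)
  expect_equal(tp$p, 2 * pt(-abs(tp$t), df), tolerance = 1e-10)

  # parameter recovery on the scaled-F model at 5000 genes
  d0 <- 4; s0_sq <- 1; dfr <- 4
  sigma2 <- s0_sq * d0 / rchisq(5000, d0)
  s2_sim <- sigma2 * rchisq(5000, dfr) / dfr
  mv <- moderate_variances(s2_sim, dfr)
  expect_lt(abs(mv$d0 - d0) / d0, 0.25)
  expect_lt(abs(mv$s0_sq - s0_sq) / s0_sq, 0.10)
  # posterior variances lie between prior and sample variance
  lo <- pmin(mv$s0_sq, s2_sim); hi <- pmax(mv$s0_sq, s2_sim)
  expect_true(all(mv$s2_post >= lo - 1e-12 & mv$s2_post <= hi + 1e-12))
})

test_that("moderation agrees with an independent empirical-Bayes fit", {
  set.seed(32)
  d0 <- 6; s0_sq <- 0.5; dfr <- 3
  sigma2 <- s0_sq * d0 / rchisq(4000, d0)
  s2_sim <- sigma2 * rchisq(4000, dfr) / dfr
  mv <- moderate_variances(s2_sim, dfr)
  sq <- limma::squeezeVar(s2_sim, df = dfr)
  expect_lt(abs(mv$d0 - sq$df.prior) / sq$df.prior, 0.1)
  expect_lt(abs(mv$s0_sq - sq$var.prior) / sq$var.prior, 0.05)
  expect_lt(max(abs(mv$s2_post - sq$var.post) / sq$var.post), 0.1)
})

test_that("all-zero variances fall back to a flagged floor", {
  mv <- moderate_variances(rep(0, 100), 4)
  expect_true(mv$fallback)
  expect_true(all(mv$s2_post > 0))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order invariance: permute, adjust, unpermute
  set.seed(41)
  p <- runif(50)
  perm <- sample.int(50)
  expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("significant sets apply strict threshold inequalities", {
  experiments <- data.frame(experiment_id = "e1", batch = "A",
                            target_gene = "g1", n_treated = 1,
                            stringsAsFactors = FALSE)
  de <- fake_de_table(data.frame(
    experiment_id = "e1",
    gene = c("g1", "g2", "g3", "g4"),
    logfc = c(0.31, 0.30, -0.35, 0.40),
    t = 0, p = 0.001,
    adj_p = c(0.005, 0.005, 0.005, 0.01),
    stringsAsFactors = FALSE), experiments)
  sets <- significant_sets(de, 0.3, 0.01)
  expect_equal(sets$e1, c(g1 = 1L, g3 = -1L))  # 0.30 and adj_p 0.01 excluded
})

test_that("self-knockdown rank flags targets in the top down-regulated 1%", {
  d <- default_sim()
  ex <- attr(d$de, "experiments")
  # the minimum-logfc target ranks first
  res1 <- self_knockdown_rank(d$de, ex$experiment_id[1])
  expect_true(res1$flagged)
  expect_lte(res1$percentile, 0.01)
  # at the planted -2 self effect nearly every experiment is flagged
  flags <- vapply(ex$experiment_id,
                  function(e) isTRUE(self_knockdown_rank(d$de, e)$flagged),
                  logical(1))
  expect_gte(mean(flags), 0.95)
})

test_that("absent targets yield NA rather than an error", {
  experiments <- data.frame(experiment_id = "e1", batch = "A",
                            target_gene = "missing_gene", n_treated = 1,
                            stringsAsFactors = FALSE)
  de <- fake_de_table(data.frame(
    experiment_id = "e1", gene = c("g1", "g2"), logfc = c(-1, 1),
    t = 0, p = 0.5, adj_p = 0.5, stringsAsFactors = FALSE), experiments)
  res <- self_knockdown_rank(de, "e1")
  expect_true(is.na(res$rank))
  expect_true(is.na(res$flagged))
})

test_that("the shortlist rule is inclusive at the experiment count", {
  sets <- c(
    lapply(1:5, function(i) sset(c("gA", "gB"))),
    lapply(1:4, function(i) sset("gC")))
  names(sets) <- paste0("e", 1:9)
  out <- shortlist_genes(sets, 5)
  expect_setequal(out, c("gA", "gB"))  # gC seen 4 times is excluded
})

test_that("moderated t is calibrated under the global null", {
  # compendium with no planted effects beyond self; self rows are excluded
  # so the remaining (gene, experiment) grid is pure noise
  p <- sim_params(module_effect = 0, n_uncoupled = 0)
  sim <- generate_compendium(seed = 8, params = p)
  de <- run_differential_expression(sim$exprs, sim$sheet, normalize = FALSE)
  null_rows <- !(de$gene %in% sim$truth$experiments$target_gene)
  for (alpha in c(0.05, 0.01)) {
    n <- sum(null_rows)
    hits <- sum(de$p[null_rows] < alpha)
    band <- qbinom(c(0.005, 0.995), n, alpha)
    expect_gte(hits, band[1])
    expect_lte(hits, band[2])
  }
})
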