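test_that("expected overlap is the hypergeometric mean", {
  expect_equal(expected_overlap(5, 4, 20), 1.0)
  expect_equal(expected_overlap(0, 7, 100), 0)
  expect_error(expected_overlap(1, 1, 0), "positive")
  expect_error(expected_overlap(30, 5, 20), "exceed")
  # brute-force sampling oracle
  set.seed(51)
  draws <- replicate(1e5, {
    length(intersect(sample.int(100, 10), sample.int(100, 7)))
  })
  expect_lt(abs(mean(draws) - expected_overlap(10, 7, 100)),
            0.01 * expected_overlap(10, 7, 100))
})

test_that("signed overlap weight hits its endpoints exactly", {
  u <- paste0("g", 1:20)
  a <- sset(u[1:5], 1)
  # identical signed sets: complete overlap, weight exactly 1
  w <- signed_overlap_weight(a, a, u)
  expect_identical(w$weight, 1)
  expect_equal(w$sign, 1L)
  # disjoint sets: observed 0 <= expected, weight exactly 0
  b <- sset(u[6:9], 1)
  w0 <- signed_overlap_weight(a, b, u)
  expect_identical(w0$weight, 0)
})

test_that("signed overlap weight matches the worked normalization example", {
  u <- paste0("g", 1:20)
  a <- sset(u[1:5], 1)
  b <- sset(u[c(1, 2, 3, 10)], 1)  # 3 shared, all same direction
  w <- signed_overlap_weight(a, b, u)
  expect_equal(w$sign, 1L)
  expect_equal(w$observed, 3L)
  expect_equal(w$expected, 1.0)
  expect_equal(w$weight, (3 - 1) / (4 - 1))
})

test_that("signed overlap weight is symmetric and direction-aware", {
  u <- paste0("g", 1:30)
  set.seed(52)
  a <- sset(sample(u, 8), sample(c(1, -1), 8, replace = TRUE))
  b <- sset(sample(u, 6), sample(c(1, -1), 6, replace = TRUE))
  expect_equal(signed_overlap_weight(a, b, u),
               signed_overlap_weight(b, a, u))
  # opposite-direction overlap flips the sign
  a2 <- sset(u[1:4], 1)
  b2 <- sset(u[1:4], -1)
  w <- signed_overlap_weight(a2, b2, u)
  expect_equal(w$sign, -1L)
  expect_equal(w$observed, 4L)
  # equal direction counts resolve to +1 with the tie flag set
  a3 <- sset(u[1:2], c(1, 1))
  b3 <- sset(u[1:2], c(1, -1))
  w3 <- signed_overlap_weight(a3, b3, u)
  expect_equal(w3$sign, 1L)
  expect_true(w3$tie)
})

test_that("weight grows monotonically with observed overlap", {
  u <- paste0("g", 1:40)
  a <- sset(u[1:10], 1)
  weights <- vapply(0:8, function(k) {
    b <- sset(c(u[seq_len(k)], u[30:(38 - k)]), 1)  # size 9, k shared
    signed_overlap_weight(a, b, u)$weight
  }, numeric(1))
  expect_true(all(diff(weights) >= 0))
})

test_that("random sets overlap at the expected rate", {
  set.seed(53)
  u <- paste0("g", 1:50)
  obs <- replicate(1e4, {
    a <- sample(u, 12); b <- sample(u, 9)
    length(intersect(a, b))
  })
  expect_lt(abs(mean(obs) - expected_overlap(12, 9, 50)),
            0.02 * expected_overlap(12, 9, 50))
})

test_that("hypergeometric enrichment agrees with exhaustive enumeration", {
  set.seed(54)
  for (rep in 1:20) {
    n_univ <- sample(10:30, 1)
    u <- paste0("g", seq_len(n_univ))
    a <- sample(u, sample.int(n_univ - 1, 1))
    b <- sample(u, sample.int(n_univ - 1, 1))
    k <- length(intersect(a, b))
    expect_lt(abs(hypergeometric_enrichment(a, b, u) -
                    enum_hyper_tail(k, length(b), n_univ, length(a))),
              1e-12)
  }
  u <- paste0("g", 1:100)
  # overlap at or below expectation is never significant
  a <- u[1:10]; b <- u[10:19]  # 1 shared = expected
  expect_gte(hypergeometric_enrichment(a, b, u), 0.5)
  # annotation equal to the universe is uninformative
  expect_equal(hypergeometric_enrichment(u[1:5], u, u), 1)
  expect_error(hypergeometric_enrichment("g1", "g1", character(0)), "empty")
})

test_that("degree pruning cascades to its fixed point", {
  # star: hub with 6 leaves, each leaf degree 1 -> leaves die, then the hub
  u <- paste0("g", 1:200)
  hub <- sset(u[1:60], 1)
  leaves <- lapply(1:6, function(i) sset(u[((i - 1) * 10 + 1):(i * 10)], 1))
  sets <- c(list(hub = hub), setNames(leaves, paste0("leaf", 1:6)))
  net <- build_network(sets, analysis_config(), universe = u)
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)
  expect_setequal(net$pruning_log, names(sets))
})

test_that("a 6-clique survives pruning at minimum degree 5", {
  u <- paste0("g", 1:100)
  shared <- u[1:30]
  sets <- lapply(1:6, function(i) sset(c(shared, u[30 + i]), 1))
  names(sets) <- paste0("e", 1:6)
  net <- build_network(sets, analysis_config(), universe = u)
  expect_equal(sort(net$nodes$experiment), paste0("e", 1:6))
  expect_true(all(net$nodes$degree == 5L))
})

test_that("pruning reaches the same fixed point from any input order", {
  set.seed(55)
  u <- paste0("g", 1:120)
  sets <- lapply(1:12, function(i)
    sset(sample(u, sample(15:40, 1)), sample(c(1, -1), 1)))
  names(sets) <- paste0("e", 1:12)
  ref <- build_network(sets, analysis_config(min_node_degree = 3),
                       universe = u)
  for (i in 1:5) {
    perm <- sample(names(sets))
    net <- build_network(sets[perm], analysis_config(min_node_degree = 3),
                         universe = u)
    expect_setequal(net$nodes$experiment, ref$nodes$experiment)
    expect_equal(nrow(net$edges), nrow(ref$edges))
  }
})

test_that("planted module groups form components with negative myc/eIF edges", {
  d <- default_sim()
  sets <- significant_sets(d$de, 0.3, 0.01)
  net <- build_network(sets, analysis_config())
  ex <- d$sim$truth$experiments
  cls <- setNames(ex$class, ex$experiment_id)
  # every module experiment is retained, singletons and uncoupled are pruned
  expect_setequal(net$nodes$experiment,
                  ex$experiment_id[!cls[ex$experiment_id] %in%
                                     c("singleton", "uncoupled")])
  e <- net$edges
  myc_eif <- (cls[e$experiment_a] == "ribosome_myc" &
                cls[e$experiment_b] == "ribosome_eif") |
    (cls[e$experiment_a] == "ribosome_eif" &
       cls[e$experiment_b] == "ribosome_myc")
  expect_true(all(e$sign[myc_eif] == -1L))
  expect_gt(sum(myc_eif), 10)
  same_module <- cls[e$experiment_a] == cls[e$experiment_b]
  expect_true(all(e$sign[same_module] == 1L))
})

test_that("percent overlap matrix is directional and selective", {
  u <- paste0("g", 1:300)
  a <- sset(u[1:50], 1)
  b <- sset(u[1:100], 1)        # A fully inside B
  c49 <- sset(u[200:248], 1)    # only 49 genes: excluded
  sets <- list(A = a, B = b, C = c49)
  res <- percent_overlap_clustering(sets, analysis_config())
  expect_setequal(res$experiments, c("A", "B"))
  expect_equal(res$percent_matrix["A", "B"], 1.0)
  expect_equal(res$percent_matrix["B", "A"], 0.5)
  expect_equal(diag(res$percent_matrix), c(A = 1, B = 1))
  expect_s3_class(res$dendrogram, "hclust")
  expect_error(percent_overlap_clustering(list(A = a), analysis_config()),
               "fewer than 2")
})

test_that("TSS-window target calling respects the half-open 2 kb window", {
  tss <- data.frame(gene = c("gA", "gB", "gC"),
                    chrom = c("chr2L", "chr2L", "chrX"),
                    position = c(3000L, 10000L, 500L),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  mk_peaks <- function(starts, ends, p) {
    gr <- GenomicRanges::GRanges("chr2L",
                                 IRanges::IRanges(starts + 1L, ends))
    gr$pvalue <- p
    gr
  }
  cfg <- analysis_config()
  # peak [990, 1010) overlaps gA's window [1000, 5000)
  expect_equal(chip_tss_targets(mk_peaks(990, 1010, 0.001), tss, cfg), "gA")
  # same interval with p = 0.02 fails the significance rule
  expect_equal(chip_tss_targets(mk_peaks(990, 1010, 0.02), tss, cfg),
               character(0))
  # a peak starting exactly at TSS + 2000 abuts the half-open window end
  expect_equal(chip_tss_targets(mk_peaks(5000, 5100, 0.001), tss, cfg),
               character(0))
  expect_equal(chip_tss_targets(mk_peaks(4999, 5100, 0.001), tss, cfg), "gA")
  # chromosome absent from the peak set leaves gC unmatched, silently
  expect_equal(chip_tss_targets(mk_peaks(c(990, 9000), c(1010, 9100),
                                         c(0.001, 0.001)), tss, cfg),
               c("gA", "gB"))
})
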