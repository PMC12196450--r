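two_class_labels <- function(n_a, n_b) {
  new_labels <- parpicompare:::new_phenotype_labels
  new_labels(sprintf("s%03d", seq_len(n_a + n_b)),
             rep(c("A", "B"), c(n_a, n_b)), c("A", "B"))
}

test_that("signal-to-noise matches hand arithmetic with the sd floor", {
  m <- rbind(
    g1 = c(10, 12, 14, 1, 2, 3),
    g2 = c(5, 5, 5, 5, 5, 5))
  colnames(m) <- sprintf("s%03d", 1:6)
  labels <- two_class_labels(3, 3)
  ranked <- rank_by_signal_to_noise(m, labels)
  # g1: mu_A = 12 (sd 2, floored to 0.2*12 = 2.4), mu_B = 2 (sd 1, floor
  # max(0.2*2, 0.2) = 0.4 does not bind) -> (12 - 2) / (2.4 + 1)
  expect_equal(unname(ranked$metric_values[ranked$gene_ids == "g1"]),
               10 / (2.4 + 1), tolerance = 1e-12)
  # g2: identical class means -> 0
  expect_equal(unname(ranked$metric_values[ranked$gene_ids == "g2"]), 0)
  expect_equal(ranked$gene_ids, c("g1", "g2"))
})

test_that("ranking ignores sample order within classes and ties break by id", {
  set.seed(7)
  m <- matrix(rnorm(20 * 12), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%03d", 1:12)))
  labels <- two_class_labels(6, 6)
  r1 <- rank_by_signal_to_noise(m, labels)
  perm <- c(sample(1:6), sample(7:12))
  r2 <- rank_by_signal_to_noise(m[, perm], labels)
  expect_equal(r1, r2)
  # duplicated rows give tied metrics; order must be lexicographic
  m2 <- rbind(m, zz_dup = m["g01", ], aa_dup = m["g01", ])
  r3 <- rank_by_signal_to_noise(m2, labels)
  pos <- match(c("aa_dup", "g01", "zz_dup"), r3$gene_ids)
  expect_equal(pos, sort(pos))
  expect_error(rank_by_signal_to_noise(m, two_class_labels(2, 10)),
               ">= 3 samples")
})

test_that("enrichment score equals the brute-force prefix oracle", {
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(10:200, 1)
    metric <- sort(rnorm(n), decreasing = TRUE)
    names(metric) <- sprintf("g%04d", 1:n)
    n_hit <- sample(seq_len(n - 1), 1)
    set <- sample(names(metric), n_hit)
    p <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(metric, set, weight_p = p)
    expect_equal(es$es, brute_es(metric, names(metric) %in% set, p),
                 tolerance = 1e-12)
    expect_lte(abs(es$es), 1)
  }
})

test_that("unweighted ES on a 10-gene list is the classic KS statistic", {
  metric <- sort(rnorm(10, sd = 2), decreasing = TRUE)
  names(metric) <- paste0("g", 1:10)
  set <- c("g1", "g4", "g9")
  es <- enrichment_score(metric, set, weight_p = 0)
  # direct enumeration: 3 hits weight 1/3, 7 misses weight 1/7
  running <- cumsum(ifelse(names(metric) %in% set, 1 / 3, -1 / 7))
  expect_equal(es$running_sum, running, tolerance = 1e-12)
  expect_equal(es$es, running[which.max(abs(running))])
})

test_that("ES attains 1 when all hits lead, and mirrored input negates it", {
  metric <- c(a = 3, b = 2, c = 1, d = 0.5, e = 0.1)
  expect_equal(enrichment_score(metric, c("a", "b"), weight_p = 0)$es, 1)
  expect_equal(enrichment_score(metric, c("a", "b"), weight_p = 1)$es, 1)
  # mirror: reverse ranks and negate the metric -> ES flips sign
  fwd <- enrichment_score(metric, c("a", "b"))$es
  mirrored <- rev(-metric)
  bwd <- enrichment_score(mirrored, c("a", "b"))$es
  expect_equal(bwd, -fwd, tolerance = 1e-12)
})

test_that("degenerate gene sets are rejected", {
  metric <- c(a = 2, b = 1, c = -1)
  expect_error(enrichment_score(metric, c("a", "b", "c")), "whole ranked list")
  expect_error(enrichment_score(metric, "nope"), "no overlap")
  zero <- c(a = 0, b = 0, c = 0)
  expect_error(enrichment_score(zero, "a", weight_p = 1), "zero")
  expect_silent(enrichment_score(zero, "a", weight_p = 0))
})

test_that("permutation null is seed-reproducible and leaves the RNG alone", {
  set.seed(9)
  m <- matrix(rnorm(100 * 16), 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%03d", 1:16)))
  labels <- two_class_labels(8, 8)
  set <- sprintf("g%03d", 1:10)
  n1 <- permutation_null(m, labels, set, n_perm = 20, seed = 123)
  n2 <- permutation_null(m, labels, set, n_perm = 20, seed = 123)
  expect_identical(n1, n2)
  expect_false(identical(n1, permutation_null(m, labels, set,
                                              n_perm = 20, seed = 124)))
  state <- .Random.seed
  permutation_null(m, labels, set, n_perm = 20, seed = 5)
  expect_identical(state, .Random.seed)
  expect_error(permutation_null(m, labels, set, n_perm = 5), "at least 10")
})

test_that("gene_set permutation null is near-symmetric for a symmetric metric", {
  set.seed(10)
  m <- matrix(rnorm(400 * 20), 400,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("s%03d", 1:20)))
  labels <- two_class_labels(10, 10)
  null <- permutation_null(m, labels, sprintf("g%03d", 1:30), n_perm = 500,
                           permutation_type = "gene_set", seed = 1)
  expect_lt(abs(mean(null)), 0.05)
})

test_that("score_gene_set recovers a planted signal and reports q = p", {
  spec <- cohort_spec(n_samples = 60, n_genes = 400,
                      planted_gene_set_size = 40, enrichment_shift = 1,
                      seed = 21)
  sim <- simulate_expression(spec)
  m <- fractional_rank_normalize(sim$matrix)
  res <- score_gene_set(m, sim$labels, sim$gene_set, n_perm = 199, seed = 3)
  expect_gt(res$es, 0)
  expect_lt(res$fdr_q, 0.05)
  expect_identical(res$fdr_q, res$nominal_p)
  expect_true(all(res$leading_edge %in% sim$gene_set))
  # full-result bit reproducibility under (seed, config)
  res2 <- score_gene_set(m, sim$labels, sim$gene_set, n_perm = 199, seed = 3)
  expect_identical(res[names(res) != "running_sum"],
                   res2[names(res2) != "running_sum"])
  expect_identical(res$running_sum, res2$running_sum)
})

test_that("leading edge sits on the correct side of the extremum", {
  metric <- c(a = 3, b = 2, c = 1, d = -1, e = -2, f = -3)
  pos <- enrichment_score(metric, c("a", "b", "f"))
  res_le <- names(metric)[pos$hit_indices[pos$hit_indices <= pos$extremum_index]]
  expect_true(all(c("a", "b") %in% res_le) || pos$es < 0)
  neg <- enrichment_score(metric, c("e", "f", "a"))
  if (neg$es < 0) {
    le <- neg$hit_indices[neg$hit_indices >= neg$extremum_index]
    expect_true(all(names(metric)[le] %in% c("e", "f", "a")))
  }
})

test_that("null cohorts give unremarkable NES and large q", {
  spec <- cohort_spec(n_samples = 60, n_genes = 300,
                      planted_gene_set_size = 30, enrichment_shift = 0,
                      seed = 77)
  sim <- simulate_expression(spec)
  m <- fractional_rank_normalize(sim$matrix)
  res <- score_gene_set(m, sim$labels, sim$gene_set, n_perm = 199, seed = 5)
  expect_lt(abs(res$nes), 2)
  expect_gt(res$fdr_q, 0.05)
})
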