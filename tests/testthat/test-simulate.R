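test_that("expression simulation is byte-identical under a fixed seed", {
  spec <- cohort_spec(n_samples = 20, n_genes = 100,
                      planted_gene_set_size = 10, seed = 31)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$gene_set, b$gene_set)
  c <- simulate_expression(cohort_spec(n_samples = 20, n_genes = 100,
                                       planted_gene_set_size = 10, seed = 32))
  expect_false(identical(a$matrix, c$matrix))
  expect_error(simulate_expression(
    cohort_spec(n_genes = 5, planted_gene_set_size = 10)), "planted")
})

test_that("the planted shift lands only on planted genes in the positive class", {
  spec <- cohort_spec(n_samples = 200, n_genes = 200,
                      planted_gene_set_size = 50, enrichment_shift = 2,
                      seed = 33)
  sim <- simulate_expression(spec)
  pos <- sim$labels$labels == "pos"
  planted_delta <- rowMeans(sim$matrix[sim$gene_set, pos]) -
    rowMeans(sim$matrix[sim$gene_set, !pos])
  other <- setdiff(rownames(sim$matrix), sim$gene_set)
  other_delta <- rowMeans(sim$matrix[other, pos]) -
    rowMeans(sim$matrix[other, !pos])
  expect_equal(mean(planted_delta), 2, tolerance = 0.15)
  expect_equal(mean(other_delta), 0, tolerance = 0.15)
})

test_that("biomarker association controls label agreement", {
  spec <- cohort_spec(n_samples = 400, n_genes = 10,
                      planted_gene_set_size = 5,
                      biomarker_specs = list(perfect = list(association = 1),
                                             noisy = list(association = 0.5)),
                      seed = 34)
  sim <- simulate_expression(spec)
  bio <- simulate_biomarkers(spec, sim$labels)
  expect_identical(bio$perfect$labels, sim$labels$labels)
  agree <- mean(bio$noisy$labels == sim$labels$labels)
  expect_equal(agree, 0.75, tolerance = 0.08)  # flip prob (1-0.5)/2
})

test_that("segment generator plants exactly the requested scar counts", {
  spec <- cohort_spec(
    n_samples = 6, n_genes = 10, planted_gene_set_size = 5,
    segment_spec = list(hi = list(k_lst = 7, k_tai = 2, k_loh = 3,
                                  fga_target = 0.5),
                        lo = list(k_lst = 0, k_tai = 0, k_loh = 0,
                                  fga_target = NULL)),
    seed = 35)
  profs <- simulate_segments(spec, rep(c("hi", "lo"), 3))
  gt <- attr(profs, "ground_truth")
  sc <- score_profiles(profs)
  expect_equal(sc$lst, gt$k_lst)
  expect_equal(sc$tai, gt$k_tai)
  expect_equal(sc$loh, gt$k_loh)
  expect_equal(sc$hrd, gt$k_lst + gt$k_tai + gt$k_loh)
  hi <- !is.na(gt$fga_target)
  expect_true(all(abs(sc$fga[hi] - gt$fga_target[hi]) <= 0.02))
  # planted zeros score zero everywhere
  expect_true(all(sc$lst[!hi] == 0 & sc$tai[!hi] == 0 & sc$loh[!hi] == 0))
})

test_that("segment generator is reproducible and rejects infeasible plans", {
  spec <- cohort_spec(n_samples = 2, n_genes = 10, planted_gene_set_size = 5,
                      segment_spec = list(c1 = list(k_lst = 4, k_tai = 1,
                                                    k_loh = 1,
                                                    fga_target = 0.3)),
                      seed = 36)
  a <- simulate_segments(spec, c("c1", "c1"))
  b <- simulate_segments(spec, c("c1", "c1"))
  expect_identical(a$S001$segments, b$S001$segments)
  bad <- cohort_spec(n_samples = 2, n_genes = 10, planted_gene_set_size = 5,
                     segment_spec = list(c1 = list(k_lst = 500)), seed = 36)
  expect_error(simulate_segments(bad, c("c1", "c1")), "infeasible")
  bad_fga <- cohort_spec(n_samples = 2, n_genes = 10, planted_gene_set_size = 5,
                         segment_spec = list(c1 = list(k_lst = 30,
                                                       fga_target = 0)),
                         seed = 36)
  expect_error(simulate_segments(bad_fga, c("c1", "c1")), "fga_target")
})

test_that("drug modules respect size, overlap and union arithmetic", {
  universe <- sprintf("g%04d", 1:1000)
  planted <- universe[1:100]
  mods <- simulate_drug_modules(planted, universe, n_modules = 22,
                                module_size_range = c(10, 10),
                                overlap_with_planted = 1, seed = 37)
  expect_length(mods, 22)
  expect_true(all(vapply(mods, function(m) all(m %in% planted), logical(1))))
  mods2 <- simulate_drug_modules(planted, universe, n_modules = 10,
                                 module_size_range = c(20, 50),
                                 overlap_with_planted = 0.5, seed = 38)
  overlaps <- vapply(mods2, function(m) mean(m %in% planted), numeric(1))
  expect_true(all(abs(overlaps - 0.5) < 0.05))
  expect_equal(length(unique(unlist(mods2))),
               length(Reduce(union, mods2)))
  expect_identical(simulate_drug_modules(planted, universe, seed = 39),
                   simulate_drug_modules(planted, universe, seed = 39))
})
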