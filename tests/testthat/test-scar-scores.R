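# One segment per arm, neutral state everywhere: the "flat genome".
flat_profile <- function(build = toy_build(), id = "flat",
                         major = 1, minor = 1, log2 = 0) {
  seg <- do.call(rbind, lapply(seq_len(nrow(build$arms)), function(i) {
    seg_row(build$arms$chrom[i], build$arms$start[i], build$arms$end[i],
            log2, major, minor)
  }))
  segment_profile(id, seg, build)
}

test_that("a flat genome has zero LST and an empty profile errors", {
  expect_equal(compute_lst(flat_profile()), 0)
  empty <- toy_profile(seg_row("chrA", 1, 1, 0)[0, ])
  expect_error(compute_lst(empty), "empty profile")
})

test_that("LST counts exactly the qualifying planted breakpoints", {
  # chrA p arm (1..100 Mb): four alternating 25 Mb segments -> 3 breakpoints
  p <- toy_profile(rbind(
    seg_row("chrA", 1, 25e6, 0, 1, 1),
    seg_row("chrA", 25e6 + 1, 50e6, 1, 2, 2),
    seg_row("chrA", 50e6 + 1, 75e6, 0, 1, 1),
    seg_row("chrA", 75e6 + 1, 100e6, 1, 2, 2)))
  expect_equal(compute_lst(p), 3)
})

test_that("a breakpoint with an 8 Mb flank does not count as an LST", {
  p <- toy_profile(rbind(
    seg_row("chrA", 1, 8e6, 1, 2, 2),
    seg_row("chrA", 8e6 + 1, 40e6, 0, 1, 1),
    seg_row("chrA", 40e6 + 1, 100e6, 1, 2, 2)))
  expect_equal(compute_lst(p), 1)  # only the 32 Mb | 60 Mb boundary
})

test_that("a state change at the centromere gap is never an LST", {
  p <- toy_profile(rbind(
    seg_row("chrA", 1, 100e6, 0, 1, 1),        # whole p arm
    seg_row("chrA", 105e6 + 1, 200e6, 1, 2, 2) # whole q arm
  ))
  expect_equal(compute_lst(p), 0)
})

test_that("LST is invariant under re-sorting and equal-state splitting", {
  seg <- rbind(
    seg_row("chrA", 1, 30e6, 0, 1, 1),
    seg_row("chrA", 30e6 + 1, 100e6, 1, 2, 2),
    seg_row("chrB", 1, 70e6, 0, 1, 1))
  base <- compute_lst(toy_profile(seg))
  expect_equal(base, 1)
  shuffled <- toy_profile(seg[c(3, 1, 2), ])
  expect_equal(compute_lst(shuffled), base)
  # split the 70 Mb segment into two adjacent equal-state pieces: the
  # sub-threshold piece is re-merged by smoothing, and an above-threshold
  # split introduces no state change either way
  split1 <- rbind(seg[1, ],
                  seg_row("chrA", 30e6 + 1, 32e6, 1, 2, 2),
                  seg_row("chrA", 32e6 + 1, 100e6, 1, 2, 2),
                  seg[3, ])
  expect_equal(compute_lst(toy_profile(split1)), base)
  split2 <- rbind(seg[1, ],
                  seg_row("chrA", 30e6 + 1, 60e6, 1, 2, 2),
                  seg_row("chrA", 60e6 + 1, 100e6, 1, 2, 2),
                  seg[3, ])
  expect_equal(compute_lst(toy_profile(split2)), base)
})

test_that("TAI counts telomere-bounded imbalance that avoids the centromere", {
  expect_equal(compute_tai(flat_profile()), 0)  # fully balanced
  # imbalance from the p terminus to mid-p-arm (50 Mb >= 11 Mb) -> 1
  p <- toy_profile(rbind(
    seg_row("chrA", 1, 50e6, 0.3, 2, 1),
    seg_row("chrA", 50e6 + 1, 100e6, 0, 1, 1),
    seg_row("chrA", 105e6 + 1, 200e6, 0, 1, 1)))
  expect_equal(compute_tai(p), 1)
  # same region but crossing the centromere contributes nothing
  q <- toy_profile(rbind(
    seg_row("chrA", 1, 150e6, 0.3, 2, 1),
    seg_row("chrA", 150e6 + 1, 200e6, 0, 1, 1)))
  expect_equal(compute_tai(q), 0)
  # interstitial imbalance (no telomere) contributes nothing
  r <- toy_profile(rbind(
    seg_row("chrA", 1, 20e6, 0, 1, 1),
    seg_row("chrA", 20e6 + 1, 60e6, 0.3, 2, 1),
    seg_row("chrA", 60e6 + 1, 100e6, 0, 1, 1)))
  expect_equal(compute_tai(r), 0)
  # sub-threshold telomeric imbalance (10 Mb < 11 Mb) contributes nothing
  s <- toy_profile(rbind(
    seg_row("chrA", 1, 10e6, 0.3, 2, 1),
    seg_row("chrA", 10e6 + 1, 100e6, 0, 1, 1)))
  expect_equal(compute_tai(s), 0)
})

test_that("TAI and LOH demand allele-specific copy number", {
  p <- toy_profile(seg_row("chrA", 1, 100e6, 0))
  expect_error(compute_tai(p), "allele-specific data required")
  expect_error(compute_loh(p), "allele-specific data required")
})

test_that("LOH counts long interstitial minor-allele-zero regions only", {
  expect_equal(compute_loh(flat_profile()), 0)  # heterozygous genome
  # 20 Mb interstitial copy-neutral LOH -> 1
  p <- toy_profile(rbind(
    seg_row("chrA", 1, 30e6, 0, 1, 1),
    seg_row("chrA", 30e6 + 1, 50e6, 0, 2, 0),
    seg_row("chrA", 50e6 + 1, 100e6, 0, 1, 1)))
  expect_equal(compute_loh(p), 1)
  # whole-chromosome LOH contributes nothing from that chromosome
  q <- toy_profile(rbind(
    seg_row("chrA", 1, 200e6, 0, 1, 0),
    seg_row("chrB", 1, 30e6, 0, 1, 1),
    seg_row("chrB", 30e6 + 1, 50e6, 0, 2, 0),
    seg_row("chrB", 50e6 + 1, 150e6, 0, 1, 1)))
  expect_equal(compute_loh(q), 1)
  # a 15 Mb region is not strictly longer than the 15 Mb cutoff
  r <- toy_profile(rbind(
    seg_row("chrA", 1, 30e6, 0, 1, 1),
    seg_row("chrA", 30e6 + 1, 45e6, 0, 2, 0),
    seg_row("chrA", 45e6 + 1, 100e6, 0, 1, 1)))
  expect_equal(compute_loh(r), 0)
})

test_that("HRD is the exact sum of LST, TAI and LOH and fails when one is missing", {
  expect_equal(compute_hrd(list(lst = 0, tai = 0, loh = 0)), 0)
  expect_equal(compute_hrd(list(lst = 5, tai = 3, loh = 2)), 10)
  expect_error(compute_hrd(list(lst = 5, tai = NA, loh = 2)),
               "could not be generated")
  expect_error(compute_hrd(list(lst = 5, loh = 2)), "tai")
})

test_that("FGA is the altered length fraction and splitting-invariant", {
  expect_equal(compute_fga(flat_profile()), 0)
  expect_equal(compute_fga(flat_profile(log2 = 0.5)), 1)
  # exactly half the assayed base pairs altered
  p <- toy_profile(rbind(
    seg_row("chrA", 1, 50e6, 0.5),
    seg_row("chrA", 50e6 + 1, 100e6, 0.1)))
  expect_equal(compute_fga(p), 0.5)
  # boundary: |log2| equal to the threshold is not altered
  expect_equal(compute_fga(toy_profile(seg_row("chrA", 1, 10e6, 0.2))), 0)
  # splitting a segment leaves FGA unchanged
  q <- toy_profile(rbind(
    seg_row("chrA", 1, 25e6, 0.5),
    seg_row("chrA", 25e6 + 1, 50e6, 0.5),
    seg_row("chrA", 50e6 + 1, 100e6, 0.1)))
  expect_equal(compute_fga(q), compute_fga(p))
  empty <- toy_profile(seg_row("chrA", 1, 1, 0)[0, ])
  expect_error(compute_fga(empty), "zero assayed length")
})

test_that("aneuploidy counts arms majority-altered in one direction", {
  b <- hg19_build()
  flat <- flat_profile(b)
  expect_equal(compute_aneuploidy(flat), 0)
  # one whole-arm gain at log2 = 0.5 -> 1
  seg <- flat$segments
  i <- which(seg$chrom == "chr1" & seg$start == 1)
  seg$log2_ratio[i] <- 0.5
  expect_equal(compute_aneuploidy(segment_profile("g1", seg, b)), 1)
  # all arms lost -> the full 39-arm autosomal count
  expect_equal(compute_aneuploidy(flat_profile(b, log2 = -0.5)), 39)
  # 40% gained + 40% lost + 20% neutral: no direction reaches the
  # majority fraction, so no arm-level call
  arm1p <- b$arms[b$arms$chrom == "chr1" & b$arms$arm == "p", ]
  c1 <- arm1p$start + round(0.4 * arm1p$length)
  c2 <- arm1p$start + round(0.8 * arm1p$length)
  p <- segment_profile("mix", rbind(
    seg_row("chr1", arm1p$start, c1, 0.5),
    seg_row("chr1", c1 + 1, c2, -0.5),
    seg_row("chr1", c2 + 1, arm1p$end, 0)), b)
  expect_equal(compute_aneuploidy(p), 0)
})

test_that("score_profiles aggregates all scores and NA without allele data", {
  with_as <- flat_profile(id = "a")
  no_as <- toy_profile(rbind(seg_row("chrA", 1, 100e6, 0.5),
                             seg_row("chrB", 1, 150e6, 0)), id = "b")
  tab <- score_profiles(list(with_as, no_as))
  expect_equal(tab$sample_id, c("a", "b"))
  expect_equal(tab$hrd[1], 0)
  expect_true(is.na(tab$tai[2]) && is.na(tab$hrd[2]))
  expect_equal(tab$fga[2], 100e6 / 250e6)
})

test_that("dichotomize_score labels and flags degenerate splits", {
  ph <- dichotomize_score(c(a = 1, b = 20, c = 14, d = 15), threshold = 15)
  expect_equal(ph$labels, c("low", "high", "low", "high"))
  expect_equal(unname(ph$n_per_class), c(2, 2))
  expect_warning(
    deg <- dichotomize_score(c(a = 1, b = 2), threshold = 15),
    "degenerate")
  expect_true(deg$degenerate)
})

test_that("median split of 100 distinct values yields 50/50 with ties low", {
  set.seed(11)
  v <- stats::setNames(sample(1000, 100), paste0("s", 1:100))
  ph <- median_split(v)
  expect_equal(unname(ph$n_per_class), c(50, 50))
  # explicit tie at the median goes to "low"
  ph2 <- median_split(c(a = 1, b = 2, c = 2, d = 9))
  expect_equal(ph2$labels, c("low", "low", "low", "high"))
})
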