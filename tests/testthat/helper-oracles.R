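# Shared fixtures and independent oracles, built in code at test time.

# Small synthetic two-chromosome build for hand-walk tests: generous arms
# so 10-20 Mb segments fit comfortably.
toy_build <- function() {
  genome_build("toy", data.frame(
    chrom = c("chrA", "chrB"),
    length = c(200e6, 150e6),
    cen_start = c(100e6, 70e6),
    cen_end = c(105e6, 75e6)))
}

# Quick profile constructor: seg is a data.frame (chrom, start, end,
# log2_ratio[, major_cn, minor_cn]).
toy_profile <- function(seg, build = toy_build(), id = "T1") {
  segment_profile(id, seg, build)
}

seg_row <- function(chrom, start, end, log2, major = NA, minor = NA) {
  data.frame(chrom = chrom, start = start, end = end, log2_ratio = log2,
             major_cn = major, minor_cn = minor)
}

# Independent brute-force enrichment score: explicit loop over every
# prefix of the ranked list, recomputing P_hit and P_miss from scratch.
# Ties in magnitude between the extreme positive and negative deviations
# resolve to the positive one, with a small relative tolerance (the same
# convention the package documents).
brute_es <- function(metric, hit, weight_p = 1) {
  n <- length(metric)
  n_hit <- sum(hit)
  w <- abs(metric)^weight_p
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  hi <- -Inf; lo <- Inf
  for (i in seq_len(n)) {
    p_hit <- sum(w[seq_len(i)][hit[seq_len(i)]]) / sum(w)
    p_miss <- sum(!hit[seq_len(i)]) / (n - n_hit)
    dev <- p_hit - p_miss
    hi <- max(hi, dev); lo <- min(lo, dev)
  }
  tol <- 1e-9 * max(abs(hi), abs(lo), 1e-300)
  if (hi >= -lo - tol) hi else lo
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments.
brute_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  mu <- sum(ranks) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% ranks
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
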