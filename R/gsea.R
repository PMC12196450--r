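#' Rank genes by the signal-to-noise metric
#'
#' Orders all measured genes by the signal-to-noise ratio between the two
#' phenotype classes: `s2n = (mu_A - mu_B) / (sd_A + sd_B)`, where each
#' class standard deviation is floored at `max(0.2 * |mu|, 0.2)` so that
#' near-constant genes cannot dominate the ranking. Class A is the first
#' (positive) class of the phenotype. Ties in the metric are broken
#' lexicographically by gene id so that rankings, and everything
#' downstream of them, are deterministic.
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @param labels A `phenotype_labels` object covering (a subset of) the
#'   matrix columns.
#' @return A `ranked_list`: list with `gene_ids` (ordered, metric
#'   descending) and `metric_values`.
#' @export
rank_by_signal_to_noise <- function(matrix, labels) {
  check_expression_matrix(matrix)
  stopifnot(inherits(labels, "phenotype_labels"))
  missing_samples <- setdiff(labels$sample_ids, colnames(matrix))
  if (length(missing_samples)) {
    stop("samples in phenotype but not in matrix: ",
         paste(utils::head(missing_samples, 3L), collapse = ", "))
  }
  m <- matrix[, labels$sample_ids, drop = FALSE]
  is_a <- labels$labels == labels$classes[1L]
  if (sum(is_a) < 3L || sum(!is_a) < 3L) {
    stop("signal-to-noise needs >= 3 samples per class; ",
         "use gene_set permutation with a correlation metric for smaller classes")
  }
  metric <- s2n_metric(m, is_a)
  ord <- order(-metric, rownames(m))
  structure(list(gene_ids = rownames(m)[ord], metric_values = metric[ord]),
            class = "ranked_list")
}

# Vectorized signal-to-noise over the rows of m for a class-A indicator.
s2n_metric <- function(m, is_a) {
  a <- m[, is_a, drop = FALSE]; b <- m[, !is_a, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  sd_a <- sqrt(rowSums((a - mu_a)^2) / (na - 1))
  sd_b <- sqrt(rowSums((b - mu_b)^2) / (nb - 1))
  sd_a <- pmax(sd_a, 0.2 * abs(mu_a), 0.2)
  sd_b <- pmax(sd_b, 0.2 * abs(mu_b), 0.2)
  (mu_a - mu_b) / (sd_a + sd_b)
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> %d genes; metric range [%.3f, %.3f]\n",
              length(x$gene_ids), min(x$metric_values), max(x$metric_values)))
  invisible(x)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list accumulating a hit increment
#' `|metric|^weight_p / sum(|metric|^weight_p over hits)` at gene-set
#' members and a miss decrement `1 / (N - N_hit)` elsewhere; the
#' enrichment score (ES) is the signed maximum deviation of the running
#' sum from zero. With `weight_p = 0` this is the classic
#' Kolmogorov-Smirnov statistic; `weight_p = 1` is the conventional
#' weighted form. When the maximal positive and negative deviations tie
#' exactly in magnitude the positive one is reported (a deterministic
#' tie-break, applied with a small relative tolerance so floating-point
#' noise cannot flip it).
#'
#' @param ranked A `ranked_list` (see [rank_by_signal_to_noise()]) or a
#'   named numeric vector of metric values sorted in decreasing order.
#' @param gene_set Character vector of member genes.
#' @param weight_p Exponent on |metric| for hit weights (default 1).
#' @return List with `es`, `running_sum` (length N), `hit_indices` and
#'   `extremum_index` (position of the signed maximum deviation).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  if (inherits(ranked, "ranked_list")) {
    genes <- ranked$gene_ids; metric <- ranked$metric_values
  } else {
    genes <- names(ranked); metric <- as.numeric(ranked)
    if (is.null(genes)) stop("ranked vector must be named by gene id")
  }
  n <- length(genes)
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no overlap with the ranked list")
  if (n_hit == n) stop("gene set covers the whole ranked list (no misses)")
  w <- abs(metric[hit])^weight_p
  if (sum(w) == 0) {
    if (weight_p > 0) stop("all hit metric values are zero: weighted ES undefined")
    w <- rep(1, n_hit)
  }
  incr <- numeric(n)
  incr[hit] <- w / sum(w)
  incr[!hit] <- -1 / (n - n_hit)
  running <- cumsum(incr)
  ext <- signed_extremum(running)
  list(es = ext$value, running_sum = running,
       hit_indices = which(hit), extremum_index = ext$index)
}

# Signed maximum deviation of a running sum. When the maximal positive and
# maximal negative deviations tie in magnitude (possible with rational
# increments, e.g. the unweighted statistic), the positive one is taken;
# the comparison carries a small relative tolerance so that accumulated
# floating-point noise cannot flip the tie-break.
signed_extremum <- function(running) {
  hi <- max(running); lo <- min(running)
  tol <- 1e-9 * max(abs(hi), abs(lo), 1e-300)
  if (hi >= -lo - tol) {
    list(value = hi, index = which.max(running))
  } else {
    list(value = lo, index = which.min(running))
  }
}

#' Permutation null distribution of the enrichment score
#'
#' Phenotype permutation shuffles the class labels over samples (no
#' strata) and recomputes the signal-to-noise ranking and ES for each
#' shuffle, preserving gene-gene correlation. Gene-set permutation keeps
#' the observed ranking and scores random member sets of equal size.
#' Reproducible for a given seed; the caller's RNG state is untouched.
#'
#' @inheritParams rank_by_signal_to_noise
#' @param gene_set Character vector of member genes.
#' @param n_perm Number of permutations (>= 10).
#' @param permutation_type `"phenotype"` or `"gene_set"`.
#' @param seed Integer seed.
#' @param weight_p Passed to [enrichment_score()].
#' @return Numeric vector of `n_perm` null ES values.
#' @export
permutation_null <- function(matrix, labels, gene_set, n_perm = 1000,
                             permutation_type = c("phenotype", "gene_set"),
                             seed = 1L, weight_p = 1) {
  permutation_type <- match.arg(permutation_type)
  if (n_perm < 10L) stop("n_perm must be at least 10")
  with_seed(seed, {
    if (permutation_type == "phenotype") {
      if (labels$degenerate) stop("degenerate phenotype cannot be permuted")
      m <- matrix[order(rownames(matrix)), labels$sample_ids, drop = FALSE]
      genes <- rownames(m)
      is_a <- labels$labels == labels$classes[1L]
      in_set <- genes %in% gene_set
      if (!any(in_set)) stop("gene set has no overlap with the matrix genes")
      vapply(seq_len(n_perm), function(i) {
        perm <- sample(is_a)
        metric <- s2n_metric(m, perm)
        ord <- order(-metric)  # rows pre-sorted by id: stable ties = lexicographic
        null_es(metric[ord], in_set[ord], weight_p)
      }, numeric(1L))
    } else {
      ranked <- rank_by_signal_to_noise(matrix, labels)
      n_hit <- sum(ranked$gene_ids %in% gene_set)
      if (n_hit == 0L) stop("gene set has no overlap with the ranked list")
      n <- length(ranked$gene_ids)
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, n_hit)
        hit <- logical(n); hit[idx] <- TRUE
        null_es(ranked$metric_values, hit, weight_p)
      }, numeric(1L))
    }
  })
}

# ES from a pre-ordered metric and hit indicator (fast path for permutations).
null_es <- function(metric, hit, weight_p) {
  n <- length(metric); n_hit <- sum(hit)
  w <- abs(metric[hit])^weight_p
  if (sum(w) == 0) w <- rep(1, n_hit)
  incr <- numeric(n)
  incr[hit] <- w / sum(w)
  incr[!hit] <- -1 / (n - n_hit)
  signed_extremum(cumsum(incr))$value
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Score one gene set against one phenotype (full GSEA)
#'
#' Runs the complete enrichment analysis for a single gene set: observed
#' signal-to-noise ranking and ES, a permutation null, the nominal p value
#' (fraction of same-sign null ES at least as extreme, with an add-one
#' correction so p is never exactly zero), the normalized enrichment score
#' (`nes = es / mean(|same-sign null ES|)`), and the leading-edge genes
#' (gene-set hits at or before the running-sum extremum for positive ES;
#' at or after it for negative ES). With a single gene set per run the FDR
#' q value equals the nominal p value.
#'
#' @inheritParams permutation_null
#' @return A `gsea_result`: list with `es`, `nes`, `nominal_p`, `fdr_q`,
#'   `leading_edge`, `gene_set_size` (members in the ranked list),
#'   `n_permutations`, `permutation_type`, `seed` and the observed
#'   `running_sum`.
#' @export
score_gene_set <- function(matrix, labels, gene_set, n_perm = 1000,
                           permutation_type = c("phenotype", "gene_set"),
                           seed = 1L, weight_p = 1) {
  permutation_type <- match.arg(permutation_type)
  ranked <- rank_by_signal_to_noise(matrix, labels)
  obs <- enrichment_score(ranked, gene_set, weight_p = weight_p)
  null <- permutation_null(matrix, labels, gene_set, n_perm = n_perm,
                           permutation_type = permutation_type,
                           seed = seed, weight_p = weight_p)
  es <- obs$es
  same_sign <- if (es >= 0) null[null >= 0] else null[null < 0]
  n_same <- length(same_sign)
  if (n_same > 0L) {
    r <- sum(abs(same_sign) >= abs(es))
    nominal_p <- (r + 1) / (n_same + 1)
    nes <- if (mean(abs(same_sign)) > 0) es / mean(abs(same_sign)) else NA_real_
  } else {
    nominal_p <- 1 / (n_perm + 1)
    nes <- NA_real_
  }
  hits <- obs$hit_indices
  le_idx <- if (es >= 0) hits[hits <= obs$extremum_index] else hits[hits >= obs$extremum_index]
  structure(list(
    es = es, nes = nes, nominal_p = nominal_p, fdr_q = nominal_p,
    leading_edge = ranked$gene_ids[le_idx],
    gene_set_size = length(obs$hit_indices),
    n_permutations = n_perm, permutation_type = permutation_type,
    seed = seed, running_sum = obs$running_sum,
    extremum_index = obs$extremum_index
  ), class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "<gsea_result> size %d: ES %.3f, NES %.3f, p %s, q %s (%d %s permutations)\n",
    x$gene_set_size, x$es, x$nes, format_pvalue(x$nominal_p, x$n_permutations),
    format_pvalue(x$fdr_q, x$n_permutations), x$n_permutations,
    x$permutation_type))
  cat(sprintf("  leading edge: %d genes\n", length(x$leading_edge)))
  invisible(x)
}

#' Format a permutation p value for reporting
#'
#' Values below the permutation resolution `1 / (n_perm + 1)` print as
#' `"<0.001"` (at 1000 permutations), matching conventional GSEA tables.
#'
#' @param p Numeric p value.
#' @param n_perm Number of permutations behind it.
#' @return Character scalar.
#' @export
format_pvalue <- function(p, n_perm = 1000) {
  floor_p <- 1 / (n_perm + 1)
  if (p <= floor_p) sprintf("<%.3g", ceiling(floor_p * 1000) / 1000)
  else sprintf("%.3f", p)
}

#' Minimal running-sum enrichment plot
#'
#' Base-graphics plot of the running enrichment score with hit positions
#' marked; plumbing for quick inspection, not a publication figure.
#'
#' @param result A `gsea_result`.
#' @param main Plot title.
#' @export
plot_running_sum <- function(result, main = "Running enrichment score") {
  stopifnot(inherits(result, "gsea_result"))
  n <- length(result$running_sum)
  plot(seq_len(n), result$running_sum, type = "l", xlab = "Rank",
       ylab = "Running ES", main = main)
  graphics::abline(h = 0, lty = 2)
  graphics::abline(v = result$extremum_index, col = "red", lty = 3)
  invisible(result)
}
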