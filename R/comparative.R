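#' Fisher z-transformation
#'
#' `atanh(es)`: maps a correlation-like statistic in (-1, 1) onto the real
#' line, where differences between independent values are approximately
#' normal. The enrichment score is treated as a correlation-like effect
#' size for this purpose.
#'
#' @param es Numeric in (-1, 1).
#' @return `atanh(es)`.
#' @export
#' @examples
#' fisher_z(0.591)  # 0.6792
fisher_z <- function(es) {
  if (any(!is.finite(es)) || any(abs(es) >= 1)) {
    stop("Fisher z requires |es| < 1")
  }
  atanh(es)
}

#' Differential enrichment-score test
#'
#' Tests whether two enrichment scores, obtained from independent sample
#' subsets of sizes `n1` and `n2`, differ: the difference of their Fisher
#' z-transforms is referred to a standard normal with standard error
#' `sqrt(1/(n1-3) + 1/(n2-3))` — the classical difference-of-correlations
#' test applied to ES values.
#'
#' @param es1,es2 Enrichment scores in (-1, 1).
#' @param n1,n2 Sample sizes behind each score (> 3).
#' @return List with `z` and two-sided `raw_p`.
#' @export
#' @examples
#' differential_es_test(0.419, 281, 0.536, 348)$z  # about -1.89
differential_es_test <- function(es1, n1, es2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (fisher_z(es1) - fisher_z(es2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, raw_p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p values
#' (wrapper over [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment fraction (GSEF)
#'
#' The fraction of a drug gene module's members found in a biomarker's
#' enriched-gene list: `|module intersect enriched| / |module|`.
#'
#' @param module Character vector of module genes (non-empty).
#' @param enriched_genes Character vector of enriched genes.
#' @return Fraction in `[0, 1]`.
#' @export
gsef_fraction <- function(module, enriched_genes) {
  if (length(module) == 0L) stop("empty gene module")
  module <- unique(module)
  mean(module %in% enriched_genes)
}

# Exact two-sided signed-rank p value for observed statistic W (sum of
# ranks of positive differences) given the rank magnitudes, via a
# dynamic-programming convolution over doubled ranks (integers even with
# average ranks from ties). Enumerates all 2^n sign assignments implicitly.
signed_rank_exact_p <- function(w_obs, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # distribution of 2W over subsets of ranks
  f <- numeric(total + 1L)  # f[s + 1] = count of subsets with doubled-sum s
  f[1L] <- 1
  for (r in r2) {
    f[(r + 1L):(total + 1L)] <- f[(r + 1L):(total + 1L)] + f[1:(total + 1L - r)]
  }
  probs <- f / sum(f)
  w2 <- round(2 * w_obs)
  mu2 <- total / 2  # E[2W]
  dev <- abs(w2 - mu2)
  support <- 0:total
  p <- sum(probs[abs(support - mu2) >= dev - 1e-9])
  min(1, p)
}

# Normal-approximation two-sided p with continuity and tie correction.
signed_rank_approx_p <- function(w_obs, ranks) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  # variance with tie correction: sum(r^2)/4 equals the usual formula
  # n(n+1)(2n+1)/24 when ranks are untied
  sigma <- sqrt(sum(ranks^2) / 4)
  z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sigma
  2 * stats::pnorm(-abs(z))
}

#' Wilcoxon signed-rank test on paired values
#'
#' Paired two-sided signed-rank test with zero differences dropped
#' (Wilcoxon's original rule) and average ranks for tied absolute
#' differences. For `n <= exact_limit` non-zero pairs the p value is
#' exact, from the full permutation distribution of the rank sum
#' (computed by convolution, valid under ties); above the limit a normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_limit Largest n for the exact path (default 25).
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return List with `statistic` (W, rank sum of positive differences),
#'   `p_value`, `n_used` (non-zero pairs), `method` and `degenerate`
#'   (TRUE when all differences are zero, in which case no test is run
#'   and `p_value` is 1).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25,
                                 method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                method = "none", degenerate = TRUE))
  }
  ranks <- rank(abs(d), ties.method = "average")
  w <- sum(ranks[d > 0])
  use_exact <- switch(method, auto = n <= exact_limit,
                      exact = TRUE, approx = FALSE)
  p <- if (use_exact) signed_rank_exact_p(w, ranks) else signed_rank_approx_p(w, ranks)
  list(statistic = w, p_value = p, n_used = n,
       method = if (use_exact) "exact" else "approx", degenerate = FALSE)
}

#' Compare gene-set enrichment fractions between two biomarkers
#'
#' For every drug gene module, computes the GSEF against the reference
#' biomarker's enriched-gene list and against another biomarker's list,
#' then tests the paired per-module fractions with the Wilcoxon
#' signed-rank test. When all paired differences are zero the comparison
#' is flagged degenerate (reported non-significant) rather than erroring.
#'
#' @param modules Named list of gene modules (character vectors).
#' @param enriched_ref Enriched-gene list of the reference biomarker.
#' @param enriched_other Enriched-gene list of the comparison biomarker.
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return A `gsef_result`: list with `fractions` (data.frame `module`,
#'   `fraction_ref`, `fraction_other`), `statistic`, `p_value`,
#'   `n_modules`, `method` and `degenerate`.
#' @export
compare_gsef <- function(modules, enriched_ref, enriched_other, ...) {
  if (length(modules) == 0L) stop("no gene modules supplied")
  if (is.null(names(modules))) names(modules) <- paste0("module_", seq_along(modules))
  f_ref <- vapply(modules, gsef_fraction, numeric(1L), enriched_genes = enriched_ref)
  f_oth <- vapply(modules, gsef_fraction, numeric(1L), enriched_genes = enriched_other)
  test <- wilcoxon_signed_rank(f_ref, f_oth, ...)
  structure(list(
    fractions = data.frame(module = names(modules), fraction_ref = unname(f_ref),
                           fraction_other = unname(f_oth),
                           stringsAsFactors = FALSE),
    statistic = test$statistic, p_value = test$p_value,
    n_modules = length(modules), n_used = test$n_used,
    method = test$method, degenerate = test$degenerate
  ), class = "gsef_result")
}

#' @export
print.gsef_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<gsef_result> degenerate: all paired GSEF differences are zero\n")
  } else {
    cat(sprintf("<gsef_result> %d modules (%d informative): W = %.1f, p = %.4g (%s)\n",
                x$n_modules, x$n_used, x$statistic, x$p_value, x$method))
  }
  invisible(x)
}
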