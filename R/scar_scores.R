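#' Count large-scale state transitions (LST)
#'
#' An LST is a breakpoint between two adjacent copy-number segments that
#' each span at least `min_segment_mb` and differ in copy state, counted
#' per chromosome arm after smoothing away segments shorter than
#' `smoothing_mb`. Segments spanning the centromere are split at the arm
#' boundary, so a state change coinciding with the centromere gap is never
#' counted. LST totals act as a genomic-scar surrogate for homologous
#' recombination deficiency.
#'
#' @param profile A [segment_profile()].
#' @param min_segment_mb Minimum flank size, in Mb, for a breakpoint to
#'   qualify (default 10).
#' @param smoothing_mb Segments shorter than this (Mb) are smoothed away
#'   before counting (default 3).
#' @param cn_tolerance Log2 tolerance for state equality without
#'   allele-specific copy number; see [smooth_segments()].
#' @return Integer LST count.
#' @export
compute_lst <- function(profile, min_segment_mb = 10, smoothing_mb = 3,
                        cn_tolerance = 0.1) {
  stopifnot(inherits(profile, "segment_profile"))
  if (nrow(profile$segments) == 0L) {
    stop("empty profile: no segments to score (a flat genome still has segments)")
  }
  min_bp <- min_segment_mb * 1e6
  arms <- profile$build$arms
  total <- 0L
  for (k in seq_len(nrow(arms))) {
    seg <- profile$segments[profile$segments$chrom == arms$chrom[k], , drop = FALSE]
    seg <- clip_segments(seg, arms$start[k], arms$end[k])
    if (nrow(seg) < 2L) next
    seg <- smooth_segment_table(seg, min_len_bp = smoothing_mb * 1e6,
                                cn_tol = cn_tolerance)
    if (nrow(seg) < 2L) next
    for (i in seq_len(nrow(seg) - 1L)) {
      if (seg_len(seg[i, ]) >= min_bp && seg_len(seg[i + 1L, ]) >= min_bp &&
          !states_equal(seg[i, ], seg[i + 1L, ], tol = cn_tolerance)) {
        total <- total + 1L
      }
    }
  }
  total
}

require_allele_specific <- function(profile, what) {
  seg <- profile$segments
  if (nrow(seg) == 0L || any(is.na(seg$major_cn)) || any(is.na(seg$minor_cn))) {
    stop("allele-specific data required: ", what,
         " needs major_cn/minor_cn on every segment")
  }
}

#' Count regions of telomeric allelic imbalance (TAI)
#'
#' A TAI region is a run of segments with unequal major and minor allele
#' copy number that reaches a telomere (the outermost assayed position of
#' its chromosome), does not cross the centromere, and spans at least
#' `min_mb`. Requires allele-specific copy number on every segment.
#'
#' @param profile A [segment_profile()] with `major_cn`/`minor_cn` set.
#' @param min_mb Minimum region length in Mb (default 11).
#' @return Integer TAI count.
#' @export
compute_tai <- function(profile, min_mb = 11) {
  stopifnot(inherits(profile, "segment_profile"))
  require_allele_specific(profile, "TAI")
  chroms <- profile$build$chromosomes
  total <- 0L
  for (tab in split_ordered(profile$segments)) {
    ch <- chroms[chroms$chrom == tab$chrom[1L], ]
    reg <- merge_allele_regions(tab)
    tel_lo <- min(tab$start)  # outermost assayed positions stand in for telomeres
    tel_hi <- max(tab$end)
    for (i in seq_len(nrow(reg))) {
      r <- reg[i, ]
      if (r$major_cn == r$minor_cn) next
      if (seg_len(r) < min_mb * 1e6) next
      crosses_cen <- r$start <= ch$cen_start && r$end > ch$cen_end
      if (crosses_cen) next
      if (r$start <= tel_lo || r$end >= tel_hi) total <- total + 1L
    }
  }
  total
}

#' Count loss-of-heterozygosity (LOH) regions
#'
#' An LOH region is a run of segments with minor allele copy number zero
#' and major allele copy number at least one, longer than `min_mb`, that
#' does not span its entire (assayed) chromosome. Whole-chromosome LOH is
#' excluded because it reflects chromosome loss rather than the focal
#' scarring associated with homologous recombination deficiency.
#'
#' @inheritParams compute_tai
#' @param min_mb Regions must be strictly longer than this many Mb
#'   (default 15).
#' @return Integer LOH count.
#' @export
compute_loh <- function(profile, min_mb = 15) {
  stopifnot(inherits(profile, "segment_profile"))
  require_allele_specific(profile, "LOH")
  total <- 0L
  for (tab in split_ordered(profile$segments)) {
    reg <- merge_allele_regions(tab)
    tel_lo <- min(tab$start); tel_hi <- max(tab$end)
    for (i in seq_len(nrow(reg))) {
      r <- reg[i, ]
      if (!(r$minor_cn == 0 && r$major_cn >= 1)) next
      if (seg_len(r) <= min_mb * 1e6) next
      if (r$start <= tel_lo && r$end >= tel_hi) next  # whole-chromosome event
      total <- total + 1L
    }
  }
  total
}

#' Aggregate the HRD score
#'
#' The homologous recombination deficiency (HRD) score is the sum of the
#' three genomic-scar components: LST + TAI + LOH. All three must be
#' available; without allele-specific copy number TAI and LOH (and hence
#' HRD) cannot be derived.
#'
#' @param scores A list or one-row data.frame with elements/columns `lst`,
#'   `tai` and `loh`.
#' @return Integer HRD score.
#' @export
#' @examples
#' compute_hrd(list(lst = 5, tai = 3, loh = 2))  # 10
compute_hrd <- function(scores) {
  comp <- lapply(c("lst", "tai", "loh"), function(k) {
    v <- scores[[k]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("HRD could not be generated: component '", k, "' is missing ",
           "(allele-specific data required for TAI/LOH)")
    }
    v
  })
  comp[[1L]] + comp[[2L]] + comp[[3L]]
}

#' Fraction of genome altered (FGA)
#'
#' The summed length of segments whose absolute log2 copy-number ratio
#' exceeds `log2_threshold`, divided by the total length of all assayed
#' segments. Chromosomes absent from the profile contribute to neither
#' numerator nor denominator.
#'
#' @param profile A [segment_profile()].
#' @param log2_threshold Alteration threshold on |log2 ratio| (default 0.2,
#'   the cBioPortal convention).
#' @return Fraction in `[0, 1]`.
#' @export
compute_fga <- function(profile, log2_threshold = 0.2) {
  stopifnot(inherits(profile, "segment_profile"))
  seg <- profile$segments
  total <- sum(as.numeric(seg_len(seg)))
  if (!is.finite(total) || total <= 0) {
    stop("zero assayed length: cannot compute FGA")
  }
  altered <- sum(as.numeric(seg_len(seg))[abs(seg$log2_ratio) > log2_threshold])
  altered / total
}

#' Arm-level aneuploidy score
#'
#' Counts chromosome arms on which at least `arm_fraction` of the assayed
#' arm length is gained (log2 ratio above `log2_threshold`) or, separately,
#' lost (below `-log2_threshold`). By default the conventional 39 autosomal
#' arms are scored (acrocentric p arms and the sex chromosomes excluded).
#'
#' @inheritParams compute_fga
#' @param arm_fraction Fraction of assayed arm length that must be altered
#'   in one direction (default 0.5).
#' @param include_sex Also score chrX/chrY arms.
#' @return Integer count of altered arms.
#' @export
compute_aneuploidy <- function(profile, arm_fraction = 0.5,
                               log2_threshold = 0.2, include_sex = FALSE) {
  stopifnot(inherits(profile, "segment_profile"))
  arms <- scoreable_arms(profile$build, include_sex = include_sex)
  n <- 0L
  for (k in seq_len(nrow(arms))) {
    seg <- profile$segments[profile$segments$chrom == arms$chrom[k], , drop = FALSE]
    seg <- clip_segments(seg, arms$start[k], arms$end[k])
    if (nrow(seg) == 0L) next
    lens <- as.numeric(seg_len(seg))
    assayed <- sum(lens)
    gained <- sum(lens[seg$log2_ratio > log2_threshold])
    lost <- sum(lens[seg$log2_ratio < -log2_threshold])
    if (max(gained, lost) >= arm_fraction * assayed) n <- n + 1L
  }
  n
}

#' Score a set of profiles on all genomic scars
#'
#' Convenience wrapper computing LST, TAI, LOH, HRD, FGA and the
#' aneuploidy score for each profile. TAI/LOH/HRD are `NA` for profiles
#' lacking allele-specific copy number.
#'
#' @param profiles List of [segment_profile()] objects.
#' @param ... Passed through to the individual scorers where names match.
#' @return data.frame with one row per sample.
#' @export
score_profiles <- function(profiles, ...) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    has_as <- nrow(p$segments) > 0L &&
      !any(is.na(p$segments$major_cn)) && !any(is.na(p$segments$minor_cn))
    lst <- compute_lst(p)
    tai <- if (has_as) compute_tai(p) else NA_integer_
    loh <- if (has_as) compute_loh(p) else NA_integer_
    hrd <- if (has_as) compute_hrd(list(lst = lst, tai = tai, loh = loh)) else NA_integer_
    data.frame(sample_id = p$sample_id, lst = lst, tai = tai, loh = loh,
               hrd = hrd, fga = compute_fga(p),
               aneuploidy = compute_aneuploidy(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dichotomize a continuous score into a two-class phenotype
#'
#' Splits numeric values at a threshold into "high"/"low" labels usable as
#' a GSEA phenotype. With `high_is = "ge"` values at the threshold are
#' "high"; with `"gt"` ties go to "low" (the convention used by
#' [median_split()]).
#'
#' @param values Named numeric vector (names are sample ids) or plain
#'   numeric with `sample_ids` supplied.
#' @param threshold Cut point.
#' @param high_is One of `"ge"`, `"gt"`: comparison that defines "high".
#' @param sample_ids Sample identifiers if `values` is unnamed.
#' @return A `phenotype_labels` object (see [make_phenotype()]); carries a
#'   `degenerate` flag (with a warning) when all samples fall in one class,
#'   which makes the phenotype unusable for permutation testing.
#' @export
#' @examples
#' dichotomize_score(c(a = 1, b = 20, c = 14, d = 15), threshold = 15)
dichotomize_score <- function(values, threshold, high_is = c("ge", "gt"),
                              sample_ids = names(values)) {
  high_is <- match.arg(high_is)
  if (any(is.na(values))) stop("values must be non-missing")
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(values))
  hi <- if (high_is == "ge") values >= threshold else values > threshold
  labels <- ifelse(hi, "high", "low")
  new_phenotype_labels(sample_ids, labels, classes = c("high", "low"))
}

#' Median split of a score vector
#'
#' Labels values above the median "high" and the rest (ties included)
#' "low".
#'
#' @inheritParams dichotomize_score
#' @return A `phenotype_labels` object.
#' @export
median_split <- function(values, sample_ids = names(values)) {
  dichotomize_score(values, threshold = stats::median(values),
                    high_is = "gt", sample_ids = sample_ids)
}
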