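#' Construct a copy-number segment profile
#'
#' A segment profile holds one sample's ordered copy-number segments on a
#' genome build. Coordinates are 1-based and inclusive (SEG convention), so
#' all length arithmetic uses `end - start + 1`. Allele-specific major/minor
#' copy numbers are optional; when absent, the scores that need them (TAI,
#' LOH, hence HRD) are unavailable for the sample.
#'
#' @param sample_id Sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `log2_ratio` and optionally `major_cn`, `minor_cn`.
#' @param build A [genome_build()].
#' @return An object of class `segment_profile`.
#' @export
segment_profile <- function(sample_id, segments, build) {
  stopifnot(inherits(build, "genome_build"))
  req <- c("chrom", "start", "end", "log2_ratio")
  if (!all(req %in% names(segments))) {
    stop("segments need columns: ", paste(req, collapse = ", "))
  }
  segments <- as.data.frame(segments)
  segments$chrom <- normalize_chrom(segments$chrom)
  if (!"major_cn" %in% names(segments)) {
    segments$major_cn <- rep(NA_real_, nrow(segments))
  }
  if (!"minor_cn" %in% names(segments)) {
    segments$minor_cn <- rep(NA_real_, nrow(segments))
  }
  segments <- segments[, c(req, "major_cn", "minor_cn")]
  validate_segments(segments, build, context = sample_id)
  ord <- order(match(segments$chrom, build$chromosomes$chrom), segments$start)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(sample_id = sample_id, segments = segments, build = build),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> %s: %d segments on %d chromosomes (%s)\n",
              x$sample_id, nrow(x$segments),
              length(unique(x$segments$chrom)), x$build$name))
  invisible(x)
}

validate_segments <- function(seg, build, context = "") {
  lab <- if (nzchar(context)) paste0(" [sample ", context, "]") else ""
  if (any(bad <- !(seg$chrom %in% build$chromosomes$chrom))) {
    stop("chromosome(s) not in build", lab, ": ",
         paste(unique(seg$chrom[bad]), collapse = ", "))
  }
  if (any(bad <- seg$start > seg$end)) {
    stop("segment start > end", lab, " at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  len <- build$chromosomes$length[match(seg$chrom, build$chromosomes$chrom)]
  if (any(bad <- seg$start < 1 | seg$end > len)) {
    stop("segment outside chromosome bounds", lab, " at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  has_as <- !is.na(seg$major_cn) & !is.na(seg$minor_cn)
  if (any(bad <- has_as & seg$major_cn < seg$minor_cn)) {
    stop("major_cn < minor_cn", lab, " at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop("overlapping segments", lab, " on ", ch)
    }
  }
  invisible(TRUE)
}

#' Read a SEG file into segment profiles
#'
#' Parses the tab-delimited SEG dialect used by cBioPortal/IGV: a header
#' line and columns for sample ID, chromosome, segment start, segment end
#' and mean log2 copy-number ratio (a num.mark column, if present, is
#' ignored). Optional `major_cn`/`minor_cn` columns carry allele-specific
#' copy number. Chromosome names are accepted with or without the "chr"
#' prefix and stored normalized.
#'
#' @param path Path to the SEG file.
#' @param build A [genome_build()] used for validation.
#' @return A named list of [segment_profile()] objects, one per sample, in
#'   order of first appearance.
#' @export
read_seg <- function(path, build) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(raw)
  pick <- function(cands, what) {
    hit <- cols[tolower(cols) %in% tolower(cands)]
    if (length(hit) == 0L) stop("SEG file lacks a ", what, " column (looked for: ",
                                paste(cands, collapse = ", "), ")")
    hit[1L]
  }
  id_col <- pick(c("ID", "Sample", "sample_id", "SampleName"), "sample")
  ch_col <- pick(c("chrom", "chr", "chromosome"), "chromosome")
  st_col <- pick(c("loc.start", "start", "Start"), "start")
  en_col <- pick(c("loc.end", "end", "End"), "end")
  lr_col <- pick(c("seg.mean", "log2_ratio", "log2", "mean"), "log2 mean")

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(bad <- is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")) {
      stop("malformed ", what, " in SEG file at line ",
           which(bad)[1L] + 1L)  # +1 for the header line
    }
    v
  }
  seg <- data.frame(
    sample = as.character(raw[[id_col]]),
    chrom = as.character(raw[[ch_col]]),
    start = num(st_col, "start"),
    end = num(en_col, "end"),
    log2_ratio = num(lr_col, "seg.mean"),
    stringsAsFactors = FALSE
  )
  if (any(bad <- is.na(seg$start) | is.na(seg$end) | is.na(seg$log2_ratio))) {
    stop("malformed row in SEG file at line ", which(bad)[1L] + 1L)
  }
  if (any(bad <- seg$start > seg$end)) {
    stop("start > end in SEG file at line ", which(bad)[1L] + 1L)
  }
  seg$major_cn <- if ("major_cn" %in% cols) num("major_cn", "major_cn") else NA_real_
  seg$minor_cn <- if ("minor_cn" %in% cols) num("minor_cn", "minor_cn") else NA_real_

  samples <- unique(seg$sample)
  profiles <- lapply(samples, function(s) {
    segment_profile(s, seg[seg$sample == s, -1L, drop = FALSE], build)
  })
  stats::setNames(profiles, samples)
}

#' Write segment profiles to a SEG file
#'
#' @param profiles A list of [segment_profile()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p) {
    cbind(ID = p$sample_id, p$segments)
  }))
  has_as <- any(!is.na(tab$major_cn) & !is.na(tab$minor_cn))
  out <- data.frame(ID = tab$ID, chrom = tab$chrom,
                    loc.start = format(tab$start, scientific = FALSE, trim = TRUE),
                    loc.end = format(tab$end, scientific = FALSE, trim = TRUE),
                    seg.mean = tab$log2_ratio)
  if (has_as) {
    out$major_cn <- tab$major_cn
    out$minor_cn <- tab$minor_cn
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Copy-state equality: exact integer comparison of (major, minor) when both
# segments carry allele-specific CN, else |delta log2| <= tol.
states_equal <- function(a, b, tol = 0.1) {
  as_a <- !is.na(a$major_cn) && !is.na(a$minor_cn)
  as_b <- !is.na(b$major_cn) && !is.na(b$minor_cn)
  if (as_a && as_b) {
    a$major_cn == b$major_cn && a$minor_cn == b$minor_cn
  } else {
    abs(a$log2_ratio - b$log2_ratio) <= tol
  }
}

seg_len <- function(seg) seg$end - seg$start + 1

# Smooth one chromosome's (or arm's) ordered segment table: repeatedly drop
# the shortest segment under min_len_bp; when its two index-neighbours have
# equal copy states the neighbours merge into one segment spanning the
# removed region (log2 is the length-weighted mean), otherwise the
# breakpoint structure around the removed segment is retained.
smooth_segment_table <- function(seg, min_len_bp, cn_tol) {
  repeat {
    lens <- seg_len(seg)
    short <- which(lens < min_len_bp)
    if (length(short) == 0L || nrow(seg) <= 1L) return(seg)
    i <- short[which.min(lens[short])]
    left <- if (i > 1L) seg[i - 1L, ] else NULL
    right <- if (i < nrow(seg)) seg[i + 1L, ] else NULL
    seg <- seg[-i, , drop = FALSE]
    if (!is.null(left) && !is.null(right) &&
        states_equal(left, right, tol = cn_tol)) {
      j <- i - 1L  # index of `left` after removal
      l1 <- seg_len(seg[j, ]); l2 <- seg_len(seg[j + 1L, ])
      seg$log2_ratio[j] <- (seg$log2_ratio[j] * l1 +
                              seg$log2_ratio[j + 1L] * l2) / (l1 + l2)
      seg$end[j] <- seg$end[j + 1L]
      seg <- seg[-(j + 1L), , drop = FALSE]
    }
    rownames(seg) <- NULL
  }
}

#' Smooth a segment profile
#'
#' Removes segments shorter than `min_len_bp` and merges their flanking
#' segments whenever the flanks share a copy state (exact integer
#' major/minor copy number when available, otherwise log2 ratios within
#' `cn_tolerance`), iterating to a fixed point per chromosome. This is the
#' pre-filtering step applied before counting large-scale state
#' transitions, where sub-threshold segments are treated as noise.
#'
#' @param profile A [segment_profile()].
#' @param min_len_bp Minimum segment length kept, in bp (default 3 Mb).
#' @param cn_tolerance Log2-ratio tolerance for state equality when
#'   allele-specific copy number is absent.
#' @return A smoothed [segment_profile()].
#' @export
smooth_segments <- function(profile, min_len_bp = 3e6, cn_tolerance = 0.1) {
  stopifnot(inherits(profile, "segment_profile"))
  if (min_len_bp <= 0) stop("min_len_bp must be positive")
  seg <- profile$segments
  out <- do.call(rbind, lapply(split_ordered(seg), smooth_segment_table,
                               min_len_bp = min_len_bp, cn_tol = cn_tolerance))
  rownames(out) <- NULL
  segment_profile(profile$sample_id, out, profile$build)
}

# Split a sorted segment table into per-chromosome tables, preserving order.
split_ordered <- function(seg) {
  split(seg, factor(seg$chrom, levels = unique(seg$chrom)))
}

# Clip a chromosome's segments to [lo, hi]; drops segments fully outside.
clip_segments <- function(seg, lo, hi) {
  keep <- seg$end >= lo & seg$start <= hi
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg)) {
    seg$start <- pmax(seg$start, lo)
    seg$end <- pmin(seg$end, hi)
  }
  seg
}

# Merge runs of index-consecutive segments with identical (major, minor)
# integer states into regions; used by the TAI and LOH counters.
merge_allele_regions <- function(seg) {
  if (nrow(seg) == 0L) return(seg)
  grp <- cumsum(c(TRUE, !(diff(seg$major_cn) == 0 & diff(seg$minor_cn) == 0)))
  out <- do.call(rbind, lapply(split(seg, grp), function(s) {
    data.frame(chrom = s$chrom[1L], start = min(s$start), end = max(s$end),
               log2_ratio = sum(s$log2_ratio * seg_len(s)) / sum(seg_len(s)),
               major_cn = s$major_cn[1L], minor_cn = s$minor_cn[1L])
  }))
  rownames(out) <- NULL
  out
}
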