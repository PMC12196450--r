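#' Specify a synthetic cohort
#'
#' Collects the knobs of the synthetic-data generator: cohort size, gene
#' universe, the planted (truly enriched) gene set and its mean shift,
#' biomarker labels with a controllable association to the planted
#' enrichment, and per-class planted genomic-scar counts. A fixed seed
#' makes the whole cohort byte-reproducible.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes in the expression universe.
#' @param planted_gene_set_size Size of the truly enriched gene set.
#' @param enrichment_shift Mean shift (in SD units of the unit-variance
#'   noise) added to planted genes in the positive class.
#' @param positive_fraction Fraction of samples in the positive class.
#' @param biomarker_specs Named list; each element is
#'   `list(association = a)` with `a` in `[0, 1]`: 1 reproduces the
#'   enrichment labels exactly, 0 is independent of them (implemented as
#'   a label-flip probability `(1 - a) / 2`).
#' @param segment_spec Named list mapping class name (`"pos"`/`"neg"`) to
#'   `list(k_lst =, k_tai =, k_loh =, fga_target =)`; `fga_target = NULL`
#'   leaves FGA uncontrolled.
#' @param n_decoys Short (2 Mb) decoy segments inserted per sample to
#'   exercise smoothing.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 120, n_genes = 1000,
                        planted_gene_set_size = 50, enrichment_shift = 1,
                        positive_fraction = 0.5, biomarker_specs = list(),
                        segment_spec = NULL, n_decoys = 2, seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1,
            planted_gene_set_size <= n_genes, enrichment_shift >= 0,
            positive_fraction > 0, positive_fraction < 1)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 planted_gene_set_size = planted_gene_set_size,
                 enrichment_shift = enrichment_shift,
                 positive_fraction = positive_fraction,
                 biomarker_specs = biomarker_specs,
                 segment_spec = segment_spec, n_decoys = n_decoys,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_ids <- function(spec) {
  list(samples = sprintf("S%03d", seq_len(spec$n_samples)),
       genes = sprintf("g%04d", seq_len(spec$n_genes)))
}

#' Simulate an expression cohort with a planted enriched gene set
#'
#' Baseline expression is i.i.d. standard normal; the planted gene set is
#' mean-shifted by `enrichment_shift` in the positive class. The returned
#' ground truth (planted set and class labels) drives the recovery and
#' calibration tests.
#'
#' @param spec A [cohort_spec()].
#' @return List with `matrix` (genes x samples), `gene_set` (planted
#'   member ids), `labels` (`phenotype_labels`, classes `pos`/`neg`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$planted_gene_set_size > spec$n_genes) {
    stop("planted gene set larger than the gene universe")
  }
  ids <- cohort_ids(spec)
  with_seed(spec$seed, {
    n_pos <- round(spec$positive_fraction * spec$n_samples)
    labels <- rep(c("pos", "neg"), c(n_pos, spec$n_samples - n_pos))
    labels <- sample(labels)
    planted <- sort(sample(ids$genes, spec$planted_gene_set_size))
    m <- matrix(stats::rnorm(spec$n_genes * spec$n_samples),
                nrow = spec$n_genes,
                dimnames = list(ids$genes, ids$samples))
    m[planted, labels == "pos"] <- m[planted, labels == "pos"] +
      spec$enrichment_shift
    list(matrix = m, gene_set = planted,
         labels = new_phenotype_labels(ids$samples, labels, c("pos", "neg")))
  })
}

#' Simulate biomarker labels tied to the planted enrichment
#'
#' Each biomarker in `spec$biomarker_specs` is generated by copying the
#' enrichment class labels and flipping each sample's label independently
#' with probability `(1 - association) / 2`, giving one-parameter control
#' over how well the biomarker tags the planted signal.
#'
#' @param spec A [cohort_spec()].
#' @param truth_labels The `phenotype_labels` returned by
#'   [simulate_expression()].
#' @return Named list of `phenotype_labels`, one per biomarker spec.
#' @export
simulate_biomarkers <- function(spec, truth_labels) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(truth_labels, "phenotype_labels"))
  if (length(spec$biomarker_specs) == 0L) return(list())
  with_seed(spec$seed + 1L, {
    out <- lapply(seq_along(spec$biomarker_specs), function(i) {
      a <- spec$biomarker_specs[[i]]$association
      stopifnot(a >= 0, a <= 1)
      flip <- stats::runif(truth_labels$n) < (1 - a) / 2
      labs <- truth_labels$labels
      labs[flip] <- ifelse(labs[flip] == "pos", "neg", "pos")
      new_phenotype_labels(truth_labels$sample_ids, labs, c("pos", "neg"))
    })
    stats::setNames(out, names(spec$biomarker_specs))
  })
}

# Per-arm allocation plan for one sample's planted scar events. Each arm
# hosts at most one feature so the planted counts cannot interact:
#  - LST arms: j+1 alternating segments (1,1,log2 0) / (2,2,log2 0.25),
#    each >= 11 Mb, giving j qualifying breakpoints;
#  - TAI arms: a telomere-bounded imbalanced region (2,1,log2 0.3) with an
#    8 Mb neutral inner flank, so the boundary never qualifies as an LST;
#  - LOH arms: a copy-neutral LOH region (2,0,log2 0) buffered by 8 Mb
#    neutral flanks on both sides, again invisible to the LST counter;
#  - FGA filler arms: a segment with neutral integer CN (1,1) but
#    log2 0.25, altering FGA without creating any copy-state change;
#  - decoy arms: a 2 Mb (2,2,log2 0.25) blip inside a neutral arm, which
#    LST smoothing must remove.
simulate_one_profile <- function(sample_id, counts, build, n_decoys) {
  k_lst <- counts$k_lst %||% 0L
  k_tai <- counts$k_tai %||% 0L
  k_loh <- counts$k_loh %||% 0L
  fga_target <- counts$fga_target
  seg_min <- 11e6; buffer <- 8e6

  arms <- build$arms[sample(nrow(build$arms)), , drop = FALSE]
  total_genome <- sum(as.numeric(arms$length))
  used <- rep(FALSE, nrow(arms))
  rows <- list()
  altered <- 0
  add <- function(chrom, start, end, log2, major, minor) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, log2_ratio = log2,
      major_cn = major, minor_cn = minor)
    if (abs(log2) > 0.2) altered <<- altered + (end - start + 1)
  }

  # -- LST arms
  remaining <- k_lst
  for (i in seq_len(nrow(arms))) {
    if (remaining <= 0L) break
    L <- arms$length[i]
    cap <- floor(L / seg_min) - 1L
    if (cap < 1L) next
    j <- min(remaining, cap)
    bounds <- round(seq(arms$start[i] - 1, arms$end[i], length.out = j + 2))
    for (s in seq_len(j + 1L)) {
      state <- if (s %% 2L == 1L) c(0, 1, 1) else c(0.25, 2, 2)
      add(arms$chrom[i], bounds[s] + 1, bounds[s + 1L],
          state[1L], state[2L], state[3L])
    }
    used[i] <- TRUE
    remaining <- remaining - j
  }
  if (remaining > 0L) {
    stop("infeasible planting: ", remaining, " LST breakpoint(s) left after ",
         "exhausting all arms (largest remaining arm too short)")
  }

  # -- TAI arms (telomere-bounded allelic imbalance)
  placed <- 0L
  for (i in seq_len(nrow(arms))) {
    if (placed >= k_tai) break
    if (used[i]) next
    L <- arms$length[i]
    if (L < seg_min + buffer + 1e6) next
    if (arms$arm[i] == "p") {
      add(arms$chrom[i], arms$start[i], arms$end[i] - buffer, 0.3, 2, 1)
      add(arms$chrom[i], arms$end[i] - buffer + 1, arms$end[i], 0, 1, 1)
    } else {
      add(arms$chrom[i], arms$start[i], arms$start[i] + buffer - 1, 0, 1, 1)
      add(arms$chrom[i], arms$start[i] + buffer, arms$end[i], 0.3, 2, 1)
    }
    used[i] <- TRUE
    placed <- placed + 1L
  }
  if (placed < k_tai) {
    stop("infeasible planting: no arm long enough for TAI region ",
         placed + 1L, " of ", k_tai)
  }

  # -- LOH arms (interstitial copy-neutral LOH)
  placed <- 0L
  for (i in seq_len(nrow(arms))) {
    if (placed >= k_loh) break
    if (used[i]) next
    L <- arms$length[i]
    if (L - 2 * buffer <= 15e6 + 1e6) next
    a <- arms$start[i]; b <- arms$end[i]
    add(arms$chrom[i], a, a + buffer - 1, 0, 1, 1)
    add(arms$chrom[i], a + buffer, b - buffer, 0, 2, 0)
    add(arms$chrom[i], b - buffer + 1, b, 0, 1, 1)
    used[i] <- TRUE
    placed <- placed + 1L
  }
  if (placed < k_loh) {
    stop("infeasible planting: no arm long enough for LOH region ",
         placed + 1L, " of ", k_loh)
  }

  # -- decoy short segments on otherwise-neutral arms
  placed <- 0L
  for (i in seq_len(nrow(arms))) {
    if (placed >= n_decoys) break
    if (used[i] || arms$length[i] < 20e6) next
    a <- arms$start[i]; b <- arms$end[i]
    mid <- round((a + b) / 2)
    add(arms$chrom[i], a, mid - 1e6 - 1, 0, 1, 1)
    add(arms$chrom[i], mid - 1e6, mid + 1e6 - 1, 0.25, 2, 2)
    add(arms$chrom[i], mid + 1e6, b, 0, 1, 1)
    used[i] <- TRUE
    placed <- placed + 1L
  }

  # -- FGA filler on remaining arms (neutral CN, altered log2)
  if (!is.null(fga_target)) {
    stopifnot(fga_target >= 0, fga_target <= 1)
    needed <- fga_target * total_genome - altered
    if (needed < -0.02 * total_genome) {
      stop("infeasible fga_target ", fga_target, ": planted events already ",
           "alter ", round(altered / total_genome, 3), " of the genome")
    }
    for (i in seq_len(nrow(arms))) {
      if (needed < 1) break
      if (used[i]) next
      a <- arms$start[i]; b <- arms$end[i]
      x <- min(round(needed), arms$length[i])
      add(arms$chrom[i], a, a + x - 1, 0.25, 1, 1)
      if (a + x <= b) add(arms$chrom[i], a + x, b, 0, 1, 1)
      used[i] <- TRUE
      needed <- needed - x
    }
    if (needed > 0.02 * total_genome) {
      stop("infeasible fga_target ", fga_target, ": ran out of arms")
    }
  }

  # -- everything else stays neutral
  for (i in which(!used)) {
    add(arms$chrom[i], arms$start[i], arms$end[i], 0, 1, 1)
  }

  prof <- segment_profile(sample_id, do.call(rbind, rows), build)
  attr(prof, "planted") <- list(k_lst = k_lst, k_tai = k_tai, k_loh = k_loh,
                                fga_target = fga_target,
                                fga_planted = altered / total_genome)
  prof
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Simulate copy-number segment profiles with planted scar counts
#'
#' Generates one profile per sample on the packaged hg19 autosomal arm
#' table, planting exactly `k_lst` qualifying large-scale state
#' transitions, `k_tai` telomeric allelic-imbalance regions and `k_loh`
#' interstitial LOH regions for the sample's class, plus decoy sub-3-Mb
#' segments that the LST smoothing step must remove, and (optionally)
#' enough neutral-copy-state altered-log2 filler to bring the fraction of
#' genome altered to `fga_target`. Each arm hosts at most one planted
#' feature, so the recorded ground truth is recovered exactly by the
#' scorers.
#'
#' @param spec A [cohort_spec()] with a `segment_spec`.
#' @param class_of_sample Character vector of class names, one per sample
#'   (defaults to all samples taking the first class in `segment_spec`).
#' @return Named list of [segment_profile()] objects; each carries its
#'   planted ground truth in attribute `"planted"`, and the list carries
#'   a `"ground_truth"` data.frame attribute.
#' @export
simulate_segments <- function(spec, class_of_sample = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(spec$segment_spec)) stop("cohort_spec has no segment_spec")
  ids <- cohort_ids(spec)
  if (is.null(class_of_sample)) {
    class_of_sample <- rep(names(spec$segment_spec)[1L], spec$n_samples)
  }
  stopifnot(length(class_of_sample) == spec$n_samples,
            all(class_of_sample %in% names(spec$segment_spec)))
  build <- hg19_build(autosomes_only = TRUE)
  with_seed(spec$seed + 2L, {
    profiles <- lapply(seq_len(spec$n_samples), function(i) {
      simulate_one_profile(ids$samples[i],
                           spec$segment_spec[[class_of_sample[i]]],
                           build, spec$n_decoys)
    })
    names(profiles) <- ids$samples
    gt <- do.call(rbind, lapply(profiles, function(p) {
      pl <- attr(p, "planted")
      data.frame(sample_id = p$sample_id, k_lst = pl$k_lst, k_tai = pl$k_tai,
                 k_loh = pl$k_loh,
                 fga_target = pl$fga_target %||% NA_real_,
                 fga_planted = pl$fga_planted)
    }))
    rownames(gt) <- NULL
    attr(profiles, "ground_truth") <- gt
    profiles
  })
}

#' Simulate PARPi-like drug gene modules
#'
#' Generates `n_modules` gene modules (stand-ins for drug-perturbation
#' signatures) that draw a controlled fraction of their members from the
#' planted gene set and the rest from the remaining gene universe.
#'
#' @param planted_set Character vector: the planted (enriched) gene set.
#' @param gene_universe Character vector: all gene ids.
#' @param n_modules Number of modules (default 22).
#' @param module_size_range Integer range of module sizes.
#' @param overlap_with_planted Fraction of each module drawn from
#'   `planted_set`.
#' @param seed Integer seed.
#' @return A `gene_set_collection` (named list of member vectors).
#' @export
simulate_drug_modules <- function(planted_set, gene_universe, n_modules = 22,
                                  module_size_range = c(20, 60),
                                  overlap_with_planted = 0.5, seed = 1L) {
  stopifnot(overlap_with_planted >= 0, overlap_with_planted <= 1,
            all(planted_set %in% gene_universe))
  other <- setdiff(gene_universe, planted_set)
  with_seed(seed + 3L, {
    sets <- lapply(seq_len(n_modules), function(i) {
      size <- if (module_size_range[1L] == module_size_range[2L]) {
        module_size_range[1L]
      } else {
        sample(module_size_range[1L]:module_size_range[2L], 1L)
      }
      n_in <- round(overlap_with_planted * size)
      n_out <- size - n_in
      if (n_in > length(planted_set) || n_out > length(other)) {
        stop("module size ", size, " infeasible within the gene universe")
      }
      sort(c(sample(planted_set, n_in), sample(other, n_out)))
    })
    names(sets) <- sprintf("PARPi_module_%02d", seq_len(n_modules))
    structure(sets,
              descriptions = stats::setNames(
                rep("synthetic PARPi perturbation module", n_modules),
                names(sets)),
              class = "gene_set_collection")
  })
}
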