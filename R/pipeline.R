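#' Run the full biomarker-comparison workflow
#'
#' For each candidate biomarker phenotype, runs the single-gene-set GSEA
#' against the compiled PARPi-response gene set; then compares every
#' biomarker to the reference biomarker (LST by default) with the
#' differential enrichment-score test, Benjamini-Hochberg-adjusted over
#' the family of comparisons; and, when drug gene modules are supplied,
#' runs the per-module GSEF Wilcoxon comparison on leading-edge gene
#' lists, again BH-adjusted. Failures (degenerate phenotypes, empty
#' gene-set intersections) are isolated per biomarker and reported in the
#' run log without aborting the run.
#'
#' @param matrix Normalized genes x samples expression matrix.
#' @param phenotypes Named list of `phenotype_labels`; names are the
#'   biomarker names and must include `reference`. Each biomarker may
#'   classify a different subset of samples; its `n` is the sample size
#'   used in the differential test.
#' @param gene_set Character vector: the compiled response gene set.
#' @param reference Name of the reference biomarker (default `"LST"`).
#' @param modules Optional named list of drug gene modules for the GSEF
#'   comparison.
#' @param n_perm,permutation_type,weight_p,seed GSEA settings; see
#'   [score_gene_set()]. Each biomarker gets a distinct sub-seed derived
#'   from `seed` so runs are reproducible as a whole.
#' @param out_dir Optional directory; when given, tab-delimited result
#'   tables, a JSON summary and the serialized configuration are written
#'   there.
#' @return A `biomarker_comparison` bundle: list with `gsea` (per-biomarker
#'   results), `gsea_table`, `differential_table`, `gsef` (per-comparison
#'   `gsef_result`s with `fdr_value`), `failures`, `log` and `config`.
#' @export
run_biomarker_comparison <- function(matrix, phenotypes, gene_set,
                                     reference = "LST", modules = NULL,
                                     n_perm = 1000,
                                     permutation_type = "phenotype",
                                     weight_p = 1, seed = 1L,
                                     out_dir = NULL) {
  stopifnot(is.list(phenotypes), !is.null(names(phenotypes)))
  if (!reference %in% names(phenotypes)) {
    stop("reference biomarker '", reference, "' not among the phenotypes")
  }
  config <- list(reference = reference, n_perm = n_perm,
                 permutation_type = permutation_type, weight_p = weight_p,
                 seed = seed, gene_set_size = length(gene_set),
                 biomarkers = names(phenotypes))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  note("run_biomarker_comparison: ", length(phenotypes), " biomarkers, ",
       "reference = ", reference, ", ", n_perm, " ", permutation_type,
       " permutations, weight_p = ", weight_p, ", seed = ", seed)

  results <- list(); failures <- list()
  for (i in seq_along(phenotypes)) {
    nm <- names(phenotypes)[i]
    res <- tryCatch({
      if (phenotypes[[nm]]$degenerate) stop("degenerate phenotype")
      score_gene_set(matrix, phenotypes[[nm]], gene_set, n_perm = n_perm,
                     permutation_type = permutation_type,
                     seed = seed + i, weight_p = weight_p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
      note("biomarker '", nm, "' failed: ", conditionMessage(res))
    } else {
      results[[nm]] <- res
      note("biomarker '", nm, "': ES ", round(res$es, 3), ", NES ",
           round(res$nes, 3), ", p ", format_pvalue(res$nominal_p, n_perm),
           " (n = ", phenotypes[[nm]]$n, ", seed ", seed + i, ")")
    }
  }

  gsea_table <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(biomarker = nm, gene_set_size = r$gene_set_size,
               es = r$es, nes = r$nes, nominal_p = r$nominal_p,
               fdr_q = r$fdr_q, n = phenotypes[[nm]]$n,
               stringsAsFactors = FALSE)
  }))

  differential_table <- NULL
  if (reference %in% names(results)) {
    ref <- results[[reference]]
    others <- setdiff(names(results), reference)
    if (length(others)) {
      rows <- lapply(others, function(nm) {
        t <- tryCatch(
          differential_es_test(ref$es, phenotypes[[reference]]$n,
                               results[[nm]]$es, phenotypes[[nm]]$n),
          error = function(e) {
            note("differential ES '", reference, " vs. ", nm, "' failed: ",
                 conditionMessage(e))
            list(z = NA_real_, raw_p = NA_real_)
          })
        data.frame(biomarker_pair = paste(reference, "vs.", nm),
                   n_ref = phenotypes[[reference]]$n, n_other = phenotypes[[nm]]$n,
                   es_ref = ref$es, es_other = results[[nm]]$es,
                   z = t$z, raw_p = t$raw_p, stringsAsFactors = FALSE)
      })
      differential_table <- do.call(rbind, rows)
      ok <- !is.na(differential_table$raw_p)
      differential_table$adjusted_p <- NA_real_
      if (any(ok)) {
        differential_table$adjusted_p[ok] <- bh_adjust(differential_table$raw_p[ok])
      }
    }
  } else {
    note("reference biomarker failed; differential ES analysis skipped")
  }

  gsef <- NULL
  if (!is.null(modules) && reference %in% names(results)) {
    others <- setdiff(names(results), reference)
    gsef <- lapply(others, function(nm) {
      compare_gsef(modules, results[[reference]]$leading_edge,
                   results[[nm]]$leading_edge)
    })
    names(gsef) <- others
    if (length(gsef)) {
      fdr <- bh_adjust(vapply(gsef, `[[`, numeric(1L), "p_value"))
      for (nm in names(gsef)) gsef[[nm]]$fdr_value <- fdr[[nm]]
      note("GSEF comparison over ", length(modules), " modules for ",
           length(gsef), " biomarker pair(s)")
    }
  }

  bundle <- structure(list(gsea = results, gsea_table = gsea_table,
                           differential_table = differential_table,
                           gsef = gsef, failures = failures,
                           log = log, config = config),
                      class = "biomarker_comparison")
  if (!is.null(out_dir)) write_comparison_bundle(bundle, out_dir)
  bundle
}

#' @export
print.biomarker_comparison <- function(x, ...) {
  cat("<biomarker_comparison>\n")
  if (!is.null(x$gsea_table)) {
    tab <- x$gsea_table
    tab$es <- round(tab$es, 3); tab$nes <- round(tab$nes, 3)
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$differential_table)) {
    cat("\nDifferential ES vs reference:\n")
    tab <- x$differential_table
    tab$z <- round(tab$z, 3)
    tab$raw_p <- signif(tab$raw_p, 3); tab$adjusted_p <- signif(tab$adjusted_p, 3)
    print(tab[, c("biomarker_pair", "n_ref", "n_other", "es_ref", "es_other",
                  "z", "adjusted_p")], row.names = FALSE)
  }
  if (length(x$failures)) {
    cat("\nFailures:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

write_comparison_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(tab, name) {
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(bundle$gsea_table, "gsea_results.tsv")
  wt(bundle$differential_table, "differential_es.tsv")
  if (!is.null(bundle$gsef)) {
    frac <- do.call(rbind, lapply(names(bundle$gsef), function(nm) {
      cbind(comparison = nm, bundle$gsef[[nm]]$fractions)
    }))
    wt(frac, "gsef_fractions.tsv")
    wt(data.frame(comparison = names(bundle$gsef),
                  statistic = vapply(bundle$gsef, `[[`, numeric(1L), "statistic"),
                  p_value = vapply(bundle$gsef, `[[`, numeric(1L), "p_value"),
                  fdr_value = vapply(bundle$gsef, `[[`, numeric(1L), "fdr_value"),
                  degenerate = vapply(bundle$gsef, `[[`, logical(1L), "degenerate")),
       "gsef_tests.tsv")
  }
  for (nm in names(bundle$gsea)) {
    writeLines(bundle$gsea[[nm]]$leading_edge,
               file.path(out_dir, paste0("leading_edge_", nm, ".txt")))
  }
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  jsonlite::write_json(bundle$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run the validation recipe: several scar phenotypes, one cohort
#'
#' Scores the same gene set against several (typically scar-derived)
#' phenotypes on one cohort and compiles the leading-edge genes of the
#' significant runs into a single response gene list — the construction
#' used to assemble a response gene set from multiple validation
#' analyses. When no run reaches the significance threshold the compiled
#' list is empty and flagged as such rather than erroring.
#'
#' @inheritParams run_biomarker_comparison
#' @param fdr_threshold Runs with `fdr_q` below this enter the
#'   compilation (default 0.25, the conventional GSEA exploratory cut).
#' @return List with `gsea` (per-phenotype results), `gsea_table`,
#'   `compiled_genes` (union of significant leading edges, sorted),
#'   `significant` (names of contributing phenotypes), `empty` (flag) and
#'   `log`.
#' @export
run_validation_recipe <- function(matrix, phenotypes, gene_set,
                                  fdr_threshold = 0.25, n_perm = 1000,
                                  permutation_type = "phenotype",
                                  weight_p = 1, seed = 1L) {
  stopifnot(is.list(phenotypes), !is.null(names(phenotypes)))
  log <- character()
  results <- list(); failures <- list()
  for (i in seq_along(phenotypes)) {
    nm <- names(phenotypes)[i]
    res <- tryCatch(
      score_gene_set(matrix, phenotypes[[nm]], gene_set, n_perm = n_perm,
                     permutation_type = permutation_type,
                     seed = seed + i, weight_p = weight_p),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
      log <- c(log, paste0("phenotype '", nm, "' failed: ",
                           conditionMessage(res)))
    } else results[[nm]] <- res
  }
  gsea_table <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(phenotype = nm, gene_set_size = r$gene_set_size, es = r$es,
               nes = r$nes, nominal_p = r$nominal_p, fdr_q = r$fdr_q,
               stringsAsFactors = FALSE)
  }))
  significant <- names(results)[vapply(results, function(r) {
    is.finite(r$fdr_q) && r$fdr_q < fdr_threshold && r$es > 0
  }, logical(1L))]
  compiled <- sort(unique(unlist(lapply(results[significant],
                                        `[[`, "leading_edge"))))
  if (is.null(compiled)) compiled <- character(0)
  empty <- length(compiled) == 0L
  log <- c(log, paste0("compiled ", length(compiled),
                       " leading-edge genes from ", length(significant),
                       " significant run(s) at FDR < ", fdr_threshold,
                       if (empty) " [empty compilation]" else ""))
  list(gsea = results, gsea_table = gsea_table, compiled_genes = compiled,
       significant = significant, empty = empty, failures = failures,
       log = log)
}
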