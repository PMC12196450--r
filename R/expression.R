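#' Two-class phenotype labels
#'
#' Internal constructor shared by [make_phenotype()], [dichotomize_score()]
#' and [median_split()]. The first class is the "positive" class, listed
#' first in CLS output and treated as class A by the signal-to-noise
#' ranking.
#'
#' @noRd
new_phenotype_labels <- function(sample_ids, labels, classes) {
  stopifnot(length(sample_ids) == length(labels))
  if (length(classes) != 2L) stop("exactly two classes required")
  if (!all(labels %in% classes)) stop("labels outside declared classes")
  n_per_class <- c(sum(labels == classes[1L]), sum(labels == classes[2L]))
  names(n_per_class) <- classes
  degenerate <- any(n_per_class == 0L)
  if (degenerate) {
    warning("degenerate phenotype: all samples in class '",
            classes[which(n_per_class > 0L)[1L]],
            "'; unusable for phenotype permutation")
  }
  structure(list(sample_ids = as.character(sample_ids),
                 labels = as.character(labels),
                 classes = as.character(classes),
                 n = length(sample_ids), n_per_class = n_per_class,
                 degenerate = degenerate),
            class = "phenotype_labels")
}

#' @export
print.phenotype_labels <- function(x, ...) {
  cat(sprintf("<phenotype_labels> n = %d: %s (%d) vs %s (%d)%s\n", x$n,
              x$classes[1L], x$n_per_class[1L], x$classes[2L],
              x$n_per_class[2L], if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Build a two-class phenotype from a sample table column
#'
#' Drops samples with missing values in `column`, requires exactly two
#' remaining classes, and puts `positive_class` first.
#'
#' @param table data.frame with a `sample_id` column (or rownames used as
#'   sample ids).
#' @param column Column holding the class variable.
#' @param positive_class The class to list first.
#' @return A `phenotype_labels` object; `n` counts only classifiable
#'   samples.
#' @export
make_phenotype <- function(table, column, positive_class) {
  if (!column %in% names(table)) stop("no column '", column, "' in table")
  ids <- if ("sample_id" %in% names(table)) table$sample_id else rownames(table)
  v <- as.character(table[[column]])
  keep <- !is.na(v) & v != ""
  v <- v[keep]; ids <- ids[keep]
  classes <- unique(v)
  if (length(classes) > 2L) {
    stop("column '", column, "' has ", length(classes),
         " classes; recode to two classes first")
  }
  if (!positive_class %in% classes) {
    stop("positive class '", positive_class, "' not present in column")
  }
  classes <- c(positive_class, setdiff(classes, positive_class))
  if (length(classes) == 1L) classes <- c(classes, paste0("not_", classes))
  new_phenotype_labels(ids, v, classes)
}

#' Recode a CRC Consensus Molecular Subtype label
#'
#' Maps CMS1-4 into the two-tier microsatellite scheme (MSI vs MSS) and
#' the three-tier scheme (Hypermutated/MSI vs Epithelial/CIN vs
#' GS/EMT/Mesenchymal): CMS1 is the hypermutated/MSI subtype, CMS2 and
#' CMS3 are epithelial/chromosomally unstable, CMS4 is mesenchymal.
#'
#' @param cms_label Character vector of labels in `CMS1`..`CMS4`; `NA`
#'   propagates.
#' @return data.frame with columns `two_tier` and `three_tier`.
#' @export
#' @examples
#' recode_cms(c("CMS1", "CMS4", NA))
recode_cms <- function(cms_label) {
  two <- c(CMS1 = "MSI", CMS2 = "MSS", CMS3 = "MSS", CMS4 = "MSS")
  three <- c(CMS1 = "Hypermutated/MSI", CMS2 = "Epithelial/CIN",
             CMS3 = "Epithelial/CIN", CMS4 = "GS/EMT/Mesenchymal")
  x <- as.character(cms_label)
  known <- is.na(x) | x %in% names(two)
  if (!all(known)) {
    stop("unknown CMS label(s): ", paste(unique(x[!known]), collapse = ", "))
  }
  data.frame(two_tier = unname(two[x]), three_tier = unname(three[x]),
             stringsAsFactors = FALSE)
}

check_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (anyNA(m)) stop("missing expression values are not allowed")
  invisible(m)
}

#' Fractional-rank (rank-based inverse normal) normalization
#'
#' Per-cohort, per-gene two-step normalization: each gene's values are
#' replaced by their fractional ranks (ties receive the average rank) and
#' the ranks are mapped to standard-normal quantiles via
#' `qnorm(rank / (n + 1))`. The transform is strictly monotone within each
#' gene, so downstream rank-based statistics are unchanged while marginal
#' scales become comparable across genes and platforms. A constant gene
#' maps to the quantile of its mean rank (0 for every sample).
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @return The normalized matrix with attribute `normalized = TRUE`.
#' @export
#' @examples
#' m <- matrix(c(3, 1, 2), 1, dimnames = list("g1", c("a", "b", "c")))
#' fractional_rank_normalize(m)  # qnorm(c(3, 1, 2) / 4)
fractional_rank_normalize <- function(matrix) {
  check_expression_matrix(matrix)
  n <- ncol(matrix)
  if (n < 2L) stop("need at least 2 samples to normalize")
  ranks <- t(apply(matrix, 1L, rank, ties.method = "average"))
  out <- stats::qnorm(ranks / (n + 1))
  dimnames(out) <- dimnames(matrix)
  attr(out, "normalized") <- TRUE
  out
}

#' Write / read a GCT v1.2 expression matrix
#'
#' GCT v1.2 is the tab-delimited matrix format consumed by GSEA: a `#1.2`
#' version line, a dimensions line, then a header row `Name`,
#' `Description`, sample ids, and one row per gene.
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @param path File path.
#' @param descriptions Optional per-gene description column (defaults to
#'   `"na"`).
#' @return `write_gct` returns `path` invisibly; `read_gct` returns the
#'   matrix.
#' @export
write_gct <- function(matrix, path, descriptions = NULL) {
  check_expression_matrix(matrix)
  if (is.null(descriptions)) descriptions <- rep("na", nrow(matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(matrix), ncol(matrix), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(matrix)), collapse = "\t"), con)
  body <- cbind(rownames(matrix), descriptions,
                format(matrix, trim = TRUE, digits = 15))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_gct
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "#1.2") {
    stop("not a GCT v1.2 file: ", path)
  }
  dims <- as.integer(strsplit(lines[2L], "\t")[[1L]])
  header <- strsplit(lines[3L], "\t")[[1L]]
  tab <- utils::read.delim(text = lines[-(1:2)], stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L]) {
    stop("GCT dimensions line disagrees with body: ", path)
  }
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- tab[[1L]]
  colnames(m) <- header[-(1:2)]
  storage.mode(m) <- "double"
  check_expression_matrix(m)
}

#' Write / read a two-class categorical CLS phenotype file
#'
#' The CLS format used by GSEA: line 1 `"<n> 2 1"`, line 2
#' `"# <classA> <classB>"`, line 3 the space-separated per-sample labels.
#'
#' @param labels A `phenotype_labels` object.
#' @param path File path.
#' @return `write_cls` returns `path` invisibly; `read_cls` returns a
#'   `phenotype_labels` object (sample ids `S1..Sn`, since CLS carries no
#'   ids).
#' @export
write_cls <- function(labels, path) {
  stopifnot(inherits(labels, "phenotype_labels"))
  writeLines(c(paste(labels$n, 2, 1),
               paste("#", labels$classes[1L], labels$classes[2L]),
               paste(labels$labels, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_cls
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated CLS file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  classes <- strsplit(trimws(sub("^#\\s*", "", lines[2L])), "\\s+")[[1L]]
  labs <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  if (hdr[2L] != 2L) stop("only two-class CLS files are supported")
  if (length(labs) != hdr[1L]) stop("CLS label count disagrees with header")
  # numeric-coded CLS (0/1) maps onto the declared class names in order
  if (all(labs %in% c("0", "1"))) labs <- classes[as.integer(labs) + 1L]
  new_phenotype_labels(paste0("S", seq_along(labs)), labs, classes)
}
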