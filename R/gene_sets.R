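#' Read / write gene sets in GMT format
#'
#' GMT is the tab-delimited gene-set format: one set per line as
#' `name TAB description TAB gene TAB gene ...`. Members are whitespace
#' stripped and matched case-sensitively; duplicate members within a set
#' are dropped with a warning.
#'
#' @param path File path.
#' @return `read_gmt` returns a `gene_set_collection`: a named list of
#'   character vectors of members, with per-set descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields (name, description, members)")
    }
    name <- fields[1L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in gene set '", name, "' deduplicated")
      members <- unique(members)
    }
    if (length(members) == 0L) stop("GMT line ", i, ": empty gene set '", name, "'")
    if (name %in% names(sets)) stop("duplicate gene set name '", name, "'")
    sets[[name]] <- members
    descs[name] <- fields[2L]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection Named list of member vectors (a `gene_set_collection`
#'   or plain named list).
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(rep("na", length(collection)),
                                               names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descs[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Compile a collection of gene sets into one union set
#'
#' Unions the members of every set in the collection — the construction
#' used to merge many PARPi-perturbation signatures into a single response
#' gene set — optionally intersected with a measured-gene universe (the
#' genes actually present in a cohort's expression matrix, which is why
#' the same compiled set has different effective sizes in different
#' cohorts). Output ordering is lexicographic for determinism.
#'
#' @param collection Named list of member vectors.
#' @param restrict_to Optional character vector: the measured-gene
#'   universe to intersect with.
#' @return Character vector of member genes, sorted.
#' @export
#' @examples
#' compile_union(list(a = c("A", "B"), b = c("B", "C")))  # A B C
compile_union <- function(collection, restrict_to = NULL) {
  if (length(collection) == 0L) stop("empty gene set collection")
  u <- sort(unique(trimws(unlist(collection, use.names = FALSE))))
  if (!is.null(restrict_to)) u <- u[u %in% restrict_to]
  if (length(u) == 0L) stop("empty union after restriction to the gene universe")
  u
}
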