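#' Construct a genome build
#'
#' A genome build is the coordinate frame against which copy-number segment
#' profiles are validated and chromosome arms are derived. It records, per
#' chromosome, the total length and the centromere interval; the p arm is
#' `[1, cen_start]` and the q arm `[cen_end + 1, length]` (the centromeric
#' band itself belongs to neither arm and is never assayed).
#'
#' @param name Identifier for the build (e.g. `"hg19"`).
#' @param chromosomes A data.frame with columns `chrom`, `length`,
#'   `cen_start`, `cen_end` (base pairs, 1-based).
#'
#' @return An object of class `genome_build`: a list with elements `name`,
#'   `chromosomes` (the validated table) and `arms` (a per-arm table with
#'   columns `chrom`, `arm`, `start`, `end`, `length`).
#' @export
#' @examples
#' toy <- genome_build("toy", data.frame(
#'   chrom = "chr1", length = 200e6, cen_start = 100e6, cen_end = 105e6))
#' toy$arms
genome_build <- function(name, chromosomes) {
  stopifnot(is.character(name), length(name) == 1L)
  req <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(req %in% names(chromosomes))) {
    stop("chromosomes table must have columns: ", paste(req, collapse = ", "))
  }
  chromosomes <- as.data.frame(chromosomes)[, req]
  chromosomes$chrom <- normalize_chrom(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom)) stop("duplicate chromosome names")
  with(chromosomes, {
    if (any(length <= 0)) stop("chromosome lengths must be positive")
    if (any(cen_start < 0 | cen_start >= cen_end | cen_end > length)) {
      stop("centromere must satisfy 0 <= cen_start < cen_end <= length")
    }
  })
  arms <- rbind(
    data.frame(chrom = chromosomes$chrom, arm = "p",
               start = 1, end = chromosomes$cen_start),
    data.frame(chrom = chromosomes$chrom, arm = "q",
               start = chromosomes$cen_end + 1, end = chromosomes$length)
  )
  arms <- arms[arms$end >= arms$start, ]
  arms$length <- arms$end - arms$start + 1
  arms <- arms[order(match(arms$chrom, chromosomes$chrom), arms$arm), ]
  rownames(arms) <- NULL
  structure(list(name = name, chromosomes = chromosomes, arms = arms),
            class = "genome_build")
}

#' The hg19 genome build
#'
#' Chromosome lengths and centromere (acen band) boundaries for the 24
#' human chromosomes in hg19/GRCh37 coordinates, shipped as a plain-text
#' table with the package.
#'
#' @param autosomes_only Drop chrX/chrY from the build.
#' @return A [genome_build()] object.
#' @export
hg19_build <- function(autosomes_only = FALSE) {
  path <- system.file("extdata", "hg19_chromosomes.tsv",
                      package = "parpicompare", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (autosomes_only) tab <- tab[!tab$chrom %in% c("chrX", "chrY"), ]
  genome_build("hg19", tab)
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %s: %d chromosomes, %d arms, %.2f Gb\n",
              x$name, nrow(x$chromosomes), nrow(x$arms),
              sum(as.numeric(x$chromosomes$length)) / 1e9))
  invisible(x)
}

# "1"/"chr1"/"MT" etc. -> "chr1"/"chrM"; case-insensitive prefix handling.
normalize_chrom <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- trimws(as.character(x))
  x <- sub("^(chr|CHR|Chr)", "", x)
  x[x %in% c("MT", "Mt", "mt")] <- "M"
  paste0("chr", x)
}

# Arm table rows for one chromosome; errors if the chromosome is unknown.
arms_of <- function(build, chrom) {
  a <- build$arms[build$arms$chrom == chrom, , drop = FALSE]
  if (nrow(a) == 0L) stop("chromosome not in build: ", chrom)
  a
}

# Arms eligible for arm-level scoring: autosomal arms minus the acrocentric
# p arms (13p, 14p, 15p, 21p, 22p), the conventional 39-arm set.
ACROCENTRIC_P <- c("chr13", "chr14", "chr15", "chr21", "chr22")

scoreable_arms <- function(build, include_sex = FALSE) {
  a <- build$arms
  if (!include_sex) a <- a[!a$chrom %in% c("chrX", "chrY"), ]
  a[!(a$arm == "p" & a$chrom %in% ACROCENTRIC_P), , drop = FALSE]
}
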