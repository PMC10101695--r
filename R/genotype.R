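#' Construct a raw genotype object
#'
#' A `raw_genotype` holds a fully imputed samples-by-markers matrix of diploid
#' nucleotide calls. Calls are stored canonically with the two alleles of a
#' call sorted lexicographically, so `"AG"` and `"GA"` are the same genotype.
#' Every marker must be biallelic or constant and no call may be missing.
#'
#' @param calls character matrix (samples x markers) of two-letter calls from
#'   \{A,C,G,T\}, e.g. `"AA"`, `"AG"`. Single letters are expanded to
#'   homozygous calls when `homozygous_shorthand = TRUE`.
#' @param sample_ids,marker_ids unique identifier vectors matching the matrix
#'   dimensions. Always treated as character.
#' @param chrom_pos optional tibble with columns `marker_id`, `chrom`, `pos`.
#' @param homozygous_shorthand accept `"A"` as `"AA"` (common for inbred
#'   lines). Default `TRUE`.
#' @return An object of class `raw_genotype`.
#' @export
raw_genotype <- function(calls, sample_ids, marker_ids, chrom_pos = NULL,
                         homozygous_shorthand = TRUE) {
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  calls <- matrix(
    canonicalize_calls(as.character(calls), homozygous_shorthand),
    nrow = length(sample_ids),
    dimnames = list(sample_ids, marker_ids)
  )
  obj <- structure(
    list(calls = calls, sample_ids = sample_ids, marker_ids = marker_ids,
         chrom_pos = chrom_pos),
    class = "raw_genotype"
  )
  validate_raw_genotype(obj)
}

validate_raw_genotype <- function(x) {
  if (anyDuplicated(x$sample_ids)) {
    abort(paste0("duplicate sample id: ",
                 paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(x$marker_ids)) {
    abort(paste0("duplicate marker id: ",
                 paste(unique(x$marker_ids[duplicated(x$marker_ids)]), collapse = ", ")))
  }
  bad <- !grepl("^[ACGT][ACGT]$", x$calls)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "missing or invalid genotype at (%s, %s): '%s' (calls must be pairs from A/C/G/T; no missing data allowed)",
      x$sample_ids[idx[1L]], x$marker_ids[idx[2L]], x$calls[idx[1L], idx[2L]]
    ))
  }
  n_alleles <- marker_allele_counts(x)
  if (any(n_alleles > 2L)) {
    abort(sprintf("marker %s has more than 2 alleles (markers must be biallelic)",
                  x$marker_ids[which(n_alleles > 2L)[1L]]))
  }
  x
}

# number of distinct alleles per marker
marker_allele_counts <- function(x) {
  vapply(seq_along(x$marker_ids), function(j) {
    length(unique(c(substr(x$calls[, j], 1L, 1L), substr(x$calls[, j], 2L, 2L))))
  }, integer(1))
}

# the (up to 2) alleles observed at marker j, sorted
marker_alleles <- function(x, j) {
  sort(unique(c(substr(x$calls[, j], 1L, 1L), substr(x$calls[, j], 2L, 2L))))
}

#' @exportS3Method base::print
print.raw_genotype <- function(x, ...) {
  cat(sprintf("<raw_genotype> %d samples x %d markers\n",
              length(x$sample_ids), length(x$marker_ids)))
  if (!is.null(x$chrom_pos)) cat("  chromosome/position map present\n")
  invisible(x)
}

#' @export
dim.raw_genotype <- function(x) {
  c(length(x$sample_ids), length(x$marker_ids))
}

#' Convert a raw genotype to a tibble
#'
#' One row per sample: a `sample_id` column followed by one character column
#' per marker, mirroring the CSV interchange layout.
#'
#' @param x a `raw_genotype`.
#' @param ... unused.
#' @return A tibble.
#' @export
as_tibble.raw_genotype <- function(x, ...) {
  dplyr::bind_cols(
    tibble(sample_id = x$sample_ids),
    as_tibble(as.data.frame(x$calls, stringsAsFactors = FALSE))
  )
}

# subset samples (used by match_samples and the simulator)
subset_samples <- function(x, keep) {
  raw_genotype(x$calls[keep, , drop = FALSE], x$sample_ids[keep], x$marker_ids,
               chrom_pos = x$chrom_pos)
}

# equality used by store guards and round-trip tests
raw_genotype_identical <- function(a, b) {
  identical(a$sample_ids, b$sample_ids) &&
    identical(a$marker_ids, b$marker_ids) &&
    identical(unname(a$calls), unname(b$calls))
}
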