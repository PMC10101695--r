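#' Persist genotypes to the unified on-disk store
#'
#' Downstream steps (encoding, filtering, splitting, optimization) read from
#' a unified store so they are independent of the original input format. The
#' store is a directory with a fixed layout:
#'
#' * `genotype/matrix.csv` — the canonicalized call matrix,
#' * `genotype/chrom_pos.csv` — optional marker coordinates,
#' * `maf.csv` — precomputed per-marker minor-allele frequency,
#' * `index/` — append-only groups holding persisted MAF-filter masks and
#'   data-split indices (JSON, written by [persist_maf_filter()] and
#'   [persist_split()]).
#'
#' All files are plain text, so a store (and in particular its small `index/`
#' group, which refers back to the large genotype matrix by position) is
#' portable across machines. Re-running with identical genotypes is a no-op;
#' attempting to overwrite a store with different genotype content is an
#' error, which protects previously persisted indices from silently pointing
#' at different data.
#'
#' @param raw a [raw_genotype()].
#' @param path store directory to create (or verify).
#' @return A `unified_store` handle (list with `path`), invisibly usable with
#'   [load_unified_store()], [store_maf()], [persist_split()].
#' @export
to_unified_store <- function(raw, path) {
  geno_csv <- file.path(path, "genotype", "matrix.csv")
  if (file.exists(geno_csv)) {
    existing <- read_genotype_csv(geno_csv)
    if (!raw_genotype_identical(existing, raw)) {
      abort(sprintf("store at '%s' already holds different genotype data; refusing to overwrite", path))
    }
    return(invisible(unified_store(path)))
  }
  dir.create(file.path(path, "genotype"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "index"), recursive = TRUE, showWarnings = FALSE)
  write_genotype_csv(raw, geno_csv)
  if (!is.null(raw$chrom_pos)) {
    readr::write_csv(raw$chrom_pos, file.path(path, "genotype", "chrom_pos.csv"),
                     progress = FALSE)
  }
  readr::write_csv(tibble(marker_id = raw$marker_ids, maf = compute_maf(raw)),
                   file.path(path, "maf.csv"), progress = FALSE)
  write_json_file(list(index_base = 1L, format_version = 1L),
                  file.path(path, "store.json"))
  invisible(unified_store(path))
}

unified_store <- function(path) {
  structure(list(path = path), class = "unified_store")
}

#' Open an existing unified store
#' @param path store directory.
#' @return A `unified_store` handle.
#' @export
open_unified_store <- function(path) {
  if (!file.exists(file.path(path, "genotype", "matrix.csv"))) {
    abort(sprintf("'%s' is not a unified store (no genotype/matrix.csv)", path))
  }
  unified_store(path)
}

#' @exportS3Method base::print
print.unified_store <- function(x, ...) {
  cat(sprintf("<unified_store> %s\n", x$path))
  invisible(x)
}

#' Load the genotypes stored in a unified store
#' @param store a `unified_store` or a store path.
#' @return A [raw_genotype()].
#' @export
load_unified_store <- function(store) {
  path <- if (inherits(store, "unified_store")) store$path else store
  raw <- read_genotype_csv(file.path(path, "genotype", "matrix.csv"))
  cp_path <- file.path(path, "genotype", "chrom_pos.csv")
  if (file.exists(cp_path)) {
    raw$chrom_pos <- readr::read_csv(cp_path, show_col_types = FALSE, progress = FALSE)
  }
  raw
}

#' Per-marker minor-allele frequencies recorded in a store
#' @param store a `unified_store` or a store path.
#' @return Tibble with columns `marker_id`, `maf`.
#' @export
store_maf <- function(store) {
  path <- if (inherits(store, "unified_store")) store$path else store
  readr::read_csv(file.path(path, "maf.csv"), show_col_types = FALSE, progress = FALSE)
}

# append-only write of a JSON index record; identical re-write is a no-op,
# a conflicting one is a corruption error
write_index_record <- function(store, rel_key, record) {
  path <- file.path(store$path, "index", rel_key)
  if (file.exists(path)) {
    existing <- read_json_file(path)
    new <- read_json_file({ tmp <- tempfile(fileext = ".json"); write_json_file(record, tmp); tmp })
    if (!identical(existing, new)) {
      abort(sprintf("index record '%s' exists with different content (corruption guard)", rel_key))
    }
    return(invisible(rel_key))
  }
  write_json_file(record, path)
  invisible(rel_key)
}

#' Persist a MAF-filter mask into a store's index group
#'
#' @param store a `unified_store`.
#' @param threshold the MAF threshold used (markers kept iff MAF > threshold).
#' @param keep logical keep-mask over the store's markers.
#' @return The index key, invisibly.
#' @export
persist_maf_filter <- function(store, threshold, keep) {
  stopifnot(inherits(store, "unified_store"), is.logical(keep))
  key <- file.path("maf_filter", paste0("threshold_", format(threshold), ".json"))
  write_index_record(store, key, list(
    threshold = threshold, index_base = 1L,
    keep_indices = which(keep), n_markers = length(keep)
  ))
  invisible(key)
}
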