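#' Minor-allele frequency per marker
#'
#' For each biallelic marker the frequency of one allele is
#' `f = (allele count) / (2 * n_samples)` and the MAF is `min(f, 1 - f)`,
#' so values lie in `[0, 0.5]` and a constant marker has MAF 0.
#'
#' @param raw a [raw_genotype()].
#' @return Numeric vector of MAFs, named by marker id.
#' @export
compute_maf <- function(raw) {
  n2 <- 2 * length(raw$sample_ids)
  maf <- vapply(seq_along(raw$marker_ids), function(j) {
    al <- marker_alleles(raw, j)
    if (length(al) == 1L) return(0)
    cnt <- sum(substr(raw$calls[, j], 1L, 1L) == al[1L]) +
      sum(substr(raw$calls[, j], 2L, 2L) == al[1L])
    f <- cnt / n2
    min(f, 1 - f)
  }, numeric(1))
  setNames(maf, raw$marker_ids)
}

#' Filter markers by minor-allele frequency
#'
#' Markers are kept iff `MAF > threshold` (strict inequality, so
#' `threshold = 0` removes exactly the constant markers). If a `store` is
#' supplied, the keep-mask is persisted under its `index/maf_filter` group so
#' the filtering step is reproducible by index alone.
#'
#' @param data a [raw_genotype()] or [encode_additive()] result.
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @param store optional `unified_store` to persist the mask into.
#' @return List with `data` (filtered, same class as input) and `keep`
#'   (logical mask over the original markers, named by marker id).
#' @export
maf_filter <- function(data, threshold, store = NULL) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 0.5) {
    abort("`threshold` must lie in [0, 0.5]")
  }
  # strict inequality, with a tiny tolerance so that a frequency that is
  # mathematically equal to the threshold is never kept through floating-
  # point noise (e.g. 1 - 19/20 vs the literal 0.05)
  strictly_above <- function(maf) maf - threshold > 1e-9
  if (inherits(data, "raw_genotype")) {
    maf <- compute_maf(data)
    keep <- strictly_above(maf)
    filtered <- raw_genotype(data$calls[, keep, drop = FALSE], data$sample_ids,
                             data$marker_ids[keep],
                             chrom_pos = if (!is.null(data$chrom_pos))
                               data$chrom_pos[keep, , drop = FALSE])
  } else if (inherits(data, "encoded_genotype")) {
    f <- colMeans(data$matrix) / 2          # minor-allele frequency from dosage
    maf <- pmin(f, 1 - f)
    if (data$encoding != "additive_012") {
      abort("maf_filter on encoded data requires the additive_012 encoding")
    }
    keep <- strictly_above(maf)
    filtered <- data
    filtered$matrix <- data$matrix[, keep, drop = FALSE]
    filtered$minor_allele <- data$minor_allele[keep]
    filtered$major_allele <- data$major_allele[keep]
    filtered$feature_map <- data$feature_map[keep, , drop = FALSE]
  } else {
    abort("`data` must be a raw_genotype or encoded_genotype")
  }
  keep <- setNames(keep, names(maf))
  if (!is.null(store)) persist_maf_filter(store, threshold, keep)
  list(data = filtered, keep = keep)
}

#' Additive (dosage) genotype encoding
#'
#' Codes each marker as the number of minor-allele copies (0, 1 or 2). The
#' minor allele is the less frequent allele; at exactly 50/50 frequency the
#' lexicographically smaller allele is taken as minor. The polarity is
#' recorded per marker so the encoding is invertible and reproducible on new
#' data.
#'
#' @param raw a [raw_genotype()].
#' @return An `encoded_genotype`: list with `matrix` (numeric, samples x
#'   markers), `encoding = "additive_012"`, `minor_allele`, `major_allele`
#'   (named character vectors; equal for constant markers) and `feature_map`
#'   (tibble mapping matrix columns to markers).
#' @export
encode_additive <- function(raw) {
  m <- length(raw$marker_ids)
  minor <- major <- character(m)
  mat <- matrix(0, nrow = length(raw$sample_ids), ncol = m,
                dimnames = list(raw$sample_ids, raw$marker_ids))
  n2 <- 2 * length(raw$sample_ids)
  for (j in seq_len(m)) {
    al <- marker_alleles(raw, j)
    if (length(al) == 1L) {
      minor[j] <- major[j] <- al
      next
    }
    cnt1 <- sum(substr(raw$calls[, j], 1L, 1L) == al[1L]) +
      sum(substr(raw$calls[, j], 2L, 2L) == al[1L])
    # ties at 50% break toward the lexicographically smaller allele (= al[1])
    if (cnt1 <= n2 - cnt1) {
      minor[j] <- al[1L]; major[j] <- al[2L]
    } else {
      minor[j] <- al[2L]; major[j] <- al[1L]
    }
    mat[, j] <- (substr(raw$calls[, j], 1L, 1L) == minor[j]) +
      (substr(raw$calls[, j], 2L, 2L) == minor[j])
  }
  structure(list(
    matrix = mat, encoding = "additive_012",
    minor_allele = setNames(minor, raw$marker_ids),
    major_allele = setNames(major, raw$marker_ids),
    feature_map = tibble(feature = raw$marker_ids, marker_id = raw$marker_ids),
    sample_ids = raw$sample_ids, marker_ids = raw$marker_ids
  ), class = "encoded_genotype")
}

#' Encode genotype calls with a stored minor-allele polarity
#'
#' Re-encodes new data using the polarity recorded during training, so that
#' dosages on new samples are comparable with the fitted model's
#' coefficients.
#'
#' @param raw a [raw_genotype()] covering at least the stored markers.
#' @param minor_allele named character vector (marker id -> minor allele).
#' @return Numeric dosage matrix over the stored markers, in stored order.
#' @export
encode_additive_with_polarity <- function(raw, minor_allele) {
  missing_markers <- setdiff(names(minor_allele), raw$marker_ids)
  if (length(missing_markers) > 0L) {
    abort(sprintf("new genotype data is missing %d training marker(s): %s",
                  length(missing_markers),
                  paste(head(missing_markers, 5L), collapse = ", ")))
  }
  calls <- raw$calls[, names(minor_allele), drop = FALSE]
  mat <- sapply(seq_along(minor_allele), function(j) {
    (substr(calls[, j], 1L, 1L) == minor_allele[j]) +
      (substr(calls[, j], 2L, 2L) == minor_allele[j])
  })
  mat <- matrix(as.numeric(mat), nrow = nrow(calls),
                dimnames = list(raw$sample_ids, names(minor_allele)))
  mat
}

#' One-hot genotype encoding
#'
#' Each marker expands into one indicator column per genotype class observed
#' at that marker (at most three: homozygous major, heterozygous, homozygous
#' minor, in that fixed order). Within a marker's block exactly one entry per
#' sample is 1.
#'
#' @param raw a [raw_genotype()].
#' @return An `encoded_genotype` with `encoding = "onehot"`; `feature_map`
#'   maps each indicator column back to its marker.
#' @export
encode_onehot <- function(raw) {
  add <- encode_additive(raw)
  blocks <- lapply(seq_along(raw$marker_ids), function(j) {
    dos <- add$matrix[, j]
    classes <- sort(unique(dos))            # 0 = hom-major < 1 = het < 2 = hom-minor
    block <- sapply(classes, function(k) as.numeric(dos == k))
    block <- matrix(block, nrow = length(dos))
    colnames(block) <- paste0(raw$marker_ids[j], "__", c("homMaj", "het", "homMin")[classes + 1L])
    block
  })
  mat <- do.call(cbind, blocks)
  rownames(mat) <- raw$sample_ids
  fmap <- tibble(
    feature = colnames(mat),
    marker_id = rep(raw$marker_ids, vapply(blocks, ncol, integer(1)))
  )
  structure(list(
    matrix = mat, encoding = "onehot",
    minor_allele = add$minor_allele, major_allele = add$major_allele,
    feature_map = fmap,
    sample_ids = raw$sample_ids, marker_ids = raw$marker_ids
  ), class = "encoded_genotype")
}

#' @exportS3Method base::print
print.encoded_genotype <- function(x, ...) {
  cat(sprintf("<encoded_genotype> %d samples x %d features (%s over %d markers)\n",
              nrow(x$matrix), ncol(x$matrix), x$encoding, length(x$marker_ids)))
  invisible(x)
}

#' Match encoded genotypes with a phenotype
#'
#' Restricts the genotype matrix to samples that appear in the phenotype
#' table with a non-missing value for the requested trait, preserving the
#' genotype row order. The number of dropped samples is reported via a
#' message.
#'
#' @param geno an `encoded_genotype`.
#' @param pheno a `phenotype_table` from [read_phenotype_csv()] or any tibble
#'   with a `sample_id` column and the trait column.
#' @param trait name of the trait column.
#' @return A `matched_dataset`: list with `X` (numeric matrix), `y`,
#'   `sample_ids`, `trait`, `trait_type`, `encoding`, `minor_allele`,
#'   `feature_map`.
#' @export
match_samples <- function(geno, pheno, trait) {
  stopifnot(inherits(geno, "encoded_genotype"))
  if (!trait %in% names(pheno)) {
    abort(sprintf("trait '%s' not found in phenotype table (available: %s)",
                  trait, paste(setdiff(names(pheno), "sample_id"), collapse = ", ")))
  }
  ph <- pheno[!is.na(pheno[[trait]]), c("sample_id", trait)]
  keep <- geno$sample_ids %in% ph$sample_id
  if (!any(keep)) abort("no shared sample ids with a non-missing phenotype value")
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("match_samples: dropped %d of %d genotyped samples without phenotype",
                    dropped, length(keep)))
  }
  ids <- geno$sample_ids[keep]
  y <- ph[[trait]][match(ids, ph$sample_id)]
  ttype <- if (inherits(pheno, "phenotype_table")) trait_types(pheno)[[trait]]
           else trait_type(y)
  if (ttype == "discrete") y <- factor(y)
  structure(list(
    X = geno$matrix[keep, , drop = FALSE], y = y, sample_ids = ids,
    trait = trait, trait_type = ttype, encoding = geno$encoding,
    minor_allele = geno$minor_allele, feature_map = geno$feature_map
  ), class = "matched_dataset")
}

#' @exportS3Method base::print
print.matched_dataset <- function(x, ...) {
  cat(sprintf("<matched_dataset> trait '%s' (%s): %d samples x %d features\n",
              x$trait, x$trait_type, nrow(x$X), ncol(x$X)))
  invisible(x)
}
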