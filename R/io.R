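#' Read a genotype matrix from CSV
#'
#' Expects a comma-separated file whose first column holds sample ids and
#' whose header row holds marker ids; each cell is a diploid call such as
#' `"AA"` or `"AG"` (heterozygous call order is irrelevant). A single symbol
#' (`"A"`) is read as a homozygous call when `homozygous_shorthand = TRUE`.
#' Missing cells are an error: the workflow requires a fully imputed matrix.
#'
#' @param path path to the CSV file.
#' @param homozygous_shorthand accept one-letter homozygous shorthand.
#' @return A [raw_genotype()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,m1,m2", "s1,AA,AG", "s2,GA,GG"), f)
#' g <- read_genotype_csv(f)
#' g$calls["s2", "m1"]  # "AG", canonicalized
read_genotype_csv <- function(path, homozygous_shorthand = TRUE) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2L) abort("genotype CSV needs a sample-id column plus >= 1 marker column")
  sample_ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  na_like <- is.na(mat) | mat %in% c("", "NA", "N", "--", ".")
  if (any(na_like)) {
    idx <- which(na_like, arr.ind = TRUE)[1L, ]
    abort(sprintf("missing genotype at (%s, %s)", sample_ids[idx[1L]],
                  colnames(mat)[idx[2L]]))
  }
  raw_genotype(mat, sample_ids, colnames(mat),
               homozygous_shorthand = homozygous_shorthand)
}

#' Write a genotype matrix to CSV
#'
#' Inverse of [read_genotype_csv()]; used for interchange and round-trip
#' checks.
#'
#' @param geno a [raw_genotype()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(geno, path) {
  readr::write_csv(as_tibble(geno), path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from PLINK text files (PED/MAP)
#'
#' Parses the PLINK 1.x whitespace-separated text dialect. PED rows carry
#' family id, individual id, four ignored pedigree/sex/phenotype columns and
#' then two allele columns per marker; MAP rows carry chromosome, marker id,
#' genetic distance (ignored) and base-pair position. The individual id
#' becomes the sample id. The PLINK missing code `"0"` (or any symbol outside
#' A/C/G/T) is rejected because the pipeline requires fully imputed data.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @return A [raw_genotype()] with `chrom_pos` populated from the MAP file.
#' @export
read_genotype_plink <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4L) abort("MAP file needs 4 columns: chrom, marker id, distance, position")
  marker_ids <- map[[2L]]
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n_allele_cols <- ncol(ped) - 6L
  if (n_allele_cols < 2L || n_allele_cols %% 2L != 0L) {
    abort("PED file needs 6 leading columns plus 2 allele columns per marker")
  }
  if (n_allele_cols / 2L != nrow(map)) {
    abort(sprintf("PED/MAP marker-count mismatch: PED has %d allele pairs, MAP has %d markers",
                  n_allele_cols / 2L, nrow(map)))
  }
  sample_ids <- ped[[2L]]
  alleles <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (any(!alleles %in% NUCLEOTIDES)) {
    bad <- alleles[!alleles %in% NUCLEOTIDES][1L]
    if (bad == "0") abort("missing genotype not allowed (PLINK missing code '0' found)")
    abort(sprintf("allele symbol '%s' outside A/C/G/T", bad))
  }
  a1 <- alleles[, seq(1L, n_allele_cols, by = 2L), drop = FALSE]
  a2 <- alleles[, seq(2L, n_allele_cols, by = 2L), drop = FALSE]
  calls <- matrix(paste0(a1, a2), nrow = nrow(ped))
  raw_genotype(calls, sample_ids, marker_ids,
               chrom_pos = tibble(marker_id = marker_ids,
                                  chrom = map[[1L]],
                                  pos = as.numeric(map[[4L]])))
}

#' Write genotypes as PLINK text files (PED/MAP)
#'
#' @param geno a [raw_genotype()].
#' @param ped_path,map_path output paths.
#' @return `ped_path`, invisibly.
#' @export
write_genotype_plink <- function(geno, ped_path, map_path) {
  n <- length(geno$sample_ids)
  m <- length(geno$marker_ids)
  a1 <- substr(geno$calls, 1L, 1L)
  a2 <- substr(geno$calls, 2L, 2L)
  allele_cols <- matrix("", nrow = n, ncol = 2L * m)
  allele_cols[, seq(1L, 2L * m, by = 2L)] <- a1
  allele_cols[, seq(2L, 2L * m, by = 2L)] <- a2
  ped <- cbind("FAM1", geno$sample_ids, "0", "0", "0", "-9", allele_cols)
  utils::write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  cp <- geno$chrom_pos %||%
    tibble(marker_id = geno$marker_ids, chrom = "0",
           pos = seq_len(m))
  utils::write.table(
    data.frame(cp$chrom, cp$marker_id, 0, cp$pos),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(ped_path)
}

#' Read a phenotype table from CSV
#'
#' The file must contain a sample-id column (first column, or one named
#' `sample_id`) and one or more trait columns. Lines starting with `#` are
#' treated as metadata comments (as written by [export_simulation()]). Each
#' requested trait is tagged `continuous` or `discrete`: a trait is discrete
#' when its distinct non-missing values are integer- or string-coded and
#' number at most `max_discrete_levels`. Missing phenotype values are kept
#' here and dropped when matching to genotypes.
#'
#' @param path path to the CSV file.
#' @param traits character vector of trait columns to keep; `NULL` keeps all.
#' @param max_discrete_levels class-count limit for discrete detection.
#' @return A `phenotype_table`: a tibble with a `sample_id` column and one
#'   column per trait, with a `trait_types` attribute naming each trait's
#'   type.
#' @export
read_phenotype_csv <- function(path, traits = NULL, max_discrete_levels = 10) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  id_col <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1L]
  df <- dplyr::rename(df, sample_id = dplyr::all_of(id_col))
  df$sample_id <- as.character(df$sample_id)
  available <- setdiff(names(df), "sample_id")
  traits <- traits %||% available
  missing_traits <- setdiff(traits, available)
  if (length(missing_traits) > 0L) {
    abort(sprintf("trait(s) not found: %s. Available traits: %s",
                  paste(missing_traits, collapse = ", "),
                  paste(available, collapse = ", ")))
  }
  out <- dplyr::select(df, "sample_id", dplyr::all_of(traits))
  types <- vapply(traits, function(tr) trait_type(out[[tr]], max_discrete_levels),
                  character(1))
  structure(out, trait_types = types, class = c("phenotype_table", class(out)))
}

# discrete iff all non-missing values are whole numbers or strings with few levels
trait_type <- function(x, max_discrete_levels = 10) {
  v <- x[!is.na(x)]
  if (length(v) == 0L) return("continuous")
  lv <- unique(v)
  integerish <- is.numeric(v) && all(v == round(v))
  stringy <- is.character(v) || is.factor(v) || is.logical(v)
  if ((integerish || stringy) && length(lv) <= max_discrete_levels) "discrete"
  else "continuous"
}

#' Trait types of a phenotype table
#' @param pheno a `phenotype_table` from [read_phenotype_csv()].
#' @return Named character vector, `"continuous"` or `"discrete"` per trait.
#' @export
trait_types <- function(pheno) attr(pheno, "trait_types")
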