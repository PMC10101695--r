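# internal helpers shared across modules

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Deterministic rounding used when turning split fractions into set sizes,
#' so that partition sizes do not depend on banker's rounding.
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
#' @noRd
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# canonicalize a vector of diploid calls: "GA" -> "AG", "A" -> "AA" (optional)
canonicalize_calls <- function(calls, homozygous_shorthand = TRUE) {
  calls <- toupper(trimws(calls))
  one <- nchar(calls) == 1L
  if (any(one)) {
    if (!homozygous_shorthand) {
      abort("single-symbol genotype calls found but `homozygous_shorthand` is FALSE")
    }
    calls[one] <- paste0(calls[one], calls[one])
  }
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  swap <- a1 > a2
  ifelse(swap, paste0(a2, a1), calls)
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# stable sub-seed derivation: keep within 32-bit signed range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% .Machine$integer.max)
}

write_json_file <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
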