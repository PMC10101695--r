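#' Declare a hyperparameter search space
#'
#' A search space is a named list of dimensions built with [param_real()],
#' [param_int()] and [param_cat()]; the optimizer samples assignments from
#' it and models declare one through their contract.
#'
#' @param ... named dimensions.
#' @return An `hp_space`.
#' @export
#' @examples
#' hp_space(strength = param_real(1e-4, 1e2, log = TRUE),
#'          mix = param_real(0.05, 0.95))
hp_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0L) return(structure(list(), class = "hp_space"))
  if (is.null(names(dims)) || any(names(dims) == "")) {
    abort("all search-space dimensions must be named")
  }
  if (anyDuplicated(names(dims))) abort("dimension names must be unique")
  stopifnot(all(vapply(dims, inherits, logical(1), "hp_dim")))
  structure(dims, class = "hp_space")
}

#' @rdname hp_space
#' @param lo,hi bounds with `lo < hi`; log scale requires `lo > 0`.
#' @param log sample on a log scale.
#' @export
param_real <- function(lo, hi, log = FALSE) {
  new_hp_dim("real", lo, hi, log)
}

#' @rdname hp_space
#' @export
param_int <- function(lo, hi, log = FALSE) {
  new_hp_dim("int", lo, hi, log)
}

#' @rdname hp_space
#' @param values vector of categorical levels.
#' @export
param_cat <- function(values) {
  stopifnot(length(values) >= 1L)
  structure(list(kind = "cat", values = values), class = "hp_dim")
}

new_hp_dim <- function(kind, lo, hi, log) {
  if (lo >= hi) abort("`lo` must be < `hi`")
  if (log && lo <= 0) abort("log scale requires lo > 0")
  structure(list(kind = kind, lo = lo, hi = hi, log = log), class = "hp_dim")
}

#' Draw one uniform assignment from a search space
#'
#' Samples every dimension independently (log-uniform where declared) using
#' the current RNG stream — the primitive behind random-search baselines and
#' the TPE's startup phase.
#'
#' @param space an [hp_space()].
#' @return Named list, one value per dimension.
#' @export
hp_sample <- function(space) sample_space(space)

# uniform draw of one assignment (uses the current RNG stream)
sample_space <- function(space) {
  purrr::map(space, function(d) {
    switch(d$kind,
      real = {
        v <- if (d$log) exp(runif(1, log(d$lo), log(d$hi)))
             else runif(1, d$lo, d$hi)
        v
      },
      int = {
        v <- if (d$log) exp(runif(1, log(d$lo), log(d$hi + 1)))
             else runif(1, d$lo, d$hi + 1)
        as.integer(min(floor(v), d$hi))
      },
      cat = d$values[[sample.int(length(d$values), 1L)]]
    )
  })
}

# canonical form for duplicate detection: reals rounded to 6 significant digits
canonical_params <- function(params) {
  paste(vapply(sort(names(params)), function(nm) {
    v <- params[[nm]]
    if (is.numeric(v) && !is.integer(v)) v <- signif(v, 6)
    paste0(nm, "=", format(v, digits = 15))
  }, character(1)), collapse = ";")
}
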