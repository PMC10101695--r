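#' Create a reproducible data split
#'
#' Builds one of three split structures over `n` samples:
#'
#' * `"train-val-test"` — three disjoint sets. The test size is
#'   `round(n * test_frac)` and the validation size `round(remaining *
#'   val_frac)` (both rounded half away from zero); the rest is training.
#' * `"cv-test"` — one held-out test set of size `round(n * test_frac)` plus
#'   `n_folds` cross-validation folds partitioning the remainder.
#' * `"nested-cv"` — `n_outer` outer folds partitioning all samples; within
#'   each outer training part, `n_inner` inner folds.
#'
#' The split is a pure function of `(n, type, parameters, seed)`: indices are
#' obtained by one seeded Mersenne-Twister permutation (R's default RNG,
#' which is stable across platforms) followed by contiguous slicing, so the
#' same inputs regenerate the same split on any machine. For discrete traits
#' a `stratify` factor spreads each class evenly across all slices.
#'
#' @param n number of samples.
#' @param type one of `"train-val-test"`, `"cv-test"`, `"nested-cv"`.
#' @param test_frac test fraction (train-val-test, cv-test).
#' @param val_frac validation fraction of the non-test part (train-val-test).
#' @param n_folds number of CV folds (cv-test).
#' @param n_outer,n_inner outer/inner fold counts (nested-cv).
#' @param seed integer seed driving the permutation.
#' @param stratify optional factor of length `n` for class-stratified slices.
#' @return A `split_indices` object; indices are 1-based row indices into the
#'   matched dataset.
#' @export
make_split <- function(n,
                       type = c("train-val-test", "cv-test", "nested-cv"),
                       test_frac = 0.2, val_frac = 0.25,
                       n_folds = 5L, n_outer = 3L, n_inner = 5L,
                       seed = 42L, stratify = NULL) {
  type <- match.arg(type)
  stopifnot(n >= 2L)
  if (type != "nested-cv" && (test_frac <= 0 || test_frac >= 1)) {
    abort("`test_frac` must lie in (0, 1)")
  }
  perm <- seeded_perm(n, seed, stratify)
  out <- switch(
    type,
    "train-val-test" = {
      if (val_frac <= 0 || val_frac >= 1) abort("`val_frac` must lie in (0, 1)")
      n_test <- round_half_away(n * test_frac)
      n_val <- round_half_away((n - n_test) * val_frac)
      n_train <- n - n_test - n_val
      if (min(n_test, n_val, n_train) < 1L) abort("split produces an empty partition")
      list(params = list(test_frac = test_frac, val_frac = val_frac),
           test = sort(perm[seq_len(n_test)]),
           val = sort(perm[n_test + seq_len(n_val)]),
           train = sort(perm[(n_test + n_val) + seq_len(n_train)]))
    },
    "cv-test" = {
      if (n_folds < 2L) abort("`n_folds` must be >= 2")
      n_test <- round_half_away(n * test_frac)
      rest <- perm[-seq_len(n_test)]
      if (n_test < 1L || length(rest) < n_folds) abort("split produces an empty partition")
      list(params = list(test_frac = test_frac, n_folds = as.integer(n_folds)),
           test = sort(perm[seq_len(n_test)]),
           folds = chunk_indices(rest, n_folds))
    },
    "nested-cv" = {
      if (n_outer < 2L || n_inner < 2L) abort("`n_outer` and `n_inner` must be >= 2")
      if (n < n_outer * n_inner) abort("split produces an empty partition")
      outer_folds <- chunk_indices(perm, n_outer)
      outer <- lapply(seq_len(n_outer), function(o) {
        train_part <- sort(unlist(outer_folds[-o], use.names = FALSE))
        # re-permute the outer training part so inner folds are not nested
        # copies of the outer slicing
        inner_perm <- train_part[seeded_perm(length(train_part), derive_seed(seed, o),
                                             stratify[train_part])]
        list(test = outer_folds[[o]], inner = chunk_indices(inner_perm, n_inner))
      })
      list(params = list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner)),
           outer = outer)
    }
  )
  structure(c(list(type = type, n = as.integer(n), seed = as.integer(seed)), out),
            class = "split_indices")
}

# evenly spread a stratification factor along the permutation: each class is
# shuffled, placed at fractional positions (i - 0.5)/n_c, and the global order
# sorts by position
seeded_perm <- function(n, seed, stratify = NULL) {
  with_seed(as.integer(seed), {
    if (is.null(stratify)) {
      sample.int(n)
    } else {
      stopifnot(length(stratify) == n)
      cls <- as.factor(stratify)
      pos <- numeric(n)
      ord_within <- sample.int(n)  # shuffles order within class deterministically
      for (lv in levels(cls)) {
        members <- which(cls == lv)
        members <- members[order(match(members, ord_within))]
        pos[members] <- (seq_along(members) - 0.5) / length(members)
      }
      order(pos, match(seq_len(n), ord_within))
    }
  })
}

# split a vector into k near-equal contiguous chunks (each sorted)
chunk_indices <- function(idx, k) {
  bounds <- round(seq(0, length(idx), length.out = k + 1))
  lapply(seq_len(k), function(i) sort(idx[(bounds[i] + 1):bounds[i + 1]]))
}

#' @exportS3Method base::print
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> %s, n = %d, seed = %d\n", x$type, x$n, x$seed))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy view of a split
#'
#' @param x a `split_indices`.
#' @param ... unused.
#' @return A tibble with columns `row`, `role` and (where applicable) `fold`
#'   / `outer_fold`.
#' @export
as_tibble.split_indices <- function(x, ...) {
  switch(
    x$type,
    "train-val-test" = dplyr::bind_rows(
      tibble(row = x$train, role = "train"),
      tibble(row = x$val, role = "val"),
      tibble(row = x$test, role = "test")
    ),
    "cv-test" = dplyr::bind_rows(
      tibble(row = x$test, role = "test", fold = NA_integer_),
      purrr::map_dfr(seq_along(x$folds), function(i)
        tibble(row = x$folds[[i]], role = "fold", fold = i))
    ),
    "nested-cv" = purrr::map_dfr(seq_along(x$outer), function(o) {
      dplyr::bind_rows(
        tibble(row = x$outer[[o]]$test, role = "outer-test",
               outer_fold = o, fold = NA_integer_),
        purrr::map_dfr(seq_along(x$outer[[o]]$inner), function(i)
          tibble(row = x$outer[[o]]$inner[[i]], role = "inner-fold",
                 outer_fold = o, fold = i))
      )
    })
  ) |> dplyr::arrange(.data$row)
}

# canonical parameter string used as the persistence key component
split_param_string <- function(split) {
  paste(names(split$params), unlist(split$params), sep = "", collapse = "_")
}

#' Key identifying a split inside a store's index group
#' @param split a `split_indices`.
#' @return Relative key string, e.g.
#'   `"datasplit/cv-test/test_frac0.2_n_folds5/seed_42.json"`.
#' @export
split_key <- function(split) {
  file.path("datasplit", split$type, split_param_string(split),
            paste0("seed_", split$seed, ".json"))
}

#' Persist split indices into a unified store
#'
#' Writes the index sets under `index/datasplit/<type>/<params>/<seed>` in
#' the store. Persisting the identical split again is a verified no-op;
#' persisting different indices under an existing key is a corruption error.
#'
#' @param store a `unified_store`.
#' @param split a `split_indices`.
#' @return The stored key, invisibly.
#' @export
persist_split <- function(store, split) {
  stopifnot(inherits(store, "unified_store"), inherits(split, "split_indices"))
  key <- split_key(split)
  write_index_record(store, key, split_record(split))
  invisible(key)
}

# canonical serialization of a split's index sets
split_record <- function(split) {
  list(
    type = split$type, params = split$params, seed = split$seed, n = split$n,
    index_base = 1L,
    indices = switch(split$type,
      "train-val-test" = list(train = split$train, val = split$val, test = split$test),
      "cv-test" = list(test = split$test, folds = split$folds),
      "nested-cv" = list(outer = lapply(split$outer, function(o)
        list(test = o$test, inner = o$inner)))
    )
  )
}

#' Load a persisted split from a store
#'
#' The stored indices are cross-checked against a regeneration from the
#' stored `(type, params, seed, n)`; a mismatch (e.g. a tampered file) is an
#' error.
#'
#' @param store a `unified_store`.
#' @param key relative key as returned by [persist_split()] / [split_key()].
#' @return A `split_indices`.
#' @export
load_split <- function(store, key) {
  path <- file.path(store$path, "index", key)
  if (!file.exists(path)) abort(sprintf("no persisted split at key '%s'", key))
  rec <- read_json_file(path)
  regenerated <- do.call(make_split, c(
    list(n = rec$n, type = rec$type, seed = rec$seed), rec$params
  ))
  # compare the stored bytes against a canonical re-serialization of the
  # regenerated split: any tampering with the stored indices shows up
  fresh_path <- tempfile(fileext = ".json")
  write_json_file(split_record(regenerated), fresh_path)
  if (!identical(readLines(path, warn = FALSE), readLines(fresh_path, warn = FALSE))) {
    abort(sprintf("stored indices at '%s' do not match regeneration from (type, params, seed, n); store may be corrupted", key))
  }
  regenerated
}

#' Check the partition contract of a split
#'
#' Verifies that within every fold context the index sets are pairwise
#' disjoint and their union covers `1..n`, and that test indices never occur
#' in any training or validation set.
#'
#' @param split a `split_indices`.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_split <- function(split) {
  all_rows <- seq_len(split$n)
  check_partition <- function(sets) {
    u <- unlist(sets, use.names = FALSE)
    if (anyDuplicated(u)) abort("split sets overlap")
    if (!setequal(u, all_rows)) abort("split sets do not cover all rows")
  }
  switch(split$type,
    "train-val-test" = check_partition(list(split$train, split$val, split$test)),
    "cv-test" = check_partition(c(list(split$test), split$folds)),
    "nested-cv" = {
      check_partition(lapply(split$outer, `[[`, "test"))
      for (o in split$outer) {
        u <- unlist(o$inner, use.names = FALSE)
        if (anyDuplicated(u)) abort("inner folds overlap")
        if (length(intersect(u, o$test)) > 0L) abort("outer test leaks into inner folds")
        if (!setequal(u, setdiff(all_rows, o$test))) abort("inner folds do not cover outer training part")
      }
    }
  )
  invisible(TRUE)
}
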