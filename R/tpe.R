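# Tree-structured Parzen estimator (TPE) suggester.
#
# Sequential model-based optimization: completed trials are split into a
# "good" fraction (best gamma share by objective) and the rest; each
# dimension gets a kernel-density (or categorical-count) model for both
# groups, `n_candidates` assignments are sampled from the good model and the
# one maximizing the density ratio l(x)/g(x) (equivalent to expected
# improvement under the TPE derivation) is suggested. Suggestions depend
# only on the trial history and the caller's RNG stream, so a single
# set.seed() upstream makes the whole search deterministic.

tpe_defaults <- function() {
  list(n_startup = 10L, gamma = 0.25, n_candidates = 24L, uniform_weight = 0.05)
}

# history: list of list(params = <assignment>, objective = <numeric>)
# (minimization orientation; callers flip sign for maximized metrics)
tpe_suggest <- function(space, history, opts = tpe_defaults()) {
  completed <- purrr::keep(history, ~ is.finite(.x$objective))
  if (length(completed) < opts$n_startup) {
    return(sample_space(space))
  }
  objs <- vapply(completed, `[[`, numeric(1), "objective")
  ord <- order(objs)
  n_good <- max(2L, ceiling(opts$gamma * length(objs)))
  good <- completed[ord[seq_len(n_good)]]
  bad <- completed[ord[-seq_len(n_good)]]
  if (length(bad) < 2L) return(sample_space(space))

  candidates <- replicate(opts$n_candidates,
                          tpe_sample_candidate(space, good, opts),
                          simplify = FALSE)
  scores <- vapply(candidates, function(cand) {
    sum(vapply(names(space), function(nm) {
      d <- space[[nm]]
      log(tpe_density(d, cand[[nm]], good, nm, opts)) -
        log(tpe_density(d, cand[[nm]], bad, nm, opts))
    }, numeric(1)))
  }, numeric(1))
  candidates[[which.max(scores)]]
}

# draw one candidate assignment from the good-group kernel model
tpe_sample_candidate <- function(space, good, opts) {
  out <- list()
  for (nm in names(space)) {
    d <- space[[nm]]
    if (d$kind == "cat") {
      probs <- tpe_cat_probs(d, good, nm)
      out[[nm]] <- d$values[[sample.int(length(d$values), 1L, prob = probs)]]
      next
    }
    kde <- tpe_kde(d, good, nm)
    i <- sample.int(length(kde$points), 1L)
    x <- rnorm(1L, kde$points[i], kde$bw[i])
    out[[nm]] <- tpe_from_internal(d, x)
  }
  out
}

# values of dimension nm across a trial group, on the internal (log?) scale
tpe_numeric_values <- function(d, group, nm) {
  v <- vapply(group, function(tr) as.numeric(tr$params[[nm]]), numeric(1))
  if (isTRUE(d$log)) log(v) else v
}

tpe_internal_bounds <- function(d) {
  if (isTRUE(d$log)) c(log(d$lo), log(d$hi)) else c(d$lo, d$hi)
}

tpe_from_internal <- function(d, x) {
  b <- tpe_internal_bounds(d)
  x <- min(max(x, b[1L]), b[2L])
  v <- if (isTRUE(d$log)) exp(x) else x
  if (d$kind == "int") v <- as.integer(min(max(round(v), d$lo), d$hi))
  v
}

# Parzen estimator with per-component bandwidths set from the distance to the
# neighboring points (the classic TPE heuristic): isolated points get wide
# kernels (exploration), dense clusters get narrow ones, and the bad-group
# density stays sharp where bad points crowd together, which stops a mediocre
# cluster from dominating the density ratio
tpe_kde <- function(d, group, nm) {
  vals <- tpe_numeric_values(d, group, nm)
  b <- tpe_internal_bounds(d)
  width <- b[2L] - b[1L]
  ord <- order(vals)
  x <- vals[ord]
  k <- length(x)
  left <- c(x[1L] - b[1L], diff(x))
  right <- c(diff(x), b[2L] - x[k])
  bw <- pmax(left, right)
  bw <- pmin(pmax(bw, width / min(100, 1 + k)), width)
  list(points = x, bw = bw)
}

# mixture of per-point gaussian kernels plus a small uniform floor
tpe_density <- function(d, value, group, nm, opts) {
  if (d$kind == "cat") {
    probs <- tpe_cat_probs(d, group, nm)
    return(probs[match(list(value), d$values)])
  }
  kde <- tpe_kde(d, group, nm)
  b <- tpe_internal_bounds(d)
  x <- if (isTRUE(d$log)) log(as.numeric(value)) else as.numeric(value)
  kern <- mean(dnorm(x, kde$points, kde$bw))
  (1 - opts$uniform_weight) * kern + opts$uniform_weight / (b[2L] - b[1L])
}

tpe_cat_probs <- function(d, group, nm) {
  counts <- vapply(d$values, function(lv)
    sum(vapply(group, function(tr) identical(tr$params[[nm]], lv), logical(1))),
    numeric(1))
  (counts + 1) / sum(counts + 1)
}

#' Optimize an arbitrary objective with the TPE suggester
#'
#' Runs the sequential tree-structured Parzen estimator against a plain R
#' function — the same suggestion engine used inside
#' [run_optimization()] — which makes the optimizer testable against grid
#' and random-search baselines on cheap surrogate objectives.
#'
#' @param fn objective `function(params)` returning a finite numeric value.
#' @param space an [hp_space()].
#' @param n_trials number of suggested trials.
#' @param seed RNG seed; the trial sequence is deterministic given
#'   `(fn, space, n_trials, seed)`.
#' @param direction `"minimize"` (default) or `"maximize"`.
#' @return List with `trials` (tibble of parameter values and objectives),
#'   `best_params` and `best_value`.
#' @export
tpe_optimize <- function(fn, space, n_trials = 30L, seed = 42L,
                         direction = "minimize") {
  stopifnot(n_trials >= 1L)
  with_seed(as.integer(seed), {
    history <- list()
    rows <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      params <- tpe_suggest(space, history)
      value <- fn(params)
      sign_value <- if (direction == "minimize") value else -value
      history <- c(history, list(list(params = params, objective = sign_value)))
      rows[[t]] <- dplyr::bind_cols(tibble(trial = t, value = value),
                                    as_tibble(params))
    }
    trials <- dplyr::bind_rows(rows)
    best <- if (direction == "minimize") which.min(trials$value) else which.max(trials$value)
    list(trials = trials, best_params = history[[best]]$params,
         best_value = trials$value[best])
  })
}
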