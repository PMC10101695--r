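#' Cross-validated objective for one hyperparameter assignment
#'
#' Fits the model on each fold's training part and scores it on the fold's
#' validation part, reporting per-fold scores and their mean. The default
#' objective is validation MSE (minimized) for continuous traits and the
#' Matthews correlation coefficient (maximized) for discrete traits.
#'
#' @param dataset a `matched_dataset` from [match_samples()].
#' @param split a `split_indices` (`train-val-test` gives a single
#'   validation set; `cv-test` gives one score per fold).
#' @param model registered model name.
#' @param params hyperparameter assignment (empty list for parameter-free
#'   models).
#' @param seed seed forwarded to stochastic model fits.
#' @return List with `fold_scores`, `objective` (mean of fold scores) and
#'   `direction`.
#' @export
cv_objective <- function(dataset, split, model, params = list(), seed = 42L) {
  contract <- get_model(model)
  folds <- fold_sets(split)
  metric <- objective_metric(dataset$trait_type)
  scores <- vapply(folds, function(f) {
    fold_score(dataset, f$train, f$val, contract, params, metric, seed)
  }, numeric(1))
  list(fold_scores = scores, objective = mean(scores), direction = metric$direction)
}

# train/validation index pairs implied by a split (outer fold for nested-cv)
fold_sets <- function(split, outer = NULL) {
  switch(split$type,
    "train-val-test" = list(list(train = split$train, val = split$val)),
    "cv-test" = lapply(seq_along(split$folds), function(i) {
      list(train = sort(unlist(split$folds[-i], use.names = FALSE)),
           val = split$folds[[i]])
    }),
    "nested-cv" = {
      if (is.null(outer)) abort("nested-cv needs an outer fold index")
      inner <- split$outer[[outer]]$inner
      lapply(seq_along(inner), function(i) {
        list(train = sort(unlist(inner[-i], use.names = FALSE)),
             val = inner[[i]])
      })
    }
  )
}

# rows available for the final refit, and the held-out test rows
refit_and_test_rows <- function(split, outer = NULL) {
  switch(split$type,
    "train-val-test" = list(refit = sort(c(split$train, split$val)),
                            test = split$test),
    "cv-test" = list(refit = sort(unlist(split$folds, use.names = FALSE)),
                     test = split$test),
    "nested-cv" = list(
      refit = sort(unlist(split$outer[[outer]]$inner, use.names = FALSE)),
      test = split$outer[[outer]]$test)
  )
}

fold_score <- function(dataset, train, val, contract, params, metric, seed) {
  fit <- fit_model(contract, dataset$X[train, , drop = FALSE], dataset$y[train],
                   params = params, trait_type = dataset$trait_type, seed = seed)
  y_hat <- predict(fit, dataset$X[val, , drop = FALSE])
  # over-penalized trials legitimately predict a constant on some folds;
  # the search objective (MSE / MCC) stays defined, so the degenerate-
  # correlation warning is noise here
  rep <- suppressWarnings(compute_metrics(dataset$y[val], y_hat, dataset$trait_type))
  rep[[metric$name]]
}

#' Median-rule pruning decision
#'
#' A running trial is stopped early when its running-mean validation score
#' after `step` folds is worse than the median of the completed trials'
#' running means at the same step. Pruning never fires at step 1 and never
#' before `warmup` trials have completed, so early trials establish the
#' reference distribution.
#'
#' @param history list of numeric fold-score vectors from completed trials.
#' @param current_scores fold scores of the running trial so far.
#' @param step number of folds evaluated so far (`= length(current_scores)`).
#' @param direction `"minimize"` or `"maximize"`.
#' @param warmup minimum number of completed trials before pruning.
#' @return `TRUE` to prune.
#' @export
prune_decision <- function(history, current_scores, step,
                           direction = "minimize", warmup = 5L) {
  stopifnot(step >= 1L, length(current_scores) == step)
  if (step < 2L || length(history) < warmup) return(FALSE)
  ref <- vapply(history, function(s) {
    if (length(s) < step) NA_real_ else mean(s[seq_len(step)])
  }, numeric(1))
  ref <- ref[is.finite(ref)]
  if (length(ref) < warmup) return(FALSE)
  current <- mean(current_scores)
  if (direction == "minimize") current > median(ref) else current < median(ref)
}

#' Duplicate-assignment guard
#'
#' Detects whether a candidate hyperparameter assignment has already been
#' evaluated, comparing real-valued parameters after rounding to 6
#' significant digits. Duplicates are recorded but not re-evaluated and do
#' not consume the trial budget.
#'
#' @param seen list of previously evaluated assignments.
#' @param candidate assignment to check.
#' @return `TRUE` iff an equivalent assignment was already evaluated.
#' @export
duplicate_guard <- function(seen, candidate) {
  canonical_params(candidate) %in% vapply(seen, canonical_params, character(1))
}

#' Run a full hyperparameter-optimization pipeline for one model
#'
#' For searchable models, a tree-structured Parzen estimator sequentially
#' suggests `n_trials` assignments; each is scored fold by fold with
#' median-rule pruning of unpromising trials and a duplicate guard
#' (duplicate suggestions are re-drawn, up to 10x the budget). The best
#' completed assignment is then refit on the train+validation data and
#' evaluated exactly once on the held-out test set. Parameter-free models
#' skip the search and run a single fit through the same pipeline. For
#' nested cross-validation the whole search is repeated per outer fold and
#' the test metrics are averaged across outer folds.
#'
#' The entire run is deterministic given `(dataset, split, model, n_trials,
#' seed)`.
#'
#' @param dataset a `matched_dataset`.
#' @param split a `split_indices` over the dataset rows.
#' @param model registered model name.
#' @param n_trials search budget (suggested trials, pruned included,
#'   duplicates excluded).
#' @param seed integer seed for suggestion sampling and stochastic fits.
#' @param pruning enable median-rule pruning.
#' @param out_dir optional directory to serialize the run into
#'   (`trials.csv`, `best_params.json`, `test_metrics.json`,
#'   `run_manifest.json`, `final_model/`).
#' @param sampler `"tpe"` (default, adaptive) or `"random"` (pure random
#'   search from per-trial substreams; its suggestion sequence is invariant
#'   to pruning decisions, which makes it the reference for pruning-
#'   soundness checks and for benchmarking the TPE).
#' @return An `optimization_run`: trials tibble, best parameters and
#'   objective, the refit model(s), test predictions and metrics.
#' @export
run_optimization <- function(dataset, split, model, n_trials = 20L, seed = 42L,
                             pruning = TRUE, out_dir = NULL,
                             sampler = c("tpe", "random")) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(dataset, "matched_dataset"), inherits(split, "split_indices"))
  if (n_trials < 1L) abort("`n_trials` must be >= 1")
  contract <- get_model(model)
  if (!dataset$trait_type %in% contract$trait_types) {
    abort(sprintf("model '%s' does not support %s traits", model, dataset$trait_type))
  }
  if (split$n != nrow(dataset$X)) abort("split was made for a different sample count")
  metric <- objective_metric(dataset$trait_type)

  run <- with_seed(as.integer(seed), {
    if (split$type == "nested-cv") {
      per_outer <- lapply(seq_along(split$outer), function(o) {
        search_and_refit(dataset, split, contract, n_trials, metric, pruning,
                         seed, outer = o, sampler = sampler)
      })
      trials <- purrr::map_dfr(seq_along(per_outer), function(o)
        dplyr::mutate(per_outer[[o]]$trials, outer_fold = o, .before = 1L))
      metrics <- purrr::map_dfr(per_outer, "test_metrics") |>
        dplyr::summarise(dplyr::across(where(is.numeric), mean))
      list(trials = trials,
           best_params = lapply(per_outer, `[[`, "best_params"),
           best_objective = mean(vapply(per_outer, `[[`, numeric(1), "best_objective")),
           fit = lapply(per_outer, `[[`, "fit"),
           predictions = purrr::map_dfr(seq_along(per_outer), function(o)
             dplyr::mutate(per_outer[[o]]$predictions, outer_fold = o, .before = 1L)),
           test_metrics = metrics)
    } else {
      search_and_refit(dataset, split, contract, n_trials, metric, pruning,
                       seed, sampler = sampler)
    }
  })

  out <- structure(c(run, list(
    model = model, trait = dataset$trait, trait_type = dataset$trait_type,
    metric = metric, seed = as.integer(seed), n_trials = as.integer(n_trials),
    pruning = pruning,
    split = list(type = split$type, params = split$params, seed = split$seed,
                 n = split$n, key = split_key(split))
  )), class = "optimization_run")
  if (!is.null(out_dir)) serialize_run(out, dataset, out_dir)
  out
}

# one search (or single param-free fit) plus refit + single test evaluation
search_and_refit <- function(dataset, split, contract, n_trials, metric,
                             pruning, seed, outer = NULL, sampler = "tpe") {
  rt <- refit_and_test_rows(split, outer)
  folds <- if (contract$kind == "searchable") fold_sets(split, outer) else NULL

  # no-leakage invariant: nothing fitted before the final evaluation may see
  # a test row
  search_rows <- sort(unique(c(rt$refit, unlist(lapply(folds, unlist)))))
  if (length(intersect(search_rows, rt$test)) > 0L) {
    abort("test rows leak into the search partitions")
  }

  trials <- tibble(
    trial = integer(), state = character(), objective = numeric(),
    pruned_at = integer(), n_folds = integer(),
    fold_scores = character(), params = character()
  )
  best_params <- list()
  best_objective <- NA_real_

  if (contract$kind == "searchable") {
    history <- list()          # for the TPE (sign-flipped to minimize)
    seen <- list()
    completed_scores <- list() # for the pruner
    n_suggested <- 0L
    attempts <- 0L
    max_attempts <- 10L * n_trials
    while (n_suggested < n_trials && attempts < max_attempts) {
      attempts <- attempts + 1L
      # "random" draws each trial from a per-trial substream, so the suggested
      # sequence is invariant to pruning decisions (used by the pruning-
      # soundness check); the TPE adapts to the completed history
      params <- if (sampler == "random") {
        with_seed(derive_seed(seed, 7000L + attempts), sample_space(contract$space))
      } else {
        tpe_suggest(contract$space, history)
      }
      if (duplicate_guard(seen, params)) {
        trials <- dplyr::add_row(trials, trial = NA_integer_, state = "duplicate",
                                 objective = NA_real_, pruned_at = NA_integer_,
                                 n_folds = 0L, fold_scores = "",
                                 params = params_json(params))
        next
      }
      seen <- c(seen, list(params))
      n_suggested <- n_suggested + 1L
      res <- tryCatch(
        evaluate_trial(dataset, folds, contract, params, metric,
                       completed_scores, pruning, seed),
        error = function(e) list(state = "failed", fold_scores = numeric(),
                                 objective = NA_real_, pruned_at = NA_integer_,
                                 message = conditionMessage(e))
      )
      trials <- dplyr::add_row(
        trials, trial = n_suggested, state = res$state,
        objective = res$objective, pruned_at = res$pruned_at,
        n_folds = length(res$fold_scores),
        fold_scores = paste(format(res$fold_scores, digits = 10), collapse = ";"),
        params = params_json(params)
      )
      if (res$state == "completed") {
        completed_scores <- c(completed_scores, list(res$fold_scores))
        sign_obj <- if (metric$direction == "minimize") res$objective else -res$objective
        history <- c(history, list(list(params = params, objective = sign_obj)))
        if (is.na(best_objective) || better_than(res$objective, best_objective, metric$direction)) {
          best_objective <- res$objective
          best_params <- params
        }
      }
    }
    if (!any(trials$state == "completed")) {
      abort(paste0("all trials failed; diagnostics:\n",
                   paste(utils::capture.output(print(trials)), collapse = "\n")))
    }
  }

  fit <- fit_model(contract, dataset$X[rt$refit, , drop = FALSE],
                   dataset$y[rt$refit], params = best_params,
                   trait_type = dataset$trait_type, seed = seed)
  y_hat <- predict(fit, dataset$X[rt$test, , drop = FALSE])
  test_metrics <- compute_metrics(dataset$y[rt$test], y_hat, dataset$trait_type)
  list(
    trials = trials, best_params = best_params, best_objective = best_objective,
    fit = fit, refit_rows = rt$refit, test_rows = rt$test,
    predictions = tibble(sample_id = dataset$sample_ids[rt$test],
                         y = as.vector(dataset$y[rt$test]),
                         y_hat = as.vector(y_hat)),
    test_metrics = test_metrics
  )
}

evaluate_trial <- function(dataset, folds, contract, params, metric,
                           completed_scores, pruning, seed) {
  scores <- numeric(0)
  for (k in seq_along(folds)) {
    scores[k] <- fold_score(dataset, folds[[k]]$train, folds[[k]]$val,
                            contract, params, metric, seed)
    if (pruning && k < length(folds) &&
        prune_decision(completed_scores, scores, k, metric$direction)) {
      return(list(state = "pruned", fold_scores = scores, objective = NA_real_,
                  pruned_at = k))
    }
  }
  list(state = "completed", fold_scores = scores, objective = mean(scores),
       pruned_at = NA_integer_)
}

better_than <- function(a, b, direction) {
  if (direction == "minimize") a < b else a > b
}

params_json <- function(params) {
  as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA))
}

#' @exportS3Method base::print
print.optimization_run <- function(x, ...) {
  cat(sprintf("<optimization_run> model '%s' on trait '%s' (%s split)\n",
              x$model, x$trait, x$split$type))
  n_comp <- sum(x$trials$state == "completed")
  cat(sprintf("  %d trials recorded (%d completed, %d pruned), objective %s (%s)\n",
              nrow(x$trials), n_comp, sum(x$trials$state == "pruned"),
              x$metric$name, x$metric$direction))
  cat("  test metrics: ",
      paste(names(x$test_metrics)[vapply(x$test_metrics, is.numeric, logical(1))],
            signif(unlist(x$test_metrics[vapply(x$test_metrics, is.numeric, logical(1))]), 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the trial table of an optimization run
#' @param x an `optimization_run`.
#' @param ... unused.
#' @return The trials tibble.
#' @export
tidy.optimization_run <- function(x, ...) x$trials

#' One-row summary of an optimization run
#' @param x an `optimization_run`.
#' @param ... unused.
#' @return Tibble with model, trait, split, trial counts, best objective and
#'   test metrics.
#' @export
glance.optimization_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(model = x$model, trait = x$trait, trait_type = x$trait_type,
           split_type = x$split$type, split_seed = x$split$seed,
           seed = x$seed,
           n_trials = nrow(x$trials),
           n_completed = sum(x$trials$state == "completed"),
           n_pruned = sum(x$trials$state == "pruned"),
           best_objective = x$best_objective %||% NA_real_),
    dplyr::rename_with(x$test_metrics, ~ paste0("test_", .x))
  )
}

#' Trial-history plot for an optimization run
#' @param object an `optimization_run`.
#' @param ... unused.
#' @return A ggplot: objective value per trial, colored by trial state, with
#'   the running best overlaid.
#' @export
autoplot.optimization_run <- function(object, ...) {
  df <- dplyr::filter(object$trials, !is.na(.data$trial))
  comp <- dplyr::filter(df, .data$state == "completed")
  minimize <- object$metric$direction == "minimize"
  comp <- dplyr::mutate(comp, best = if (minimize) cummin(.data$objective)
                                     else cummax(.data$objective))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$objective)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$state), na.rm = TRUE) +
    ggplot2::geom_step(data = comp, ggplot2::aes(y = .data$best),
                       linetype = "dashed") +
    ggplot2::labs(x = "trial", y = object$metric$name,
                  title = sprintf("%s on '%s'", object$model, object$trait)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
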