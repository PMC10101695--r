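# Run-directory serialization and re-application of fitted models.
#
# A run directory is fully text-based:
#   trials.csv        all trials with states and fold scores
#   best_params.json  best assignment (per outer fold for nested-cv)
#   test_metrics.json held-out metrics
#   run_manifest.json inputs, seeds, split key, trial counts
#   predictions.csv   held-out predictions
#   final_model/model.json + final_model/effects.csv
#     enough metadata (marker ids, minor-allele polarity, training column
#     means, coefficients) to re-encode and predict new genotype data.

serialize_run <- function(run, dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$trials, file.path(out_dir, "trials.csv"), progress = FALSE)
  write_json_file(run$best_params, file.path(out_dir, "best_params.json"))
  write_json_file(as.list(run$test_metrics), file.path(out_dir, "test_metrics.json"))
  readr::write_csv(run$predictions, file.path(out_dir, "predictions.csv"),
                   progress = FALSE)
  manifest <- list(
    model = run$model, trait = run$trait, trait_type = run$trait_type,
    objective = run$metric, seed = run$seed, n_trials = run$n_trials,
    pruning = run$pruning, split = run$split,
    n_samples = nrow(dataset$X), n_features = ncol(dataset$X),
    encoding = dataset$encoding,
    n_trials_recorded = nrow(run$trials),
    n_completed = sum(run$trials$state == "completed"),
    n_pruned = sum(run$trials$state == "pruned"),
    best_objective = if (is.finite(run$best_objective %||% NA_real_))
      run$best_objective
  )
  # parameter-free runs have no search objective; drop the field entirely
  write_json_file(purrr::compact(manifest), file.path(out_dir, "run_manifest.json"))
  # nested-cv keeps one fit per outer fold; serialize the first outer fit as
  # the representative applicable model
  fit <- if (run$split$type == "nested-cv") run$fit[[1L]] else run$fit
  params <- if (run$split$type == "nested-cv") run$best_params[[1L]] else run$best_params
  serialize_final_model(fit, dataset, params, file.path(out_dir, "final_model"))
  invisible(out_dir)
}

serialize_final_model <- function(fit, dataset, params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    model_class = class(fit)[1L], trait_type = dataset$trait_type,
    encoding = dataset$encoding, params = params,
    markers = names(dataset$minor_allele),
    minor_allele = as.list(dataset$minor_allele)
  )
  if (inherits(fit, "rrblup_fit") || inherits(fit, "bayes_fit")) {
    meta$mu <- fit$mu
    meta$col_means <- as.numeric(fit$col_means)
    eff <- tibble(feature = colnames(dataset$X), effect = as.numeric(fit$u))
  } else if (inherits(fit, "penalized_fit")) {
    meta$intercept <- as.numeric(fit$intercept)
    meta$family <- fit$family
    meta$classes <- fit$classes
    eff <- as_tibble(as.data.frame(fit$beta))
    names(eff) <- if (fit$family == "multinomial") paste0("effect_", fit$classes)
                  else "effect"
    eff <- dplyr::bind_cols(tibble(feature = colnames(dataset$X)), eff)
  } else {
    abort(sprintf("model class '%s' cannot be serialized to a run directory",
                  class(fit)[1L]))
  }
  write_json_file(meta, file.path(dir, "model.json"))
  readr::write_csv(eff, file.path(dir, "effects.csv"), progress = FALSE)
  invisible(dir)
}

#' Apply a previously optimized model to new genotype data
#'
#' Loads the final model serialized in a run directory, re-encodes the new
#' genotypes with the stored minor-allele polarity (the marker set and
#' polarity must match training), centers dosages with the stored training
#' column means where the model requires it, and predicts.
#'
#' @param run_dir a run directory written by [run_optimization()].
#' @param new_genotype a [raw_genotype()] covering all training markers.
#' @return Tibble with `sample_id` and `prediction`.
#' @export
apply_final_model <- function(run_dir, new_genotype) {
  meta_path <- file.path(run_dir, "final_model", "model.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("'%s' does not contain a serialized final model", run_dir))
  }
  meta <- read_json_file(meta_path)
  if (meta$encoding != "additive_012") {
    abort("re-application is supported for the additive_012 encoding only")
  }
  eff <- readr::read_csv(file.path(run_dir, "final_model", "effects.csv"),
                         show_col_types = FALSE, progress = FALSE)
  minor <- unlist(meta$minor_allele)
  Z <- encode_additive_with_polarity(new_genotype, minor)
  pred <- switch(meta$model_class,
    rrblup_fit = ,
    bayes_fit = {
      as.numeric(meta$mu +
        sweep(Z, 2L, as.numeric(meta$col_means)) %*% eff$effect)
    },
    penalized_fit = {
      if (meta$family == "gaussian") {
        as.numeric(meta$intercept + Z %*% eff$effect)
      } else if (meta$family == "binomial") {
        eta <- meta$intercept + Z %*% eff$effect
        unlist(meta$classes)[1L + as.integer(eta > 0)]
      } else {
        beta <- as.matrix(eff[, paste0("effect_", unlist(meta$classes))])
        eta <- sweep(Z %*% beta, 2L, -as.numeric(meta$intercept))
        unlist(meta$classes)[max.col(eta, ties.method = "first")]
      }
    },
    abort(sprintf("unsupported serialized model class '%s'", meta$model_class))
  )
  tibble(sample_id = new_genotype$sample_ids, prediction = pred)
}
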