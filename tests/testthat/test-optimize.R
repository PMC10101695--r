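make_ds <- function(n = 60, m = 25, h2 = 0.6, seed = 1) {
  g <- simulate_genotypes(n, m, seed = seed)
  sim <- simulate_phenotype(g, n_causal = 5, h2 = h2, seed = seed + 1)
  match_samples(encode_additive(g), sim$phenotype, "sim_trait")
}

test_that("cv objective reports one score per fold and their exact mean", {
  ds <- make_ds()
  sp <- make_split(60, "cv-test", n_folds = 5, seed = 2)
  res <- cv_objective(ds, sp, "linreg-l2", list(strength = 0.5))
  expect_length(res$fold_scores, 5L)
  expect_equal(res$objective, mean(res$fold_scores))
  expect_equal(res$direction, "minimize")

  sp_tvt <- make_split(60, "train-val-test", seed = 2)
  res2 <- cv_objective(ds, sp_tvt, "linreg-l2", list(strength = 0.5))
  expect_length(res2$fold_scores, 1L)
})

test_that("median-rule pruning honours warm-up, step-1 and the median comparison", {
  history <- lapply(list(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(5, 5)), identity)
  # no pruning before 5 completed trials
  expect_false(prune_decision(history[1:4], c(4.5, 4.5), 2))
  # never prunes at step 1
  expect_false(prune_decision(history, 100, 1))
  # running mean 4.5 vs median of {1..5} = 3 -> prune when minimizing
  expect_true(prune_decision(history, c(4.5, 4.5), 2))
  expect_false(prune_decision(history, c(2.0, 2.0), 2))
  # direction flips the comparison
  expect_false(prune_decision(history, c(4.5, 4.5), 2, direction = "maximize"))
  expect_true(prune_decision(history, c(2.0, 2.0), 2, direction = "maximize"))
})

test_that("duplicate detection rounds reals to 6 significant digits", {
  seen <- list(list(a = 1L, b = "x", c = 0.123456789))
  expect_true(duplicate_guard(seen, list(a = 1L, b = "x", c = 0.123456789 + 1e-12)))
  expect_false(duplicate_guard(seen, list(a = 1L, b = "y", c = 0.123456789)))
  expect_false(duplicate_guard(seen, list(a = 2L, b = "x", c = 0.123456789)))
  expect_true(duplicate_guard(seen, list(c = 0.123457, b = "x", a = 1L)))  # order-free
})

test_that("optimization runs are deterministic given the seed", {
  ds <- make_ds()
  sp <- make_split(60, "cv-test", n_folds = 4, seed = 2)
  a <- run_optimization(ds, sp, "linreg-l2", n_trials = 8, seed = 7)
  b <- run_optimization(ds, sp, "linreg-l2", n_trials = 8, seed = 7)
  expect_identical(a$trials, b$trials)
  expect_identical(a$best_params, b$best_params)
  expect_identical(a$test_metrics, b$test_metrics)
  c <- run_optimization(ds, sp, "linreg-l2", n_trials = 8, seed = 8)
  expect_false(identical(a$trials$params, c$trials$params))
})

test_that("pruning only removes trials, never changes completed objectives", {
  ds <- make_ds(seed = 5)
  sp <- make_split(60, "cv-test", n_folds = 5, seed = 3)
  # the random sampler's suggestion sequence is invariant to pruning, so the
  # two runs evaluate identical parameters trial by trial
  on_ <- run_optimization(ds, sp, "linreg-l2", n_trials = 15, seed = 9,
                          pruning = TRUE, sampler = "random")
  off <- run_optimization(ds, sp, "linreg-l2", n_trials = 15, seed = 9,
                          pruning = FALSE, sampler = "random")
  expect_identical(on_$trials$params, off$trials$params)
  comp_on <- dplyr::filter(on_$trials, state == "completed")
  comp_off <- dplyr::filter(off$trials, state == "completed")
  expect_true(any(on_$trials$state == "pruned"))
  expect_gte(nrow(comp_off), nrow(comp_on))
  # per trial id, a trial completed under pruning has the same objective
  merged <- dplyr::inner_join(comp_on, comp_off, by = "trial")
  expect_equal(merged$objective.x, merged$objective.y)
})

test_that("failed trials are logged and the search continues", {
  register_model("sometimes-fails", list(
    kind = "searchable", trait_types = "continuous",
    default_encoding = "additive_012", allowed_encodings = "additive_012",
    space = hp_space(strength = param_real(0, 1)),
    fit = function(X, y, params, trait_type, seed) {
      if (params$strength > 0.5) stop("unstable region")
      regularized_linear_fit(X, y, "l2", strength = params$strength + 0.01)
    }
  ), overwrite = TRUE)
  ds <- make_ds(seed = 8)
  sp <- make_split(60, "cv-test", n_folds = 3, seed = 4)
  run <- run_optimization(ds, sp, "sometimes-fails", n_trials = 12, seed = 10)
  expect_true(any(run$trials$state == "failed"))
  expect_true(any(run$trials$state == "completed"))
  expect_true(is.finite(run$test_metrics$mse))
  expect_lte(run$best_params$strength, 0.5)
})

test_that("the test set never intersects search or refit partitions", {
  ds <- make_ds(seed = 11)
  for (type in c("train-val-test", "cv-test")) {
    sp <- make_split(60, type, seed = 6)
    run <- run_optimization(ds, sp, "linreg-l2", n_trials = 6, seed = 12)
    expect_length(intersect(run$refit_rows, run$test_rows), 0L)
    folds <- gselect:::fold_sets(sp)
    for (f in folds) {
      expect_length(intersect(f$train, run$test_rows), 0L)
      expect_length(intersect(f$val, run$test_rows), 0L)
    }
  }
})

test_that("nested cross-validation searches per outer fold and averages test metrics", {
  ds <- make_ds(seed = 13)
  sp <- make_split(60, "nested-cv", n_outer = 3, n_inner = 2, seed = 6)
  run <- run_optimization(ds, sp, "linreg-l2", n_trials = 5, seed = 14)
  expect_equal(sort(unique(run$trials$outer_fold)), 1:3)
  expect_length(run$best_params, 3L)
  expect_equal(nrow(run$predictions), 60L)  # every sample predicted once as outer test
  expect_true(is.finite(run$test_metrics$mse))
})

test_that("serialized runs can be re-applied to new genotype data", {
  g <- simulate_genotypes(50, 20, seed = 21)
  sim <- simulate_phenotype(g, n_causal = 4, h2 = 0.7, seed = 22)
  ds <- match_samples(encode_additive(g), sim$phenotype, "sim_trait")
  sp <- make_split(50, "cv-test", n_folds = 3, seed = 23)
  dir <- tempfile()
  run <- run_optimization(ds, sp, "rrblup", seed = 24, out_dir = dir)
  expect_true(file.exists(file.path(dir, "run_manifest.json")))
  expect_true(file.exists(file.path(dir, "final_model", "model.json")))

  # applying to the training genotypes reproduces the fit's predictions
  preds <- apply_final_model(dir, g)
  expect_equal(preds$prediction, unname(predict(run$fit, ds$X)), tolerance = 1e-8)

  # a missing training marker is named in the error
  g_missing <- raw_genotype(g$calls[, -3], g$sample_ids, g$marker_ids[-3])
  expect_error(apply_final_model(dir, g_missing), g$marker_ids[3])
})

test_that("the TPE suggester beats its startup phase on a smooth surrogate", {
  space <- hp_space(x = param_real(0, 10))
  res <- tpe_optimize(function(p) (p$x - 7.3)^2, space, n_trials = 30, seed = 2)
  startup_best <- min(res$trials$value[1:10])
  expect_lte(res$best_value, startup_best)
  res2 <- tpe_optimize(function(p) (p$x - 7.3)^2, space, n_trials = 30, seed = 2)
  expect_identical(res$trials, res2$trials)
})
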