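run_grid <- function(root, traits = c("t1", "t2"), models = c("rrblup", "linreg-l2"),
                     seed = 1) {
  g <- simulate_genotypes(50, 15, seed = seed)
  enc <- encode_additive(g)
  for (i in seq_along(traits)) {
    sim <- simulate_phenotype(g, n_causal = 3, h2 = 0.6, seed = seed + i,
                              trait_name = traits[i])
    ds <- match_samples(enc, sim$phenotype, traits[i])
    sp <- make_split(50, "cv-test", n_folds = 3, seed = seed)
    for (mod in models) {
      run_optimization(ds, sp, mod, n_trials = 4, seed = seed,
                       out_dir = file.path(root, traits[i], "split", mod,
                                           paste0("run-", seed)))
    }
  }
  root
}

test_that("run summaries have one deterministic row per run", {
  root <- run_grid(tempfile())
  csv1 <- tempfile(fileext = ".csv")
  sm <- summarize_runs(root, out_csv = csv1)
  expect_equal(nrow(sm), 4L)   # 2 traits x 2 models
  expect_setequal(sm$model, c("rrblup", "linreg-l2"))
  expect_setequal(sm$trait, c("t1", "t2"))
  expect_true(all(is.finite(sm$test_mse)))

  csv2 <- tempfile(fileext = ".csv")
  summarize_runs(root, out_csv = csv2)
  expect_identical(readLines(csv1), readLines(csv2))   # byte-identical re-run

  expect_error(summarize_runs(tempfile()), "no runs found")
})

test_that("malformed run directories become warning rows, not failures", {
  root <- run_grid(tempfile(), traits = "t1")
  bad <- file.path(root, "t1", "split", "broken", "run-1")
  dir.create(bad, recursive = TRUE)
  writeLines("{not json", file.path(bad, "run_manifest.json"))
  sm <- suppressWarnings(summarize_runs(root))
  expect_equal(sum(sm$status == "ok"), 2L)
  expect_equal(sum(sm$status == "malformed"), 1L)
})

test_that("heat-map tables pivot models by phenotypes with explicit missing cells", {
  root <- run_grid(tempfile())
  sm <- summarize_runs(root)
  tab <- heatmap_table(sm, "mse")
  expect_equal(dim(tab), c(2L, 3L))   # model column + 2 traits
  # cells equal the corresponding summary rows
  for (i in seq_len(nrow(sm))) {
    expect_equal(tab[[sm$trait[i]]][tab$model == sm$model[i]], sm$test_mse[i])
  }
  # drop one combination -> explicit NA, not zero
  sm_miss <- dplyr::filter(sm, !(model == "rrblup" & trait == "t2"))
  tab_miss <- heatmap_table(sm_miss, "mse")
  expect_true(is.na(tab_miss$t2[tab_miss$model == "rrblup"]))
  expect_error(heatmap_table(sm, "made-up-metric"), "unknown metric")
  expect_s3_class(plot_heatmap(sm, "mse"), "ggplot")
})

test_that("effect-size/importance pairing reports rank correlations", {
  g <- simulate_genotypes(80, 40, seed = 31)
  sim <- simulate_phenotype(g, n_causal = 5, h2 = 0.8, seed = 32)
  perfect <- tibble::tibble(marker_id = names(sim$beta),
                            importance = abs(unname(sim$beta)))
  tab <- effectsize_vs_importance(sim, perfect)
  expect_equal(attr(tab, "rank_correlation"), 1)
  expect_equal(sum(tab$causal), 5L)
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")

  # random permutations of the importances decorrelate the ranks
  set.seed(33)
  rcs <- replicate(20, {
    shuffled <- perfect
    shuffled$importance <- sample(shuffled$importance)
    attr(effectsize_vs_importance(sim, shuffled), "rank_correlation")
  })
  expect_lt(abs(mean(rcs)), 0.15)

  wrong <- dplyr::mutate(perfect, marker_id = paste0("x", marker_id))
  expect_error(effectsize_vs_importance(sim, wrong), "do not match")
})

test_that("model importances recover simulated causal architecture directionally", {
  rcs <- vapply(1:5, function(s) {
    g <- simulate_genotypes(120, 60, seed = 40 + s)
    sim <- simulate_phenotype(g, n_causal = 5, h2 = 0.8, seed = 50 + s)
    fit <- rrblup_fit(encode_additive(g)$matrix, sim$y)
    attr(effectsize_vs_importance(sim, feature_importance(fit)),
         "rank_correlation")
  }, numeric(1))
  expect_gt(median(rcs), 0)
})
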