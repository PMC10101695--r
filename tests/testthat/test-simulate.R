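test_that("simulated genotypes follow Hardy-Weinberg with the requested MAF", {
  g <- simulate_genotypes(2000, 20, maf_range = c(0.4999, 0.5), seed = 1)
  het <- vapply(seq_len(20), function(j) {
    calls <- g$calls[, j]
    mean(substr(calls, 1, 1) != substr(calls, 2, 2))
  }, numeric(1))
  expect_equal(mean(het), 0.5, tolerance = 0.02)   # 2pq = 0.5 at p = 0.5

  g2 <- simulate_genotypes(2000, 50, maf_range = c(0.2, 0.3), seed = 2)
  maf <- compute_maf(g2)
  expect_true(all(maf > 0.2 - 0.05 & maf < 0.3 + 0.05))

  expect_identical(simulate_genotypes(30, 10, seed = 9)$calls,
                   simulate_genotypes(30, 10, seed = 9)$calls)
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
})

test_that("realized heritability concentrates at the target", {
  g <- simulate_genotypes(1000, 200, seed = 3)
  sim <- simulate_phenotype(g, n_causal = 20, h2 = 0.5, seed = 4)
  expect_equal(sim$realized_h2, 0.5, tolerance = 0.05)
  expect_equal(var(sim$g) / var(sim$y_continuous), sim$realized_h2)
  # stored parts reconstruct the phenotype exactly
  expect_equal(sim$g + (sim$y_continuous - sim$g), sim$y_continuous)
})

test_that("degenerate simulation settings behave as constructed", {
  g <- simulate_genotypes(300, 50, seed = 5)
  # h2 = 0: pure noise, no genetic signal
  sim0 <- simulate_phenotype(g, n_causal = 5, h2 = 0, seed = 6)
  expect_equal(sim0$realized_h2, 0)
  expect_equal(var(sim0$g), 0)
  # single equal-effect marker: genetic value is that marker's centered dosage
  sim1 <- simulate_phenotype(g, n_causal = 1, h2 = 0.5,
                             effect_distribution = "equal", seed = 7)
  Z <- encode_additive(g)$matrix
  dosage <- Z[, sim1$causal_markers]
  expect_equal(abs(cor(sim1$g, dosage)), 1)
  # no genetic variance to scale
  expect_error(simulate_phenotype(g, n_causal = 0, h2 = 0.5, seed = 8),
               "no genetic variance")
})

test_that("noise options and discretization keep the stated construction", {
  g <- simulate_genotypes(1500, 100, seed = 9)
  sim_g <- simulate_phenotype(g, n_causal = 10, h2 = 0.4,
                              noise_distribution = "gamma", seed = 10)
  expect_equal(sim_g$realized_h2, 0.4, tolerance = 0.06)
  eps <- sim_g$y_continuous - sim_g$g
  expect_gt(mean(((eps - mean(eps)) / sd(eps))^3), 0.5)   # right-skewed noise
  expect_lt(abs(mean(eps)), sd(eps) * 0.1)                # mean-centered

  sim_d <- simulate_phenotype(g, n_causal = 10, h2 = 0.5, n_classes = 2, seed = 11)
  expect_s3_class(sim_d$y, "factor")
  expect_equal(unname(table(sim_d$y))[1], 750L, tolerance = 1)  # median split

  sim_bg <- simulate_phenotype(g, n_causal = 0, h2 = 0.3,
                               include_background = TRUE, seed = 12)
  expect_equal(sim_bg$realized_h2, 0.3, tolerance = 0.06)
})

test_that("exported simulations round-trip and embed their own recipe", {
  g <- simulate_genotypes(60, 30, seed = 13)
  sim <- simulate_phenotype(g, n_causal = 4, h2 = 0.6, seed = 14)
  dir <- tempfile()
  files <- export_simulation(sim, dir)
  ph <- read_phenotype_csv(files$phenotype)
  expect_equal(ph$sim_trait, unname(sim$y_continuous))
  expect_equal(unname(trait_types(ph)), "continuous")

  truth <- readr::read_csv(files$ground_truth, comment = "#",
                           show_col_types = FALSE)
  expect_equal(nrow(truth), 30L)
  expect_equal(truth$beta, unname(sim$beta))

  # the embedded config + seed regenerates the identical phenotype
  meta <- jsonlite::fromJSON(sub("^# ", "", readLines(files$phenotype, n = 1)))
  sim2 <- simulate_phenotype(g, n_causal = meta$n_causal, h2 = meta$h2,
                             effect_distribution = meta$effect_distribution,
                             include_background = meta$include_background,
                             noise_distribution = meta$noise_distribution,
                             seed = meta$seed)
  expect_identical(sim2$y_continuous, sim$y_continuous)
})

test_that("models learn simulated signal but not permuted noise", {
  g <- simulate_genotypes(150, 100, seed = 15)
  sim <- simulate_phenotype(g, n_causal = 10, h2 = 0.8, seed = 16)
  Z <- encode_additive(g)$matrix
  train <- 1:110; test <- 111:150
  fit <- rrblup_fit(Z[train, ], sim$y[train])
  r_signal <- cor(sim$y[test], predict(fit, Z[test, ]))
  expect_gt(r_signal, 0.3)

  set.seed(17)
  r_null <- replicate(10, {
    y_perm <- sample(sim$y)
    f <- rrblup_fit(Z[train, ], y_perm[train])
    cor(y_perm[test], predict(f, Z[test, ]))
  })
  expect_lt(abs(mean(r_null)), 0.15)
  expect_gt(r_signal, max(r_null))
})
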