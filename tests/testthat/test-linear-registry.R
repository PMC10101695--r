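test_that("unpenalized limit matches ordinary least squares", {
  set.seed(4)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- X %*% c(1, -2, 0.5, 0, 3) + rnorm(200, sd = 0.1)
  fit <- regularized_linear_fit(X, y, "l2", strength = 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta[, 1]), unname(ols[-1]), tolerance = 1e-4)
})

test_that("l2 penalty ties out against RR-BLUP with fixed shrinkage", {
  set.seed(6)
  X <- matrix(rbinom(80 * 6, 2, 0.3), 80, 6)
  y <- rnorm(80)
  s <- 0.5
  fit <- regularized_linear_fit(X, y, "l2", strength = s)
  # glmnet standardizes y internally, so its penalty s corresponds to the
  # ridge normal equations with lambda = n * s / sd(y) (1/n-variance sd)
  sy <- sqrt(mean((y - mean(y))^2))
  oracle <- ridge_oracle(X, y, nrow(X) * s / sy)
  expect_equal(unname(fit$beta[, 1]), oracle, tolerance = 1e-6)
})

test_that("huge penalties drive coefficients to zero", {
  set.seed(7)
  X <- matrix(rnorm(100), 20, 5)
  fit <- regularized_linear_fit(X, rnorm(20), "l1", strength = 1e4)
  expect_equal(max(abs(fit$beta)), 0)
  expect_error(regularized_linear_fit(X, rnorm(20), "l2", strength = -1),
               "non-negative")
})

test_that("discrete traits get a logistic fit returning class labels", {
  set.seed(9)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- factor(ifelse(X[, 1] + rnorm(200, sd = 0.5) > 0, "case", "control"))
  fit <- regularized_linear_fit(X, y, "l2", strength = 0.01)
  preds <- predict(fit, X)
  expect_s3_class(preds, "factor")
  expect_setequal(levels(preds), c("case", "control"))
  expect_gt(mean(preds == y), 0.8)
})

test_that("model registry enforces the contract rules", {
  expect_error(register_model("rrblup", list()), "already registered")
  expect_error(
    register_model("searchable-no-space", list(
      kind = "searchable", trait_types = "continuous",
      default_encoding = "additive_012", allowed_encodings = "additive_012",
      fit = function(X, y, params, trait_type, seed) NULL
    )), "non-empty hyperparameter space")
  expect_error(
    register_model("paramfree-with-space", list(
      kind = "param_free", trait_types = "continuous",
      default_encoding = "additive_012", allowed_encodings = "additive_012",
      space = hp_space(a = param_real(0, 1)),
      fit = function(X, y, params, trait_type, seed) NULL
    )), "must not expose")
  expect_error(get_model("nope"), "unknown model")
  expect_true(all(c("rrblup", "bayesA", "bayesB", "bayesC",
                    "linreg-l1", "linreg-l2", "elasticnet") %in% list_models()))
})

test_that("a registered parameter-free mean predictor runs end-to-end without trials", {
  registerS3method("predict", "mean_fit",
                   function(object, X_new, ...) rep(object$mu, nrow(X_new)),
                   envir = asNamespace("gselect"))
  register_model("mean-predictor", list(
    kind = "param_free", trait_types = "continuous",
    default_encoding = "additive_012", allowed_encodings = "additive_012",
    fit = function(X, y, params, trait_type, seed)
      structure(list(mu = mean(y)), class = "mean_fit")
  ), overwrite = TRUE)
  g <- simulate_genotypes(40, 10, seed = 1)
  sim <- simulate_phenotype(g, n_causal = 3, h2 = 0.5, seed = 2)
  ds <- match_samples(encode_additive(g), sim$phenotype, "sim_trait")
  sp <- make_split(40, "cv-test", n_folds = 3, seed = 3)
  # constant predictions make correlation metrics degenerate by design
  run <- suppressWarnings(run_optimization(ds, sp, "mean-predictor", seed = 4))
  expect_equal(nrow(run$trials), 0L)
  expect_true(is.finite(run$test_metrics$mse))
  # a mean predictor is the R^2 = 0 baseline up to sampling noise
  expect_lt(abs(run$test_metrics$r2), 0.6)
})

test_that("feature importances aggregate one-hot blocks by absolute sums", {
  set.seed(12)
  Z <- matrix(rbinom(90, 2, 0.3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(30)
  fit <- rrblup_fit(Z, y, lambda = 1)
  imp <- feature_importance(fit)
  expect_equal(imp$importance, unname(abs(fit$u)))

  fake <- structure(list(beta = matrix(c(0.1, 0.2, -0.3), 3, 1,
                                       dimnames = list(paste0("m1__", 1:3), NULL)),
                         intercept = 0, family = "gaussian", classes = NULL,
                         penalty = "l2", strength = 1, mix = NA, m = 3),
                    class = "penalized_fit")
  fmap <- tibble::tibble(feature = paste0("m1__", 1:3), marker_id = rep("m1", 3))
  agg <- feature_importance(fake, feature_map = fmap)
  expect_equal(agg$importance, 0.6)

  expect_error(feature_importance(structure(list(), class = "weird_fit")),
               "does not support feature importances")
})

test_that("causal markers rank high in importances on strongly heritable traits", {
  ranks <- vapply(1:5, function(s) {
    g <- simulate_genotypes(150, 100, seed = 900 + s)
    sim <- simulate_phenotype(g, n_causal = 5, h2 = 0.8,
                              effect_distribution = "equal", seed = 910 + s)
    fit <- rrblup_fit(encode_additive(g)$matrix, sim$y)
    imp <- feature_importance(fit)
    r <- rank(-imp$importance)
    median(r[imp$marker_id %in% sim$causal_markers])
  }, numeric(1))
  expect_lt(median(ranks), 20)   # well above the null median of 50
})
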