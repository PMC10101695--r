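# gselect

Genomic selection — predicting phenotypes (yield, disease status, breeding
values) from genome-wide marker data — is a routine task in plant and
animal breeding and in quantitative genetics, yet comparing prediction
models fairly requires machinery that is easy to get subtly wrong:
reproducible data splits, leakage-free hyperparameter tuning, and
simulations with a known ground truth. gselect packages that machinery for
R users: a tidyverse-style pipeline from raw genotype files to optimized,
evaluated, re-applicable prediction models, plus a phenotype simulator for
controlled model assessment.

## What it implements

**Models.** A native RR-BLUP: the linear mixed model
*y* = *μ***1** + *Zu* + *e* with *u* ~ N(0, σ²ᵤI), *e* ~ N(0, σ²ₑI),
variance components by REML via a single eigendecomposition, effects by the
BLUP *û* = *Z*ᶜ′(*Z*ᶜ*Z*ᶜ′ + λI)⁻¹(*y* − ȳ) with shrinkage λ = σ²ₑ/σ²ᵤ —
identical to closed-form ridge on centered dosages. Native single-site
Gibbs samplers for the Bayesian alphabet: **Bayes A** (per-marker effect
variances, scaled-inverse-χ² priors), **Bayes B** (per-marker variances plus
a point mass at zero with prior exclusion probability π), **Bayes C**
(shared variance plus point mass), all bit-reproducible from a seed.
Penalized linear/logistic baselines (L1, L2, elastic net via glmnet), and a
registry for plugging in external learners.

**Pipeline.** Genotype input from CSV or PLINK text (PED/MAP) with strict
validation (fully imputed, biallelic, canonicalized calls); a plain-text
unified store that persists genotypes, per-marker minor-allele frequencies,
filter masks and split indices (append-only, tamper-checked); MAF filtering;
additive-dosage and one-hot encodings; three seed-reproducible split types
(train–validation–test, CV with a held-out test set, nested CV). Searchable
models are tuned by a built-in tree-structured Parzen estimator with
median-rule pruning of unpromising trials; the best configuration is refit
and evaluated exactly once on the untouched test set. Runs serialize to
text-only run directories that `summarize_runs()` collects into one table
and `apply_final_model()` re-applies to new genotypes.

**Simulator.** `simulate_genotypes()` (independent biallelic markers under
Hardy–Weinberg) and `simulate_phenotype()` (linear mixed model with chosen
causal marker count, effect distribution, optional polygenic background,
gaussian or skewed noise, exact-in-construction target heritability
h² = var(g)/var(y), optional discretization) — with every draw recorded so
model assessments have a ground truth.

## Worked example

```r
library(gselect)

geno <- simulate_genotypes(n_samples = 200, n_markers = 300, seed = 5)
flt  <- maf_filter(geno, 0.05)
sim  <- simulate_phenotype(flt$data, n_causal = 20, h2 = 0.6, seed = 6,
                           trait_name = "yield")
sim
#> <simulated_phenotype> 'yield': 200 samples, 20 causal markers,
#>   target h2 = 0.60, realized h2 = 0.712

enc   <- encode_additive(flt$data)
ds    <- match_samples(enc, sim$phenotype, "yield")
split <- make_split(nrow(ds$X), "cv-test", test_frac = 0.2, n_folds = 5,
                    seed = 5)

run_rrblup <- run_optimization(ds, split, "rrblup", seed = 5)
run_rrblup
#> <optimization_run> model 'rrblup' on trait 'yield' (cv-test split)
#>   0 trials recorded (0 completed, 0 pruned), objective mse (minimize)
#>   test metrics:  n=40, mse=10.79, rmse=3.285, mae=2.757, r2=0.1298,
#>   explained_variance=0.1322, pearson_r=0.3733

glance(run_rrblup$fit)
#> # A tibble: 1 × 8
#>       n     m method sigma2_u sigma2_e lambda    h2 loglik
#>   <int> <int> <chr>     <dbl>    <dbl>  <dbl> <dbl>  <dbl>
#> 1   160   296 reml     0.0639     5.38   84.2 0.570  -597.

run_enet <- run_optimization(ds, split, "elasticnet", n_trials = 20, seed = 5)
run_enet
#> <optimization_run> model 'elasticnet' on trait 'yield' (cv-test split)
#>   20 trials recorded (8 completed, 12 pruned), objective mse (minimize)
#>   test metrics:  n=40, mse=6.963, rmse=2.639, mae=2.157, r2=0.4384,
#>   explained_variance=0.4404, pearson_r=0.6819

imp <- feature_importance(run_rrblup$fit)
tab <- effectsize_vs_importance(sim, imp)
attr(tab, "rank_correlation")
#> [1] 0.18497
```

Reading the output: RR-BLUP (parameter-free, so zero search trials) was fit
on the 160 train+validation samples and evaluated once on the 40 held-out
test samples; its REML heritability estimate (0.570) tracks the simulation's
realized value. The elastic net ran a 20-trial TPE search in which the
median pruner stopped 12 unpromising trials early; with only 20 causal
markers among 296, its sparsity-inducing penalty predicts better here
(test r = 0.68 vs 0.37). The positive rank correlation between RR-BLUP's
|effect| importances and the true simulated effect sizes shows the causal
architecture is partially recovered even by the dense model.

A command-line wrapper over the same functions ships at
`inst/cli/gselect.R` (subcommands `run`, `simulate`, `summarize`, `apply`,
plus `--list-models` / `--version`).

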