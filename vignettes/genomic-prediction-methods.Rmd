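---
title: "Models and methods in gselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gselect)
```

gselect predicts phenotypes from genome-wide marker data. This vignette is
the package's own account of the statistics it implements: the models and
their assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The prediction problem

The data are a fully imputed biallelic genotype matrix (samples × markers,
diploid nucleotide calls) and one or more trait columns, continuous or
discrete. After minor-allele-frequency (MAF) filtering and encoding, every
model sees a numeric matrix $Z$ ($n \times m$, by default the additive
dosage coding counting minor-allele copies 0/1/2) and a phenotype vector
$y$.

Everything downstream of parsing operates on a *unified store*: a plain-text
directory holding the canonical genotype matrix, the precomputed per-marker
MAF, and an append-only `index/` group in which filter masks and data-split
indices are persisted as JSON. The store refuses to overwrite existing
genotype content and treats identical re-writes as no-ops, so persisted
indices can never silently refer to different data. Indices are 1-based (the
natural convention in R) and every persisted record carries an explicit
`index_base` field, so the on-disk contract is unambiguous for other
tooling.

## RR-BLUP

Ridge-regression BLUP assumes

$$y = \mu\mathbf{1} + Z u + e,\qquad u \sim N(0, \sigma_u^2 I_m),\qquad
  e \sim N(0, \sigma_e^2 I_n),$$

i.e. many small, exchangeable marker effects. Columns of $Z$ are centered by
their training means and deliberately *not* variance-scaled: scaling changes
the implied per-allele effect-size prior and we prefer the dosage scale to
remain interpretable. $\mu$ is the phenotype mean.

Variance components are estimated by REML. Rather than iterating a
mixed-model solver, we use the classic eigendecomposition trick: with
$K = Z_c Z_c'$ projected onto the orthogonal complement of the intercept
(via the QR basis of $\mathbf{1}$), the restricted likelihood profiled over
$\sigma_u^2$ is a smooth 1-D function of $\lambda = \sigma_e^2/\sigma_u^2$,
which we minimize with `optimize()` over $\log\lambda \in [-15, 15]$ — wide
enough to cover heritabilities from ~0 to ~1 at any reasonable scale, and a
single $n \times n$ eigendecomposition suffices. Effects are the BLUP

$$\hat u = Z_c'(K + \lambda I)^{-1}(y - \bar y),$$

which is algebraically identical to the closed-form ridge estimate
$(Z_c'Z_c + \lambda I)^{-1} Z_c' y_c$; the test suite enforces this identity
to $10^{-8}$ relative tolerance, so the dual-form implementation can never
drift from the textbook estimator. The reported heritability is
$\hat h^2 = \widehat{\mathrm{var}}(g) / (\widehat{\mathrm{var}}(g) +
\hat\sigma_e^2)$ with $\widehat{\mathrm{var}}(g) = \hat\sigma_u^2\,
\mathrm{tr}(K)/n$.

## The Bayesian alphabet

Bayes A, B and C are implemented as native single-site Gibbs samplers (in
C++ via Rcpp), not as a wrapper around an external package:

* **Bayes A** — $u_j \mid \sigma_j^2 \sim N(0, \sigma_j^2)$ with
  scaled-inverse-$\chi^2(\nu_u, S_u)$ priors on each $\sigma_j^2$:
  marker-specific shrinkage, every marker in the model.
* **Bayes B** — Bayes A plus a point mass at zero: each marker is excluded
  with prior probability $\pi$.
* **Bayes C** — point mass plus a single shared variance $\sigma_u^2$ for
  all included markers.

Inclusion indicators are sampled from the exact marginal odds (effect
integrated out), effects from their conjugate normal full conditionals, and
all variances from scaled-inverse-$\chi^2$ full conditionals; for excluded
markers in Bayes B the variance is refreshed from its prior so the chain
remains irreducible. The residual variance has a
scaled-inverse-$\chi^2(\nu_e, S_e)$ prior.

Defaults, all overridable: $\nu_u = \nu_e = 5$; prior scales from a
method-of-moments heuristic that puts the prior mode of the per-marker
effect variance at $0.5\,\mathrm{var}(y)\,h_0^2/m$ with $h_0^2 = 0.5$, and
the residual mode at $0.5\,\mathrm{var}(y)$ — a weakly informative
half-genetic/half-residual split. $\pi = 0.95$ is fixed rather than
estimated (estimating it is a known extension; a fixed value keeps the
sampler simple and the runs comparable). The default chain is 6,000
iterations with 1,000 burn-in and thinning 5 — sized for desk-scale data;
long analyses should raise it. Chains are driven by R's RNG, so a seed makes
the entire posterior summary bit-reproducible.

Two limiting behaviours anchor the sampler's correctness in the tests: with
$\pi = 0$ and both variances held fixed, Bayes C is a Bayesian ridge whose
posterior mean must approach the closed-form ridge solution at
$\lambda = \sigma_e^2/\sigma_u^2$ (checked at $n = 50$, $m = 10$, 20,000
iterations, max-abs tolerance 0.05); and on permuted phenotypes Bayes B's
posterior inclusion frequencies must stay near the prior's complement.

RR-BLUP and the Bayes models are continuous-only and refuse discrete traits
explicitly; penalized linear models (glmnet: L1, L2, elastic net) cover both
trait types and switch to logistic/multinomial fits for discrete traits.

## Hyperparameter optimization

Searchable models declare a space of real (optionally log-scaled), integer
and categorical dimensions. Search is sequential model-based optimization
with a native tree-structured Parzen estimator: after 10 uniform startup
trials, completed trials are split at the best 25% by objective; each
dimension gets a kernel model for the good and bad groups; 24 candidates are
drawn from the good model and the one maximizing the density ratio
$l(x)/g(x)$ is suggested. Kernels use the classic per-component bandwidth
heuristic — each point's bandwidth is its distance to the farther of its
neighbors, clamped to $[\mathrm{width}/\min(100, k+1), \mathrm{width}]$ —
plus a 5% uniform mixture. The per-component bandwidths matter: a pooled
bandwidth lets a dense cluster of mediocre trials dominate both the
sampling and the ratio, and the search stalls on it; neighbor-distance
bandwidths keep the bad-group density sharp exactly where bad points crowd,
which restores the drilling behaviour the estimator is known for.

The objective is the mean validation score across folds — MSE (minimized)
for continuous traits, Matthews correlation (maximized) for discrete ones;
both are conventional defaults and configurable in principle through the
metric layer. Fold scores are reported incrementally and a **median pruner**
stops a trial whose running mean after $k$ folds is worse than the median of
completed trials' running means at the same $k$ — never at the first fold
and never before 5 trials have completed, so early trials build the
reference. A duplicate guard (reals rounded to 6 significant digits) records
repeated suggestions without re-evaluating them or consuming the budget,
with a retry cap of 10× the budget.

After the search the best assignment is refit on the train+validation data
and evaluated exactly once on the held-out test set; for nested
cross-validation the entire search repeats per outer fold and test metrics
are averaged. Parameter-free models (RR-BLUP, the Bayes variants, or any
registered mean-style baseline) run through the same pipeline with zero
trials. A `sampler = "random"` mode draws each trial from a per-trial seed
substream; because that sequence is invariant to pruning decisions, it is
the reference implementation for the pruning-soundness check (pruning may
only remove trials, never change a completed trial's objective) and the
baseline the TPE must beat.

Run directories are named deterministically from the seed rather than
time-stamped: two invocations with identical inputs must produce
byte-identical manifests, and a timestamp in the path would break exactly
the reproducibility the manifest exists to witness.

## Data splitting

Three split types are supported: train–validation–test, cross-validation
with a separate test set, and nested cross-validation. All are pure
functions of `(n, type, parameters, seed)`: one seeded Mersenne–Twister
permutation followed by contiguous slicing. Sizes round half away from zero,
test first, then validation from the remainder — stable and
order-independent. Discrete traits use class-stratified assignment (each
class is spread evenly along the permutation); continuous traits are split
sample-wise only. Persisted splits are verified on load by regenerating from
the stored descriptor and comparing bytes, so tampering or drift is caught
rather than silently used. Kinship-aware splitting and LD pruning are out of
scope; users with strong family structure should interpret test metrics
accordingly.

## The phenotype simulator

`simulate_genotypes()` draws independent biallelic markers under
Hardy–Weinberg proportions with per-marker allele frequencies uniform in a
requested MAF range. `simulate_phenotype()` then builds
$y = g + \varepsilon$ with $g = Z_c\beta$ over a uniformly drawn causal set
(gaussian, laplace or equal effects), optionally plus an i.i.d. polygenic
background contributing ~10% of the causal genetic variance (an explicit
kinship draw would be equivalent in distribution but costlier and harder to
reproduce exactly). The residual variance is set from the *empirical*
genetic variance, $\mathrm{var}(\varepsilon) = \mathrm{var}(g)(1 - h^2)/h^2$,
so the realized $\mathrm{var}(g)/\mathrm{var}(y)$ concentrates tightly at
the target $h^2$ (±0.05 at $n = 1000$ in the checks). Noise is gaussian or a
mean-centered gamma (shape 2) for right-skewed traits; discretization cuts
the phenotype at quantiles (median for 2 classes, terciles for 3). Every
draw is recorded — causal ids, effects, genetic values, realized $h^2$,
config, seed — and the export embeds the recipe as `#` metadata lines, so a
simulation is always regenerable from its own files.

What the simulator does *not* emulate: linkage disequilibrium and genetic
maps, population and family structure, epistasis, genotype-by-environment
interaction, and multi-trait correlation. Tests passing on simulated data
therefore demonstrate correctness of the estimators under their own
assumptions, not performance on structured real populations — the gap a
practitioner should keep in mind when transferring conclusions.

## Numerical choices and degenerate inputs

* Genotype calls are canonicalized with alleles sorted lexicographically
  ("GA" ≡ "AG"); single-letter homozygous shorthand is accepted by default
  (common for inbred lines) and switchable off.
* MAF filtering keeps markers with MAF strictly above the threshold, with a
  $10^{-9}$ tolerance so a frequency mathematically equal to the threshold
  is never kept through floating-point noise; masks are monotone in the
  threshold by construction.
* The additive coding counts *minor*-allele copies; 50/50 ties break to the
  lexicographically smaller allele. The polarity is stored per marker and
  reapplied when new data are encoded for prediction.
* Constant phenotypes, empty sample intersections, empty partitions,
  mismatched marker sets and out-of-range parameters are errors, not
  warnings. Degenerate *metrics* (constant truth or predictions) are the one
  exception: they are reported as `NA` with a flag so batch summaries
  survive degenerate folds.
* Model-fit failures inside a search mark the trial failed and the search
  continues; only an all-failed search aborts.

## Problem sizes in the checks

The verification suite runs at deliberately desk-sized scales — e.g. REML
recovery at $n = 500$, $m = 200$ over 20 seeds per heritability level,
the Gibbs ridge limit at $n = 50$, $m = 10$ with a 20,000-iteration chain,
optimizer benchmarks with 30-trial budgets against a 1,000-point grid —
chosen so the full suite re-runs in about a minute while still exercising
every contract at the sizes where the statistics are informative.

## Known limitations

Bayesian models are continuous-only; $\pi$ is fixed; no GBLUP/kinship
variant; no multi-trait or GxE modelling; neural and tree ensembles are
reachable only through the model-registry adapter, not shipped; the
re-application path (`apply_final_model()`) supports the additive encoding.
Parallel trial execution is deliberately absent — sequential execution keeps
end-to-end determinism trivial, and is a documented future extension.
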