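#' Simulate independent biallelic genotypes
#'
#' Generates a samples-by-markers nucleotide matrix for fixtures and
#' controlled experiments: each marker draws two distinct alleles, a minor
#' frequency uniformly from `maf_range`, and genotypes under Hardy-Weinberg
#' proportions (dosage ~ Binomial(2, q)). Markers are mutually independent
#' (no linkage disequilibrium). Deterministic per seed.
#'
#' @param n_samples,n_markers dimensions.
#' @param maf_range interval inside `(0, 0.5]` for the drawn allele
#'   frequency.
#' @param seed RNG seed.
#' @return A [raw_genotype()].
#' @export
simulate_genotypes <- function(n_samples, n_markers, maf_range = c(0.05, 0.5),
                               seed = 42L) {
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L]) {
    abort("`maf_range` must be an interval inside (0, 0.5]")
  }
  with_seed(as.integer(seed), {
    calls <- matrix("", n_samples, n_markers)
    for (j in seq_len(n_markers)) {
      al <- sort(sample(NUCLEOTIDES, 2L))
      q <- runif(1, maf_range[1L], maf_range[2L])
      dos <- rbinom(n_samples, 2L, q)
      calls[, j] <- c(paste0(al[1L], al[1L]), paste0(al[1L], al[2L]),
                      paste0(al[2L], al[2L]))[dos + 1L]
    }
    raw_genotype(calls,
                 sample_ids = sprintf("S%04d", seq_len(n_samples)),
                 marker_ids = sprintf("M%05d", seq_len(n_markers)))
  })
}

#' Simulate a phenotype with known causal architecture
#'
#' Builds a phenotype from genotypes under a linear mixed model with an
#' exact, recorded construction:
#'
#' 1. draw `n_causal` causal markers uniformly without replacement among the
#'    polymorphic markers;
#' 2. draw their raw effects from `effect_distribution` (`"gaussian"`,
#'    `"laplace"` or `"equal"`, i.e. all effects 1);
#' 3. genetic value `g = Zc beta`, with an optional polygenic background
#'    term over all markers (i.i.d. small effects contributing about 10% of
#'    the causal genetic variance);
#' 4. residual variance set to `var(g) * (1 - h2) / h2` using the empirical
#'    `var(g)`, so the realized heritability `var(g)/var(y)` concentrates at
#'    the target;
#' 5. noise drawn from `noise_distribution` — gaussian, or a mean-centered
#'    gamma (shape 2) for a right-skewed trait;
#' 6. optional discretization into classes by phenotype quantiles (median
#'    split for 2 classes, terciles for 3, ...).
#'
#' With `h2 = 0` the phenotype is pure noise (unit variance). Everything —
#' causal ids, effects, genetic values, realized heritability, config and
#' seed — is stored in the result, so any analysis is recomputable.
#'
#' @param geno a [raw_genotype()] or `encoded_genotype` (additive).
#' @param n_causal number of causal markers.
#' @param h2 target heritability in `[0, 1)`.
#' @param effect_distribution `"gaussian"`, `"laplace"` or `"equal"`.
#' @param include_background add an i.i.d. polygenic term over all markers.
#' @param noise_distribution `"gaussian"` or `"gamma"`.
#' @param n_classes optional number of classes for a discretized trait.
#' @param trait_name column name used on export.
#' @param seed RNG seed.
#' @return A `simulated_phenotype`: `phenotype` tibble (`sample_id`, trait
#'   column), `y` (numeric or factor), `g`, `beta` (full-length, zeros
#'   off-causal), `causal_markers`, `realized_h2`, `config`.
#' @export
simulate_phenotype <- function(geno, n_causal = 10L, h2 = 0.5,
                               effect_distribution = c("gaussian", "laplace", "equal"),
                               include_background = FALSE,
                               noise_distribution = c("gaussian", "gamma"),
                               n_classes = NULL, trait_name = "sim_trait",
                               seed = 42L) {
  effect_distribution <- match.arg(effect_distribution)
  noise_distribution <- match.arg(noise_distribution)
  if (h2 < 0 || h2 >= 1) abort("`h2` must lie in [0, 1)")
  enc <- if (inherits(geno, "encoded_genotype")) geno else encode_additive(geno)
  if (enc$encoding != "additive_012") abort("simulation needs the additive encoding")
  Z <- enc$matrix
  n <- nrow(Z); m <- ncol(Z)
  if (n_causal > m) abort("`n_causal` exceeds the number of markers")
  polymorphic <- which(apply(Z, 2L, var) > 0)
  if (h2 > 0 && n_causal > 0 && length(polymorphic) < n_causal) {
    abort("not enough polymorphic markers for the requested causal count")
  }
  with_seed(as.integer(seed), {
    beta <- numeric(m)
    names(beta) <- colnames(Z)
    causal <- integer(0)
    if (n_causal > 0L) {
      causal <- sort(sample(polymorphic, n_causal))
      beta[causal] <- switch(effect_distribution,
        gaussian = rnorm(n_causal),
        laplace = sample(c(-1, 1), n_causal, replace = TRUE) * rexp(n_causal),
        equal = rep(1, n_causal)
      )
    }
    Zc <- sweep(Z, 2L, colMeans(Z))
    g <- as.numeric(Zc %*% beta)
    if (include_background) {
      target_bg <- if (var(g) > 0) 0.1 * var(g) else 1
      u_bg <- rnorm(m, 0, sqrt(target_bg / max(1, sum(apply(Zc, 2L, var)))))
      g <- g + as.numeric(Zc %*% u_bg)
    }
    if (h2 == 0) {
      g <- numeric(n)
      var_e <- 1
    } else {
      if (var(g) == 0) abort("no genetic variance to scale: h2 > 0 needs causal markers or a background term")
      var_e <- var(g) * (1 - h2) / h2
    }
    eps <- switch(noise_distribution,
      gaussian = rnorm(n, 0, sqrt(var_e)),
      gamma = {
        sc <- sqrt(var_e / 2)            # shape 2: var = 2 * scale^2
        raw <- rgamma(n, shape = 2, scale = sc)
        raw - 2 * sc                     # mean-centered to preserve location
      }
    )
    y <- g + eps
    realized_h2 <- if (var(y) > 0) var(g) / var(y) else 0
    y_out <- y
    if (!is.null(n_classes)) {
      qs <- quantile(y, probs = seq(0, 1, length.out = n_classes + 1L))
      qs[1L] <- -Inf; qs[n_classes + 1L] <- Inf
      y_out <- cut(y, breaks = qs, labels = as.character(seq_len(n_classes) - 1L))
    }
    structure(list(
      phenotype = tibble(sample_id = enc$sample_ids, !!trait_name := y_out),
      y = y_out, y_continuous = y, g = g, beta = beta,
      causal_markers = colnames(Z)[causal],
      realized_h2 = realized_h2,
      trait_name = trait_name,
      config = list(n_causal = as.integer(n_causal), h2 = h2,
                    effect_distribution = effect_distribution,
                    include_background = include_background,
                    noise_distribution = noise_distribution,
                    n_classes = n_classes, seed = as.integer(seed))
    ), class = "simulated_phenotype")
  })
}

#' @exportS3Method base::print
print.simulated_phenotype <- function(x, ...) {
  cat(sprintf("<simulated_phenotype> '%s': %d samples, %d causal markers, target h2 = %.2f, realized h2 = %.3f\n",
              x$trait_name, length(x$g), length(x$causal_markers),
              x$config$h2, x$realized_h2))
  invisible(x)
}

#' Tidy per-marker ground truth of a simulation
#' @param x a `simulated_phenotype`.
#' @param ... unused.
#' @return Tibble with `marker_id`, `beta`, `causal`.
#' @export
tidy.simulated_phenotype <- function(x, ...) {
  tibble(marker_id = names(x$beta), beta = unname(x$beta),
         causal = names(x$beta) %in% x$causal_markers)
}

#' Export a simulation as phenotype and ground-truth CSVs
#'
#' Writes `phenotype.csv` (readable by [read_phenotype_csv()]) and
#' `ground_truth.csv` (one row per marker with the true effect and causal
#' flag). The full simulation config including the seed is embedded as
#' `#`-prefixed metadata comment lines, so the phenotype can be regenerated
#' exactly from the files alone.
#'
#' @param sim a `simulated_phenotype`.
#' @param out_dir output directory.
#' @return Named list of the two file paths, invisibly.
#' @export
export_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "simulated_phenotype"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("# %s", as.character(jsonlite::toJSON(sim$config, auto_unbox = TRUE,
                                                        digits = NA)))
  pheno_path <- file.path(out_dir, "phenotype.csv")
  writeLines(meta, pheno_path)
  suppressWarnings(
    readr::write_csv(sim$phenotype, pheno_path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  )
  truth_path <- file.path(out_dir, "ground_truth.csv")
  writeLines(meta, truth_path)
  suppressWarnings(
    readr::write_csv(tidy(sim), truth_path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  )
  invisible(list(phenotype = pheno_path, ground_truth = truth_path))
}
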