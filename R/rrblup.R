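#' Fit RR-BLUP (ridge-regression BLUP) marker effects
#'
#' Fits the linear mixed model `y = mu + Z u + e` with i.i.d. random marker
#' effects `u ~ N(0, sigma2_u I)` and residuals `e ~ N(0, sigma2_e I)`.
#' Columns of `Z` are centered by their training means (no variance
#' scaling); `mu` is the phenotype mean. Variance components are estimated
#' by REML using a single eigendecomposition of the centered genomic
#' covariance `Zc Zc'` restricted to the orthogonal complement of the
#' intercept, followed by a 1-D optimization over the log variance ratio.
#' Marker effects are the BLUP
#' `u_hat = Zc' (Zc Zc' + lambda I)^-1 (y - mean(y))` with shrinkage
#' `lambda = sigma2_e / sigma2_u`, which is algebraically identical to the
#' closed-form ridge estimate `(Zc'Zc + lambda I)^-1 Zc' y` on centered
#' data.
#'
#' @param Z additive dosage matrix (samples x markers), e.g.
#'   `encode_additive(raw)$matrix`.
#' @param y continuous phenotype vector.
#' @param lambda optional fixed shrinkage; `NULL` (default) estimates it by
#'   REML.
#' @return An `rrblup_fit`: `mu`, `u` (named effects), `sigma2_u`,
#'   `sigma2_e`, `lambda`, `h2` (genomic heritability estimate
#'   `var(g)/(var(g)+sigma2_e)` with `var(g) = sigma2_u tr(Zc Zc')/n`),
#'   `col_means`, `loglik` (restricted, up to a constant).
#' @export
#' @examples
#' set.seed(1)
#' Z <- matrix(rbinom(200 * 50, 2, 0.3), 200, 50)
#' u <- rnorm(50, 0, 0.3)
#' y <- Z %*% u + rnorm(200)
#' fit <- rrblup_fit(Z, y)
#' fit$h2
rrblup_fit <- function(Z, y, lambda = NULL) {
  Z <- as.matrix(Z)
  y <- as.numeric(y)
  n <- nrow(Z)
  if (n < 3L) abort("RR-BLUP needs at least 3 samples")
  if (length(y) != n) abort("length(y) must equal nrow(Z)")
  if (var(y) == 0) abort("constant phenotype: variance components are not identifiable")
  col_means <- colMeans(Z)
  Zc <- sweep(Z, 2L, col_means)
  mu <- mean(y)
  yc <- y - mu
  K <- tcrossprod(Zc)

  reml <- NULL
  if (is.null(lambda)) {
    # orthonormal basis of the complement of the intercept column
    Q <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1L, drop = FALSE]
    M <- crossprod(Q, K %*% Q)
    eg <- eigen(M, symmetric = TRUE)
    theta <- pmax(eg$values, 0)
    eta <- as.numeric(crossprod(eg$vectors, crossprod(Q, y)))
    # restricted log-likelihood profiled over sigma2_u, as a function of
    # log(lambda) with lambda = sigma2_e / sigma2_u
    negll <- function(log_lambda) {
      d <- theta + exp(log_lambda)
      0.5 * sum(log(d)) + 0.5 * (n - 1) * log(sum(eta^2 / d))
    }
    opt <- optimize(negll, interval = c(-15, 15), tol = 1e-9)
    if (!is.finite(opt$objective)) abort("REML optimization failed to converge")
    lambda <- exp(opt$minimum)
    sigma2_u <- sum(eta^2 / (theta + lambda)) / (n - 1)
    sigma2_e <- lambda * sigma2_u
    reml <- list(loglik = -opt$objective)
  } else {
    if (lambda <= 0) abort("`lambda` must be positive")
    sigma2_u <- NA_real_
    sigma2_e <- NA_real_
  }

  sol <- solve(K + lambda * diag(n), yc)
  u_hat <- as.numeric(crossprod(Zc, sol))
  var_g <- if (!is.na(sigma2_u)) sigma2_u * mean(diag(K)) else NA_real_
  structure(list(
    mu = mu, u = setNames(u_hat, colnames(Z)),
    sigma2_u = sigma2_u, sigma2_e = sigma2_e, lambda = lambda,
    h2 = if (!is.na(var_g)) var_g / (var_g + sigma2_e) else NA_real_,
    col_means = col_means, n = n, m = ncol(Z),
    method = if (is.null(reml)) "fixed-lambda" else "reml",
    loglik = if (is.null(reml)) NA_real_ else reml$loglik
  ), class = "rrblup_fit")
}

#' Predict from an RR-BLUP fit
#'
#' New dosages are centered with the training column means before applying
#' the effect vector: `y_hat = mu + (Z_new - means) u_hat`.
#'
#' @param object an `rrblup_fit`.
#' @param Z_new dosage matrix over the same markers, in the same encoding.
#' @param ... unused.
#' @return Numeric prediction vector.
#' @export
predict.rrblup_fit <- function(object, Z_new, ...) {
  Z_new <- as.matrix(Z_new)
  if (ncol(Z_new) != object$m) {
    abort(sprintf("marker-count mismatch: fit has %d markers, new data has %d",
                  object$m, ncol(Z_new)))
  }
  as.numeric(object$mu + sweep(Z_new, 2L, object$col_means) %*% object$u)
}

#' @exportS3Method base::print
print.rrblup_fit <- function(x, ...) {
  cat(sprintf("<rrblup_fit> n = %d, m = %d (%s)\n", x$n, x$m, x$method))
  if (x$method == "reml") {
    cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g, lambda = %.4g, h2 = %.3f\n",
                x$sigma2_u, x$sigma2_e, x$lambda, x$h2))
  } else {
    cat(sprintf("  fixed lambda = %.4g\n", x$lambda))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy marker effects of an RR-BLUP fit
#' @param x an `rrblup_fit`.
#' @param ... unused.
#' @return Tibble with columns `marker_id`, `effect`.
#' @export
tidy.rrblup_fit <- function(x, ...) {
  tibble(marker_id = names(x$u) %||% paste0("m", seq_along(x$u)),
         effect = unname(x$u))
}

#' One-row model summary of an RR-BLUP fit
#' @param x an `rrblup_fit`.
#' @param ... unused.
#' @return Tibble with variance components, shrinkage and heritability.
#' @export
glance.rrblup_fit <- function(x, ...) {
  tibble(n = x$n, m = x$m, method = x$method, sigma2_u = x$sigma2_u,
         sigma2_e = x$sigma2_e, lambda = x$lambda, h2 = x$h2,
         loglik = x$loglik)
}
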