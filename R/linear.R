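#' Penalized linear / logistic regression baseline
#'
#' Thin wrapper around glmnet providing L1 (lasso), L2 (ridge) and
#' elastic-net penalties for continuous (linear) and discrete (logistic /
#' multinomial) traits. `strength` is the penalty weight on the glmnet
#' objective `(1/2n) RSS + strength * penalty`; with `penalty = "l2"` and no
#' standardization, coefficients at strength `s` match the ridge normal
#' equations with `lambda = n * s`, which ties this baseline to
#' [rrblup_fit()] with fixed shrinkage.
#'
#' @param X feature matrix (samples x features).
#' @param y continuous vector or factor (discrete).
#' @param penalty `"l1"`, `"l2"` or `"elastic-net"`.
#' @param strength non-negative penalty strength (glmnet lambda).
#' @param mix elastic-net mixing in (0, 1); ignored for l1/l2.
#' @return A `penalized_fit`: coefficients, intercept(s), family, classes.
#' @export
regularized_linear_fit <- function(X, y, penalty = c("l2", "l1", "elastic-net"),
                                   strength = 1, mix = 0.5) {
  penalty <- match.arg(penalty)
  if (strength < 0) abort("`strength` must be non-negative")
  X <- as.matrix(X)
  discrete <- is.factor(y) || is.character(y)
  alpha <- switch(penalty, l1 = 1, l2 = 0, `elastic-net` = mix)
  if (discrete) {
    y <- factor(y)
    family <- if (nlevels(y) > 2L) "multinomial" else "binomial"
  } else {
    y <- as.numeric(y)
    family <- "gaussian"
  }
  # glmnet's coordinate descent is most accurate when warm-started along a
  # decreasing path; the requested strength is the path's final value
  lam_path <- if (strength > 0) strength * c(64, 16, 4, 1) else c(0.1, 0.01, 0)
  fit <- glmnet::glmnet(X, y, family = family, alpha = alpha,
                        lambda = lam_path, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  cf <- coef(fit, s = min(lam_path))
  if (family == "multinomial") {
    beta <- do.call(cbind, lapply(cf, function(b) as.numeric(b)[-1L]))
    intercept <- vapply(cf, function(b) as.numeric(b)[1L], numeric(1))
    colnames(beta) <- names(cf)
  } else {
    beta <- matrix(as.numeric(cf)[-1L], ncol = 1L)
    intercept <- as.numeric(cf)[1L]
  }
  rownames(beta) <- colnames(X)
  structure(list(
    beta = beta, intercept = intercept, family = family,
    classes = if (discrete) levels(y) else NULL,
    penalty = penalty, strength = strength,
    mix = if (penalty == "elastic-net") mix else NA_real_,
    m = ncol(X)
  ), class = "penalized_fit")
}

#' Predict from a penalized linear fit
#' @param object a `penalized_fit`.
#' @param X_new feature matrix over the training features.
#' @param ... unused.
#' @return Numeric predictions (continuous) or a factor of class labels.
#' @export
predict.penalized_fit <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$m) {
    abort(sprintf("feature-count mismatch: fit has %d features, new data has %d",
                  object$m, ncol(X_new)))
  }
  eta <- sweep(X_new %*% object$beta, 2L, -object$intercept)
  switch(object$family,
    gaussian = as.numeric(eta),
    binomial = factor(object$classes[1L + as.integer(eta[, 1L] > 0)],
                      levels = object$classes),
    multinomial = factor(object$classes[max.col(eta, ties.method = "first")],
                         levels = object$classes)
  )
}

#' @exportS3Method base::print
print.penalized_fit <- function(x, ...) {
  cat(sprintf("<penalized_fit> %s (%s), strength = %.4g\n",
              x$penalty, x$family, x$strength))
  invisible(x)
}

#' Tidy coefficients of a penalized fit
#' @param x a `penalized_fit`.
#' @param ... unused.
#' @return Tibble with `feature`, `estimate` (mean |coefficient| across
#'   classes for multinomial fits).
#' @export
tidy.penalized_fit <- function(x, ...) {
  est <- if (ncol(x$beta) > 1L) rowMeans(abs(x$beta)) else x$beta[, 1L]
  tibble(feature = rownames(x$beta), estimate = unname(est))
}
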