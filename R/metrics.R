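#' Evaluation metrics for continuous traits
#'
#' Computes MSE, RMSE, MAE, R-squared (`1 - SSE/SST`), explained variance
#' and Pearson correlation. When the observed values are constant, the
#' correlation-based metrics are undefined and reported as `NA` with a
#' `degenerate` flag instead of an error, so batch summaries survive
#' degenerate folds.
#'
#' @param y observed values.
#' @param y_hat predicted values, same length (>= 2).
#' @return A one-row tibble: `n`, `mse`, `rmse`, `mae`, `r2`,
#'   `explained_variance`, `pearson_r`, `degenerate`.
#' @export
metrics_continuous <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  mse <- mean((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  degenerate <- sst == 0 || sd(y_hat) == 0
  if (degenerate) warn("constant observations or predictions: correlation metrics reported as NA")
  tibble(
    n = length(y),
    mse = mse,
    rmse = sqrt(mse),
    mae = mean(abs(y - y_hat)),
    r2 = if (sst > 0) 1 - sum((y - y_hat)^2) / sst else NA_real_,
    explained_variance = if (sst > 0) 1 - var(y - y_hat) / var(y) else NA_real_,
    pearson_r = if (!degenerate) cor(y, y_hat) else NA_real_,
    degenerate = degenerate
  )
}

#' Evaluation metrics for discrete traits
#'
#' Computes accuracy, macro-averaged F1 and the multi-class Matthews
#' correlation coefficient (the generalized correlation form over the
#' confusion matrix, which reduces to the familiar binary formula for two
#' classes). A single-class truth vector makes MCC undefined; it is reported
#' as `NA` with a `degenerate` flag.
#'
#' @param y observed labels.
#' @param y_hat predicted labels.
#' @return A one-row tibble: `n`, `accuracy`, `f1_macro`, `mcc`,
#'   `degenerate`.
#' @export
metrics_discrete <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  labels <- sort(unique(c(as.character(y), as.character(y_hat))))
  y <- factor(as.character(y), levels = labels)
  y_hat <- factor(as.character(y_hat), levels = labels)
  cm <- table(truth = y, pred = y_hat)
  n <- length(y)
  acc <- sum(diag(cm)) / n
  f1 <- vapply(labels, function(lv) {
    tp <- cm[lv, lv]
    prec_den <- sum(cm[, lv]); rec_den <- sum(cm[lv, ])
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- if (rec_den > 0) tp / rec_den else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  # generalized MCC: (c*s - sum p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))
  tk <- rowSums(cm); pk <- colSums(cm); s <- n; c_ <- sum(diag(cm))
  den <- sqrt(as.numeric(s^2 - sum(pk^2))) * sqrt(as.numeric(s^2 - sum(tk^2)))
  degenerate <- length(unique(as.character(y))) < 2L
  mcc <- if (degenerate) NA_real_ else if (den == 0) 0 else
    (c_ * s - sum(pk * tk)) / den
  if (degenerate) warn("single-class observations: MCC reported as NA")
  tibble(n = n, accuracy = acc, f1_macro = mean(f1), mcc = mcc,
         degenerate = degenerate)
}

# dispatch on trait type; returns a one-row tibble
compute_metrics <- function(y, y_hat, trait_type) {
  if (trait_type == "continuous") metrics_continuous(y, y_hat)
  else metrics_discrete(y, y_hat)
}

# the scalar objective used by the optimizer
objective_metric <- function(trait_type) {
  if (trait_type == "continuous") list(name = "mse", direction = "minimize")
  else list(name = "mcc", direction = "maximize")
}
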