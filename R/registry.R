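#' Register a prediction model
#'
#' Models plug into the pipeline through a small contract: either a
#' *searchable* model exposing a hyperparameter space that the optimizer
#' explores, or a *parameter-free* model that is fitted once with fixed
#' settings but runs through the same pipeline (same splits, same test
#' evaluation). A contract declares the trait types it supports and its
#' default and allowed genotype encodings.
#'
#' @param name unique registry name.
#' @param contract list with fields:
#'   * `kind` — `"searchable"` or `"param_free"`;
#'   * `trait_types` — subset of `c("continuous", "discrete")`;
#'   * `default_encoding`, `allowed_encodings` — genotype encodings;
#'   * `space` — an [hp_space()] (searchable models only; must be non-empty);
#'   * `fit` — `function(X, y, params, trait_type, seed)` returning a fitted
#'     object with a `predict(fit, X_new)` method;
#'   * `importance` — optional `function(fit)` returning one score per
#'     feature column.
#' @param overwrite replace an existing entry (default `FALSE`: duplicate
#'   names are an error).
#' @return The contract, invisibly.
#' @export
register_model <- function(name, contract, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!overwrite && !is.null(the$registry[[name]])) {
    abort(sprintf("model '%s' is already registered", name))
  }
  required <- c("kind", "trait_types", "default_encoding", "allowed_encodings", "fit")
  missing_fields <- setdiff(required, names(contract))
  if (length(missing_fields) > 0L) {
    abort(sprintf("model contract is missing field(s): %s",
                  paste(missing_fields, collapse = ", ")))
  }
  if (!contract$kind %in% c("searchable", "param_free")) {
    abort("contract `kind` must be 'searchable' or 'param_free'")
  }
  if (contract$kind == "searchable" &&
      (is.null(contract$space) || length(contract$space) == 0L)) {
    abort("a searchable model must expose a non-empty hyperparameter space")
  }
  if (contract$kind == "param_free" && length(contract$space %||% list()) > 0L) {
    abort("a parameter-free model must not expose a hyperparameter space")
  }
  contract$name <- name
  assign(name, contract, envir = the$registry)
  invisible(contract)
}

#' Look up a registered model contract
#' @param name registry name.
#' @return The contract list.
#' @export
get_model <- function(name) {
  contract <- the$registry[[name]]
  if (is.null(contract)) {
    abort(sprintf("unknown model '%s' (registered: %s)", name,
                  paste(list_models(), collapse = ", ")))
  }
  contract
}

#' Names of all registered models
#' @return Character vector.
#' @export
list_models <- function() sort(ls(the$registry))

# fit a registered model on a feature matrix
fit_model <- function(contract, X, y, params = list(), trait_type = "continuous",
                      seed = 42L) {
  if (!trait_type %in% contract$trait_types) {
    abort(sprintf("model '%s' does not support %s traits", contract$name, trait_type))
  }
  contract$fit(X = X, y = y, params = params, trait_type = trait_type, seed = seed)
}

#' Per-marker feature importances of a fitted model
#'
#' Returns one non-negative score per original marker: absolute
#' coefficients / posterior-mean effects per feature column, with one-hot
#' blocks aggregated by the sum of absolute column scores.
#'
#' @param fit a fitted model (`rrblup_fit`, `bayes_fit`, `penalized_fit`, or
#'   any object whose contract provided an `importance` function).
#' @param feature_map optional tibble with columns `feature`, `marker_id`
#'   (as carried by `encoded_genotype` / `matched_dataset`); `NULL` treats
#'   each column as its own marker.
#' @param contract optional model contract supplying a custom `importance`.
#' @return Tibble with columns `marker_id`, `importance`, sorted by the
#'   original marker order (stable ties).
#' @export
feature_importance <- function(fit, feature_map = NULL, contract = NULL) {
  scores <-
    if (!is.null(contract) && !is.null(contract$importance)) contract$importance(fit)
    else if (inherits(fit, "rrblup_fit")) abs(fit$u)
    else if (inherits(fit, "bayes_fit")) abs(fit$u)
    else if (inherits(fit, "penalized_fit")) {
      s <- rowMeans(abs(fit$beta)); setNames(as.numeric(s), rownames(fit$beta))
    } else {
      abort(sprintf("model of class '%s' does not support feature importances",
                    class(fit)[1L]))
    }
  if (is.null(feature_map)) {
    return(tibble(marker_id = names(scores) %||% paste0("f", seq_along(scores)),
                  importance = abs(unname(scores))))
  }
  stopifnot(length(scores) == nrow(feature_map))
  tibble(marker_id = feature_map$marker_id, score = abs(unname(scores))) |>
    dplyr::group_by(marker_id = factor(.data$marker_id,
                                       levels = unique(feature_map$marker_id))) |>
    dplyr::summarise(importance = sum(.data$score), .groups = "drop") |>
    dplyr::mutate(marker_id = as.character(.data$marker_id))
}

# built-in model registrations (run at load time)
register_builtin_models <- function() {
  enc_linear <- c("additive_012", "onehot")
  register_model("rrblup", list(
    kind = "param_free", trait_types = "continuous",
    default_encoding = "additive_012", allowed_encodings = "additive_012",
    fit = function(X, y, params, trait_type, seed) rrblup_fit(X, y)
  ), overwrite = TRUE)
  for (v in c("A", "B", "C")) {
    local({
      variant <- v
      register_model(paste0("bayes", variant), list(
        kind = "param_free", trait_types = "continuous",
        default_encoding = "additive_012", allowed_encodings = "additive_012",
        fit = function(X, y, params, trait_type, seed) {
          defaults <- list(pi = if (variant == "A") 0 else 0.95,
                           n_iter = 6000L, burn_in = 1000L, thin = 5L)
          args <- modifyList(defaults, params[intersect(names(params), names(defaults))])
          bayes_fit(X, y, variant = variant, pi = args$pi, n_iter = args$n_iter,
                    burn_in = args$burn_in, thin = args$thin, seed = seed)
        }
      ), overwrite = TRUE)
    })
  }
  strength_dim <- param_real(1e-4, 1e2, log = TRUE)
  register_model("linreg-l1", list(
    kind = "searchable", trait_types = c("continuous", "discrete"),
    default_encoding = "additive_012", allowed_encodings = enc_linear,
    space = hp_space(strength = strength_dim),
    fit = function(X, y, params, trait_type, seed)
      regularized_linear_fit(X, y, penalty = "l1", strength = params$strength)
  ), overwrite = TRUE)
  register_model("linreg-l2", list(
    kind = "searchable", trait_types = c("continuous", "discrete"),
    default_encoding = "additive_012", allowed_encodings = enc_linear,
    space = hp_space(strength = strength_dim),
    fit = function(X, y, params, trait_type, seed)
      regularized_linear_fit(X, y, penalty = "l2", strength = params$strength)
  ), overwrite = TRUE)
  register_model("elasticnet", list(
    kind = "searchable", trait_types = c("continuous", "discrete"),
    default_encoding = "additive_012", allowed_encodings = enc_linear,
    space = hp_space(strength = strength_dim, mix = param_real(0.05, 0.95)),
    fit = function(X, y, params, trait_type, seed)
      regularized_linear_fit(X, y, penalty = "elastic-net",
                             strength = params$strength, mix = params$mix)
  ), overwrite = TRUE)
}
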