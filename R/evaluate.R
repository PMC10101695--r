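#' Summarize all optimization runs under a results directory
#'
#' Walks `results_root` for run directories (identified by a
#' `run_manifest.json`), reads each run's manifest and test metrics, and
#' returns one row per run ordered lexicographically by (trait, split key,
#' model, seed) so repeated summarization is byte-identical. Malformed run
#' directories are kept as warning rows (`status = "malformed"`) rather
#' than aborting the whole summary.
#'
#' @param results_root directory containing run directories (at any depth).
#' @param out_csv optional path to also write the summary as CSV.
#' @return A tibble with identification columns, trial counts, best
#'   parameters (JSON) and one `test_*` column per metric.
#' @export
summarize_runs <- function(results_root, out_csv = NULL) {
  manifests <- sort(list.files(results_root, pattern = "^run_manifest\\.json$",
                               recursive = TRUE, full.names = TRUE))
  if (length(manifests) == 0L) abort(sprintf("no runs found under '%s'", results_root))
  rows <- purrr::map(manifests, function(mf) {
    dir <- dirname(mf)
    tryCatch({
      man <- read_json_file(mf)
      tm <- read_json_file(file.path(dir, "test_metrics.json"))
      tm <- tm[vapply(tm, is.numeric, logical(1))]
      names(tm) <- paste0("test_", names(tm))
      bp <- read_json_file(file.path(dir, "best_params.json"))
      dplyr::bind_cols(
        tibble(
          status = "ok",
          trait = man$trait, split_key = man$split$key, model = man$model,
          seed = man$seed, trait_type = man$trait_type,
          n_trials = man$n_trials_recorded, n_completed = man$n_completed,
          n_pruned = man$n_pruned,
          best_objective = if (is.numeric(man$best_objective) &&
                               length(man$best_objective) == 1L)
            man$best_objective else NA_real_,
          best_params = as.character(jsonlite::toJSON(bp, auto_unbox = TRUE, digits = NA)),
          run_dir = dir
        ),
        as_tibble(tm)
      )
    }, error = function(e) {
      warn(sprintf("skipping malformed run directory '%s': %s", dir,
                   conditionMessage(e)))
      tibble(status = "malformed", trait = NA_character_,
             split_key = NA_character_, model = NA_character_,
             seed = NA_integer_, run_dir = dir)
    })
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$trait, .data$split_key, .data$model, .data$seed,
                   .data$run_dir)
  if (!is.null(out_csv)) readr::write_csv(out, out_csv, progress = FALSE)
  out
}

#' Models-by-phenotypes metric table
#'
#' Pivots a run summary into a models x phenotypes matrix of one metric.
#' Missing (model, phenotype) combinations stay `NA`, never 0. The numeric
#' table is the contract; [plot_heatmap()] renders it.
#'
#' @param summary tibble from [summarize_runs()].
#' @param metric metric column to tabulate (with or without the `test_`
#'   prefix).
#' @return A tibble with a `model` column and one column per trait.
#' @export
heatmap_table <- function(summary, metric = "pearson_r") {
  col <- if (metric %in% names(summary)) metric else paste0("test_", metric)
  if (!col %in% names(summary)) {
    available <- sub("^test_", "", grep("^test_", names(summary), value = TRUE))
    abort(sprintf("unknown metric '%s' (available: %s)", metric,
                  paste(available, collapse = ", ")))
  }
  summary |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$model, .data$trait) |>
    dplyr::summarise(value = mean(.data[[col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value") |>
    dplyr::arrange(.data$model)
}

#' Render a heat map of model-by-phenotype performance
#' @param summary tibble from [summarize_runs()].
#' @param metric metric to display.
#' @return A ggplot tile plot.
#' @export
plot_heatmap <- function(summary, metric = "pearson_r") {
  tab <- heatmap_table(summary, metric)
  long <- tidyr::pivot_longer(tab, -"model", names_to = "trait",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$model,
                                     fill = .data$value)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)), na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "phenotype", y = "model", fill = metric) +
    ggplot2::theme_minimal()
}

#' Compare simulated effect sizes with model feature importances
#'
#' Pairs the known absolute effect sizes of a simulated phenotype with the
#' per-marker importances of a fitted model and reports their Spearman rank
#' correlation — a direct check of how well a model recovers the causal
#' architecture it was trained on.
#'
#' @param sim a `simulated_phenotype` from [simulate_phenotype()].
#' @param importances tibble with columns `marker_id`, `importance` (from
#'   [feature_importance()]).
#' @return A tibble of class `effect_importance` with columns `marker_id`,
#'   `true_effect` (absolute), `importance`, `causal`; the rank correlation
#'   is attached as attribute `rank_correlation`.
#' @export
effectsize_vs_importance <- function(sim, importances) {
  stopifnot(inherits(sim, "simulated_phenotype"))
  truth <- tibble(marker_id = names(sim$beta), true_effect = abs(unname(sim$beta)),
                  causal = names(sim$beta) %in% sim$causal_markers)
  if (!setequal(truth$marker_id, importances$marker_id)) {
    abort("marker sets of the simulation and the importances do not match")
  }
  out <- dplyr::left_join(truth, importances, by = "marker_id") |>
    dplyr::select("marker_id", "true_effect", "importance", "causal")
  rc <- suppressWarnings(cor(out$true_effect, out$importance, method = "spearman"))
  structure(out, rank_correlation = rc,
            class = c("effect_importance", class(out)))
}

#' Scatter plot of true effect sizes against importances
#' @param object an `effect_importance` table.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.effect_importance <- function(object, ...) {
  rc <- attr(object, "rank_correlation")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$true_effect,
                                       y = .data$importance,
                                       color = .data$causal)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "|true effect|", y = "feature importance",
                  title = sprintf("rank correlation = %.3f", rc)) +
    ggplot2::theme_minimal()
}
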