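#' Ablation variants of the forecaster
#'
#' Returns the `model_config` implementing a named ablation of the reference
#' architecture:
#'
#' * `gcn1`, `gcn2`, `gcn3` - one/two/three clipped GCN layers (`gcn2` is the
#'   full model);
#' * `gcn2_noclip` - two GCN layers without target-node extraction; node
#'   embeddings are mean-pooled per snapshot (pooling configurable via
#'   `base$noclip_pool`);
#' * `hidden16`, `hidden32`, `hidden64` - LSTM hidden size;
#' * `lstm_only` - no GCN and no graph: the target drug's raw window feeds
#'   the LSTM directly;
#' * `kg_gcn_mlp` - the LSTM replaced by a one-hidden-layer perceptron of 64
#'   ReLU units over the mean snapshot embedding;
#' * `gcn_lstm_single_node` - the full architecture on a single-node graph
#'   (no knowledge-graph relations).
#'
#' @param name Variant name (see above).
#' @param base Base `model_config` to modify.
#' @return A `model_config`.
#' @export
build_variant <- function(name, base = model_config()) {
  valid <- c(
    "gcn1", "gcn2", "gcn3", "gcn2_noclip", "hidden16", "hidden32",
    "hidden64", "lstm_only", "kg_gcn_mlp", "gcn_lstm_single_node"
  )
  if (!name %in% valid) {
    kgd_abort(
      sprintf(
        "unknown variant '%s'; valid names: %s",
        name, paste(valid, collapse = ", ")
      ),
      class = "kgd_error_argument"
    )
  }
  cfg <- base
  switch(name,
    gcn1 = cfg$n_gcn_layers <- 1L,
    gcn2 = cfg$n_gcn_layers <- 2L,
    gcn3 = cfg$n_gcn_layers <- 3L,
    gcn2_noclip = {
      cfg$n_gcn_layers <- 2L
      cfg$clip <- FALSE
    },
    hidden16 = cfg$hidden <- 16L,
    hidden32 = cfg$hidden <- 32L,
    hidden64 = cfg$hidden <- 64L,
    lstm_only = {
      cfg$n_gcn_layers <- 0L
      cfg$hop <- 0
    },
    kg_gcn_mlp = cfg$temporal <- "mlp",
    gcn_lstm_single_node = cfg$hop <- 0
  )
  cfg
}

#' Multi-seed training and evaluation experiment
#'
#' Trains one model per target drug and per seed, scores rolling one-step
#' forecasts over the test weeks (inverse-scaled to raw units), and reports
#' MAE/RMSE/SMAPE per seed with mean and sample standard deviation across
#' seeds. Metrics aggregate over all target drugs' test weeks.
#'
#' @param panel A demand panel (raw units).
#' @param graph A `drug_graph`.
#' @param targets Drug ids to forecast (default: all panel drugs).
#' @param variant Variant name (see [build_variant()]) or a `model_config`.
#' @param control A `train_config`; its `seed` is replaced per run.
#' @param seeds Integer seeds, one independent run each (default 0:4).
#' @param ... Passed to [fit_kgf()] (e.g. `window`, `padding`).
#' @return A `kgf_experiment`: list with `per_seed` (tibble of metrics),
#'   `per_drug` (tibble of per-seed per-drug metrics), `predictions` (all
#'   test forecasts), `summary` (mean and sd per metric), `variant`.
#' @export
run_experiment <- function(panel, graph, targets = NULL, variant = "gcn2",
                           control = train_config(), seeds = 0:4, ...) {
  config <- if (inherits(variant, "model_config")) {
    variant
  } else {
    build_variant(variant, model_config(hidden = control$hidden_dim,
      dropout = control$dropout
    ))
  }
  variant_name <- if (is.character(variant)) variant else "custom"
  targets <- targets %||% sort(unique(panel$drug_id))
  runs <- purrr::map_dfr(seeds, function(seed) {
    drug_seeds <- derive_seeds(seed, length(targets))
    purrr::map_dfr(seq_along(targets), function(k) {
      ctl <- control
      ctl$seed <- drug_seeds[k]
      fit <- fit_kgf(panel, graph, targets[k], config = config, control = ctl, ...)
      predict(fit, split = "test") |>
        mutate(drug_id = targets[k], seed = seed)
    })
  })
  per_seed <- runs |>
    group_by(.data$seed) |>
    group_modify(~ compute_metrics(.x, "actual", "predicted")) |>
    ungroup()
  per_drug <- runs |>
    group_by(.data$seed, .data$drug_id) |>
    group_modify(~ compute_metrics(.x, "actual", "predicted")) |>
    ungroup()
  summary <- per_seed |>
    tidyr::pivot_longer(c("mae", "rmse", "smape"),
      names_to = "metric", values_to = "value"
    ) |>
    group_by(.data$metric) |>
    summarise(
      mean = mean(.data$value),
      sd = if (n() > 1L) sd(.data$value) else 0,
      median = stats::median(.data$value),
      .groups = "drop"
    )
  structure(
    list(
      per_seed = per_seed,
      per_drug = per_drug,
      predictions = runs,
      summary = summary,
      variant = variant_name,
      seeds = seeds,
      targets = targets
    ),
    class = "kgf_experiment"
  )
}

#' @export
print.kgf_experiment <- function(x, ...) {
  cat(sprintf(
    "<kgf_experiment> variant %s | %d drugs x %d seeds\n",
    x$variant, length(x$targets), length(x$seeds)
  ))
  print(x$summary)
  invisible(x)
}

#' Run the ablation sweep
#'
#' Trains and evaluates a set of named variants under identical data and
#' seeds and returns one summary row per variant (MAE/RMSE/SMAPE mean and sd
#' across seeds), mirroring an ablation table layout.
#'
#' @param panel,graph,targets,control,seeds,... As in [run_experiment()].
#' @param variants Character vector of variant names (see [build_variant()]).
#' @return Tibble with one row per variant and metric summary columns; the
#'   full experiments are attached as attribute `"experiments"`.
#' @export
run_ablation <- function(panel, graph,
                         variants = c(
                           "gcn2", "gcn1", "gcn3", "gcn2_noclip",
                           "lstm_only", "kg_gcn_mlp", "gcn_lstm_single_node"
                         ),
                         targets = NULL, control = train_config(),
                         seeds = 0:4, ...) {
  experiments <- lapply(variants, function(v) {
    run_experiment(panel, graph,
      targets = targets, variant = v,
      control = control, seeds = seeds, ...
    )
  })
  names(experiments) <- variants
  rows <- purrr::map_dfr(experiments, function(ex) {
    ex$summary |>
      tidyr::pivot_wider(
        names_from = "metric",
        values_from = c("mean", "sd", "median")
      )
  }, .id = "variant")
  attr(rows, "experiments") <- experiments
  rows
}
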