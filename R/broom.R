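# broom-style methods for fitted objects and experiment reports.

#' Tidy a fitted forecaster
#'
#' One row per test-week forecast (raw demand units).
#'
#' @param x A `kgf_fit`.
#' @param split `"test"` (default), `"val"` or `"train"`.
#' @param ... Unused.
#' @return Tibble with `drug_id`, `week`, `actual`, `predicted`.
#' @method tidy kgf_fit
#' @export
tidy.kgf_fit <- function(x, split = "test", ...) {
  predict(x, split = split) |>
    mutate(drug_id = x$target, .before = 1L)
}

#' Glance at a fitted forecaster
#'
#' @param x A `kgf_fit`.
#' @param ... Unused.
#' @return One-row tibble: target, subgraph size, parameter count, epochs,
#'   best validation loss, and test metrics.
#' @method glance kgf_fit
#' @export
glance.kgf_fit <- function(x, ...) {
  m <- compute_metrics(predict(x, split = "test"), "actual", "predicted")
  total <- count_parameters(x$config)
  tibble(
    target = x$target,
    n_nodes = length(x$nodes),
    n_parameters = total$parameters[total$block == "total"],
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    mae = m$mae,
    rmse = m$rmse,
    smape = m$smape
  )
}

#' Tidy a multi-seed experiment
#'
#' @param x A `kgf_experiment`.
#' @param ... Unused.
#' @return Per-seed metrics tibble (columns `seed`, `mae`, `rmse`, `smape`,
#'   `n`).
#' @method tidy kgf_experiment
#' @export
tidy.kgf_experiment <- function(x, ...) {
  x$per_seed
}

#' Glance at a multi-seed experiment
#'
#' @param x A `kgf_experiment`.
#' @param ... Unused.
#' @return One-row tibble of metric means, standard deviations and medians
#'   across seeds.
#' @method glance kgf_experiment
#' @export
glance.kgf_experiment <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(
      names_from = "metric",
      values_from = c("mean", "sd", "median")
    ) |>
    mutate(variant = x$variant, n_seeds = length(x$seeds), .before = 1L)
}
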