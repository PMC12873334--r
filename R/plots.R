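# ggplot2 visualisations for panels, graphs, fits and experiments.

#' Plot a demand panel
#'
#' Weekly demand lines per drug; unobserved (zero-filled) weeks are marked.
#'
#' @param panel A demand panel tibble.
#' @param drugs Optional subset of drug ids.
#' @return A ggplot object.
#' @export
plot_panel <- function(panel, drugs = NULL) {
  validate_panel(panel)
  if (!is.null(drugs)) {
    panel <- panel |> filter(.data$drug_id %in% drugs)
  }
  ggplot(panel, aes(x = .data$week, y = .data$demand, colour = .data$drug_id)) +
    geom_line(linewidth = 0.4) +
    geom_point(
      data = panel |> filter(!.data$observed),
      shape = 4, size = 1, colour = "grey40"
    ) +
    labs(x = "week", y = "units sold", colour = "drug") +
    theme_minimal()
}

#' Plot a drug knowledge graph
#'
#' Force-directed layout with substitution and combination edges
#' distinguished by linetype; device nodes are isolated.
#'
#' @param graph A `drug_graph`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_graph <- function(graph, seed = 42L) {
  stopifnot(inherits(graph, "drug_graph"))
  ig <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
  xy <- with_seed(seed, igraph::layout_with_fr(ig))
  nodes <- tibble(
    drug_id = graph$node_index,
    x = xy[, 1], y = xy[, 2],
    item_type = unname(graph$item_type)
  )
  edges <- graph$relations |>
    left_join(nodes |> select("drug_id", xa = "x", ya = "y"),
      by = c(endpoint_a = "drug_id")
    ) |>
    left_join(nodes |> select("drug_id", xb = "x", yb = "y"),
      by = c(endpoint_b = "drug_id")
    )
  ggplot() +
    geom_segment(
      data = edges,
      aes(
        x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
        linetype = .data$relation
      ),
      colour = "grey50"
    ) +
    geom_point(
      data = nodes,
      aes(x = .data$x, y = .data$y, shape = .data$item_type),
      size = 3
    ) +
    geom_text(
      data = nodes,
      aes(x = .data$x, y = .data$y, label = .data$drug_id),
      vjust = -1, size = 3
    ) +
    theme_void() +
    labs(linetype = "relation", shape = "item type")
}

#' Plot the training-loss trajectory of a fit
#'
#' @param object A `kgf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kgf_fit
#' @export
autoplot.kgf_fit <- function(object, ...) {
  object$trajectory |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
      names_to = "set", values_to = "loss"
    ) |>
    ggplot(aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    geom_vline(xintercept = object$best_epoch, linetype = 2, colour = "grey50") +
    labs(
      x = "epoch", y = "MSE loss (scaled units)",
      title = sprintf("Training trajectory: %s", object$target)
    ) +
    theme_minimal()
}

#' Plot forecasts against actual demand
#'
#' @param fit A `kgf_fit`.
#' @param split Evaluation split (default `"test"`).
#' @return A ggplot object.
#' @export
plot_forecast <- function(fit, split = "test") {
  predict(fit, split = split) |>
    tidyr::pivot_longer(c("actual", "predicted"),
      names_to = "series", values_to = "demand"
    ) |>
    ggplot(aes(x = .data$week, y = .data$demand, colour = .data$series)) +
    geom_line() +
    geom_point(size = 1) +
    labs(
      x = "week", y = "units sold",
      title = sprintf("%s: one-step forecasts (%s weeks)", fit$target, split)
    ) +
    theme_minimal()
}

#' Plot per-seed metrics of an experiment
#'
#' @param object A `kgf_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kgf_experiment
#' @export
autoplot.kgf_experiment <- function(object, ...) {
  object$per_seed |>
    tidyr::pivot_longer(c("mae", "rmse", "smape"),
      names_to = "metric", values_to = "value"
    ) |>
    ggplot(aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_point(aes(colour = factor(.data$seed)), position = position_jitter(width = 0.1)) +
    facet_wrap(~ .data$metric, scales = "free") +
    labs(
      x = NULL, y = "value", colour = "seed",
      title = sprintf("Test metrics across seeds: %s", object$variant)
    ) +
    theme_minimal()
}
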