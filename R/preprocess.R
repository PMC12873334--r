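#' Aggregate transactions into a weekly demand panel
#'
#' Sums transaction quantities per drug per ISO-8601 week and fills every
#' unrecorded drug-week with zero so the panel spans a gapless, consecutive
#' week axis (absence of sales is read as zero demand, not missing data).
#' The `observed` flag records whether a week had at least one transaction —
#' the "valid sales week" notion used by [filter_min_history()].
#'
#' @param transactions Data frame with columns `drug_id`, `date` (`Date` or
#'   ISO-8601 string), `quantity` (non-negative numbers).
#' @param span Optional length-2 `Date` vector forcing the panel to cover the
#'   ISO weeks containing these dates (defaults to the transaction range).
#' @return A demand panel: tibble with columns `drug_id`, `week` (1-based
#'   consecutive index), `week_start` (`Date`, Monday), `iso_week` (label),
#'   `demand`, `observed` (logical).
#' @export
aggregate_weekly <- function(transactions, span = NULL) {
  assert_columns(transactions, c("drug_id", "date", "quantity"), "transactions")
  if (nrow(transactions) == 0L) {
    kgd_abort("transaction table is empty", class = "kgd_error_argument")
  }
  tx <- as_tibble(transactions)
  tx$date <- as.Date(tx$date)
  if (any(is.na(tx$date))) {
    kgd_abort("unparseable date(s) in transactions", class = "kgd_error_validation")
  }
  if (any(is.na(tx$quantity)) || any(tx$quantity < 0)) {
    kgd_abort("quantities must be non-negative", class = "kgd_error_validation")
  }
  tx$week_start <- iso_week_start(tx$date)
  lo <- min(tx$week_start)
  hi <- max(tx$week_start)
  if (!is.null(span)) {
    span <- iso_week_start(as.Date(span))
    lo <- min(lo, span)
    hi <- max(hi, span)
  }
  weeks <- tibble(
    week_start = seq(lo, hi, by = 7L),
  ) |>
    mutate(week = row_number(), iso_week = iso_week_label(.data$week_start))
  cells <- tx |>
    group_by(.data$drug_id, .data$week_start) |>
    summarise(demand = sum(.data$quantity), n_tx = n(), .groups = "drop")
  tidyr::expand_grid(
    drug_id = sort(unique(tx$drug_id)),
    week_start = weeks$week_start
  ) |>
    left_join(cells, by = c("drug_id", "week_start")) |>
    left_join(weeks, by = "week_start") |>
    mutate(
      demand = tidyr::replace_na(.data$demand, 0),
      observed = tidyr::replace_na(.data$n_tx, 0L) > 0L
    ) |>
    select("drug_id", "week", "week_start", "iso_week", "demand", "observed") |>
    arrange(.data$drug_id, .data$week)
}

validate_panel <- function(panel) {
  assert_columns(panel, c("drug_id", "week", "demand", "observed"), "demand panel")
  invisible(panel)
}

#' Demand panel as drug-by-week matrices
#'
#' @param panel A demand panel (long tibble, see [aggregate_weekly()]).
#' @return List with `demand` (drugs x weeks matrix), `mask` (0/1 matrix of
#'   observed weeks), `drug_ids`, `weeks` (integer axis).
#' @export
panel_matrix <- function(panel) {
  validate_panel(panel)
  drugs <- sort(unique(panel$drug_id))
  weeks <- sort(unique(panel$week))
  if (!identical(weeks, seq(min(weeks), max(weeks)))) {
    kgd_abort("panel week axis has gaps", class = "kgd_error_validation")
  }
  demand <- matrix(0, length(drugs), length(weeks), dimnames = list(drugs, weeks))
  mask <- demand
  i <- match(panel$drug_id, drugs)
  j <- match(panel$week, weeks)
  demand[cbind(i, j)] <- panel$demand
  mask[cbind(i, j)] <- as.numeric(panel$observed)
  list(demand = demand, mask = mask, drug_ids = drugs, weeks = weeks)
}

#' Drop drugs with insufficient sales history
#'
#' Retains exactly the drugs with at least `min_valid_weeks` valid sales
#' weeks (weeks with at least one transaction). Sparsely sold or discontinued
#' items would otherwise inject noise into training. The week axis is
#' unchanged.
#'
#' @param panel A demand panel.
#' @param min_valid_weeks Minimum number of valid weeks (default 40).
#' @return The filtered panel (same columns).
#' @export
filter_min_history <- function(panel, min_valid_weeks = 40) {
  validate_panel(panel)
  keep <- panel |>
    group_by(.data$drug_id) |>
    summarise(valid = sum(.data$observed), .groups = "drop") |>
    filter(.data$valid >= min_valid_weeks)
  out <- panel |> filter(.data$drug_id %in% keep$drug_id)
  if (nrow(out) == 0L) {
    warn("all drugs filtered out: empty panel")
  }
  out
}

#' Correct outliers by the sliding-window three-sigma rule
#'
#' Slides a window of `window_length` weeks over the series with stride 1.
#' Within each window, any value deviating from the window mean by more than
#' `sigma` population standard deviations is replaced by that window's mean;
#' means and standard deviations are always computed from the original
#' (pre-replacement) values, in a single sweep. A value covered by several
#' firing windows takes the mean of the last window (left to right) in which
#' it fires. Constant windows (zero standard deviation) never fire.
#'
#' @param series Numeric vector of weekly values.
#' @param window_length Window size in weeks (default 16, the sample window).
#' @param sigma Deviation threshold in standard deviations (default 3).
#' @return Numeric vector of the same length with outliers replaced.
#' @export
clip_outliers <- function(series, window_length = 16, sigma = 3) {
  if (window_length < 2) {
    kgd_abort("window_length must be at least 2", class = "kgd_error_argument")
  }
  n <- length(series)
  if (n < window_length) {
    warn("series shorter than the window: returned unchanged")
    return(series)
  }
  out <- series
  for (start in seq_len(n - window_length + 1L)) {
    idx <- start:(start + window_length - 1L)
    w <- series[idx]
    m <- mean(w)
    s <- sqrt(mean((w - m)^2)) # population formula
    if (s == 0) next
    fires <- abs(w - m) > sigma * s
    out[idx[fires]] <- m
  }
  out
}

#' Chronological train / validation / test split
#'
#' The final `test_weeks` weeks of the panel are reserved for evaluation, the
#' `val_weeks` weeks immediately preceding them for tuning and early
#' stopping, and all remaining history for training. The training range must
#' admit at least one sliding-window sample (`window + 1` weeks).
#'
#' @param panel A demand panel.
#' @param test_weeks Test length in weeks (default 8).
#' @param val_weeks Validation length in weeks (default 4).
#' @param window Sample window length used downstream (default 16).
#' @return A `split_spec`: list with integer week-index vectors `train`,
#'   `val`, `test`.
#' @export
chronological_split <- function(panel, test_weeks = 8, val_weeks = 4, window = 16) {
  validate_panel(panel)
  weeks <- sort(unique(panel$week))
  L <- length(weeks)
  need <- test_weeks + val_weeks + window + 1
  if (L < need) {
    kgd_abort(
      sprintf(
        "panel has %d weeks; at least %d are needed (%d test + %d val + %d-week window + 1 target)",
        L, need, test_weeks, val_weeks, window
      ),
      class = "kgd_error_history"
    )
  }
  structure(
    list(
      train = weeks[seq_len(L - test_weeks - val_weeks)],
      val = weeks[(L - test_weeks - val_weeks + 1):(L - test_weeks)],
      test = weeks[(L - test_weeks + 1):L]
    ),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "<split_spec> train %d-%d | val %d-%d | test %d-%d\n",
    min(x$train), max(x$train), min(x$val), max(x$val), min(x$test), max(x$test)
  ))
  invisible(x)
}

#' Min-max scaling fitted on a restricted range
#'
#' Fits a min-max transform on `fit_idx` only (the training weeks) and
#' applies it to the whole series, so validation and test values may fall
#' outside \[0, 1\]. A constant fit range maps to all zeros by convention.
#' Metrics are always computed after the inverse transform, in raw units.
#'
#' @param series Numeric vector.
#' @param fit_idx Integer indices of the values used to fit the transform.
#' @return List with `scaled` (transformed series), `transform` and `inverse`
#'   (functions), `min`, `max`.
#' @export
scale_series <- function(series, fit_idx = seq_along(series)) {
  if (length(fit_idx) == 0L) {
    kgd_abort("fit_idx must be non-empty", class = "kgd_error_argument")
  }
  lo <- min(series[fit_idx])
  hi <- max(series[fit_idx])
  if (hi > lo) {
    fwd <- function(x) (x - lo) / (hi - lo)
    inv <- function(x) x * (hi - lo) + lo
  } else {
    fwd <- function(x) rep(0, length(x))
    inv <- function(x) rep(lo, length(x))
  }
  list(scaled = fwd(series), transform = fwd, inverse = inv, min = lo, max = hi)
}

#' Assemble sliding-window graph samples for a target drug
#'
#' For the target drug, extracts its `hop`-neighbourhood from the knowledge
#' graph (restricted to drugs present in the panel) and slides a
#' `window`-week window over the series with stride one week. Each admissible
#' anchor week `t` yields one supervised sample: `window` snapshots of node
#' features and the target drug's demand at week `t + 1` as the label.
#' Snapshot `s` carries, for every subgraph node, that node's demand over the
#' `window` weeks ending at the snapshot's week. With `padding = "causal"`
#' (default) the history is truncated at the left edge of the sample window
#' and zero-padded, so a sample touches exactly `window` raw weeks; with
#' `padding = "full"` real earlier weeks are used where available (a sample
#' then spans up to `2 * window - 1` raw weeks). Both readings give node
#' features of dimension `window`, matching the model's input layer.
#'
#' @param panel A demand panel (optionally already scaled).
#' @param graph A `drug_graph` covering the panel drugs.
#' @param target Target drug id.
#' @param window Window length in weeks (default 16).
#' @param hop Neighbourhood radius (default 2).
#' @param clip Apply the in-window three-sigma outlier rule to each node's
#'   window slice before building snapshots (default TRUE). Clipping inside
#'   the sample window uses no information from later weeks.
#' @param padding `"causal"` or `"full"` (see Details).
#' @return A `graph_window_set`: list of samples, each with elements
#'   `snapshot_features` (list of `window` matrices, nodes x `window`),
#'   `target_value`, `week_of_target`; attributes carry the induced
#'   `adjacency`, `nodes`, `target_position`, `window` and `padding`.
#' @export
assemble_windows <- function(panel, graph, target, window = 16, hop = 2,
                             clip = TRUE, padding = c("causal", "full")) {
  padding <- match.arg(padding)
  validate_panel(panel)
  if (window < 1) {
    kgd_abort("window must be at least 1", class = "kgd_error_argument")
  }
  mat <- panel_matrix(panel)
  if (!target %in% mat$drug_ids) {
    kgd_abort(
      sprintf("target drug %s is not in the panel (filtered out?)", target),
      class = "kgd_error_lookup"
    )
  }
  sub <- khop_subgraph(restrict_graph(graph, mat$drug_ids), target, hop)
  dem <- mat$demand[sub$nodes, , drop = FALSE]
  L <- ncol(dem)
  anchors <- if (L > window) seq(window, L - 1L) else integer(0)
  if (length(anchors) == 0L) {
    warn("series too short for any sample window")
  }
  samples <- lapply(anchors, function(t) {
    win <- dem[, (t - window + 1L):t, drop = FALSE]
    if (clip) {
      win <- matrix(
        t(apply(win, 1L, clip_outliers, window_length = window)),
        nrow = length(sub$nodes), byrow = FALSE
      )
    }
    snaps <- lapply(seq_len(window), function(s) {
      if (padding == "causal") {
        feat <- cbind(
          matrix(0, nrow(win), window - s),
          win[, seq_len(s), drop = FALSE]
        )
      } else {
        cols <- (t - window + s - window + 1L):(t - window + s)
        feat <- matrix(0, nrow(dem), window)
        ok <- cols >= 1L
        feat[, ok] <- dem[, cols[ok], drop = FALSE]
      }
      dimnames(feat) <- NULL
      feat
    })
    list(
      snapshot_features = snaps,
      target_value = dem[sub$target_position, t + 1L],
      week_of_target = mat$weeks[t + 1L]
    )
  })
  structure(
    samples,
    adjacency = sub$adjacency,
    nodes = sub$nodes,
    target_position = sub$target_position,
    target = target,
    window = window,
    padding = padding,
    class = "graph_window_set"
  )
}

#' @export
print.graph_window_set <- function(x, ...) {
  cat(sprintf(
    "<graph_window_set> target %s: %d samples, %d-node subgraph, window %d\n",
    attr(x, "target"), length(x), length(attr(x, "nodes")), attr(x, "window")
  ))
  invisible(x)
}

# Scale every drug's series by its own min-max fitted on the training weeks.
# Returns the scaled panel plus the per-drug inverse transforms.
scale_panel <- function(panel, split) {
  validate_panel(panel)
  fit_weeks <- split$train
  scaled <- panel |>
    group_by(.data$drug_id) |>
    arrange(.data$week, .by_group = TRUE) |>
    group_modify(function(df, key) {
      sc <- scale_series(df$demand, which(df$week %in% fit_weeks))
      df$demand <- sc$scaled
      df
    }) |>
    ungroup()
  scalers <- panel |>
    group_by(.data$drug_id) |>
    arrange(.data$week, .by_group = TRUE) |>
    group_map(function(df, key) scale_series(df$demand, which(df$week %in% fit_weeks)))
  names(scalers) <- sort(unique(panel$drug_id))
  list(panel = scaled, scalers = scalers)
}
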