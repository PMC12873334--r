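#' Training configuration
#'
#' Optimiser and schedule settings. The defaults are the selected optimum of
#' the grid search over learning rate \{0.0001, 0.001, 0.005\}, hidden
#' dimension \{16, 32, 64\} and dropout \{0.1, 0.2, 0.3, 0.5\}: learning rate
#' 0.001, hidden 64, dropout 0.2, with Adam, early stopping after 500 epochs
#' without validation-loss improvement, and at most 5000 epochs.
#'
#' @param learning_rate Adam learning rate.
#' @param hidden_dim Temporal-block hidden size (overrides the model config).
#' @param dropout Dropout rate (overrides the model config).
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Maximum training epochs.
#' @param seed Seed for weight initialisation and dropout.
#' @param min_delta Minimum decrease of the validation loss that counts as an
#'   improvement (guards against float noise).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, hidden_dim = 64, dropout = 0.2,
                         patience = 500, max_epochs = 5000, seed = 0L,
                         min_delta = 1e-8) {
  stopifnot(patience <= max_epochs, learning_rate >= 0, patience >= 1)
  structure(
    list(
      learning_rate = learning_rate, hidden_dim = as.integer(hidden_dim),
      dropout = dropout, patience = as.integer(patience),
      max_epochs = as.integer(max_epochs), seed = as.integer(seed),
      min_delta = min_delta
    ),
    class = "train_config"
  )
}

#' Train a model by Adam with early stopping
#'
#' Minimises the mean-squared-error objective over the training samples by
#' full-batch Adam. After every epoch the validation loss is evaluated
#' (dropout off); the weights with the best validation loss are kept and
#' training halts when the validation loss has not improved for `patience`
#' epochs, or at `max_epochs`. Fully reproducible given the seed.
#'
#' @param params Initial `model_params` (see [init_model_params()]).
#' @param data_train,data_val Batched sample sets from assembled windows
#'   (internal layout; produced by [fit_kgf()] or `build_model_data`).
#' @param config The `model_config` the parameters were built for.
#' @param control A `train_config`.
#' @return List with `params` (best weights), `trajectory` (tibble of
#'   per-epoch `train_loss`, `val_loss`), `best_epoch`, `epochs_run`.
#' @export
train_model <- function(params, data_train, data_val, config,
                        control = train_config()) {
  if (data_train$n_samples == 0L || data_val$n_samples == 0L) {
    kgd_abort("training and validation sets must be non-empty",
      class = "kgd_error_argument"
    )
  }
  state <- adam_init(params)
  best <- list(params = params, val = Inf, epoch = 0L)
  wait <- 0L
  train_loss <- val_loss <- numeric(0)
  with_seed(control$seed + 1L, {
    for (epoch in seq_len(control$max_epochs)) {
      fwd <- train_step(params, config, data_train, training = TRUE)
      if (!is.finite(fwd$loss)) {
        kgd_abort(
          sprintf("non-finite training loss at epoch %d", epoch),
          class = "kgd_error_numeric"
        )
      }
      step <- adam_step(params, fwd$grads, state, control$learning_rate)
      params <- step$params
      state <- step$state
      train_loss[epoch] <- fwd$loss
      vl <- forward_batch(params, config, data_val, training = FALSE)$loss
      val_loss[epoch] <- vl
      if (vl < best$val - control$min_delta) {
        best <- list(params = params, val = vl, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
  })
  list(
    params = best$params,
    trajectory = tibble(
      epoch = seq_along(train_loss),
      train_loss = train_loss,
      val_loss = val_loss
    ),
    best_epoch = best$epoch,
    best_val_loss = best$val,
    epochs_run = length(train_loss)
  )
}

#' Fit the forecaster for one target drug
#'
#' End-to-end per-drug fit: chronological 8/4/remainder split, per-drug
#' min-max scaling fitted on the training weeks, sliding-window sample
#' assembly over the target's graph neighbourhood, and Adam training with
#' early stopping. Forecasts are produced as rolling one-step predictions
#' using true observed history (teacher forcing), then inverse-scaled to raw
#' demand units.
#'
#' @param panel A demand panel (raw units; see [aggregate_weekly()]).
#' @param graph A `drug_graph`.
#' @param target Target drug id (must survive filtering / be in the panel).
#' @param config A `model_config` (default: the reference architecture).
#' @param control A `train_config`. Its `hidden_dim` and `dropout` override
#'   the model config.
#' @param window Sample window length (default 16).
#' @param test_weeks,val_weeks Chronological split sizes (defaults 8 and 4).
#' @param scale Min-max scale each drug on the training weeks (default TRUE).
#' @param clip Apply in-window outlier correction during assembly.
#' @param padding Snapshot padding, `"causal"` (default) or `"full"`.
#' @return A `kgf_fit` object; see [predict.kgf_fit()], [tidy.kgf_fit()],
#'   [glance.kgf_fit()].
#' @export
fit_kgf <- function(panel, graph, target, config = model_config(),
                    control = train_config(), window = 16, test_weeks = 8,
                    val_weeks = 4, scale = TRUE, clip = TRUE,
                    padding = "causal") {
  stopifnot(inherits(config, "model_config"), inherits(control, "train_config"))
  config$hidden <- control$hidden_dim
  config$dropout <- control$dropout
  config$feature_dim <- as.integer(window)
  split <- chronological_split(panel, test_weeks, val_weeks, window)
  scalers <- NULL
  work <- panel
  if (scale) {
    sc <- scale_panel(panel, split)
    work <- sc$panel
    scalers <- sc$scalers
  }
  windows <- assemble_windows(
    work, graph, target,
    window = window, hop = config$hop, clip = clip, padding = padding
  )
  weeks <- vapply(windows, function(s) s$week_of_target, numeric(1))
  sets <- list(
    train = which(weeks %in% split$train),
    val = which(weeks %in% split$val),
    test = which(weeks %in% split$test)
  )
  if (length(sets$train) == 0L || length(sets$val) == 0L) {
    kgd_abort("not enough history to form training and validation samples",
      class = "kgd_error_history"
    )
  }
  data <- lapply(sets, function(idx) build_model_data(windows, idx))
  params0 <- init_model_params(config, seed = control$seed)
  fit <- train_model(params0, data$train, data$val, config, control)
  actual <- panel |>
    filter(.data$drug_id == target) |>
    arrange(.data$week)
  structure(
    list(
      target = target,
      config = config,
      control = control,
      params = fit$params,
      trajectory = fit$trajectory,
      best_epoch = fit$best_epoch,
      best_val_loss = fit$best_val_loss,
      epochs_run = fit$epochs_run,
      data = data,
      split = split,
      inverse = if (scale) scalers[[target]]$inverse else identity,
      actual = setNames(actual$demand, actual$week),
      nodes = attr(windows, "nodes")
    ),
    class = "kgf_fit"
  )
}

#' @export
print.kgf_fit <- function(x, ...) {
  cat(sprintf(
    "<kgf_fit> target %s | %d-node subgraph | %d epochs (best %d) | val loss %.5g\n",
    x$target, length(x$nodes), x$epochs_run, x$best_epoch, x$best_val_loss
  ))
  invisible(x)
}

#' Forecasts from a fitted model
#'
#' Rolling one-step forecasts for the requested split, produced with true
#' observed history as input (teacher forcing) and inverse-scaled to raw
#' demand units. With `recursive = TRUE` the test weeks are instead forecast
#' recursively: each predicted (scaled) value replaces the true one in later
#' input windows.
#'
#' @param object A `kgf_fit`.
#' @param split `"test"` (default), `"val"` or `"train"`.
#' @param recursive Recursive multi-step forecasting over the split
#'   (default FALSE).
#' @param ... Unused.
#' @return Tibble with columns `week`, `actual`, `predicted`.
#' @export
predict.kgf_fit <- function(object, split = "test", recursive = FALSE, ...) {
  data <- object$data[[split]]
  if (is.null(data)) {
    kgd_abort(sprintf("unknown split: %s", split), class = "kgd_error_argument")
  }
  if (!recursive) {
    yhat <- forward_batch(object$params, object$config, data, training = FALSE)$yhat
  } else {
    nb <- data$n_samples
    nn <- data$n_nodes
    tw <- data$window
    tpos <- data$target_position
    yhat <- numeric(nb)
    x_all <- data$x_all
    for (b in seq_len(nb)) {
      rows <- as.vector(outer(1:nn, (seq_len(tw) - 1L) * nb * nn + (b - 1L) * nn, "+"))
      one <- data
      one$x_all <- x_all[rows, , drop = FALSE]
      one$y <- data$y[b]
      one$target_rows <- (seq_len(tw) - 1L) * nn + tpos
      one$n_samples <- 1L
      yhat[b] <- forward_batch(object$params, object$config, one, training = FALSE)$yhat
      if (b < nb) {
        # overwrite the target drug's later feature entries with the forecast
        # (causal padding: window position j appears in snapshot s >= j at
        # column tw - s + j)
        for (bb in (b + 1):nb) {
          j <- tw + 1L - (bb - b) # forecast week's position in sample bb's window
          if (j >= 1L) {
            for (s in j:tw) {
              x_all[(s - 1L) * nb * nn + (bb - 1L) * nn + tpos, tw - s + j] <- yhat[b]
            }
          }
        }
      }
    }
  }
  tibble(
    week = data$weeks,
    actual = unname(object$actual[as.character(data$weeks)]),
    predicted = object$inverse(yhat)
  )
}

#' Grid search over training hyperparameters
#'
#' Trains one model per grid point and per target drug, scores the
#' validation-set SMAPE (inverse-scaled), and returns the configuration with
#' the lowest mean validation SMAPE. Ties are broken by grid enumeration
#' order (first row wins).
#'
#' @param panel A demand panel.
#' @param graph A `drug_graph`.
#' @param targets Drug ids to fit (default: all panel drugs).
#' @param grid Data frame with columns among `learning_rate`, `hidden_dim`,
#'   `dropout` (default: the full search grid).
#' @param control Base `train_config` supplying the remaining settings.
#' @param config Base `model_config`.
#' @param ... Passed to [fit_kgf()].
#' @return The winning `train_config`; the scored grid is attached as
#'   attribute `"scores"` (tibble with a `val_smape` column).
#' @export
grid_search <- function(panel, graph, targets = NULL, grid = NULL,
                        control = train_config(), config = model_config(),
                        ...) {
  if (is.null(grid)) {
    grid <- tidyr::expand_grid(
      learning_rate = c(0.0001, 0.001, 0.005),
      hidden_dim = c(16, 32, 64),
      dropout = c(0.1, 0.2, 0.3, 0.5)
    )
  }
  grid <- as_tibble(grid)
  if (nrow(grid) == 0L) {
    kgd_abort("empty search grid", class = "kgd_error_argument")
  }
  targets <- targets %||% unique(panel$drug_id)
  scores <- vapply(seq_len(nrow(grid)), function(r) {
    ctl <- control
    for (nm in names(grid)) ctl[[nm]] <- grid[[nm]][r]
    preds <- purrr::map_dfr(targets, function(tg) {
      fit <- fit_kgf(panel, graph, tg, config = config, control = ctl, ...)
      predict(fit, split = "val")
    })
    compute_metrics(preds, truth = "actual", estimate = "predicted")$smape
  }, numeric(1))
  best <- which.min(scores) # ties: first enumerated grid row
  out <- control
  for (nm in names(grid)) out[[nm]] <- grid[[nm]][best]
  attr(out, "scores") <- grid |> mutate(val_smape = scores)
  out
}
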