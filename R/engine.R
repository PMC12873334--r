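# Batched training engine: R-side packing and optimiser around the compiled
# forward/backward kernel in src/engine.cpp.
#
# All samples of one target drug share the same induced subgraph, so a batch
# of B samples over an N-node subgraph with T_w snapshots is processed as one
# (T_w*B*N)-row feature matrix per GCN layer (rows ordered snapshot-major,
# then sample, then node). The kernel's hand-derived gradients are checked
# against finite differences in the test suite.

# Pack a subset of assembled window samples into the batched layout.
build_model_data <- function(windows, idx = seq_along(windows)) {
  stopifnot(inherits(windows, "graph_window_set"))
  samples <- windows[idx]
  if (length(samples) == 0L) {
    kgd_abort("no samples in the requested subset", class = "kgd_error_argument")
  }
  adj <- attr(windows, "adjacency")
  n <- nrow(adj)
  b <- length(samples)
  tw <- attr(windows, "window")
  tpos <- attr(windows, "target_position")
  x_all <- do.call(rbind, lapply(seq_len(tw), function(s) {
    do.call(rbind, lapply(samples, function(smp) smp$snapshot_features[[s]]))
  }))
  list(
    ahat = normalize_adjacency(adj)$propagation_matrix,
    x_all = x_all,
    y = vapply(samples, function(smp) smp$target_value, numeric(1)),
    weeks = vapply(samples, function(smp) smp$week_of_target, numeric(1)),
    # row of each (snapshot, sample) pair's target node in the stacked layout
    target_rows = rep((seq_len(tw) - 1L) * b * n, each = b) +
      (rep(seq_len(b), tw) - 1L) * n + tpos,
    target_position = tpos,
    n_nodes = n,
    n_samples = b,
    window = tw
  )
}

# Kernel-facing view of a model_config.
engine_conf <- function(config) {
  list(
    n_gcn_layers = config$n_gcn_layers,
    clip = isTRUE(config$clip),
    pool_mean = identical(config$noclip_pool, "mean"),
    use_lstm = identical(config$temporal, "lstm"),
    hidden = config$hidden,
    dropout = config$dropout
  )
}

# Forward pass only. With training = TRUE, inverted-dropout masks are drawn
# from R's RNG stream (reproducible under set.seed).
forward_batch <- function(params, config, data, training = FALSE) {
  res <- .engine_pass(
    params, engine_conf(config), data$x_all, data$ahat, data$y,
    data$target_rows, data$n_samples, data$window, training, FALSE
  )
  res$yhat <- drop(res$yhat)
  res
}

# Forward + backward in one call; grads match the structure of `params`.
train_step <- function(params, config, data, training = TRUE) {
  res <- .engine_pass(
    params, engine_conf(config), data$x_all, data$ahat, data$y,
    data$target_rows, data$n_samples, data$window, training, TRUE
  )
  res$yhat <- drop(res$yhat)
  res$grads <- conform_grads(params, res$grads)
  res
}

# The kernel returns vectors as n x 1 matrices; match parameter shapes.
conform_grads <- function(p, g) {
  if (is.list(p)) {
    out <- Map(conform_grads, p, g[names(p) %||% seq_along(p)])
    names(out) <- names(p)
    out
  } else if (is.null(dim(p))) {
    drop(g)
  } else {
    g
  }
}

# Zero-filled structure matching a parameter list.
zero_like <- function(x) {
  if (is.list(x)) {
    lapply(x, zero_like)
  } else if (is.null(dim(x))) {
    numeric(length(x))
  } else {
    array(0, dim = dim(x))
  }
}

# One Adam step over nested parameter/gradient structures.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      list(
        p = lapply(out, `[[`, "p"),
        m = lapply(out, `[[`, "m"),
        v = lapply(out, `[[`, "v")
      )
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- Map(upd, params, grads[names(params)], state$m, state$v)
  list(
    params = structure(lapply(out, `[[`, "p"),
      class = "model_params",
      config = attr(params, "config")
    ),
    state = list(
      t = state$t,
      m = lapply(out, `[[`, "m"),
      v = lapply(out, `[[`, "v")
    )
  )
}

adam_init <- function(params) {
  list(t = 0L, m = zero_like(params), v = zero_like(params))
}
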