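# The compiled batched engine is validated two ways: against the exported
# single-sample operations (an independent composition of the same maths) and
# against finite-difference gradients.

make_window_set <- function(n_nodes = 3, n_samples = 4, window = 5, seed = 9,
                            chain = TRUE) {
  kgdemand:::with_seed(seed, {
    adj <- matrix(0, n_nodes, n_nodes)
    if (chain && n_nodes > 1) {
      for (i in seq_len(n_nodes - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
    }
    samples <- lapply(seq_len(n_samples), function(b) {
      list(
        snapshot_features = lapply(seq_len(window), function(s) {
          matrix(runif(n_nodes * window), n_nodes, window)
        }),
        target_value = runif(1),
        week_of_target = b
      )
    })
    structure(
      samples,
      adjacency = adj, nodes = sprintf("N%d", seq_len(n_nodes)),
      target_position = min(2L, n_nodes), target = "N2", window = as.integer(window),
      padding = "causal", class = "graph_window_set"
    )
  })
}

test_that("the batched engine equals the composed single-sample operations", {
  win <- make_window_set()
  data <- kgdemand:::build_model_data(win)
  cfg <- model_config(
    hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0, hop = 2
  )
  params <- init_model_params(cfg, seed = 10)
  got <- kgdemand:::forward_batch(params, cfg, data)$yhat

  ng <- normalize_adjacency(attr(win, "adjacency"))
  lstm_ref <- kgdemand:::lstm_params_split(params$lstm, cfg$hidden)
  want <- vapply(win, function(smp) {
    emb <- t(vapply(
      smp$snapshot_features,
      function(X) clipped_gcn_forward(ng, X, params$gcn, attr(win, "target_position")),
      numeric(cfg$gcn_dim)
    ))
    predict_head(lstm_forward(emb, lstm_ref), params$head_w)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the lstm-only variant feeds the raw target window to the LSTM", {
  win <- make_window_set(n_nodes = 1, chain = FALSE)
  data <- kgdemand:::build_model_data(win)
  cfg <- build_variant("lstm_only", model_config(
    hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0
  ))
  params <- init_model_params(cfg, seed = 11)
  got <- kgdemand:::forward_batch(params, cfg, data)$yhat
  lstm_ref <- kgdemand:::lstm_params_split(params$lstm, cfg$hidden)
  want <- vapply(win, function(smp) {
    emb <- do.call(rbind, lapply(smp$snapshot_features, function(X) X[1, ]))
    predict_head(lstm_forward(emb, lstm_ref), params$head_w)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences for every block", {
  win <- make_window_set()
  data <- kgdemand:::build_model_data(win)
  configs <- list(
    gcn2 = model_config(hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0),
    noclip = model_config(
      hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0,
      clip = FALSE, noclip_pool = "mean"
    ),
    gcn1_mlp = model_config(
      n_gcn_layers = 1, temporal = "mlp",
      hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0
    ),
    lstm_only = build_variant("lstm_only", model_config(
      hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0
    ))
  )
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    params <- init_model_params(cfg, seed = 12)
    # keep the ReLU head alive and move every pre-activation off the ReLU
    # kink (zero biases + dead inputs put some exactly at zero, where the
    # central difference sees the subgradient 1/2 instead of the convention 0)
    params$head_w <- abs(params$head_w) + 0.05
    jitter <- function(v) v + stats::runif(length(v), 0.01, 0.1)
    for (l in seq_along(params$gcn)) params$gcn[[l]]$b <- jitter(params$gcn[[l]]$b)
    if (!is.null(params$lstm)) params$lstm$b <- jitter(params$lstm$b)
    if (!is.null(params$mlp)) params$mlp$b <- jitter(params$mlp$b)
    got <- kgdemand:::train_step(params, cfg, data, training = FALSE)
    expect_gt(sum(abs(got$yhat)), 0)
    loss_at <- function(p) kgdemand:::forward_batch(p, cfg, data)$loss
    eps <- 1e-6
    flat_check <- function(getter, setter, g_analytic, label) {
      v <- getter(params)
      probe <- seq_len(min(length(v), 12L))
      for (k in probe) {
        pa <- params
        va <- v
        va[k] <- va[k] + eps
        pa <- setter(pa, va)
        pb <- params
        vb <- v
        vb[k] <- vb[k] - eps
        pb <- setter(pb, vb)
        num <- (loss_at(pa) - loss_at(pb)) / (2 * eps)
        expect_equal(as.numeric(g_analytic)[k], num,
          tolerance = 1e-4,
          label = sprintf("%s %s[%d]", nm, label, k)
        )
      }
    }
    flat_check(
      function(p) p$head_w, function(p, v) {
        p$head_w <- v
        p
      },
      got$grads$head_w, "head_w"
    )
    for (l in seq_along(params$gcn)) {
      flat_check(
        function(p) p$gcn[[l]]$W, function(p, v) {
          p$gcn[[l]]$W <- matrix(v, nrow(p$gcn[[l]]$W))
          p
        },
        got$grads$gcn[[l]]$W, sprintf("gcn%d_W", l)
      )
      flat_check(
        function(p) p$gcn[[l]]$b, function(p, v) {
          p$gcn[[l]]$b <- v
          p
        },
        got$grads$gcn[[l]]$b, sprintf("gcn%d_b", l)
      )
    }
    if (cfg$temporal == "lstm") {
      for (blk in c("Wx", "Uh", "b")) {
        flat_check(
          function(p) p$lstm[[blk]], function(p, v) {
            p$lstm[[blk]] <- if (is.matrix(p$lstm[[blk]])) {
              matrix(v, nrow(p$lstm[[blk]]))
            } else {
              v
            }
            p
          },
          got$grads$lstm[[blk]], paste0("lstm_", blk)
        )
      }
    } else {
      flat_check(
        function(p) p$mlp$W, function(p, v) {
          p$mlp$W <- matrix(v, nrow(p$mlp$W))
          p
        },
        got$grads$mlp$W, "mlp_W"
      )
    }
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  win <- make_window_set(n_samples = 8)
  d_train <- kgdemand:::build_model_data(win, 1:6)
  d_val <- kgdemand:::build_model_data(win, 7:8)
  cfg <- model_config(hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0.2)
  ctl <- train_config(
    learning_rate = 0.01, hidden_dim = 4, max_epochs = 12,
    patience = 12, seed = 5
  )
  p0 <- init_model_params(cfg, seed = 5)
  run1 <- train_model(p0, d_train, d_val, cfg, ctl)
  run2 <- train_model(p0, d_train, d_val, cfg, ctl)
  expect_identical(run1$trajectory, run2$trajectory)
  expect_identical(run1$params, run2$params)
})

test_that("the running best of the loss trajectory is non-increasing", {
  win <- make_window_set(n_samples = 10)
  d_train <- kgdemand:::build_model_data(win, 1:8)
  d_val <- kgdemand:::build_model_data(win, 9:10)
  cfg <- model_config(hidden = 4, gcn_dim = 4, feature_dim = 5, dropout = 0)
  ctl <- train_config(
    learning_rate = 0.02, hidden_dim = 4, max_epochs = 40,
    patience = 40, seed = 2
  )
  p0 <- init_model_params(cfg, seed = 2)
  p0$head_w <- abs(p0$head_w) + 0.05
  run <- train_model(p0, d_train, d_val, cfg, ctl)
  best <- cummin(run$trajectory$train_loss)
  expect_true(all(diff(best) <= 0))
  # the model actually learns on this smooth problem
  expect_lt(tail(best, 1), run$trajectory$train_loss[1])
})
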