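#' Symmetrically normalised adjacency with self-loops
#'
#' Computes the GCN propagation operator from a binary adjacency matrix M:
#' self-loops are added (M' = M + I), the degree matrix D' accumulates the
#' self-looped row sums, and the propagation matrix is
#' A_hat = D'^(-1/2) M' D'^(-1/2). Self-loops guarantee every node keeps its
#' own signal and make every degree at least one, so the normalisation is
#' always finite; the symmetric scaling keeps the operator's spectrum in
#' \[-1, 1\], avoiding scale blow-up across layers.
#'
#' @param M Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return A `normalized_graph`: list with `self_looped_adjacency`, `degree`
#'   (diagonal matrix) and `propagation_matrix`.
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))$propagation_matrix
#' @export
normalize_adjacency <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || !isTRUE(all.equal(M, t(M)))) {
    kgd_abort("adjacency must be symmetric", class = "kgd_error_validation")
  }
  if (any(diag(M) != 0)) {
    kgd_abort("adjacency must have a zero diagonal", class = "kgd_error_validation")
  }
  mprime <- M + diag(nrow(M))
  deg <- rowSums(mprime)
  dinv <- 1 / sqrt(deg)
  ahat <- mprime * tcrossprod(dinv)
  structure(
    list(
      self_looped_adjacency = mprime,
      degree = diag(deg, nrow = length(deg)),
      propagation_matrix = ahat
    ),
    class = "normalized_graph"
  )
}

#' One graph-convolution layer
#'
#' Applies the GCN propagation rule: each node aggregates its neighbours'
#' (and its own) features through the normalised adjacency, then a learned
#' linear map and a nonlinearity: `activation(A_hat %*% H %*% W + b)`, the
#' bias broadcast over rows.
#'
#' @param normalized A `normalized_graph` (see [normalize_adjacency()]).
#' @param H Node feature matrix (N x d_in).
#' @param W Weight matrix (d_in x d_out).
#' @param b Bias vector (length d_out).
#' @param activation Elementwise activation function (default [relu]).
#' @return N x d_out matrix of updated node features.
#' @export
gcn_layer_forward <- function(normalized, H, W, b = rep(0, ncol(W)),
                              activation = relu) {
  stopifnot(inherits(normalized, "normalized_graph"))
  ahat <- normalized$propagation_matrix
  if (nrow(H) != nrow(ahat) || ncol(H) != nrow(W)) {
    kgd_abort(
      sprintf(
        "shape mismatch: A_hat %dx%d, H %dx%d, W %dx%d",
        nrow(ahat), ncol(ahat), nrow(H), ncol(H), nrow(W), ncol(W)
      ),
      class = "kgd_error_shape"
    )
  }
  pre <- sweep(ahat %*% H %*% W, 2L, b, "+")
  activation(pre)
}

#' Clipped multi-layer GCN forward pass
#'
#' Runs the stacked GCN layers (ReLU at every layer) over one snapshot's node
#' features and then clips: only the target drug's row of the final layer is
#' returned, discarding all other node embeddings. After two layers the
#' target's representation has already aggregated its 2-hop neighbourhood, so
#' the clip concentrates downstream temporal modelling on the prediction
#' target while removing interference from related drugs' own embeddings.
#'
#' @param normalized A `normalized_graph`.
#' @param snapshot_features N x F node feature matrix for one snapshot.
#' @param gcn_params List of layers, each `list(W, b)` (see
#'   [init_model_params()]; element `gcn` has this shape).
#' @param target_position Row index of the target drug.
#' @return Numeric vector: the target row of the last layer's output.
#' @export
clipped_gcn_forward <- function(normalized, snapshot_features, gcn_params,
                                target_position) {
  H <- snapshot_features
  for (layer in gcn_params) {
    H <- gcn_layer_forward(normalized, H, layer$W, layer$b)
  }
  if (target_position > nrow(H)) {
    kgd_abort("target_position exceeds node count", class = "kgd_error_argument")
  }
  H[target_position, ]
}

#' LSTM forward pass over a sequence of input vectors
#'
#' Iterates the gate equations over the sequence: at each step the forget
#' gate f, input gate i and output gate o are sigmoids of a learned affine
#' map of the current input and previous hidden state, the candidate cell
#' state is the tanh counterpart, the cell state is
#' `c_t = f_t * c_{t-1} + i_t * candidate`, and the hidden state is
#' `h_t = o_t * tanh(c_t)` (all products elementwise). With all recurrent
#' matrices `U` zero the gates depend on the current input only, the
#' recurrence-free special case.
#'
#' @param sequence Numeric matrix (T x d_in) or list of T input vectors.
#' @param params List with per-gate input weights `Wf, Wi, Wc, Wo`
#'   (d_in x hidden), recurrent weights `Uf, Ui, Uc, Uo` (hidden x hidden)
#'   and biases `bf, bi, bc, bo` (length hidden, one bias per gate).
#' @param initial Optional list with `hidden` and `cell` start vectors
#'   (default zeros).
#' @return An `lstm_state`: list with final `hidden`, `cell`, and the last
#'   step's gate activations `f`, `i`, `o` and `candidate`.
#' @export
lstm_forward <- function(sequence, params, initial = NULL) {
  if (is.list(sequence) && !is.data.frame(sequence)) {
    sequence <- do.call(rbind, sequence)
  }
  sequence <- matrix(as.numeric(sequence), nrow = NROW(sequence))
  if (nrow(sequence) == 0L) {
    kgd_abort("sequence must be non-empty", class = "kgd_error_argument")
  }
  hdim <- length(params$bf)
  h <- initial$hidden %||% rep(0, hdim)
  cc <- initial$cell %||% rep(0, hdim)
  f <- i <- o <- cand <- rep(NA_real_, hdim)
  for (t in seq_len(nrow(sequence))) {
    x <- sequence[t, ]
    f <- sigmoid(drop(x %*% params$Wf + h %*% params$Uf) + params$bf)
    i <- sigmoid(drop(x %*% params$Wi + h %*% params$Ui) + params$bi)
    cand <- tanh(drop(x %*% params$Wc + h %*% params$Uc) + params$bc)
    o <- sigmoid(drop(x %*% params$Wo + h %*% params$Uo) + params$bo)
    cc <- f * cc + i * cand
    h <- o * tanh(cc)
  }
  structure(
    list(hidden = h, cell = cc, f = f, i = i, o = o, candidate = cand),
    class = "lstm_state"
  )
}

#' Regression head: hidden state to demand forecast
#'
#' Maps the LSTM's final hidden state to a scalar forecast through a single
#' bias-free linear layer followed by ReLU. Demand is a non-negative
#' quantity and min-max-scaled targets stay non-negative, so the clamp is
#' consistent with the data.
#'
#' @param state An `lstm_state` or a numeric hidden-state vector.
#' @param weight Numeric weight vector (length = hidden size).
#' @return Non-negative forecast scalar.
#' @export
predict_head <- function(state, weight) {
  h <- if (inherits(state, "lstm_state")) state$hidden else state
  if (length(h) != length(weight)) {
    kgd_abort(
      sprintf("hidden size %d does not match head weight %d", length(h), length(weight)),
      class = "kgd_error_shape"
    )
  }
  relu(sum(h * weight))
}

#' Mean squared error loss
#'
#' Mean of squared differences over all entries, the training objective.
#'
#' @param predictions,truths Numeric vectors/matrices of equal shape.
#' @return Scalar loss.
#' @export
mse_loss <- function(predictions, truths) {
  if (length(predictions) == 0L || length(predictions) != length(truths)) {
    kgd_abort("predictions and truths must have equal, non-zero length",
      class = "kgd_error_shape"
    )
  }
  mean((as.numeric(predictions) - as.numeric(truths))^2)
}

#' Model architecture configuration
#'
#' Describes one forecaster architecture. The reference configuration (two
#' clipped GCN layers of width 64 over 16-dimensional node features, an LSTM
#' with hidden size 64, a bias-free 64-to-1 ReLU head, dropout 0.2) is the
#' default. Ablation variants reshape this configuration via
#' [build_variant()].
#'
#' @param n_gcn_layers Number of GCN layers (0 = feed raw target window to
#'   the temporal block; 1-3 supported).
#' @param clip If TRUE (default) only the target node's embedding is kept
#'   after the last GCN layer; if FALSE node embeddings are pooled.
#' @param noclip_pool Pooling used when `clip = FALSE`: `"mean"` (default) or
#'   `"sum"` over nodes.
#' @param temporal Temporal block: `"lstm"` (default) or `"mlp"` (one hidden
#'   layer of `hidden` ReLU units over the mean snapshot embedding).
#' @param hidden Temporal block hidden size (default 64).
#' @param gcn_dim Width of each GCN layer (default 64).
#' @param feature_dim Node feature dimension = window length (default 16).
#' @param dropout Dropout rate applied to each GCN layer output and the
#'   final temporal feature during training (default 0.2).
#' @param hop Neighbourhood radius used when assembling samples (default 2;
#'   0 gives a single-node graph).
#' @return A `model_config` list.
#' @export
model_config <- function(n_gcn_layers = 2, clip = TRUE, noclip_pool = "mean",
                         temporal = c("lstm", "mlp"), hidden = 64,
                         gcn_dim = 64, feature_dim = 16, dropout = 0.2,
                         hop = 2) {
  temporal <- match.arg(temporal)
  stopifnot(
    n_gcn_layers %in% 0:3, hidden >= 1, gcn_dim >= 1, feature_dim >= 1,
    dropout >= 0, dropout < 1, hop >= 0, noclip_pool %in% c("mean", "sum")
  )
  structure(
    list(
      n_gcn_layers = as.integer(n_gcn_layers), clip = clip,
      noclip_pool = noclip_pool, temporal = temporal,
      hidden = as.integer(hidden), gcn_dim = as.integer(gcn_dim),
      feature_dim = as.integer(feature_dim), dropout = dropout,
      hop = hop
    ),
    class = "model_config"
  )
}

# Dimension of the temporal block's input vector.
temporal_input_dim <- function(config) {
  if (config$n_gcn_layers > 0L) config$gcn_dim else config$feature_dim
}

#' Initialise trainable parameters
#'
#' Weights are drawn from a uniform distribution scaled by the inverse square
#' root of the fan-in; biases start at zero; the head weights take the
#' non-negative half of that range so the initial forecast is positive
#' (demand is non-negative and a ReLU head with an all-negative initial
#' pre-activation would never receive a gradient). The LSTM keeps one bias
#' vector per gate. Fully deterministic given the seed.
#'
#' @param config A `model_config`.
#' @param seed Integer seed for the initialisation stream.
#' @return Named list of parameter arrays (`model_params`): `gcn` (list of
#'   `list(W, b)` per layer), `lstm` (concatenated gate matrices `Wx`, `Uh`,
#'   `b`, gate order f, i, c, o) or `mlp` (`W`, `b`), and `head_w`.
#' @export
init_model_params <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    uinit <- function(nr, nc) {
      k <- 1 / sqrt(nr)
      matrix(runif(nr * nc, -k, k), nr, nc)
    }
    gcn <- list()
    d_in <- config$feature_dim
    for (l in seq_len(config$n_gcn_layers)) {
      gcn[[l]] <- list(W = uinit(d_in, config$gcn_dim), b = rep(0, config$gcn_dim))
      d_in <- config$gcn_dim
    }
    t_in <- temporal_input_dim(config)
    h <- config$hidden
    params <- list(gcn = gcn, head_w = abs(drop(uinit(h, 1L))))
    if (config$temporal == "lstm") {
      params$lstm <- list(
        Wx = uinit(t_in, 4L * h),
        Uh = uinit(h, 4L * h),
        b = rep(0, 4L * h)
      )
    } else {
      params$mlp <- list(W = uinit(t_in, h), b = rep(0, h))
    }
    structure(params, class = "model_params", config = config)
  })
}

# Split concatenated LSTM parameters into the per-gate layout used by
# lstm_forward() (gate order f, i, c, o).
lstm_params_split <- function(lstm, hidden) {
  g <- function(M, k) M[, ((k - 1) * hidden + 1):(k * hidden), drop = FALSE]
  list(
    Wf = g(lstm$Wx, 1), Wi = g(lstm$Wx, 2), Wc = g(lstm$Wx, 3), Wo = g(lstm$Wx, 4),
    Uf = g(lstm$Uh, 1), Ui = g(lstm$Uh, 2), Uc = g(lstm$Uh, 3), Uo = g(lstm$Uh, 4),
    bf = lstm$b[(0 * hidden + 1):(1 * hidden)],
    bi = lstm$b[(1 * hidden + 1):(2 * hidden)],
    bc = lstm$b[(2 * hidden + 1):(3 * hidden)],
    bo = lstm$b[(3 * hidden + 1):(4 * hidden)]
  )
}

#' Trainable parameter counts per block
#'
#' Exact accounting of trainable scalars: each GCN layer holds
#' `d_in * d_out + d_out` (weights plus bias), the LSTM holds
#' `4 * (d_in * h + h * h + h)` (four gates, each with input weights,
#' recurrent weights and a single bias vector), the MLP variant
#' `d_in * h + h`, and the head `h` (bias-free). At the reference
#' configuration (16-dimensional features, width-64 GCN layers, hidden 64)
#' the blocks count 1088, 4160, 33024 and 64 scalars - 38336 in total.
#'
#' @param config A `model_config` (default: the reference configuration).
#' @return Tibble with columns `block` and `parameters`, plus a `"total"` row.
#' @examples
#' count_parameters()
#' @export
count_parameters <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  blocks <- character()
  counts <- integer()
  d_in <- config$feature_dim
  for (l in seq_len(config$n_gcn_layers)) {
    blocks <- c(blocks, sprintf("gcn_layer_%d", l))
    counts <- c(counts, d_in * config$gcn_dim + config$gcn_dim)
    d_in <- config$gcn_dim
  }
  t_in <- temporal_input_dim(config)
  h <- config$hidden
  if (config$temporal == "lstm") {
    blocks <- c(blocks, "lstm")
    counts <- c(counts, 4L * (t_in * h + h * h + h))
  } else {
    blocks <- c(blocks, "mlp")
    counts <- c(counts, t_in * h + h)
  }
  blocks <- c(blocks, "head")
  counts <- c(counts, h)
  tibble(block = c(blocks, "total"), parameters = c(counts, sum(counts)))
}
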