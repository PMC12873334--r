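# Shared fixture builders: everything is generated in code at test time.

# Drug records with two substitution groups and one device.
tiny_records <- function() {
  tibble::tibble(
    drug_id = c("A", "B", "C", "D", "E"),
    raw_name = c("alpha", "beta", "gamma", "delta", "mask"),
    core_name = raw_name,
    inn_name = c("alphum", "betum", "gammum", "deltum", NA),
    atc_code = c("J01CA04", "J01CA01", "J01DB01", "J01DB02", NA),
    item_type = c(rep("pharmaceutical", 4), "device")
  )
}

# A drug_graph for an undirected path 1-2-...-n.
path_graph <- function(n, ids = sprintf("P%d", seq_len(n))) {
  records <- tibble::tibble(drug_id = ids, item_type = "pharmaceutical")
  edges <- tibble::tibble(
    endpoint_a = ids[-n], endpoint_b = ids[-1], relation = "substitution"
  )
  assemble_graph(records, edges)
}

# Random symmetric 0/1 adjacency with zero diagonal.
rand_adjacency <- function(n, p = 0.4) {
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  m[up] <- as.numeric(stats::runif(sum(up)) < p)
  m + t(m)
}

# Long demand panel from a drugs x weeks matrix (week_start = Mondays).
panel_from_matrix <- function(m, start = as.Date("2021-01-04")) {
  drugs <- rownames(m) %||% sprintf("D%d", seq_len(nrow(m)))
  weeks <- seq_len(ncol(m))
  tidyr::expand_grid(drug_id = drugs, week = weeks) |>
    dplyr::mutate(
      week_start = start + (week - 1L) * 7L,
      iso_week = format(week_start, "%G-W%V"),
      demand = as.numeric(m[cbind(match(drug_id, drugs), week)]),
      observed = demand > 0
    ) |>
    dplyr::arrange(drug_id, week)
}

`%||%` <- rlang::`%||%`

# Deterministic smooth panel over a path graph, for fast training smoke tests.
smoke_panel <- function(n_drugs = 2, weeks = 45, seed = 11) {
  kgdemand:::with_seed(seed, {
    m <- t(vapply(seq_len(n_drugs), function(i) {
      50 + 20 * sin(2 * pi * (seq_len(weeks) + 5 * i) / 26) +
        stats::rnorm(weeks, 0, 2)
    }, numeric(weeks)))
    rownames(m) <- sprintf("P%d", seq_len(n_drugs))
    panel_from_matrix(round(pmax(m, 0)))
  })
}

# Reference brute-force GCN layer: per-node loop over neighbours.
gcn_layer_oracle <- function(ahat, H, W, b, act = function(x) pmax(x, 0)) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    acc <- rep(0, ncol(W))
    for (j in seq_len(n)) {
      acc <- acc + ahat[i, j] * as.numeric(H[j, , drop = FALSE] %*% W)
    }
    out[i, ] <- act(acc + b)
  }
  out
}

# Scalar LSTM parameters used in hand-worked gate examples.
scalar_lstm_params <- function(U = c(0, 0, 0, 0)) {
  list(
    Wf = matrix(0.5), Wi = matrix(-0.3), Wc = matrix(0.8), Wo = matrix(1.0),
    Uf = matrix(U[1]), Ui = matrix(U[2]), Uc = matrix(U[3]), Uo = matrix(U[4]),
    bf = 0.1, bi = 0.2, bc = 0, bo = -0.2
  )
}
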