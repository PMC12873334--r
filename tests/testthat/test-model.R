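test_that("adjacency normalisation matches hand-evaluated cases", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1))$propagation_matrix, matrix(1, 1, 1))

  two <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  expect_equal(two$propagation_matrix, matrix(0.5, 2, 2))
  expect_equal(diag(two$degree), c(2, 2))
  expect_equal(two$self_looped_adjacency, matrix(c(1, 1, 1, 1), 2))

  # 3-node star, centre first
  star <- matrix(0, 3, 3)
  star[1, 2:3] <- star[2:3, 1] <- 1
  ahat <- normalize_adjacency(star)$propagation_matrix
  expect_equal(ahat[1, 1], 1 / 3)
  expect_equal(ahat[1, 2], 1 / sqrt(6))
  expect_equal(ahat[2, 2], 1 / 2)
  expect_equal(ahat[2, 3], 0)

  expect_error(
    normalize_adjacency(matrix(c(0, 1, 0, 0), 2)),
    class = "kgd_error_validation"
  )
  expect_error(
    normalize_adjacency(diag(2)),
    class = "kgd_error_validation"
  )
})

test_that("normalisation equals the dense matrix formula on random graphs", {
  set.seed(1)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    m <- rand_adjacency(n)
    got <- normalize_adjacency(m)
    mp <- m + diag(n)
    dinv <- diag(1 / sqrt(rowSums(mp)), n)
    expect_equal(got$propagation_matrix, dinv %*% mp %*% dinv, tolerance = 1e-8)
    expect_identical(got$propagation_matrix, t(got$propagation_matrix))
    ev <- eigen(got$propagation_matrix, only.values = TRUE)$values
    expect_true(all(ev <= 1 + 1e-10 & ev >= -1 - 1e-10))
  }
})

test_that("a GCN layer matches the per-node aggregation oracle", {
  ng <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  expect_equal(
    gcn_layer_forward(normalize_adjacency(matrix(0, 1, 1)), matrix(3), diag(1)),
    matrix(3)
  )
  expect_equal(
    gcn_layer_forward(normalize_adjacency(matrix(0, 1, 1)), matrix(-3), diag(1)),
    matrix(0) # ReLU clamp
  )
  expect_equal(
    gcn_layer_forward(ng, matrix(rnorm(4), 2), matrix(0, 2, 3)),
    matrix(0, 2, 3)
  )
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    ng <- normalize_adjacency(rand_adjacency(n))
    H <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    b <- rnorm(3)
    expect_equal(
      gcn_layer_forward(ng, H, W, b),
      gcn_layer_oracle(ng$propagation_matrix, H, W, b),
      tolerance = 1e-6
    )
  }
  ng2 <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  expect_error(
    gcn_layer_forward(ng2, matrix(1, 3, 4), matrix(1, 4, 2)),
    class = "kgd_error_shape"
  )
})

test_that("clipping returns the target row of the full two-layer output", {
  set.seed(3)
  n <- 5
  ng <- normalize_adjacency(rand_adjacency(n))
  X <- matrix(rnorm(n * 3), n, 3)
  gcn <- list(
    list(W = matrix(rnorm(12), 3, 4), b = rnorm(4)),
    list(W = matrix(rnorm(16), 4, 4), b = rnorm(4))
  )
  full <- gcn_layer_forward(ng, gcn_layer_forward(ng, X, gcn[[1]]$W, gcn[[1]]$b),
    gcn[[2]]$W, gcn[[2]]$b
  )
  for (tpos in 1:n) {
    expect_equal(clipped_gcn_forward(ng, X, gcn, tpos), full[tpos, ])
  }
})

test_that("two-layer GCN output is local to the 2-hop neighbourhood", {
  set.seed(4)
  # path graph: nodes 4..6 are >= 3 hops from node 1
  path <- matrix(0, 6, 6)
  for (i in 1:5) path[i, i + 1] <- path[i + 1, i] <- 1
  ng <- normalize_adjacency(path)
  X <- matrix(rnorm(6 * 3), 6, 3)
  gcn <- list(
    list(W = matrix(rnorm(12), 3, 4), b = rnorm(4)),
    list(W = matrix(rnorm(16), 4, 4), b = rnorm(4))
  )
  base <- clipped_gcn_forward(ng, X, gcn, 1)
  Xp <- X
  Xp[4:6, ] <- rnorm(9) * 10
  expect_equal(clipped_gcn_forward(ng, Xp, gcn, 1), base, tolerance = 1e-12)
  # ... but perturbing a 2-hop node changes it
  Xq <- X
  Xq[3, ] <- Xq[3, ] + 5
  expect_false(isTRUE(all.equal(clipped_gcn_forward(ng, Xq, gcn, 1), base)))

  # star graph: leaves are mutually 2 hops apart, centre 1 hop
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  ngs <- normalize_adjacency(star)
  Xs <- matrix(rnorm(12), 4, 3)
  base_leaf <- clipped_gcn_forward(ngs, Xs, gcn, 2)
  Xs2 <- Xs
  Xs2[3, ] <- Xs2[3, ] + 1 # another leaf: exactly 2 hops, must matter
  expect_false(isTRUE(all.equal(clipped_gcn_forward(ngs, Xs2, gcn, 2), base_leaf)))
})

test_that("clipped GCN output is invariant to node permutation", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    m <- rand_adjacency(n)
    ng <- normalize_adjacency(m)
    X <- matrix(rnorm(n * 3), n, 3)
    gcn <- list(
      list(W = matrix(rnorm(12), 3, 4), b = rnorm(4)),
      list(W = matrix(rnorm(16), 4, 4), b = rnorm(4))
    )
    tpos <- sample(n, 1)
    base <- clipped_gcn_forward(ng, X, gcn, tpos)
    perm <- sample(n)
    ngp <- normalize_adjacency(m[perm, perm])
    expect_equal(
      clipped_gcn_forward(ngp, X[perm, , drop = FALSE], gcn, which(perm == tpos)),
      base,
      tolerance = 1e-6
    )
  }
})

test_that("LSTM gates match the hand-worked scalar example", {
  # one step, no recurrence: frozen longhand values
  st1 <- lstm_forward(matrix(1, 1, 1), scalar_lstm_params())
  expect_equal(st1$f, 0.6456563062, tolerance = 1e-9)
  expect_equal(st1$i, 0.4750208125, tolerance = 1e-9)
  expect_equal(st1$candidate, 0.6640367703, tolerance = 1e-9)
  expect_equal(st1$o, 0.6899744811, tolerance = 1e-9)
  expect_equal(st1$cell, 0.3154312862, tolerance = 1e-9)
  expect_equal(st1$hidden, 0.2106975378, tolerance = 1e-9)

  # two steps with recurrent weights engaged
  st2 <- lstm_forward(
    matrix(c(1, -0.5), 2, 1),
    scalar_lstm_params(U = c(0.4, 0.2, -0.6, 0.3))
  )
  expect_equal(st2$cell, -0.1355027024, tolerance = 1e-9)
  expect_equal(st2$hidden, -0.0465953590, tolerance = 1e-9)
})

test_that("LSTM degenerate and range properties hold", {
  zero <- list(
    Wf = matrix(0, 2, 3), Wi = matrix(0, 2, 3), Wc = matrix(0, 2, 3),
    Wo = matrix(0, 2, 3), Uf = matrix(0, 3, 3), Ui = matrix(0, 3, 3),
    Uc = matrix(0, 3, 3), Uo = matrix(0, 3, 3),
    bf = rep(0, 3), bi = rep(0, 3), bc = rep(0, 3), bo = rep(0, 3)
  )
  st <- lstm_forward(matrix(rnorm(10), 5, 2), zero)
  expect_equal(st$hidden, rep(0, 3))
  expect_equal(st$cell, rep(0, 3))

  set.seed(6)
  p <- zero
  for (nm in names(p)) p[[nm]] <- p[[nm]] + rnorm(length(p[[nm]]))
  st <- lstm_forward(matrix(rnorm(20, sd = 5), 10, 2), p)
  expect_true(all(abs(st$hidden) < 1))
  expect_true(all(st$f > 0 & st$f < 1))
  expect_true(all(st$o > 0 & st$o < 1))
  expect_error(lstm_forward(matrix(0, 0, 2), p), class = "kgd_error_argument")
})

test_that("zero recurrent weights reproduce the input-only gate equations", {
  set.seed(7)
  p <- scalar_lstm_params()
  for (nm in c("Wf", "Wi", "Wc", "Wo")) p[[nm]] <- matrix(rnorm(6), 2, 3)
  for (nm in c("Uf", "Ui", "Uc", "Uo")) p[[nm]] <- matrix(0, 3, 3)
  for (nm in c("bf", "bi", "bc", "bo")) p[[nm]] <- rnorm(3)
  xs <- matrix(rnorm(8), 4, 2)
  got <- lstm_forward(xs, p)
  # literal recurrence-free oracle: gates from x_t only, cell still recursive
  sig <- function(z) 1 / (1 + exp(-z))
  cc <- rep(0, 3)
  h <- rep(0, 3)
  for (t in 1:4) {
    x <- xs[t, ]
    f <- sig(drop(x %*% p$Wf) + p$bf)
    i <- sig(drop(x %*% p$Wi) + p$bi)
    cand <- tanh(drop(x %*% p$Wc) + p$bc)
    o <- sig(drop(x %*% p$Wo) + p$bo)
    cc <- f * cc + i * cand
    h <- o * tanh(cc)
  }
  expect_equal(got$hidden, h, tolerance = 1e-12)
  expect_equal(got$cell, cc, tolerance = 1e-12)
})

test_that("the regression head is a non-negative bias-free linear map", {
  expect_equal(predict_head(rep(0, 4), rnorm(4)), 0)
  expect_equal(predict_head(c(1, 1), c(-2, 1)), 0) # negative pre-activation
  expect_equal(predict_head(c(0.5, 2, -1), c(1, 2, 3)), 1.5)
  set.seed(8)
  for (rep in 1:20) {
    expect_gte(predict_head(rnorm(6), rnorm(6)), 0)
  }
  expect_error(predict_head(rep(0, 3), rep(0, 4)), class = "kgd_error_shape")
})

test_that("MSE loss matches hand arithmetic and is quadratic in the error", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(2, 4), c(1, 2)), 2.5)
  y <- rnorm(10)
  yh <- rnorm(10)
  expect_equal(mse_loss(y + 3 * (yh - y), y), 9 * mse_loss(yh, y))
  expect_error(mse_loss(1:3, 1:4), class = "kgd_error_shape")
})

test_that("parameter accounting matches the reference architecture exactly", {
  counts <- count_parameters()
  get <- function(block) counts$parameters[counts$block == block]
  expect_identical(get("gcn_layer_1"), 1088L)
  expect_identical(get("gcn_layer_2"), 4160L)
  expect_identical(get("lstm"), 33024L)
  expect_identical(get("head"), 64L)
  expect_identical(get("total"), 38336L)

  # counts agree with the actual initialised arrays
  params <- init_model_params(model_config(), seed = 1)
  n_actual <- sum(vapply(
    rapply(params, length, how = "unlist"),
    identity, numeric(1)
  ))
  expect_equal(n_actual, 38336)

  # variants
  lo <- count_parameters(build_variant("lstm_only"))
  expect_false(any(grepl("gcn", lo$block)))
  mlp <- count_parameters(build_variant("kg_gcn_mlp"))
  expect_identical(mlp$parameters[mlp$block == "mlp"], 64L * 64L + 64L)
  h16 <- count_parameters(build_variant("hidden16"))
  expect_identical(h16$parameters[h16$block == "lstm"], 4L * (64L * 16L + 16L * 16L + 16L))
})
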