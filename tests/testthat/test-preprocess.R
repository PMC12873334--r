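test_that("weekly aggregation sums quantities and zero-fills gaps", {
  tx <- tibble::tibble(
    drug_id = "A",
    date = as.Date(c("2021-01-04", "2021-01-06", "2021-01-10", "2021-01-18")),
    quantity = c(1, 2, 3, 4)
  )
  panel <- aggregate_weekly(tx)
  expect_equal(panel$demand, c(6, 0, 4))
  expect_identical(panel$observed, c(TRUE, FALSE, TRUE))
  expect_equal(panel$week, 1:3)

  single <- aggregate_weekly(tibble::tibble(
    drug_id = "A", date = as.Date("2021-03-03"), quantity = 5
  ))
  expect_equal(nrow(single), 1L)
  expect_equal(single$demand, 5)

  expect_error(aggregate_weekly(tx[0, ]), class = "kgd_error_argument")
  tx$quantity[1] <- -1
  expect_error(aggregate_weekly(tx), class = "kgd_error_validation")
})

test_that("aggregation conserves total quantity on random transaction sets", {
  set.seed(7)
  for (rep in 1:5) {
    tx <- tibble::tibble(
      drug_id = sample(c("A", "B", "C"), 60, TRUE),
      date = as.Date("2021-01-01") + sample(0:120, 60, TRUE),
      quantity = sample(1:9, 60, TRUE)
    )
    panel <- aggregate_weekly(tx)
    expect_equal(sum(panel$demand), sum(tx$quantity))
    # gapless consecutive week axis
    expect_equal(sort(unique(panel$week)), seq_len(max(panel$week)))
  }
})

test_that("history filter keeps drugs with at least 40 valid weeks", {
  m <- matrix(0, 3, 60)
  m[1, 1:39] <- 1 # 39 valid weeks: removed
  m[2, 1:40] <- 1 # 40 valid weeks: retained
  panel <- panel_from_matrix(m)
  kept <- expect_no_warning(filter_min_history(panel))
  expect_identical(sort(unique(kept$drug_id)), "D2")
  # idempotent, and the week axis is unchanged
  expect_identical(filter_min_history(kept), kept)
  expect_equal(max(kept$week), 60)
  expect_warning(
    filter_min_history(panel, min_valid_weeks = 61),
    "empty panel"
  )
})

test_that("three-sigma outliers are replaced by the original window mean", {
  series <- c(rep(10, 15), 200)
  out <- clip_outliers(series, window_length = 16)
  expect_equal(out[16], 21.875) # mean of the original window
  expect_equal(out[1:15], rep(10, 15))

  expect_identical(clip_outliers(rep(5, 20)), rep(5, 20)) # sd = 0 never fires
  smooth <- sin(seq_len(30)) + 10
  expect_identical(clip_outliers(smooth), smooth) # all within 3 sigma

  expect_warning(short <- clip_outliers(c(1, 2), window_length = 16), "unchanged")
  expect_identical(short, c(1, 2))
  expect_error(clip_outliers(1:10, window_length = 1), class = "kgd_error_argument")
})

test_that("outlier correction only touches values that fail the 3-sigma test", {
  set.seed(3)
  for (rep in 1:5) {
    x <- rnorm(50, 100, 5)
    spikes <- c(20, 40) # far enough apart never to share a window
    x[spikes] <- x[spikes] * 8
    out <- clip_outliers(x, window_length = 16)
    changed <- which(out != x)
    expect_true(all(spikes %in% changed))
    # every replaced value equals some original 16-week window mean
    means <- vapply(
      seq_len(length(x) - 15),
      function(s) mean(x[s:(s + 15)]), numeric(1)
    )
    for (k in changed) {
      expect_true(any(abs(out[k] - means) < 1e-12))
    }
    # untouched values pass the test in every window containing them
    for (k in setdiff(seq_along(x), changed)) {
      for (s in max(1, k - 15):min(k, length(x) - 15)) {
        w <- x[s:(s + 15)]
        m <- mean(w)
        sdev <- sqrt(mean((w - m)^2))
        if (sdev > 0) expect_lte(abs(x[k] - m), 3 * sdev)
      }
    }
  }
})

test_that("chronological split is 8/4/remainder with minimum history", {
  panel <- panel_from_matrix(matrix(1, 1, 52))
  sp <- chronological_split(panel)
  expect_equal(sp$train, 1:40)
  expect_equal(sp$val, 41:44)
  expect_equal(sp$test, 45:52)
  expect_equal(length(intersect(sp$train, c(sp$val, sp$test))), 0L)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:52)

  expect_error(
    chronological_split(panel_from_matrix(matrix(1, 1, 13))),
    class = "kgd_error_history"
  )
  expect_error(
    chronological_split(panel_from_matrix(matrix(1, 1, 12))),
    class = "kgd_error_history"
  )
})

test_that("min-max scaling is fitted on the training range only", {
  x <- c(2, 4, 6, 8, 10, 20)
  sc <- scale_series(x, fit_idx = 1:5)
  expect_equal(sc$scaled[1:5], c(0, 0.25, 0.5, 0.75, 1))
  expect_gt(sc$scaled[6], 1) # test value above the fitted max
  expect_equal(sc$inverse(sc$transform(x)), x)

  const <- scale_series(rep(7, 5))
  expect_equal(const$scaled, rep(0, 5))
  expect_equal(const$inverse(0), 7)
  expect_error(scale_series(x, integer(0)), class = "kgd_error_argument")
})

test_that("window assembly yields L - 16 samples with causal padding", {
  g <- path_graph(1, ids = "D1")
  for (L in c(17, 40, 33)) {
    panel <- panel_from_matrix(matrix(seq_len(L), 1, L, dimnames = list("D1", NULL)))
    w <- assemble_windows(panel, g, "D1", clip = FALSE)
    expect_length(w, L - 16)
  }
  expect_warning(
    w0 <- assemble_windows(panel_from_matrix(matrix(1:16, 1, 16, dimnames = list("D1", NULL))), g, "D1"),
    "too short"
  )
  expect_length(w0, 0L)

  panel <- panel_from_matrix(matrix(1:20, 1, 20, dimnames = list("D1", NULL)))
  w <- assemble_windows(panel, g, "D1", clip = FALSE)
  s1 <- w[[1]]
  expect_length(s1$snapshot_features, 16L)
  # snapshot s carries the window's first s weeks, left-padded with zeros
  expect_equal(s1$snapshot_features[[1]], matrix(c(rep(0, 15), 1), 1))
  expect_equal(s1$snapshot_features[[16]], matrix(1:16, 1))
  expect_equal(s1$target_value, 17)
  expect_equal(s1$week_of_target, 17)
  # full-lookback padding uses real earlier weeks instead of zeros
  wf <- assemble_windows(panel, g, "D1", clip = FALSE, padding = "full")
  s4 <- wf[[4]] # anchor week 19
  expect_equal(s4$snapshot_features[[16]], matrix(4:19, 1))
  expect_equal(s4$snapshot_features[[1]], matrix(c(rep(0, 12), 1:4), 1))

  expect_error(
    assemble_windows(panel, g, "missing"),
    class = "kgd_error_lookup"
  )
})

test_that("windows cover the subgraph and track the target position", {
  g <- path_graph(4)
  m <- matrix(rep(1:30, each = 4) + 0:3, 4, 30, dimnames = list(sprintf("P%d", 1:4), NULL))
  panel <- panel_from_matrix(m)
  w <- assemble_windows(panel, g, "P2", hop = 1, clip = FALSE)
  expect_identical(attr(w, "nodes"), c("P1", "P2", "P3"))
  expect_equal(attr(w, "target_position"), 2L)
  expect_equal(dim(w[[1]]$snapshot_features[[1]]), c(3L, 16L))
  # target value comes from the target drug's row
  expect_equal(w[[1]]$target_value, unname(m["P2", 17]))
})
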