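#' Configuration for the synthetic pharmacy-sales simulator
#'
#' The simulator emulates the statistical structure of retail pharmacy
#' demand that the knowledge graph is meant to exploit: drugs in the same ATC
#' level-4 group ride a shared seasonal group-demand curve and compete for
#' market share (substitution: anti-correlated share drift within the group),
#' DDI-paired drugs receive a shared latent co-prescription count
#' (combination: positively correlated additive demand), observations are
#' negative-binomial counts with injected multiplicative outliers and missing
#' weeks, and device items follow independent seasonal series with no graph
#' relations. One drug is made sparse by default so the 40-valid-week history
#' filter is exercised.
#'
#' @param n_drugs Total catalog size (pharmaceuticals + devices).
#' @param n_atc_groups Number of synthetic ATC level-4 groups.
#' @param device_fraction Fraction of items that are devices (no ATC code).
#' @param n_ddi_pairs Number of DDI (combination) pairs.
#' @param weeks Number of simulated weeks (>= 52 recommended).
#' @param seasonal_amplitude Amplitude of the 52-week group seasonality.
#' @param share_drift Step size of the logistic-normal random walk of
#'   within-group market shares.
#' @param coupling Co-prescription coupling strength kappa: each DDI pair
#'   carries two latent count streams (one led by each endpoint) of mean
#'   `kappa * coupling_share * (mu_i + mu_j) / 2` times an AR(1) episode
#'   factor. Zero disables coupling.
#' @param coupling_share Base share of the pair's mean demand carried by one
#'   co-prescription stream at kappa = 1 (default 0.12: at the default
#'   kappa = 2 the episode streams are the dominant cross-drug signal while
#'   each drug's own sales remain mostly its own).
#' @param dispersion Negative-binomial size parameter of observation noise
#'   (larger = closer to Poisson).
#' @param group_noise_sd Innovation standard deviation of the AR(1)
#'   log-normal group-level demand fluctuations (shared within a group).
#' @param base_demand Length-2 range of per-group base weekly demand.
#' @param outlier_prob Per-cell probability of an injected outlier.
#' @param outlier_mult Length-2 range of the outlier multiplier.
#' @param missing_week_prob Per-cell probability that a week is zeroed
#'   (no transactions recorded).
#' @param observation_noise If FALSE, observed demand equals its mean exactly
#'   (no negative-binomial sampling, outliers or device count noise) - the
#'   degenerate limit used to validate the generator.
#' @param n_sparse_drugs Number of pharmaceutical drugs simulated with too
#'   few valid weeks to pass the history filter.
#' @param start_date First Monday of the simulated period.
#' @param seed Root seed; every generator output is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_drugs = 12, n_atc_groups = 3, device_fraction = 1 / 6,
                       n_ddi_pairs = 2, weeks = 120, seasonal_amplitude = 0.4,
                       share_drift = 0.15, coupling = 2, coupling_share = 0.12,
                       dispersion = 8,
                       group_noise_sd = 0.15, base_demand = c(60, 200),
                       outlier_prob = 0.01, outlier_mult = c(4, 8),
                       missing_week_prob = 0.03, n_sparse_drugs = 1,
                       observation_noise = TRUE,
                       start_date = as.Date("2020-01-06"), seed = 1L) {
  stopifnot(
    n_drugs >= n_atc_groups, device_fraction >= 0, device_fraction <= 1,
    weeks >= 20, coupling >= 0, outlier_prob >= 0, outlier_prob <= 1,
    missing_week_prob >= 0, missing_week_prob <= 1, dispersion > 0
  )
  structure(
    list(
      n_drugs = as.integer(n_drugs), n_atc_groups = as.integer(n_atc_groups),
      device_fraction = device_fraction, n_ddi_pairs = as.integer(n_ddi_pairs),
      weeks = as.integer(weeks), seasonal_amplitude = seasonal_amplitude,
      share_drift = share_drift, coupling = coupling,
      coupling_share = coupling_share, dispersion = dispersion,
      group_noise_sd = group_noise_sd, base_demand = base_demand,
      outlier_prob = outlier_prob, outlier_mult = outlier_mult,
      missing_week_prob = missing_week_prob,
      n_sparse_drugs = as.integer(n_sparse_drugs),
      observation_noise = isTRUE(observation_noise),
      start_date = as.Date(start_date), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Pronounceable synthetic drug names, deterministic under the active RNG.
synth_names <- function(n) {
  con <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  vapply(seq_len(n), function(i) {
    paste0(
      paste0(sample(con, 3, TRUE), sample(vow, 3, TRUE), collapse = ""),
      sample(c("ol", "ine", "cin", "pril", "mab", "dine"), 1)
    )
  }, character(1))
}

#' Generate a synthetic drug catalog with ATC groups
#'
#' Pharmaceutical items are assigned synthetic ATC codes such that drugs in
#' the same group share a 5-character level-4 prefix and differ only in the
#' last two characters; `device_fraction` of the items become devices
#' ("mask", "syringe", ...) with no ATC code. Raw names carry dosage tokens
#' so the name-cleaning step is exercised; the companion `inn_map` and
#' `drug_db` tables (synthetic stand-ins for INN and drug-database lookups)
#' make every pharmaceutical matchable.
#'
#' @param config A `sim_config`.
#' @return List with `catalog` (tibble: `drug_id`, `raw_name`, `item_type`),
#'   `inn_map`, `drug_db`, `groups` (tibble: `drug_id`, `group`),
#'   `ddi_pairs` (tibble: `drug_id_a`, `drug_id_b`).
#' @export
gen_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_drugs
    n_dev <- round(n * config$device_fraction)
    n_pharma <- n - n_dev
    if (n_pharma < config$n_atc_groups && n_pharma > 0) {
      kgd_abort("fewer pharmaceutical drugs than ATC groups",
        class = "kgd_error_argument"
      )
    }
    ids <- sprintf("D%03d", seq_len(n))
    pharma_ids <- ids[seq_len(n_pharma)]
    device_ids <- setdiff(ids, pharma_ids)
    # synthetic level-4 prefixes: letter + 2 digits + 2 letters
    prefixes <- character(0)
    while (length(unique(prefixes)) < config$n_atc_groups) {
      prefixes <- unique(c(prefixes, paste0(
        sample(LETTERS, 1), sprintf("%02d", sample(1:19, 1)),
        paste0(sample(LETTERS, 2, TRUE), collapse = "")
      )))
    }
    group <- rep(seq_len(config$n_atc_groups), length.out = n_pharma)
    member <- stats::ave(group, group, FUN = seq_along)
    atc <- paste0(prefixes[group], sprintf("%02d", member))
    cores <- synth_names(n_pharma)
    raw <- if (n_pharma > 0) {
      doses <- paste(sample(c(5, 10, 50, 100, 250, 500), n_pharma, TRUE), "mg")
      paste(
        paste0(toupper(substr(cores, 1, 1)), substr(cores, 2, nchar(cores))),
        doses
      )
    } else {
      character(0)
    }
    devices <- c(
      "mask", "syringe", "thermometer", "bandage", "glove", "test strip",
      "nebulizer", "lancet"
    )
    dev_names <- rep(devices, length.out = n_dev)
    catalog <- tibble(
      drug_id = c(pharma_ids, device_ids),
      raw_name = c(raw, dev_names),
      item_type = c(
        rep("pharmaceutical", n_pharma),
        rep("device", n_dev)
      )
    )
    inns <- paste0(cores, "um")
    ddi <- if (config$n_ddi_pairs > 0 && n_pharma >= 2) {
      # couple drugs from different groups so substitution and combination
      # signals stay distinguishable
      cand <- tidyr::expand_grid(a = seq_len(n_pharma), b = seq_len(n_pharma)) |>
        filter(.data$a < .data$b, group[.data$a] != group[.data$b])
      if (nrow(cand) == 0L) {
        cand <- tidyr::expand_grid(a = seq_len(n_pharma), b = seq_len(n_pharma)) |>
          filter(.data$a < .data$b)
      }
      # greedily keep pairs disjoint so each coupling stream is identifiable
      cand <- cand[sample.int(nrow(cand)), ]
      take <- cand[0, ]
      used <- integer(0)
      for (r in seq_len(nrow(cand))) {
        if (nrow(take) >= config$n_ddi_pairs) break
        if (!(cand$a[r] %in% used) && !(cand$b[r] %in% used)) {
          take <- dplyr::bind_rows(take, cand[r, ])
          used <- c(used, cand$a[r], cand$b[r])
        }
      }
      tibble(
        drug_id_a = pharma_ids[take$a],
        drug_id_b = pharma_ids[take$b]
      )
    } else {
      tibble(drug_id_a = character(), drug_id_b = character())
    }
    list(
      catalog = catalog,
      inn_map = tibble(core_name = cores, inn = inns),
      drug_db = tibble(inn = inns, atc_code = atc),
      groups = tibble(drug_id = pharma_ids, group = group),
      ddi_pairs = ddi
    )
  })
}

#' Simulate a weekly demand panel
#'
#' Group demand follows `base_g * (1 + a * sin(2 * pi * t / 52 + phase_g)) *
#' exp(eps)` with shared log-normal noise; within-group market shares follow
#' a logistic-normal random walk (substitution drift); each drug's mean is
#' the group curve times its share. Every DDI pair carries a shared Poisson
#' co-prescription count with AR(1)-persistent episode intensity, added to
#' the first endpoint in the prescribing week and to the partner one week
#' later (dispensing lag), so partner history is genuinely forecast-relevant
#' for the target. Observed demand is negative
#' binomial around the mean, with multiplicative outliers injected at
#' `outlier_prob` and weeks zeroed at `missing_week_prob`. Devices follow
#' independent seasonal log-AR(1) Poisson series. Sparse drugs are active in
#' only ~30 random weeks, below the default history floor.
#'
#' @param catalog,groups,ddi_pairs Output pieces of [gen_catalog()].
#' @param config A `sim_config`.
#' @return List with `panel` (demand panel tibble, see [aggregate_weekly()])
#'   and `truth` (list: group curves, share trajectories, coupling draws,
#'   outlier and missing cells, sparse drug ids).
#' @export
simulate_demand <- function(catalog, groups, ddi_pairs, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    w <- config$weeks
    tseq <- seq_len(w)
    ids <- catalog$drug_id
    n <- length(ids)
    mu <- matrix(0, n, w, dimnames = list(ids, NULL))
    ngroups <- max(groups$group %||% 0, 0)
    group_base <- runif(ngroups, config$base_demand[1], config$base_demand[2])
    group_phase <- runif(ngroups, 0, 2 * pi)
    group_curves <- matrix(0, ngroups, w)
    shares <- list()
    for (g in seq_len(ngroups)) {
      # persistent (AR(1)) group-level fluctuations: disease waves span weeks,
      # so the group's current level is informative about next week
      eps <- numeric(w)
      eps[1] <- rnorm(1, 0, config$group_noise_sd)
      if (w > 1) {
        for (t in 2:w) {
          eps[t] <- 0.8 * eps[t - 1] + rnorm(1, 0, config$group_noise_sd)
        }
      }
      group_curves[g, ] <- group_base[g] *
        (1 + config$seasonal_amplitude * sin(2 * pi * tseq / 52 + group_phase[g])) *
        exp(eps)
      members <- groups$drug_id[groups$group == g]
      m <- length(members)
      z <- matrix(0, m, w)
      z[, 1] <- rnorm(m, 0, 0.3)
      if (w > 1) {
        for (t in 2:w) {
          z[, t] <- z[, t - 1] + rnorm(m, 0, config$share_drift)
        }
      }
      sh <- apply(z, 2, function(col) exp(col) / sum(exp(col)))
      sh <- matrix(sh, nrow = m)
      rownames(sh) <- members
      shares[[g]] <- sh
      mu[members, ] <- group_curves[g, , drop = FALSE][rep(1, m), ] * sh
    }
    # co-prescription counts across DDI pairs: each pair carries two
    # AR(1)-persistent episode streams, one led by each endpoint; the leading
    # drug is dispensed in the prescribing week and the partner one week
    # later, so partner history is forecast-relevant for both endpoints (not
    # just correlated with them)
    coupling_draws <- list()
    if (nrow(ddi_pairs) > 0 && config$coupling > 0) {
      for (r in seq_len(nrow(ddi_pairs))) {
        a <- ddi_pairs$drug_id_a[r]
        b <- ddi_pairs$drug_id_b[r]
        for (lead in list(c(a, b), c(b, a))) {
          episode <- numeric(w)
          episode[1] <- rnorm(1, 0, 0.4)
          if (w > 1) {
            for (t in 2:w) episode[t] <- 0.8 * episode[t - 1] + rnorm(1, 0, 0.4)
          }
          lambda <- config$coupling * config$coupling_share *
            (mu[a, ] + mu[b, ]) / 2 * exp(episode)
          draw <- if (config$observation_noise) rpois(w, lambda) else lambda
          coupling_draws[[paste(lead[1], lead[2], sep = "~")]] <- draw
        }
      }
    }
    # negative-binomial observation noise
    demand <- matrix(0, n, w, dimnames = list(ids, NULL))
    pharma <- catalog$drug_id[catalog$item_type == "pharmaceutical"]
    for (id in pharma) {
      demand[id, ] <- if (config$observation_noise) {
        rnbinom(w, size = config$dispersion, mu = pmax(mu[id, ], 1e-8))
      } else {
        mu[id, ]
      }
    }
    for (key in names(coupling_draws)) {
      pair <- strsplit(key, "~", fixed = TRUE)[[1]]
      draw <- coupling_draws[[key]]
      demand[pair[1], ] <- demand[pair[1], ] + draw
      # partner dispensed one week later
      demand[pair[2], 2:w] <- demand[pair[2], 2:w] + draw[1:(w - 1)]
    }
    # devices: independent seasonal log-AR(1) Poisson counts
    dev_ids <- catalog$drug_id[catalog$item_type == "device"]
    for (id in dev_ids) {
      base <- runif(1, config$base_demand[1], config$base_demand[2]) / 2
      phase <- runif(1, 0, 2 * pi)
      ar <- numeric(w)
      ar[1] <- rnorm(1, 0, 0.1)
      if (w > 1) {
        for (t in 2:w) ar[t] <- 0.7 * ar[t - 1] + rnorm(1, 0, 0.1)
      }
      lam <- base * (1 + 0.2 * sin(2 * pi * tseq / 52 + phase)) * exp(ar)
      demand[id, ] <- if (config$observation_noise) rpois(w, lam) else lam
    }
    # outliers
    outlier_cells <- which(
      matrix(runif(n * w) < config$outlier_prob, n, w) & demand > 0,
      arr.ind = TRUE
    )
    if (nrow(outlier_cells) > 0) {
      mult <- runif(nrow(outlier_cells), config$outlier_mult[1], config$outlier_mult[2])
      demand[outlier_cells] <- round(demand[outlier_cells] * mult)
    }
    # missing weeks
    missing <- matrix(runif(n * w) < config$missing_week_prob, n, w,
      dimnames = list(ids, NULL)
    )
    # sparse drugs: active only in ~30 random weeks
    sparse_ids <- character(0)
    coupled_ids <- unique(c(ddi_pairs$drug_id_a, ddi_pairs$drug_id_b))
    sparse_pool <- setdiff(pharma, coupled_ids) # keep DDI endpoints in the panel
    if (config$n_sparse_drugs > 0 && length(sparse_pool) > config$n_sparse_drugs) {
      sparse_ids <- tail(sparse_pool, config$n_sparse_drugs)
      for (id in sparse_ids) {
        active <- sample.int(w, min(30, w))
        missing[id, setdiff(tseq, active)] <- TRUE
      }
    }
    demand[missing] <- 0
    week_start <- seq(config$start_date, by = 7L, length.out = w)
    panel <- tidyr::expand_grid(drug_id = ids, week = tseq) |>
      mutate(
        week_start = week_start[.data$week],
        iso_week = iso_week_label(.data$week_start),
        demand = demand[cbind(match(.data$drug_id, ids), .data$week)],
        observed = .data$demand > 0
      ) |>
      arrange(.data$drug_id, .data$week)
    list(
      panel = panel,
      truth = list(
        group_curves = group_curves,
        shares = shares,
        coupling_draws = coupling_draws,
        outlier_cells = outlier_cells,
        missing = missing,
        sparse_ids = sparse_ids
      )
    )
  })
}

#' Decompose a demand panel into transaction records
#'
#' Splits each positive weekly quantity into one to three transactions with
#' random dates inside the ISO week, such that re-aggregating the
#' transactions with [aggregate_weekly()] reproduces the panel's demand cells
#' exactly.
#'
#' @param panel A demand panel with `week_start` dates.
#' @param config A `sim_config` (supplies the seed).
#' @return Tibble of transactions: `drug_id`, `date`, `quantity`.
#' @export
emit_transactions <- function(panel, config) {
  assert_columns(panel, c("drug_id", "week_start", "demand"), "panel")
  with_seed(config$seed + 2L, {
    cells <- panel |> filter(.data$demand > 0)
    rows <- purrr::pmap_dfr(
      list(cells$drug_id, cells$week_start, cells$demand),
      function(id, ws, q) {
        q <- as.integer(round(q))
        k <- sample.int(min(3L, q), 1L)
        if (k == 1L) {
          qty <- q
        } else {
          cuts <- sort(sample.int(q - 1L, k - 1L))
          qty <- diff(c(0L, cuts, q))
        }
        tibble(
          drug_id = id,
          date = ws + sample(0:6, k, replace = TRUE),
          quantity = qty
        )
      }
    )
    rows |> arrange(.data$date, .data$drug_id)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [gen_catalog()], [simulate_demand()] and [emit_transactions()] under
#' one configuration and returns every table the pipeline reads.
#'
#' @param config A `sim_config`.
#' @return List with `catalog`, `inn_map`, `drug_db`, `ddi_pairs`, `groups`,
#'   `panel`, `transactions`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cat_out <- gen_catalog(config)
  sim <- simulate_demand(cat_out$catalog, cat_out$groups, cat_out$ddi_pairs, config)
  tx <- emit_transactions(sim$panel, config)
  c(cat_out, list(panel = sim$panel, transactions = tx, truth = sim$truth))
}
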