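# CSV dialects, artifact writers, and the pipeline runner.

read_checked <- function(path, required, what, col_types = NULL) {
  if (!file.exists(path)) {
    kgd_abort(sprintf("file not found: %s", path), class = "kgd_error_io")
  }
  df <- readr::read_csv(path, col_types = col_types, show_col_types = FALSE)
  assert_columns(df, required, what)
  df
}

#' Read a transactions CSV
#'
#' Columns: `drug_id`, `date` (ISO-8601), `quantity`. Rows with unparseable
#' dates are dropped with a warning naming the count; a missing column is a
#' schema error.
#'
#' @param path CSV path.
#' @return Tibble of transactions.
#' @export
read_transactions <- function(path) {
  df <- read_checked(
    path, c("drug_id", "date", "quantity"), "transactions",
    col_types = readr::cols(.default = readr::col_character())
  )
  df$drug_id <- as.character(df$drug_id)
  df$quantity <- as.numeric(df$quantity)
  parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- is.na(parsed)
  if (any(bad)) {
    warn(sprintf(
      "dropping %d row(s) with unparseable dates (lines %s)",
      sum(bad), paste(head(which(bad), 5L) + 1L, collapse = ", ")
    ))
  }
  df$date <- parsed
  df[!bad, , drop = FALSE]
}

#' Read the catalog, DDI and lookup CSVs
#'
#' `read_catalog()` expects `drug_id`, `raw_name`, `item_type` (optional
#' `atc_code`); `read_ddi()` expects `drug_id_a`, `drug_id_b`;
#' `read_inn_map()` expects `core_name`, `inn`; `read_drug_db()` expects
#' `inn`, `atc_code`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_catalog <- function(path) {
  read_checked(path, c("drug_id", "raw_name", "item_type"), "catalog")
}

#' @rdname read_catalog
#' @export
read_ddi <- function(path) {
  read_checked(path, c("drug_id_a", "drug_id_b"), "ddi")
}

#' @rdname read_catalog
#' @export
read_inn_map <- function(path) {
  read_checked(path, c("core_name", "inn"), "inn_map")
}

#' @rdname read_catalog
#' @export
read_drug_db <- function(path) {
  read_checked(path, c("inn", "atc_code"), "drug_db")
}

#' Export a knowledge graph to CSV and Matrix Market files
#'
#' Writes `edges.csv` (`drug_id_a`, `drug_id_b`, `relation`), `nodes.csv`
#' (`drug_id`, `item_type`, row order = adjacency order) and
#' `adjacency.mtx` (sparse Matrix Market).
#'
#' @param graph A `drug_graph`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
export_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "drug_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("edges.csv", "nodes.csv", "adjacency.mtx"))
  readr::write_csv(
    graph$relations |>
      transmute(
        drug_id_a = .data$endpoint_a, drug_id_b = .data$endpoint_b,
        relation = .data$relation
      ),
    paths[1]
  )
  readr::write_csv(
    tibble(drug_id = graph$node_index, item_type = unname(graph$item_type)),
    paths[2]
  )
  Matrix::writeMM(Matrix::Matrix(graph$adjacency, sparse = TRUE), paths[3])
  invisible(paths)
}

#' Write a synthetic dataset to CSV fixtures
#'
#' Emits the exact CSV dialects the pipeline reads (transactions, catalog,
#' ddi, inn_map, drug_db) plus a ground-truth JSON summary.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$transactions, file.path(dir, "transactions.csv"))
  readr::write_csv(dataset$catalog, file.path(dir, "catalog.csv"))
  readr::write_csv(dataset$ddi_pairs, file.path(dir, "ddi.csv"))
  readr::write_csv(dataset$inn_map, file.path(dir, "inn_map.csv"))
  readr::write_csv(dataset$drug_db, file.path(dir, "drug_db.csv"))
  truth <- list(
    groups = dataset$groups,
    sparse_ids = dataset$truth$sparse_ids,
    n_outliers = nrow(dataset$truth$outlier_cells)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds every weight block by name plus the model and
#' training configuration; loading restores them bit-exactly.
#'
#' @param fit A `kgf_fit`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_checkpoint()` invisibly returns `path`; `load_checkpoint()`
#'   returns the `kgf_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "kgf_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "kgf_fit"))
  fit
}

#' Default pipeline configuration
#'
#' All tunable constants of the end-to-end pipeline in one list: input paths,
#' preprocessing constants (window 16, minimum 40 valid weeks, three-sigma
#' outlier rule, 8 test + 4 validation weeks, 2-hop neighbourhoods), the
#' training block, the simulator block, and output settings. Values loaded
#' from a YAML file override the defaults key by key.
#'
#' @param path Optional YAML file.
#' @param overrides Named list applied after the file.
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    paths = list(
      transactions = "transactions.csv", catalog = "catalog.csv",
      ddi = "ddi.csv", inn_map = "inn_map.csv", drug_db = "drug_db.csv"
    ),
    window = 16, min_valid_weeks = 40, outlier_sigma = 3,
    test_weeks = 8, val_weeks = 4, hop = 2,
    train = list(
      learning_rate = 0.001, hidden_dim = 64, dropout = 0.2,
      patience = 500, max_epochs = 5000
    ),
    sim = list(),
    variant = "gcn2",
    seeds = 0:4,
    out_dir = "kgdemand_out",
    seed = 1L
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  if (length(overrides) > 0) {
    cfg <- utils::modifyList(cfg, overrides)
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run one pipeline stage end to end
#'
#' Subcommands: `simulate` (write a synthetic fixture dataset),
#' `build-graph` (catalog + DDI tables to graph export), `preprocess`
#' (transactions to weekly panel with history filter and split manifest),
#' `train` (per-target model checkpoints), `evaluate` (multi-seed metrics
#' JSON/CSV), `ablate` (variant sweep table). Every artifact is stamped with
#' the configuration hash and seed, so identical (config, seed) re-runs
#' produce identical artifacts.
#'
#' @param config A `run_config`.
#' @param command One of the subcommands above.
#' @param targets Optional drug ids for `train`/`evaluate`/`ablate`
#'   (default: all surviving drugs).
#' @return Invisibly, a list of written artifact paths.
#' @export
run_pipeline <- function(config = run_config(), command, targets = NULL) {
  command <- match.arg(
    command,
    c("simulate", "build-graph", "preprocess", "train", "evaluate", "ablate")
  )
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = config_hash(config), seed = config$seed)
  ctl <- do.call(train_config, c(config$train, list(seed = config$seed)))

  if (command == "simulate") {
    sc <- do.call(sim_config, utils::modifyList(config$sim, list(seed = config$seed)))
    ds <- simulate_dataset(sc)
    write_sim_dataset(ds, out)
    jsonlite::write_json(stamp, file.path(out, "stamp.json"), auto_unbox = TRUE)
    return(invisible(list(dir = out)))
  }

  catalog <- read_catalog(config$paths$catalog)
  inn_map <- read_inn_map(config$paths$inn_map)
  drug_db <- read_drug_db(config$paths$drug_db)
  ddi <- read_ddi(config$paths$ddi)
  graph <- build_knowledge_graph(catalog, inn_map, drug_db, ddi)

  if (command == "build-graph") {
    paths <- export_graph(graph, out)
    jsonlite::write_json(stamp, file.path(out, "stamp.json"), auto_unbox = TRUE)
    return(invisible(list(paths = paths)))
  }

  tx <- read_transactions(config$paths$transactions)
  panel <- aggregate_weekly(tx)
  n0 <- length(unique(panel$drug_id))
  panel <- filter_min_history(panel, config$min_valid_weeks)
  n1 <- length(unique(panel$drug_id))
  message(sprintf(
    "history filter: %d of %d drugs retain >= %d valid weeks",
    n1, n0, config$min_valid_weeks
  ))
  split <- chronological_split(panel, config$test_weeks, config$val_weeks, config$window)

  if (command == "preprocess") {
    wide <- panel |>
      select("drug_id", "iso_week", "demand") |>
      tidyr::pivot_wider(names_from = "iso_week", values_from = "demand")
    readr::write_csv(wide, file.path(out, "panel.csv"))
    jsonlite::write_json(
      c(stamp, list(
        train = range(split$train), val = range(split$val), test = range(split$test),
        drugs_in = n0, drugs_kept = n1
      )),
      file.path(out, "split.json"),
      auto_unbox = TRUE
    )
    return(invisible(list(panel = file.path(out, "panel.csv"))))
  }

  targets <- targets %||% sort(unique(panel$drug_id))

  if (command == "train") {
    paths <- character(0)
    cfg <- build_variant(config$variant, model_config(
      hidden = ctl$hidden_dim, dropout = ctl$dropout, hop = config$hop
    ))
    for (tg in targets) {
      fit <- fit_kgf(panel, graph, tg,
        config = cfg, control = ctl,
        window = config$window, test_weeks = config$test_weeks,
        val_weeks = config$val_weeks
      )
      p <- file.path(out, sprintf("checkpoint_%s.rds", tg))
      save_checkpoint(fit, p)
      paths <- c(paths, p)
    }
    jsonlite::write_json(stamp, file.path(out, "stamp.json"), auto_unbox = TRUE)
    return(invisible(list(checkpoints = paths)))
  }

  if (command == "evaluate") {
    ckpt <- file.path(out, sprintf("checkpoint_%s.rds", targets))
    missing_ck <- ckpt[!file.exists(ckpt)]
    if (length(missing_ck) > 0) {
      kgd_abort(
        sprintf("missing checkpoint(s): %s", paste(missing_ck, collapse = ", ")),
        class = "kgd_error_io"
      )
    }
    preds <- purrr::map_dfr(seq_along(targets), function(k) {
      predict(load_checkpoint(ckpt[k])) |> mutate(drug_id = targets[k])
    })
    metrics <- compute_metrics(preds, "actual", "predicted")
    readr::write_csv(preds, file.path(out, "predictions.csv"))
    jsonlite::write_json(
      c(stamp, as.list(metrics)),
      file.path(out, "metrics.json"),
      auto_unbox = TRUE, digits = NA
    )
    return(invisible(list(metrics = file.path(out, "metrics.json"))))
  }

  # ablate
  tab <- run_ablation(panel, graph,
    targets = targets, control = ctl,
    seeds = config$seeds, window = config$window,
    test_weeks = config$test_weeks, val_weeks = config$val_weeks
  )
  readr::write_csv(tab, file.path(out, "ablation.csv"))
  jsonlite::write_json(stamp, file.path(out, "stamp.json"), auto_unbox = TRUE)
  invisible(list(ablation = file.path(out, "ablation.csv")))
}
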