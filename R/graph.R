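#' Substitution edges from shared ATC level-4 subgroup
#'
#' Two drugs are treated as substitutes when their ATC codes share the same
#' first five characters (the level-4 chemical subgroup, e.g. "J01CA" for
#' penicillins with extended spectrum). One undirected edge is emitted per
#' unordered pair of records sharing a prefix; records without an ATC code
#' contribute no edges.
#'
#' @param records Data frame of drug records with columns `drug_id`,
#'   `atc_code` (see [prepare_catalog()]).
#' @return Tibble of edges: `endpoint_a`, `endpoint_b`, `relation =
#'   "substitution"`, with `endpoint_a < endpoint_b` and no duplicates.
#' @export
substitution_edges <- function(records) {
  assert_columns(records, c("drug_id", "atc_code"), "records")
  if (anyDuplicated(records$drug_id) > 0L) {
    kgd_abort("records have duplicate drug_id values", class = "kgd_error_table")
  }
  coded <- records |> filter(!is.na(.data$atc_code))
  if (any(nchar(coded$atc_code) < 5L)) {
    bad <- coded$drug_id[nchar(coded$atc_code) < 5L]
    kgd_abort(
      sprintf(
        "ATC code shorter than 5 characters for: %s",
        paste(bad, collapse = ", ")
      ),
      class = "kgd_error_validation"
    )
  }
  if (nrow(coded) < 2L) {
    return(empty_edges())
  }
  coded |>
    mutate(atc4 = substr(.data$atc_code, 1L, 5L)) |>
    inner_join(
      coded |> mutate(atc4 = substr(.data$atc_code, 1L, 5L)),
      by = "atc4", suffix = c("_a", "_b"), relationship = "many-to-many"
    ) |>
    filter(.data$drug_id_a < .data$drug_id_b) |>
    transmute(
      endpoint_a = .data$drug_id_a,
      endpoint_b = .data$drug_id_b,
      relation = "substitution"
    ) |>
    distinct() |>
    arrange(.data$endpoint_a, .data$endpoint_b)
}

#' Combination edges from drug-drug interaction records
#'
#' Each drug-drug interaction (DDI) pair whose endpoints are both present in
#' the cleaned catalog (a strict intersection) yields one undirected
#' combination edge. Duplicate and order-swapped pairs collapse to a single
#' edge; self-pairs are rejected with a warning; pairs touching a device
#' record are dropped (devices lack chemical interaction properties and stay
#' isolated in the graph).
#'
#' @param records Data frame of drug records with columns `drug_id` and,
#'   optionally, `item_type`.
#' @param ddi_pairs Data frame with columns `drug_id_a`, `drug_id_b`.
#' @return Tibble of edges: `endpoint_a`, `endpoint_b`,
#'   `relation = "combination"`.
#' @export
combination_edges <- function(records, ddi_pairs) {
  assert_columns(records, "drug_id", "records")
  assert_columns(ddi_pairs, c("drug_id_a", "drug_id_b"), "ddi_pairs")
  self <- ddi_pairs$drug_id_a == ddi_pairs$drug_id_b
  if (any(self)) {
    warn(sprintf("dropping %d self-pair DDI row(s)", sum(self)))
    ddi_pairs <- ddi_pairs[!self, , drop = FALSE]
  }
  known <- records$drug_id
  if ("item_type" %in% names(records)) {
    known <- records$drug_id[records$item_type != "device"]
  }
  edges <- as_tibble(ddi_pairs) |>
    filter(.data$drug_id_a %in% known, .data$drug_id_b %in% known) |>
    transmute(
      endpoint_a = pmin(.data$drug_id_a, .data$drug_id_b),
      endpoint_b = pmax(.data$drug_id_a, .data$drug_id_b),
      relation = "combination"
    ) |>
    distinct() |>
    arrange(.data$endpoint_a, .data$endpoint_b)
  if (nrow(edges) == 0L) empty_edges() else edges
}

empty_edges <- function() {
  tibble(
    endpoint_a = character(),
    endpoint_b = character(),
    relation = character()
  )
}

#' Assemble the drug knowledge graph
#'
#' Builds the node-indexed binary adjacency matrix over all catalog drugs.
#' Substitution and combination edges receive the same unit weight (relative
#' influence is learned downstream by the GCN weight matrices); a pair present
#' under both relations still has adjacency 1 but keeps both labels. Device
#' records become isolated nodes. Node order follows catalog order.
#'
#' @param records Data frame of drug records (`drug_id`, `item_type`).
#' @param edges Data frame of relation edges as produced by
#'   [substitution_edges()] and/or [combination_edges()] (rows may be
#'   concatenated).
#' @return A `drug_graph` object: list with `node_index` (character vector),
#'   `adjacency` (N x N symmetric 0/1 matrix with zero diagonal), `relations`
#'   (tibble of labelled unordered pairs) and `item_type` (named vector).
#' @export
assemble_graph <- function(records, edges) {
  assert_columns(records, c("drug_id", "item_type"), "records")
  edges <- if (nrow(edges) == 0L) empty_edges() else as_tibble(edges)
  assert_columns(edges, c("endpoint_a", "endpoint_b", "relation"), "edges")
  nodes <- records$drug_id
  unknown <- setdiff(c(edges$endpoint_a, edges$endpoint_b), nodes)
  if (length(unknown) > 0L) {
    kgd_abort(
      sprintf(
        "edge endpoint(s) not in catalog: %s",
        paste(unknown, collapse = ", ")
      ),
      class = "kgd_error_integrity"
    )
  }
  if (any(edges$endpoint_a == edges$endpoint_b)) {
    kgd_abort("self-edges are not allowed", class = "kgd_error_integrity")
  }
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  relations <- edges |>
    transmute(
      endpoint_a = pmin(.data$endpoint_a, .data$endpoint_b),
      endpoint_b = pmax(.data$endpoint_a, .data$endpoint_b),
      relation = .data$relation
    ) |>
    distinct() |>
    arrange(.data$endpoint_a, .data$endpoint_b, .data$relation)
  if (nrow(relations) > 0L) {
    ia <- match(relations$endpoint_a, nodes)
    ib <- match(relations$endpoint_b, nodes)
    adj[cbind(ia, ib)] <- 1
    adj[cbind(ib, ia)] <- 1
  }
  structure(
    list(
      node_index = nodes,
      adjacency = adj,
      relations = relations,
      item_type = setNames(records$item_type, nodes)
    ),
    class = "drug_graph"
  )
}

#' @export
print.drug_graph <- function(x, ...) {
  n_edges <- sum(x$adjacency) / 2
  cat(sprintf(
    "<drug_graph> %d nodes (%d device), %d edges (%d substitution, %d combination)\n",
    length(x$node_index),
    sum(x$item_type == "device"),
    n_edges,
    sum(x$relations$relation == "substitution"),
    sum(x$relations$relation == "combination")
  ))
  invisible(x)
}

#' Extract the k-hop neighbourhood of a target drug
#'
#' Breadth-first neighbourhood of the target: all nodes within graph distance
#' `k`, the induced adjacency submatrix, and the target's row position in it.
#' `k = 0` yields the single-node graph of the target; `k = Inf` yields the
#' target's connected component. The default `k = 2` matches the receptive
#' field of the two-layer GCN.
#'
#' @param graph A `drug_graph`.
#' @param target Drug id present in the graph.
#' @param k Hop count (non-negative; may be `Inf`).
#' @return List with `nodes` (character vector, graph order), `adjacency`
#'   (induced submatrix) and `target_position` (row index of the target).
#' @export
khop_subgraph <- function(graph, target, k = 2) {
  stopifnot(inherits(graph, "drug_graph"))
  if (!target %in% graph$node_index) {
    kgd_abort(sprintf("unknown target drug: %s", target), class = "kgd_error_lookup")
  }
  if (length(k) != 1L || is.na(k) || k < 0) {
    kgd_abort("k must be a single non-negative hop count", class = "kgd_error_argument")
  }
  ig <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
  d <- igraph::distances(ig, v = match(target, graph$node_index))[1L, ]
  keep <- which(d <= k)
  nodes <- graph$node_index[keep]
  list(
    nodes = nodes,
    adjacency = graph$adjacency[keep, keep, drop = FALSE],
    target_position = match(target, nodes)
  )
}

#' Restrict a drug graph to a subset of drugs
#'
#' Induced subgraph on the drugs present in `keep` (e.g. the drugs surviving
#' the minimum-history filter), preserving node order and relation labels.
#'
#' @param graph A `drug_graph`.
#' @param keep Character vector of drug ids to retain.
#' @return A `drug_graph` over `intersect(graph$node_index, keep)`.
#' @export
restrict_graph <- function(graph, keep) {
  stopifnot(inherits(graph, "drug_graph"))
  idx <- graph$node_index %in% keep
  nodes <- graph$node_index[idx]
  relations <- graph$relations |>
    filter(.data$endpoint_a %in% nodes, .data$endpoint_b %in% nodes)
  structure(
    list(
      node_index = nodes,
      adjacency = graph$adjacency[idx, idx, drop = FALSE],
      relations = relations,
      item_type = graph$item_type[idx]
    ),
    class = "drug_graph"
  )
}

#' Build the knowledge graph from catalog tables
#'
#' One-call construction: record preparation, substitution edges from ATC
#' level-4 prefixes, combination edges from DDI pairs, and graph assembly.
#'
#' @param catalog Raw catalog (`drug_id`, `raw_name`, `item_type`).
#' @param inn_map,drug_db Lookup tables (see [match_catalog()]).
#' @param ddi_pairs DDI table (`drug_id_a`, `drug_id_b`).
#' @return A `drug_graph`.
#' @export
build_knowledge_graph <- function(catalog, inn_map, drug_db, ddi_pairs) {
  records <- prepare_catalog(catalog, inn_map, drug_db)
  edges <- bind_rows(
    substitution_edges(records),
    combination_edges(records, ddi_pairs)
  )
  assemble_graph(records, edges)
}
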