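#' Strip dosage and pack tokens from a product name
#'
#' Pharmacy catalogs list products with dosage strength and pack sizes in the
#' name ("Amoxicillin 500 mg", "Paracetamol 120 mg/5 ml Syrup"). To match a
#' product against generic-name (INN) and drug-database tables, the name is
#' reduced to its core: lower-cased, dosage/strength tokens (a number followed
#' by a unit among mg, g, mcg, ug, ml, l, iu, %, including compound forms such
#' as "mg/5 ml") and pack-count tokens ("x 10", "20 tablets") removed, and
#' whitespace collapsed.
#'
#' @param raw_name Character vector of product names as printed in the catalog.
#' @return Character vector of cleaned core names, same length as the input.
#' @examples
#' clean_product_name("Amoxicillin 500 mg")
#' clean_product_name("Paracetamol 120 mg/5 ml Syrup")
#' @export
clean_product_name <- function(raw_name) {
  if (length(raw_name) == 0L || any(is.na(raw_name)) || any(!nzchar(raw_name))) {
    kgd_abort("raw_name must be non-empty", class = "kgd_error_argument")
  }
  unit <- "(mg|mcg|µg|ug|g|ml|l|iu|%)"
  num <- "[0-9]+([.,][0-9]+)?"
  x <- stringr::str_to_lower(raw_name)
  # compound strengths first: "120 mg/5 ml", "5 mg/ml"
  x <- stringr::str_replace_all(
    x,
    stringr::regex(paste0("\\b", num, "\\s*", unit, "\\s*/\\s*(", num, "\\s*)?", unit)),
    " "
  )
  # plain strength tokens: "500 mg", "0.9 %"
  x <- stringr::str_replace_all(
    x,
    stringr::regex(paste0("\\b", num, "\\s*", unit, "(?![a-z])")),
    " "
  )
  # pack counts: "x10", "x 10", "10 tablets", "30 caps", "5 vials"
  x <- stringr::str_replace_all(x, stringr::regex("\\bx\\s*[0-9]+\\b"), " ")
  x <- stringr::str_replace_all(
    x,
    stringr::regex("\\b[0-9]+\\s*(tabs?|tablets?|caps?|capsules?|strips?|sachets?|vials?|pcs?|pieces?)\\b"),
    " "
  )
  x <- stringr::str_squish(x)
  x
}

#' Match cleaned product names to INN and ATC codes
#'
#' Two lookup tables drive the standardisation: `inn_map` maps a cleaned core
#' name to its International Nonproprietary Name (INN), and `drug_db` maps an
#' INN to its 7-character ATC code. A name found in both tables becomes a
#' matched record carrying `inn_name` and `atc_code`; a name absent from
#' either table is returned in `unmatched`. No name is silently dropped:
#' `nrow(matched) + length(unmatched)` always equals `length(core_names)`.
#'
#' @param core_names Character vector of cleaned core names
#'   (see [clean_product_name()]).
#' @param inn_map Data frame with columns `core_name`, `inn` (unique keys).
#' @param drug_db Data frame with columns `inn`, `atc_code` (unique keys).
#' @return A list with elements `matched` (tibble: `core_name`, `inn_name`,
#'   `atc_code`) and `unmatched` (character vector).
#' @export
match_catalog <- function(core_names, inn_map, drug_db) {
  assert_columns(inn_map, c("core_name", "inn"), "inn_map")
  assert_columns(drug_db, c("inn", "atc_code"), "drug_db")
  if (anyDuplicated(inn_map$core_name) > 0L) {
    kgd_abort("inn_map has duplicate core_name keys", class = "kgd_error_table")
  }
  if (anyDuplicated(drug_db$inn) > 0L) {
    kgd_abort("drug_db has duplicate inn keys", class = "kgd_error_table")
  }
  inn <- inn_map$inn[match(core_names, inn_map$core_name)]
  atc <- drug_db$atc_code[match(inn, drug_db$inn)]
  ok <- !is.na(inn) & !is.na(atc)
  list(
    matched = tibble(
      core_name = core_names[ok],
      inn_name = inn[ok],
      atc_code = atc[ok]
    ),
    unmatched = core_names[!ok]
  )
}

#' Build drug records from a raw catalog and lookup tables
#'
#' Convenience wrapper chaining [clean_product_name()] and [match_catalog()]
#' over a raw catalog table. Pharmaceutical items that fail to match keep
#' `NA` in `inn_name`/`atc_code` (they enter the graph as isolated nodes);
#' devices are never matched and carry no ATC code.
#'
#' @param catalog Data frame with columns `drug_id`, `raw_name`, `item_type`
#'   (`"pharmaceutical"` or `"device"`); an `atc_code` column, if present, is
#'   ignored in favour of the lookup result.
#' @param inn_map,drug_db Lookup tables as in [match_catalog()].
#' @return Tibble of drug records: `drug_id`, `raw_name`, `core_name`,
#'   `inn_name`, `atc_code`, `item_type`.
#' @export
prepare_catalog <- function(catalog, inn_map, drug_db) {
  assert_columns(catalog, c("drug_id", "raw_name", "item_type"), "catalog")
  if (anyDuplicated(catalog$drug_id) > 0L) {
    kgd_abort("catalog has duplicate drug_id values", class = "kgd_error_table")
  }
  bad_type <- setdiff(unique(catalog$item_type), c("pharmaceutical", "device"))
  if (length(bad_type) > 0L) {
    kgd_abort(
      sprintf("unknown item_type value(s): %s", paste(bad_type, collapse = ", ")),
      class = "kgd_error_schema"
    )
  }
  records <- as_tibble(catalog) |>
    mutate(core_name = clean_product_name(.data$raw_name))
  pharma <- records$item_type == "pharmaceutical"
  res <- match_catalog(records$core_name[pharma], inn_map, drug_db)
  idx <- match(records$core_name, res$matched$core_name)
  records$inn_name <- ifelse(pharma, res$matched$inn_name[idx], NA_character_)
  records$atc_code <- ifelse(pharma, res$matched$atc_code[idx], NA_character_)
  records |>
    select("drug_id", "raw_name", "core_name", "inn_name", "atc_code", "item_type")
}
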