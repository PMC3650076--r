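# fixtures: machine-readable encodings of the published benchmark tables,
# and small constructed worlds derived from them for end-to-end checks.

#' Per-genus benchmark table fixture
#'
#' The selected-genera benchmark table: per genus, total holdings in the
#' institution-level registry (`wiews_total`), total records in the
#' accession-level database (`genesys_total`), the distinct-accession
#' estimate, Treaty-covered accessions (`treaty`) and vault deposits
#' (`sgsv`); `annex1` is FALSE for genera footnoted as outside the Treaty's
#' Annex 1 crop list. One cell is printed with a corrupted separator in the
#' source and is stored with the value implied by group-total arithmetic
#' (see its `note`).
#'
#' @return Tibble with columns `genus`, `crop_group`, `wiews_total`,
#'   `genesys_total`, `distinct`, `treaty`, `sgsv`, `annex1`, `note`.
#' @export
fixture_table1 <- function() {
  vg_read_csv(vg_extdata("table1_genus.csv"), col_types = "cciiiiilc")
}

#' Crop-group total rows of the benchmark table
#'
#' The printed group rows, including the grand totals. `complete` is TRUE
#' for groups whose printed member genus rows sum exactly to the group row
#' (verifiable desk arithmetic), FALSE where the group total includes
#' unprinted genera, and NA for the grand-total rows.
#'
#' @return Tibble `crop_group`, `wiews_total`, `genesys_total`, `distinct`,
#'   `treaty`, `sgsv`, `complete`.
#' @export
fixture_table1_groups <- function() {
  vg_read_csv(vg_extdata("table1_groups.csv"), col_types = "ciiiiil")
}

#' Treaty coverage component totals
#'
#' The two printed Multilateral-System components: Annex 1 accessions held
#' in Contracting-Party countries (excluding Article 15 institutes) and
#' accessions held by Article 15 institutions. Their sum is the grand-total
#' Treaty cell of the benchmark table.
#'
#' @return Tibble `component`, `n_accessions`.
#' @export
fixture_treaty_components <- function() {
  vg_read_csv(vg_extdata("treaty_components.csv"), col_types = "ci")
}

#' Top-ten institutional profile fixture
#'
#' The printed institutional-coverage table for 29 food-crop genera:
#' `entries` lists, per genus, the ten largest collections (holder label,
#' host-country code, and the printed bracket percentage of that collection
#' backed up in the vault); `counts` carries the printed per-genus counts of
#' collections in the vault and under deposit-agreement conditions.
#' `bracket_consistent` flags rows whose printed count equals the number of
#' nonzero bracket percentages; printed brackets are rounded and can mask
#' small deposits, so the remaining rows are not reproducible from brackets
#' alone.
#'
#' @return List of two tibbles, `entries` and `counts`.
#' @export
fixture_table2 <- function() {
  list(
    entries = vg_read_csv(vg_extdata("table2_entries.csv"), col_types = "ciccci"),
    counts = vg_read_csv(vg_extdata("table2_counts.csv"), col_types = "ciil")
  )
}

#' Study-genus candidate list fixture
#'
#' The 206 candidate genera of the selection cascade plus the six non-PGRFA
#' genera removed before it, with their printed fate: 156 retained, 26
#' excluded for vault absence, 24 excluded for vault absence attributed to
#' recalcitrant/intermediate seeds. Only 46 of the retained names are
#' printed in the source (the benchmark table and the text); the remaining
#' 110 are synthetic placeholder names flagged `provenance = "synthetic"`.
#'
#' @return Tibble `genus`, `status`, `provenance`.
#' @export
fixture_genus_lists <- function() {
  vg_read_csv(vg_extdata("genus_list.csv"), col_types = "ccc")
}

#' Holdings and deposits that realise the selection-cascade fixture
#'
#' Builds the minimal inputs on which [select_study_genera()] reproduces
#' the published cascade: every candidate genus (and the six non-PGRFA
#' genera) is given holdings above the threshold, and only the retained 156
#' have vault deposits. Holdings counts are synthetic (the source prints
#' the genus lists, not per-genus candidate counts).
#'
#' @return List with tibbles `holdings` and `deposits`.
#' @export
fixture_selection_inputs <- function() {
  gl <- fixture_genus_lists()
  holdings <- tibble(
    institute_code = "FIX001",
    genus = gl$genus,
    n_total = 1500L,
    n_indigenous = NA_integer_
  )
  deposited <- gl$genus[gl$status == "retained"]
  deposits <- tibble(
    depositor_code = "FIX001",
    genus = deposited,
    n_deposited = 10L
  )
  list(holdings = holdings, deposits = deposits)
}

#' Construct a world realising the institutional-profile fixture
#'
#' Builds a synthetic world whose top-ten holder profile for each fixture
#' genus reproduces the printed bracket percentages: every listed
#' collection is given a holdings count of 1000 accessions (the source does
#' not print holdings), and deposits of ten times the bracket percentage,
#' so the computed backup share equals the printed bracket exactly.
#' Holdings are ranked by the printed order via descending synthetic counts.
#'
#' @param genera Genera to include (default: all 29).
#' @return A `vaultgap_world`.
#' @export
fixture_world_table2 <- function(genera = NULL) {
  entries <- fixture_table2()$entries
  if (!is.null(genera)) entries <- filter(entries, .data$genus %in% genera)
  if (!nrow(entries)) abort_value("fixture_world_table2: no matching genera")
  entries <- entries |>
    mutate(institute_code = sprintf("%s%02d%s", .data$country, .data$rank,
                                    substr(.data$genus, 1, 3)))
  # preserve printed rank: strictly decreasing holdings by rank
  holdings <- entries |>
    mutate(n_total = 1000L + (11L - .data$rank),
           n_indigenous = NA_integer_) |>
    select("institute_code", "genus", "n_total", "n_indigenous")
  deposits <- entries |>
    filter(.data$backup_pct > 0) |>
    mutate(n_deposited = as.integer(.data$backup_pct * (1000L + (11L - .data$rank)) / 100)) |>
    select(depositor_code = "institute_code", "genus", "n_deposited")
  registry <- entries |>
    distinct(.data$institute_code, .data$country, .data$holder_type) |>
    mutate(
      inst_type = if_else(.data$holder_type == "iarc", "international_IARC",
                          "national"),
      article15 = .data$holder_type == "iarc",
      sda_signed = FALSE,
      sgsv_depositor = .data$institute_code %in% deposits$depositor_code
    ) |>
    select("institute_code", "country", "inst_type", "article15",
           "sda_signed", "sgsv_depositor")
  assemble_world(holdings = holdings, registry = registry, deposits = deposits)
}
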