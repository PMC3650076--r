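# taxonomy: genus normalization, seed-storage behaviour, crop groups, and
# the study-genus selection cascade.

SEED_BEHAVIORS <- c("recalcitrant", "intermediate", "orthodox")

#' Default genus synonym map
#'
#' A named character vector mapping raw genus names to canonical ones,
#' applied after case/whitespace normalization. The default is minimal:
#' the hybrid cereal Triticale is kept as a genus-level name, so its
#' botanical label xTriticosecale maps onto it. Users can extend or replace
#' the map; `Lycopersicon` is deliberately *not* folded into `Solanum`,
#' matching the convention of global holdings registries that list both.
#'
#' @return Named character vector (names = raw, values = canonical).
#' @export
default_synonym_map <- function() {
  c(Triticosecale = "Triticale", Xtriticosecale = "Triticale")
}

#' Normalize a genus name
#'
#' Trims whitespace, title-cases (first letter upper, rest lower), and
#' applies a synonym map. Unknown names pass through unchanged, so the
#' operation is total and idempotent.
#'
#' @param raw Character vector of raw genus names.
#' @param synonym_map Named character vector, raw -> canonical.
#' @return Character vector of canonical genus names.
#' @examples
#' normalize_genus(c(" triticum ", "ZEA", "Triticosecale"))
#' @export
normalize_genus <- function(raw, synonym_map = default_synonym_map()) {
  x <- trimws(as.character(raw))
  if (any(is.na(x) | x == "")) {
    abort_value("normalize_genus: empty genus name")
  }
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  if (length(synonym_map)) {
    hit <- match(x, names(synonym_map))
    x[!is.na(hit)] <- unname(synonym_map[hit[!is.na(hit)]])
  }
  x
}

#' Classify the seed-storage behaviour of genera
#'
#' Assigns each genus the majority seed-storage class (orthodox,
#' intermediate, recalcitrant) over its species entries in a
#' species-behaviour reference table. Ties break pessimistically toward the
#' less storable class (recalcitrant over intermediate over orthodox), so a
#' genus is only treated as seed-bankable on positive evidence. A genus with
#' no entries is `"unknown"`.
#'
#' @param genus Character vector of canonical genus names.
#' @param species_behavior_table Tibble with columns `genus`,
#'   `species_epithet`, `behavior` (values among recalcitrant, intermediate,
#'   orthodox). Defaults to the small synthetic demonstration table shipped
#'   with the package.
#' @return Character vector of behaviour labels, one per input genus.
#' @examples
#' classify_seed_behavior(c("Triticum", "Quercus", "Nosuchgenus"))
#' @export
classify_seed_behavior <- function(genus,
                                   species_behavior_table = default_seed_behavior_table()) {
  tab <- as_tibble(species_behavior_table)
  bad <- !tab$behavior %in% SEED_BEHAVIORS
  if (any(bad)) {
    abort_schema(paste0("Unknown seed behaviour label(s): ",
                        fmt_items(tab$behavior[bad])))
  }
  vapply(genus, function(g) {
    beh <- tab$behavior[tab$genus == g]
    if (!length(beh)) return("unknown")
    counts <- table(factor(beh, levels = SEED_BEHAVIORS))
    # which.max on the recalcitrant-first level order is the pessimistic
    # tie-break
    SEED_BEHAVIORS[which.max(counts)]
  }, character(1), USE.NAMES = FALSE)
}

#' Shipped species seed-behaviour demonstration table
#'
#' A small synthetic reference (not a copy of any curated database) used in
#' examples and tests; real analyses should supply a table derived from a
#' seed-information resource such as Kew's SID.
#'
#' @return Tibble with columns `genus`, `species_epithet`, `behavior`.
#' @export
default_seed_behavior_table <- function() {
  vg_read_csv(vg_extdata("seed_behavior_synthetic.csv"), col_types = "ccc")
}

#' Default crop-group scheme
#'
#' Genus to crop-group mapping following the FAO State of the World style
#' groups (Cereals, Food Legumes, Forage Crops, Roots and Tubers,
#' Vegetables, Oil Crops, ...). Unmapped genera fall into `"Other"`.
#'
#' @return Tibble with columns `genus`, `crop_group`.
#' @export
default_crop_groups <- function() {
  vg_read_csv(vg_extdata("crop_groups.csv"), col_types = "cc")
}

#' Assign genera to crop groups
#'
#' @param genus Character vector of canonical genus names.
#' @param scheme Tibble with columns `genus`, `crop_group`.
#' @return Character vector of group labels (`"Other"` when unmapped).
#' @examples
#' assign_crop_group(c("Triticum", "Phaseolus", "Xyzus"))
#' @export
assign_crop_group <- function(genus, scheme = default_crop_groups()) {
  idx <- match(genus, scheme$genus)
  out <- scheme$crop_group[idx]
  out[is.na(idx)] <- "Other"
  out
}

#' Default non-PGRFA genus exclusion list
#'
#' Genera held in genebank registries that are not plant genetic resources
#' for food and agriculture (model and forestry/ornamental taxa) and are
#' dropped from study-genus selection.
#'
#' @return Character vector of genus names.
#' @export
default_non_pgrfa <- function() {
  c("Arabidopsis", "Picea", "Pinus", "Populus", "Pseudotsuga", "Rhododendron")
}

#' Study-genus selection parameters
#'
#' @param min_accessions Global holdings threshold; a genus is retained only
#'   when its total accessions are strictly greater than this (default 1000,
#'   i.e. "more than 1000 accessions").
#' @param non_pgrfa_exclusions Genera excluded as not being PGRFA.
#' @param require_sgsv_presence Keep only genera with at least one deposited
#'   sample in the vault. This is a study-design proxy (the current vault
#'   collection is taken as representative of what is seed-bankable), not a
#'   biological rule, hence a flag.
#' @return A `selection_params` list.
#' @export
selection_params <- function(min_accessions = 1000,
                             non_pgrfa_exclusions = default_non_pgrfa(),
                             require_sgsv_presence = TRUE) {
  stopifnot(min_accessions >= 0)
  structure(
    list(min_accessions = as.integer(min_accessions),
         non_pgrfa_exclusions = non_pgrfa_exclusions,
         require_sgsv_presence = isTRUE(require_sgsv_presence)),
    class = "selection_params"
  )
}

#' Select study genera with an audited filter cascade
#'
#' Applies the fixed cascade: (1) name cleanup and synonym merging,
#' (2) removal of non-PGRFA genera, (3) global holdings threshold
#' (strictly more than `min_accessions` accessions summed over all
#' institutions), (4) optionally, presence in the safety-vault deposits.
#' Every removal is recorded with its stage, and the audit counts are
#' non-increasing through the cascade.
#'
#' @param holdings Holdings-summary tibble (`institute_code`, `genus`,
#'   `n_total`, ...). Genus names may be raw; they are normalized first.
#' @param deposits Deposit tibble (`depositor_code`, `genus`,
#'   `n_deposited`); only consulted when `require_sgsv_presence` is set.
#' @param params A [selection_params()] object.
#' @param synonym_map Passed to [normalize_genus()].
#' @return A `genus_selection` object: list with `genera` (retained
#'   canonical names, sorted), `audit` (stage counts tibble) and `removed`
#'   (tibble of genus/stage). Has [tidy()] and [glance()] methods.
#' @examples
#' inputs <- fixture_selection_inputs()
#' sel <- select_study_genera(inputs$holdings, inputs$deposits)
#' glance(sel)
#' @export
select_study_genera <- function(holdings, deposits = NULL,
                                params = selection_params(),
                                synonym_map = default_synonym_map()) {
  holdings <- as_tibble(holdings)
  raw_genera <- unique(holdings$genus)
  n_raw <- length(raw_genera)

  per_raw <- holdings |>
    group_by(genus) |>
    summarise(n_total = sum(.data$n_total), .groups = "drop")
  per_genus <- per_raw |>
    mutate(genus = normalize_genus(.data$genus, synonym_map)) |>
    group_by(genus) |>
    summarise(n_total = sum(.data$n_total), .groups = "drop")
  after_cleanup <- per_genus$genus
  n_cleanup <- length(after_cleanup)

  keep_pgrfa <- setdiff(after_cleanup, params$non_pgrfa_exclusions)
  removed_pgrfa <- setdiff(after_cleanup, keep_pgrfa)

  over <- per_genus$genus[per_genus$n_total > params$min_accessions]
  keep_threshold <- intersect(keep_pgrfa, over)
  removed_threshold <- setdiff(keep_pgrfa, keep_threshold)

  if (params$require_sgsv_presence) {
    deposits <- as_tibble(deposits %||% empty_deposits())
    in_vault <- deposits |>
      mutate(genus = normalize_genus(.data$genus, synonym_map)) |>
      filter(.data$n_deposited > 0) |>
      pull(.data$genus) |>
      unique()
    keep_sgsv <- intersect(keep_threshold, in_vault)
  } else {
    keep_sgsv <- keep_threshold
  }
  removed_sgsv <- setdiff(keep_threshold, keep_sgsv)

  removed <- bind_rows(
    tibble(genus = removed_pgrfa, stage = "non_pgrfa_filter"),
    tibble(genus = removed_threshold, stage = "holdings_threshold"),
    tibble(genus = removed_sgsv, stage = "sgsv_presence_filter")
  )
  audit <- tibble(
    stage = c("raw", "name_cleanup", "non_pgrfa_filter", "holdings_threshold",
              "sgsv_presence_filter"),
    n_retained = c(n_raw, n_cleanup, length(keep_pgrfa), length(keep_threshold),
                   length(keep_sgsv))
  )
  structure(
    list(genera = sort(keep_sgsv), audit = audit, removed = removed,
         params = params),
    class = "genus_selection"
  )
}

#' @export
print.genus_selection <- function(x, ...) {
  cat("<genus_selection>\n")
  for (i in seq_len(nrow(x$audit))) {
    cat(sprintf("  %-22s %d genera\n", x$audit$stage[i], x$audit$n_retained[i]))
  }
  invisible(x)
}

#' @rdname select_study_genera
#' @param x A `genus_selection` object.
#' @param ... Unused.
#' @export
tidy.genus_selection <- function(x, ...) {
  bind_rows(
    tibble(genus = x$genera, stage = "retained"),
    x$removed
  ) |> arrange(.data$genus)
}

#' @rdname select_study_genera
#' @export
glance.genus_selection <- function(x, ...) {
  a <- setNames(as.list(x$audit$n_retained), paste0("n_", x$audit$stage))
  as_tibble(a)
}
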