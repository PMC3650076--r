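# coverage: per-genus benchmark rows, crop-group aggregation, backup-share
# percentages, and top-N institutional profiles.

#' Reporting options
#'
#' @param top_n How many largest institutional collections to profile per
#'   genus (default 10).
#' @return A `reporting_options` list. Percentages are rounded half away
#'   from zero to integers and profile averages to one decimal, matching
#'   the conventions of published benchmark tables.
#' @export
reporting_options <- function(top_n = 10) {
  stopifnot(top_n >= 1)
  structure(list(top_n = as.integer(top_n)), class = "reporting_options")
}

#' Backup share as an integer percentage
#'
#' `round(100 * numerator / denominator)` with halves away from zero. A
#' zero denominator yields `NA` (rendered `"na"` by the table writers).
#' Values above 100 are reported as-is: a vault can hold more samples of a
#' genus than a comparison database records accessions.
#'
#' @param numerator,denominator Nonnegative counts (vectorized).
#' @return Integer vector of percentages (`NA` where the denominator is 0).
#' @examples
#' backup_share(145698, 270237)  # 54
#' backup_share(21455, 2833)     # 757
#' @export
backup_share <- function(numerator, denominator) {
  n <- max(length(numerator), length(denominator))
  num <- rep_len(as.numeric(numerator), n)
  den <- rep_len(as.numeric(denominator), n)
  if (any(den < 0, na.rm = TRUE)) abort_value("backup_share: negative denominator")
  out <- rep(NA_integer_, n)
  ok <- !is.na(den) & den > 0 & !is.na(num)
  out[ok] <- as.integer(round_half_up(100 * num[ok] / den[ok]))
  out
}

#' Build per-genus coverage benchmark rows
#'
#' Assembles one row per genus with the five benchmark counts: total
#' holdings from the institution-level summary (`wiews_total`), total
#' accession-level records from an accession database world
#' (`genesys_total`), the distinct-accession estimate, Treaty coverage, and
#' vault deposits (`sgsv`). Rows are ordered by crop group and descending
#' `wiews_total` within group.
#'
#' @param world A `vaultgap_world` holding the institution-level summary,
#'   registry and deposits.
#' @param genus_set Canonical genus names to report.
#' @param distinct_estimates Optional precomputed [estimate_distinct()]
#'   tibble; computed from `world` when `NULL`.
#' @param treaty_coverages Optional precomputed [treaty_coverage()] tibble;
#'   requires `ctx` when `NULL` (left `NA` if neither is given).
#' @param genesys_world Optional second `vaultgap_world` (or accession
#'   tibble) representing the accession-level database; defaults to the
#'   accessions of `world`.
#' @param scheme Crop-group scheme tibble.
#' @param ctx Optional [treaty_context()] used when `treaty_coverages` is
#'   `NULL`.
#' @return Tibble with columns `genus`, `crop_group`, `wiews_total`,
#'   `genesys_total`, `distinct`, `treaty`, `sgsv`.
#' @export
build_coverage_rows <- function(world, genus_set,
                                distinct_estimates = NULL,
                                treaty_coverages = NULL,
                                genesys_world = NULL,
                                scheme = default_crop_groups(),
                                ctx = NULL) {
  stopifnot(inherits(world, "vaultgap_world"))
  genus_set <- unique(genus_set)
  if (!length(genus_set)) {
    return(tibble(genus = character(), crop_group = character(),
                  wiews_total = integer(), genesys_total = integer(),
                  distinct = integer(), treaty = integer(), sgsv = integer()))
  }

  wiews <- world$holdings |>
    filter(.data$genus %in% genus_set) |>
    group_by(.data$genus) |>
    summarise(wiews_total = sum(.data$n_total), .groups = "drop")

  gen_acc <- if (is.null(genesys_world)) world$accessions
             else if (inherits(genesys_world, "vaultgap_world")) genesys_world$accessions
             else as_tibble(genesys_world)
  genesys <- gen_acc |>
    filter(.data$genus %in% genus_set) |>
    count(.data$genus, name = "genesys_total")

  if (is.null(distinct_estimates)) {
    distinct_estimates <- estimate_distinct(world, genus_set)
  }
  if (is.null(treaty_coverages) && !is.null(ctx)) {
    treaty_coverages <- treaty_coverage(world, genus_set, ctx)
  }

  sgsv <- world$deposits |>
    filter(.data$genus %in% genus_set) |>
    group_by(.data$genus) |>
    summarise(sgsv = sum(.data$n_deposited), .groups = "drop")

  out <- tibble(genus = genus_set) |>
    mutate(crop_group = assign_crop_group(.data$genus, scheme)) |>
    left_join(wiews, by = "genus") |>
    left_join(genesys, by = "genus") |>
    left_join(select(distinct_estimates, "genus", distinct = "n_distinct"),
              by = "genus")
  if (!is.null(treaty_coverages)) {
    out <- left_join(out,
                     select(treaty_coverages, "genus", treaty = "n_covered"),
                     by = "genus")
  } else {
    out$treaty <- NA_integer_
  }
  out |>
    left_join(sgsv, by = "genus") |>
    mutate(across(c("wiews_total", "genesys_total", "distinct", "sgsv"),
                  \(x) as.integer(coalesce(x, 0L)))) |>
    arrange(.data$crop_group, desc(.data$wiews_total), .data$genus)
}

#' Aggregate coverage rows into crop-group totals
#'
#' Each group row is the exact column sum of its member rows; a grand-total
#' row (`crop_group = "Total"`) is appended. Column-sum conservation holds
#' under any grouping scheme: per-column group sums equal the ungrouped
#' totals.
#'
#' @param rows Tibble from [build_coverage_rows()] (or any tibble with a
#'   `crop_group` column and numeric benchmark columns).
#' @return Tibble with one row per crop group plus the total row.
#' @export
aggregate_groups <- function(rows) {
  num_cols <- intersect(c("wiews_total", "genesys_total", "distinct",
                          "treaty", "sgsv"), names(rows))
  groups <- rows |>
    group_by(.data$crop_group) |>
    summarise(n_genera = n(),
              across(all_of(num_cols), \(x) sum(x, na.rm = FALSE)),
              .groups = "drop") |>
    arrange(.data$crop_group)
  total <- rows |>
    summarise(crop_group = "Total", n_genera = n(),
              across(all_of(num_cols), \(x) sum(x, na.rm = FALSE)))
  bind_rows(groups, total)
}

#' Rank the largest institutional collections of a genus
#'
#' Descending by holdings count; ties broken ascending by institute code so
#' the ranking is total and reproducible; truncated at `top_n`.
#'
#' @param holdings Holdings-summary tibble.
#' @param genus Canonical genus name (single).
#' @param opts A [reporting_options()].
#' @return Tibble `institute_code`, `holdings_count`, `rank`.
#' @export
rank_holders <- function(holdings, genus, opts = reporting_options()) {
  stopifnot(length(genus) == 1)
  as_tibble(holdings) |>
    filter(.data$genus == !!genus) |>
    group_by(.data$institute_code) |>
    summarise(holdings_count = sum(.data$n_total), .groups = "drop") |>
    arrange(desc(.data$holdings_count), .data$institute_code) |>
    slice_head(n = opts$top_n) |>
    mutate(rank = row_number()) |>
    select("rank", "institute_code", "holdings_count")
}

#' Profile the vault backup status of a genus's largest collections
#'
#' For the `top_n` largest institutional collections of a genus: how many
#' samples each has deposited in the vault, the backup share percentage,
#' and two summary counts — collections with at least one deposited sample
#' (`n_in_sgsv`) and collections operating under deposit-agreement
#' conditions (`n_under_sda`: the institute either has a signed agreement
#' or has deposited; a deposit implies an agreement, the converse is not
#' assumed).
#'
#' @param world A `vaultgap_world`.
#' @param genus Canonical genus name (single).
#' @param opts A [reporting_options()].
#' @return A `genus_profile` object: list with `genus`, `entries` (ranked
#'   tibble) and the two counts. Has [tidy()] and [glance()] methods.
#' @export
profile_genus <- function(world, genus, opts = reporting_options()) {
  stopifnot(inherits(world, "vaultgap_world"), length(genus) == 1)
  dep <- world$deposits |>
    filter(.data$genus == !!genus) |>
    group_by(institute_code = .data$depositor_code) |>
    summarise(deposited_count = sum(.data$n_deposited), .groups = "drop")
  entries <- rank_holders(world$holdings, genus, opts) |>
    left_join(dep, by = "institute_code") |>
    left_join(select(world$registry, "institute_code", "country", "sda_signed"),
              by = "institute_code") |>
    mutate(
      deposited_count = as.integer(coalesce(.data$deposited_count, 0L)),
      backup_share_pct = backup_share(.data$deposited_count, .data$holdings_count),
      in_sgsv = .data$deposited_count > 0,
      under_sda = coalesce(.data$sda_signed, FALSE) | .data$in_sgsv
    ) |>
    select("rank", "institute_code", "country", "holdings_count",
           "deposited_count", "backup_share_pct", "in_sgsv", "under_sda")
  structure(
    list(genus = genus, entries = entries,
         n_in_sgsv = sum(entries$in_sgsv),
         n_under_sda = sum(entries$under_sda)),
    class = "genus_profile"
  )
}

#' @export
print.genus_profile <- function(x, ...) {
  cat(sprintf("<genus_profile> %s: %d of %d largest collections in vault, %d under agreement\n",
              x$genus, x$n_in_sgsv, nrow(x$entries), x$n_under_sda))
  print(x$entries)
  invisible(x)
}

#' @rdname profile_genus
#' @param x A `genus_profile`.
#' @param ... Unused.
#' @export
tidy.genus_profile <- function(x, ...) {
  mutate(x$entries, genus = x$genus, .before = 1)
}

#' @rdname profile_genus
#' @export
glance.genus_profile <- function(x, ...) {
  tibble(genus = x$genus, n_entries = nrow(x$entries),
         n_in_sgsv = x$n_in_sgsv, n_under_sda = x$n_under_sda)
}

#' Average backup counts over genus profiles
#'
#' Arithmetic means of the per-genus counts of vault-represented and
#' agreement-covered collections, rounded half away from zero to one
#' decimal.
#'
#' @param summaries A list of `genus_profile` objects, or a tibble with
#'   columns `n_in_sgsv` and `n_under_sda`.
#' @return One-row tibble `n_genera`, `avg_in_sgsv`, `avg_under_sda`.
#' @examples
#' summarize_profiles(fixture_table2()$counts)
#' @export
summarize_profiles <- function(summaries) {
  if (inherits(summaries, "genus_profile")) summaries <- list(summaries)
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- purrr::map_dfr(summaries, glance)
  }
  summaries <- as_tibble(summaries)
  if (!nrow(summaries)) abort_value("summarize_profiles: empty profile list")
  require_columns(summaries, c("n_in_sgsv", "n_under_sda"), "profile summary")
  tibble(
    n_genera = nrow(summaries),
    avg_in_sgsv = round_half_up(mean(summaries$n_in_sgsv), 1),
    avg_under_sda = round_half_up(mean(summaries$n_under_sda), 1)
  )
}
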