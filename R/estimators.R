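# estimators: SoW2-style distinct-accession counting and ITPGRFA coverage
# (Annex 1 holdings in Contracting Parties + Article 15 collections,
# without double counting).

#' Read an Annex 1 crop rule table
#'
#' Each row is one crop of the Treaty's Annex 1: the genera it covers and,
#' where the Annex itself restricts at species level, the epithets
#' explicitly included (single-species crops such as cassava) or excluded
#' (e.g. wild relatives carved out of maize). Lists are semicolon-separated
#' in the file and parsed into list-columns.
#'
#' @param path CSV with columns `crop_label`, `genera`, `included_species`,
#'   `excluded_species`.
#' @return Tibble with list-columns `genera`, `included_species`,
#'   `excluded_species`.
#' @export
read_annex1_rules <- function(path) {
  df <- vg_read_csv(path, col_types = "cccc")
  split_list <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) character(0)
      else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  out <- tibble(
    crop_label = df$crop_label,
    genera = split_list(df$genera),
    included_species = split_list(df$included_species),
    excluded_species = split_list(df$excluded_species)
  )
  bad <- vapply(out$genera, length, integer(1)) == 0
  if (any(bad)) {
    abort_schema(paste0("Annex 1 rule(s) with empty genus list: ",
                        fmt_items(out$crop_label[bad])))
  }
  overlap <- mapply(function(i, e) length(intersect(i, e)) > 0,
                    out$included_species, out$excluded_species)
  if (any(overlap)) {
    abort_schema(paste0("Annex 1 rule(s) with overlapping include/exclude lists: ",
                        fmt_items(out$crop_label[overlap])))
  }
  out
}

#' Default curated Annex 1 rule set
#'
#' Shipped genus-level rules with species include/exclude restrictions for
#' the crops where Annex 1 itself restricts. The set is curated so that the
#' genera footnoted as outside Annex 1 in the benchmark tables have no rule.
#' It is an editable configuration, not an authoritative legal text.
#'
#' @return Tibble as returned by [read_annex1_rules()].
#' @export
default_annex1_rules <- function() {
  if (is.null(the$annex1_rules)) {
    the$annex1_rules <- read_annex1_rules(vg_extdata("annex1_rules.csv"))
  }
  the$annex1_rules
}

#' Treaty context: who is in the Multilateral System
#'
#' @param contracting_parties Character vector of ISO alpha-3 codes of
#'   countries that are Contracting Parties to the Treaty.
#' @param article15_institutes Character vector of institute codes whose
#'   collections are in the Multilateral System under Article 15.
#' @param rules Annex 1 rule tibble ([default_annex1_rules()]).
#' @return A `treaty_context` list.
#' @export
treaty_context <- function(contracting_parties = character(),
                           article15_institutes = character(),
                           rules = default_annex1_rules()) {
  structure(
    list(contracting_parties = unique(toupper(contracting_parties)),
         article15_institutes = unique(article15_institutes),
         rules = rules),
    class = "treaty_context"
  )
}

#' Derive a treaty context from a world's registry flags
#'
#' Article 15 institutes are those flagged `article15` in the registry;
#' Contracting Parties must still be supplied (membership is a property of
#' countries, not of the collection data).
#'
#' @param world A `vaultgap_world`.
#' @inheritParams treaty_context
#' @return A `treaty_context`.
#' @export
treaty_context_from_world <- function(world, contracting_parties,
                                      rules = default_annex1_rules()) {
  treaty_context(
    contracting_parties = contracting_parties,
    article15_institutes =
      world$registry$institute_code[which(world$registry$article15)],
    rules = rules
  )
}

#' Does a (genus, species) pair fall under Annex 1?
#'
#' True iff some rule lists the genus, the epithet is in the rule's included
#' list (when the rule has one), and the epithet is not in its excluded
#' list. An empty epithet matches only rules without an included-species
#' restriction and is never blocked by an excluded list: at genus-level
#' resolution, exclusion of specific species cannot be established.
#'
#' @param genus Character vector of canonical genus names.
#' @param species_epithet Character vector (recycled) of epithets; `""` or
#'   `NA` for genus-only records.
#' @param rules Annex 1 rule tibble.
#' @return Logical vector.
#' @examples
#' match_annex1("Zea", c("mays", "perennis", ""))
#' match_annex1("Amaranthus", "caudatus")  # not an Annex 1 crop
#' @export
match_annex1 <- function(genus, species_epithet = "",
                         rules = default_annex1_rules()) {
  n <- max(length(genus), length(species_epithet))
  genus <- rep_len(genus, n)
  sp <- rep_len(coalesce(as.character(species_epithet), ""), n)
  sp <- trimws(sp)
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(rules))) {
    g <- rules$genera[[i]]
    inc <- rules$included_species[[i]]
    exc <- rules$excluded_species[[i]]
    hit <- genus %in% g
    if (length(inc)) {
      hit <- hit & sp %in% inc
    }
    if (length(exc)) {
      hit <- hit & !(nzchar(sp) & sp %in% exc)
    }
    out <- out | hit
  }
  out
}

iarc_codes <- function(registry) {
  registry$institute_code[registry$inst_type == "international_IARC"]
}

# Split per-(institute, genus) data into the accession path (institutes
# reporting accession-level records for that genus) and the summary path
# (holdings rows with no accession-level backing). The accession path wins
# when both exist.
split_paths <- function(world, genera) {
  acc <- world$accessions |> filter(.data$genus %in% genera)
  acc_pairs <- acc |> distinct(.data$institute_code, .data$genus)
  hold <- world$holdings |>
    filter(.data$genus %in% genera) |>
    anti_join(acc_pairs, by = c("institute_code", "genus"))
  list(accessions = acc, summary = hold)
}

#' Estimate distinct accessions per genus (SoW2 counting rule)
#'
#' Implements the FAO State of the World counting method for distinct
#' accessions: the sum of (a) accessions in national (non-IARC) collections
#' whose reported origin country equals the country of the holding genebank
#' ("indigenous" accessions), and (b) all accessions held in trust by
#' International Agricultural Research Centers, regardless of origin.
#'
#' For component (a), accession-level passport data are used where an
#' institute reports them for the genus; otherwise the institute's
#' `n_indigenous` holdings summary is used (the accession path is
#' preferred, and when both exist the summary is cross-checked with a
#' warning on disagreement). An `UNKNOWN` origin never counts as indigenous
#' under the default policy.
#'
#' @param world A `vaultgap_world`.
#' @param genera Canonical genus names; default all genera present in the
#'   world. A genus absent from the world yields a zero-count row (and a
#'   message), not an error.
#' @param unknown_origin_policy How records with `UNKNOWN` origin enter
#'   component (a): `"non_indigenous"` (default, conservative), never
#'   indigenous; `"indigenous"`, counted as indigenous (upper bound);
#'   `"drop"`, removed from all counting including the IARC component.
#' @param check_summary Cross-check accession-path counts against holdings
#'   rows where both exist and warn on disagreement.
#' @return Tibble with one row per genus: `genus`,
#'   `n_indigenous_national`, `n_iarc`, `n_distinct` (their sum).
#' @export
estimate_distinct <- function(world, genera = NULL,
                              unknown_origin_policy = c("non_indigenous",
                                                        "indigenous", "drop"),
                              check_summary = TRUE) {
  stopifnot(inherits(world, "vaultgap_world"))
  policy <- match.arg(unknown_origin_policy)
  all_genera <- unique(c(world$accessions$genus, world$holdings$genus))
  if (is.null(genera)) genera <- sort(all_genera)
  missing <- setdiff(genera, all_genera)
  if (length(missing)) {
    inform(paste0("Genera absent from world, reported as zero: ",
                  fmt_items(missing)))
  }

  iarcs <- iarc_codes(world$registry)
  paths <- split_paths(world, genera)
  acc <- paths$accessions |>
    left_join(select(world$registry, "institute_code", "country"),
              by = "institute_code")

  if (check_summary) check_path_agreement(world, acc)

  if (policy == "drop") {
    acc <- acc |> filter(.data$origin_country != UNKNOWN_COUNTRY)
  }
  acc <- acc |>
    mutate(
      is_iarc = .data$institute_code %in% iarcs,
      indigenous = if (policy == "indigenous") {
        .data$origin_country == .data$country |
          .data$origin_country == UNKNOWN_COUNTRY
      } else {
        .data$origin_country == .data$country
      }
    )

  acc_part <- acc |>
    group_by(.data$genus) |>
    summarise(
      a_acc = sum(.data$indigenous & !.data$is_iarc),
      b_acc = sum(.data$is_iarc),
      .groups = "drop"
    )
  sum_part <- paths$summary |>
    mutate(is_iarc = .data$institute_code %in% iarcs) |>
    group_by(.data$genus) |>
    summarise(
      a_sum = sum(coalesce(.data$n_indigenous[!.data$is_iarc], 0L)),
      b_sum = sum(.data$n_total[.data$is_iarc]),
      .groups = "drop"
    )

  tibble(genus = genera) |>
    left_join(acc_part, by = "genus") |>
    left_join(sum_part, by = "genus") |>
    mutate(
      n_indigenous_national =
        as.integer(coalesce(.data$a_acc, 0L) + coalesce(.data$a_sum, 0L)),
      n_iarc = as.integer(coalesce(.data$b_acc, 0L) + coalesce(.data$b_sum, 0L)),
      n_distinct = .data$n_indigenous_national + .data$n_iarc
    ) |>
    select("genus", "n_indigenous_national", "n_iarc", "n_distinct")
}

# warn when an institute reports both accession-level and summary data for a
# genus and the two disagree
check_path_agreement <- function(world, acc_with_country) {
  both <- acc_with_country |>
    group_by(.data$institute_code, .data$genus) |>
    summarise(
      acc_total = n(),
      acc_indig = sum(.data$origin_country == .data$country),
      .groups = "drop"
    ) |>
    dplyr::inner_join(world$holdings, by = c("institute_code", "genus"))
  off <- both |>
    filter(.data$acc_total != .data$n_total |
             (!is.na(.data$n_indigenous) & .data$acc_indig != .data$n_indigenous))
  if (nrow(off)) {
    warn(paste0("Accession-level and summary counts disagree for ",
                nrow(off), " (institute, genus) pair(s), e.g. ",
                fmt_items(paste0(off$institute_code, ":", off$genus), 5),
                "; the accession path is used."))
  }
  invisible(off)
}

#' Count accessions covered by the ITPGRFA Multilateral System
#'
#' Two additive components per genus, with no double counting: (1) Annex 1
#' matching accessions (species-level rules via [match_annex1()]) held by
#' institutes located in Contracting-Party countries, *excluding* Article 15
#' institutes; (2) all accessions of the genus held by Article 15
#' institutes, with no species filter. Every institute contributes to at
#' most one component (Article 15 institutes only to component 2), which is
#' recorded in the `attribution` attribute of the result.
#'
#' Institutes with no accession-level records for a genus enter through the
#' holdings summary: for component 1 only when the genus matches a rule with
#' no species restriction (a species filter cannot be applied to a summary
#' row), and for component 2 with their full `n_total`.
#'
#' @param world A `vaultgap_world`.
#' @param genera Canonical genus names; default all in the world.
#' @param ctx A [treaty_context()].
#' @return Tibble with one row per genus: `genus`, `n_annex1_in_cp`,
#'   `n_article15`, `n_covered` (their sum). Attribute `attribution` maps
#'   each contributing institute to its single component.
#' @export
treaty_coverage <- function(world, genera = NULL, ctx) {
  stopifnot(inherits(world, "vaultgap_world"), inherits(ctx, "treaty_context"))
  unresolved <- setdiff(ctx$article15_institutes, world$registry$institute_code)
  if (length(unresolved)) {
    abort_integrity(paste0("Article 15 institute(s) not in registry: ",
                           fmt_items(unresolved)))
  }
  all_genera <- unique(c(world$accessions$genus, world$holdings$genus))
  if (is.null(genera)) genera <- sort(all_genera)

  art15 <- ctx$article15_institutes
  paths <- split_paths(world, genera)
  acc <- paths$accessions |>
    left_join(select(world$registry, "institute_code", "country"),
              by = "institute_code") |>
    mutate(
      is_art15 = .data$institute_code %in% art15,
      in_cp = .data$country %in% ctx$contracting_parties,
      annex1 = match_annex1(.data$genus, .data$species_epithet, ctx$rules)
    )

  acc_part <- acc |>
    group_by(.data$genus) |>
    summarise(
      c1_acc = sum(!.data$is_art15 & .data$in_cp & .data$annex1),
      c2_acc = sum(.data$is_art15),
      .groups = "drop"
    )
  sum_part <- paths$summary |>
    left_join(select(world$registry, "institute_code", "country"),
              by = "institute_code") |>
    mutate(
      is_art15 = .data$institute_code %in% art15,
      in_cp = .data$country %in% ctx$contracting_parties,
      annex1_genus = match_annex1(.data$genus, "", ctx$rules)
    ) |>
    group_by(.data$genus) |>
    summarise(
      c1_sum = sum(.data$n_total[!.data$is_art15 & .data$in_cp & .data$annex1_genus]),
      c2_sum = sum(.data$n_total[.data$is_art15]),
      .groups = "drop"
    )

  out <- tibble(genus = genera) |>
    left_join(acc_part, by = "genus") |>
    left_join(sum_part, by = "genus") |>
    mutate(
      n_annex1_in_cp =
        as.integer(coalesce(.data$c1_acc, 0L) + coalesce(.data$c1_sum, 0L)),
      n_article15 =
        as.integer(coalesce(.data$c2_acc, 0L) + coalesce(.data$c2_sum, 0L)),
      n_covered = .data$n_annex1_in_cp + .data$n_article15
    ) |>
    select("genus", "n_annex1_in_cp", "n_article15", "n_covered")

  contributing <- unique(c(paths$accessions$institute_code,
                           paths$summary$institute_code))
  attribution <- tibble(
    institute_code = contributing,
    component = if_else(contributing %in% art15, "article15", "annex1_in_cp")
  )
  attr(out, "attribution") <- attribution
  out
}
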