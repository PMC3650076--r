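# World builders and independent brute-force oracles used across tests.
# The oracles are written in plain base R, straight from the definitions,
# and share no code with the package implementations they check.

make_registry <- function(codes, countries, types,
                          article15 = types == "international_IARC") {
  tibble::tibble(
    institute_code = codes, country = countries, inst_type = types,
    article15 = article15, sda_signed = FALSE, sgsv_depositor = FALSE
  )
}

# a small hand-specified world: two national banks (NOR, ETH), one IARC
tiny_world <- function() {
  acc <- tibble::tibble(
    institute_code = c(rep("NOR001", 5), rep("ETH001", 3), rep("IARC01", 4)),
    accession_id = sprintf("A%02d", 1:12),
    genus = c(rep("Hordeum", 8), rep("Hordeum", 2), rep("Eragrostis", 2)),
    species_epithet = "",
    origin_country = c("NOR", "NOR", "ETH", "UNKNOWN", "NOR",
                       "ETH", "ETH", "NOR",
                       "MEX", "PER", "ETH", "ETH")
  )
  reg <- make_registry(c("NOR001", "ETH001", "IARC01"),
                       c("NOR", "ETH", "PHL"),
                       c("national", "national", "international_IARC"))
  dep <- tibble::tibble(depositor_code = c("NOR001", "IARC01"),
                        genus = c("Hordeum", "Eragrostis"),
                        n_deposited = c(3L, 2L))
  assemble_world(accessions = acc, registry = reg, deposits = dep)
}

# brute-force SoW2 distinct count, straight from the two clauses
oracle_distinct <- function(world, genus) {
  acc <- as.data.frame(world$accessions)
  reg <- as.data.frame(world$registry)
  hold <- as.data.frame(world$holdings)
  n_a <- 0L
  n_b <- 0L
  for (i in seq_len(nrow(reg))) {
    inst <- reg$institute_code[i]
    is_iarc <- reg$inst_type[i] == "international_IARC"
    rows <- acc[acc$institute_code == inst & acc$genus == genus, , drop = FALSE]
    if (nrow(rows) > 0) {
      if (is_iarc) {
        n_b <- n_b + nrow(rows)
      } else {
        n_a <- n_a + sum(rows$origin_country == reg$country[i])
      }
    } else {
      hrows <- hold[hold$institute_code == inst & hold$genus == genus, , drop = FALSE]
      if (nrow(hrows) > 0) {
        if (is_iarc) {
          n_b <- n_b + sum(hrows$n_total)
        } else {
          n_a <- n_a + sum(ifelse(is.na(hrows$n_indigenous), 0L, hrows$n_indigenous))
        }
      }
    }
  }
  c(a = n_a, b = n_b, total = n_a + n_b)
}

# brute-force Treaty coverage from the two clauses (accession-level part)
oracle_treaty <- function(world, genus, ctx) {
  acc <- as.data.frame(world$accessions)
  reg <- as.data.frame(world$registry)
  hold <- as.data.frame(world$holdings)
  c1 <- 0L
  c2 <- 0L
  for (i in seq_len(nrow(reg))) {
    inst <- reg$institute_code[i]
    art15 <- inst %in% ctx$article15_institutes
    rows <- acc[acc$institute_code == inst & acc$genus == genus, , drop = FALSE]
    if (nrow(rows) > 0) {
      if (art15) {
        c2 <- c2 + nrow(rows)
      } else if (reg$country[i] %in% ctx$contracting_parties) {
        for (j in seq_len(nrow(rows))) {
          if (match_annex1(genus, rows$species_epithet[j], ctx$rules)) c1 <- c1 + 1L
        }
      }
    } else {
      hrows <- hold[hold$institute_code == inst & hold$genus == genus, , drop = FALSE]
      if (nrow(hrows) > 0) {
        if (art15) {
          c2 <- c2 + sum(hrows$n_total)
        } else if (reg$country[i] %in% ctx$contracting_parties &&
                   match_annex1(genus, "", ctx$rules)) {
          c1 <- c1 + sum(hrows$n_total)
        }
      }
    }
  }
  c(c1 = c1, c2 = c2, total = c1 + c2)
}

# small random world config for property tests (<= ~200 accessions)
small_config <- function(...) {
  world_config(
    genus_catalog = tibble::tibble(
      genus = c("Hordeum", "Eragrostis", "Vigna"),
      crop_group = c("Cereals", "Cereals", "Food Legumes"),
      seed_behavior = "orthodox",
      n_founders = c(40L, 25L, 15L)
    ),
    n_countries = 5, institutes_per_country = 2, n_iarcs = 2,
    ...
  )
}
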