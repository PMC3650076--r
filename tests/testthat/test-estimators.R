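# distinct-accession estimator and Treaty coverage

test_that("distinct estimate reproduces the hand-enumerated two-clause count", {
  # one national bank (NOR) with 3 indigenous + 2 foreign, one IARC with 5
  acc <- tibble::tibble(
    institute_code = c(rep("NOR001", 5), rep("IARC01", 5)),
    accession_id = sprintf("A%02d", 1:10),
    genus = "Hordeum", species_epithet = "",
    origin_country = c("NOR", "NOR", "NOR", "ETH", "ETH", rep("MEX", 5))
  )
  reg <- make_registry(c("NOR001", "IARC01"), c("NOR", "PHL"),
                       c("national", "international_IARC"))
  w <- assemble_world(accessions = acc, registry = reg)
  est <- estimate_distinct(w)
  expect_equal(est$n_indigenous_national, 3L)
  expect_equal(est$n_iarc, 5L)
  expect_equal(est$n_distinct, 8L)
})

test_that("clean-assumption identity: all-indigenous national holdings count fully", {
  acc <- tibble::tibble(
    institute_code = rep(c("KEN01", "ETH01"), each = 4),
    accession_id = sprintf("A%02d", 1:8),
    genus = "Eleusine", species_epithet = "",
    origin_country = rep(c("KEN", "ETH"), each = 4)
  )
  reg <- make_registry(c("KEN01", "ETH01"), c("KEN", "ETH"),
                       c("national", "national"))
  w <- assemble_world(accessions = acc, registry = reg)
  expect_equal(estimate_distinct(w)$n_distinct, 8L)
})

test_that("UNKNOWN origin follows the selected policy", {
  acc <- tibble::tibble(
    institute_code = "NOR001", accession_id = sprintf("A%d", 1:4),
    genus = "Avena", species_epithet = "",
    origin_country = c("NOR", "UNKNOWN", "UNKNOWN", "ETH")
  )
  reg <- make_registry("NOR001", "NOR", "national")
  w <- assemble_world(accessions = acc, registry = reg)
  expect_equal(estimate_distinct(w)$n_distinct, 1L)
  expect_equal(estimate_distinct(w, unknown_origin_policy = "indigenous")$n_distinct, 3L)
  expect_equal(estimate_distinct(w, unknown_origin_policy = "drop")$n_distinct, 1L)
})

test_that("summary path is used where accession-level data are absent", {
  hold <- tibble::tibble(
    institute_code = c("KEN01", "IARC01"),
    genus = "Sorghum",
    n_total = c(100L, 40L),
    n_indigenous = c(30L, NA)
  )
  reg <- make_registry(c("KEN01", "IARC01"), c("KEN", "IND"),
                       c("national", "international_IARC"))
  w <- assemble_world(holdings = hold, registry = reg)
  est <- estimate_distinct(w)
  expect_equal(est$n_indigenous_national, 30L)
  expect_equal(est$n_iarc, 40L)
})

test_that("accession path wins over a disagreeing summary, with a warning", {
  acc <- tibble::tibble(
    institute_code = "KEN01", accession_id = c("A1", "A2"),
    genus = "Sorghum", species_epithet = "",
    origin_country = c("KEN", "KEN")
  )
  hold <- tibble::tibble(institute_code = "KEN01", genus = "Sorghum",
                         n_total = 9L, n_indigenous = 1L)
  reg <- make_registry("KEN01", "KEN", "national")
  w <- assemble_world(accessions = acc, holdings = hold, registry = reg)
  expect_warning(est <- estimate_distinct(w), "disagree")
  expect_equal(est$n_distinct, 2L)
})

test_that("a genus absent from the world yields a zero row, not an error", {
  w <- tiny_world()
  expect_message(est <- estimate_distinct(w, c("Hordeum", "Ghostus")),
                 "Ghostus")
  expect_equal(est$n_distinct[est$genus == "Ghostus"], 0L)
})

test_that("distinct estimate equals the brute-force oracle on random small worlds", {
  for (seed in 1:100) {
    cfg <- small_config(
      p_cross_country_dup = (seed %% 4) / 6,
      p_iarc_dup = (seed %% 3) / 5,
      p_within_country_dup = (seed %% 5) / 8,
      p_missing_origin = (seed %% 7) / 10
    )
    sim <- generate_world(cfg, seed = seed)
    expect_lte(nrow(sim$world$accessions), 200 * 2) # small worlds by design
    est <- estimate_distinct(sim$world, check_summary = FALSE)
    for (g in est$genus) {
      expect_identical(unname(est$n_distinct[est$genus == g]),
                       unname(oracle_distinct(sim$world, g)[["total"]]),
                       info = sprintf("seed %d genus %s", seed, g))
    }
  }
})

test_that("adding a foreign accession to a national bank never changes the estimate; adding to an IARC adds one", {
  w <- tiny_world()
  base <- estimate_distinct(w, "Hordeum")$n_distinct
  grow <- function(world, inst, origin) {
    acc <- dplyr::bind_rows(world$accessions, tibble::tibble(
      institute_code = inst, accession_id = "NEW1", genus = "Hordeum",
      species_epithet = "", origin_country = origin))
    assemble_world(acc, world$holdings, world$registry, world$deposits)
  }
  w_foreign <- grow(w, "NOR001", "PER")
  expect_equal(estimate_distinct(w_foreign, "Hordeum")$n_distinct, base)
  w_iarc <- grow(w, "IARC01", "PER")
  expect_equal(estimate_distinct(w_iarc, "Hordeum")$n_distinct, base + 1L)
  w_iarc_unk <- grow(w, "IARC01", "UNKNOWN")
  expect_equal(estimate_distinct(w_iarc_unk, "Hordeum")$n_distinct, base + 1L)
})

test_that("Annex 1 matching honours genus lists, inclusions and exclusions", {
  rules <- tibble::tibble(
    crop_label = c("Maize", "Cassava"),
    genera = list("Zea", "Manihot"),
    included_species = list(character(0), "esculenta"),
    excluded_species = list("perennis", character(0))
  )
  expect_true(match_annex1("Zea", "mays", rules))
  expect_false(match_annex1("Zea", "perennis", rules))
  expect_true(match_annex1("Zea", "", rules))   # genus-only record passes
  expect_false(match_annex1("Manihot", "glaziovii", rules))
  expect_true(match_annex1("Manihot", "esculenta", rules))
  expect_false(match_annex1("Manihot", "", rules)) # inclusion-restricted
  expect_false(match_annex1("Amaranthus", "caudatus", rules))
})

test_that("footnoted non-Annex-1 genera have no rule in the default set", {
  t1 <- fixture_table1()
  outside <- t1$genus[!t1$annex1]
  expect_false(any(match_annex1(outside, "", default_annex1_rules())))
  inside <- t1$genus[t1$annex1]
  expect_true(all(vapply(inside, function(g) {
    rules <- default_annex1_rules()
    any(vapply(rules$genera, function(gl) g %in% gl, logical(1)))
  }, logical(1))))
})

test_that("Treaty coverage counts the two components without double counting", {
  # 12 accessions spanning both components
  acc <- tibble::tibble(
    institute_code = c(rep("NOR001", 4), rep("BRA001", 4), rep("IARC01", 4)),
    accession_id = sprintf("A%02d", 1:12),
    genus = "Zea",
    species_epithet = c("mays", "mays", "perennis", "", rep("mays", 8)),
    origin_country = "MEX"
  )
  reg <- make_registry(c("NOR001", "BRA001", "IARC01"),
                       c("NOR", "BRA", "MEX"),
                       c("national", "national", "international_IARC"))
  w <- assemble_world(accessions = acc, registry = reg)
  ctx <- treaty_context(contracting_parties = "NOR",
                        article15_institutes = "IARC01")
  tc <- treaty_coverage(w, "Zea", ctx)
  # NOR is a CP: 3 of its 4 records match (perennis excluded); BRA is not a
  # CP; the IARC contributes all 4 with no species filter
  expect_equal(tc$n_annex1_in_cp, 3L)
  expect_equal(tc$n_article15, 4L)
  expect_equal(tc$n_covered, 7L)
  expect_equal(unname(oracle_treaty(w, "Zea", ctx)[["total"]]), 7L)

  attribution <- attr(tc, "attribution")
  expect_equal(anyDuplicated(attribution$institute_code), 0L)
  expect_equal(attribution$component[attribution$institute_code == "IARC01"],
               "article15")
})

test_that("no contracting parties and no Article 15 institutes means zero coverage", {
  w <- tiny_world()
  ctx <- treaty_context()
  expect_equal(treaty_coverage(w, "Hordeum", ctx)$n_covered, 0L)
})

test_that("Treaty coverage equals the brute-force oracle on random worlds and never exceeds total holdings", {
  rules <- default_annex1_rules()
  for (seed in 1:25) {
    sim <- generate_world(small_config(p_iarc_dup = 0.4,
                                       p_cross_country_dup = 0.3), seed = seed)
    cp <- sim$truth$contracting_parties
    ctx <- treaty_context(contracting_parties = cp,
                          article15_institutes =
                            iarc <- sim$world$registry$institute_code[
                              sim$world$registry$article15],
                          rules = rules)
    tc <- treaty_coverage(sim$world, ctx = ctx)
    for (g in tc$genus) {
      expect_identical(unname(tc$n_covered[tc$genus == g]),
                       unname(oracle_treaty(sim$world, g, ctx)[["total"]]))
      total_g <- sum(sim$world$accessions$genus == g)
      expect_lte(tc$n_covered[tc$genus == g], total_g)
    }
  }
})
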