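# benchmark rows, group aggregation, shares, profiles

test_that("backup_share reproduces published percentage arithmetic", {
  expect_equal(backup_share(145698, 270237), 54L)
  expect_equal(backup_share(32822, 134185), 24L)
  expect_equal(backup_share(21455, 2833), 757L)  # >100% reported as-is
  expect_equal(backup_share(0, 5), 0L)
  expect_true(is.na(backup_share(3, 0)))
  expect_error(backup_share(1, -2), class = "vaultgap_value_error")
})

test_that("backup_share rounds halves away from zero and is scale-invariant", {
  expect_equal(backup_share(1, 8), 13L)    # 12.5 -> 13
  expect_equal(backup_share(3, 8), 38L)    # 37.5 -> 38
  for (k in c(2, 7, 100)) {
    expect_equal(backup_share(145698 * k, 270237 * k), 54L)
    expect_equal(backup_share(3 * k, 8 * k), 38L)
  }
})

test_that("round_half_up differs from banker's rounding exactly on halves", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -1.5)), c(1, 2, 3, -1, -2))
  expect_equal(round_half_up(3.75, 1), 3.8)
  expect_equal(round_half_up(5.4827586, 1), 5.5)
})

test_that("coverage rows assemble the five benchmarks and sort within groups", {
  w <- tiny_world()
  rows <- build_coverage_rows(w, c("Hordeum", "Eragrostis"))
  expect_named(rows, c("genus", "crop_group", "wiews_total", "genesys_total",
                       "distinct", "treaty", "sgsv"))
  # tiny_world has no holdings summary, so wiews_total is 0; genesys counts
  # accession records; sgsv sums deposits
  h <- rows[rows$genus == "Hordeum", ]
  expect_equal(h$genesys_total, 10L)
  expect_equal(h$distinct, 7L)
  expect_equal(h$sgsv, 3L)
  expect_equal(rows$crop_group, c("Cereals", "Cereals"))
  expect_true(is.na(h$treaty)) # no treaty context supplied

  expect_equal(nrow(build_coverage_rows(w, character())), 0L)
})

test_that("row ordering is stable: by group, then descending holdings", {
  hold <- tibble::tibble(
    institute_code = "I1",
    genus = c("Zea", "Triticum", "Phaseolus"),
    n_total = c(50L, 80L, 70L), n_indigenous = NA_integer_
  )
  reg <- make_registry("I1", "KEN", "national")
  w <- assemble_world(holdings = hold, registry = reg)
  rows <- suppressMessages(build_coverage_rows(w, c("Zea", "Triticum", "Phaseolus")))
  expect_equal(rows$genus, c("Triticum", "Zea", "Phaseolus"))
})

test_that("group aggregation conserves column sums under random partitions", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    rows <- tibble::tibble(
      genus = sprintf("G%02d", seq_len(n)),
      crop_group = sample(LETTERS[1:4], n, replace = TRUE),
      wiews_total = sample.int(1e5, n),
      genesys_total = sample.int(1e4, n),
      distinct = sample.int(1e4, n),
      treaty = sample.int(1e4, n),
      sgsv = sample.int(1e3, n)
    )
    agg <- aggregate_groups(rows)
    total <- agg[agg$crop_group == "Total", ]
    for (col in c("wiews_total", "genesys_total", "distinct", "treaty", "sgsv")) {
      expect_equal(sum(agg[[col]][agg$crop_group != "Total"]), sum(rows[[col]]))
      expect_equal(total[[col]], sum(rows[[col]]))
    }
  }
})

test_that("a single-genus group row equals the genus row", {
  rows <- tibble::tibble(genus = "Zea", crop_group = "Cereals",
                         wiews_total = 10L, genesys_total = 5L,
                         distinct = 4L, treaty = 3L, sgsv = 2L)
  agg <- aggregate_groups(rows)
  expect_equal(agg$wiews_total, c(10L, 10L))
  expect_equal(agg$sgsv, c(2L, 2L))
})

test_that("holder ranking sorts by count then code and truncates", {
  hold <- tibble::tibble(
    institute_code = c("C", "A", "B", "D"),
    genus = "Zea",
    n_total = c(10L, 20L, 20L, 5L),
    n_indigenous = NA_integer_
  )
  r <- rank_holders(hold, "Zea")
  expect_equal(r$institute_code, c("A", "B", "C", "D")) # tie broken by code
  expect_equal(r$holdings_count, c(20L, 20L, 10L, 5L))

  r2 <- rank_holders(hold, "Zea", reporting_options(top_n = 2))
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$institute_code, c("A", "B"))

  # agreement with a full-sort oracle on a synthetic world
  sim <- generate_world(small_config(p_within_country_dup = 0.5), seed = 3)
  hh <- sim$world$holdings
  got <- rank_holders(hh, "Hordeum", reporting_options(top_n = 1000))
  agg <- aggregate(n_total ~ institute_code, data = hh[hh$genus == "Hordeum", ], sum)
  ord <- agg[order(-agg$n_total, agg$institute_code), ]
  expect_equal(got$institute_code, ord$institute_code)
  expect_equal(got$holdings_count, ord$n_total)
})

test_that("genus profiles count vault presence and agreement coverage", {
  hold <- tibble::tibble(
    institute_code = c("A", "B", "C"), genus = "Zea",
    n_total = c(100L, 80L, 60L), n_indigenous = NA_integer_
  )
  reg <- make_registry(c("A", "B", "C"), c("KEN", "ETH", "NOR"),
                       rep("national", 3))
  reg$sda_signed <- c(FALSE, TRUE, FALSE)
  dep <- tibble::tibble(depositor_code = "A", genus = "Zea", n_deposited = 25L)
  w <- assemble_world(holdings = hold, registry = reg, deposits = dep)
  p <- profile_genus(w, "Zea")
  expect_equal(p$n_in_sgsv, 1L)        # only A deposited
  expect_equal(p$n_under_sda, 2L)      # A (deposit implies agreement) + B (flag)
  expect_equal(p$entries$backup_share_pct, c(25L, 0L, 0L))
  expect_true(all(glance(p)[, c("n_in_sgsv", "n_under_sda")] <= nrow(p$entries)))

  # no deposits, no agreements -> both zero
  w0 <- assemble_world(holdings = hold,
                       registry = make_registry(c("A", "B", "C"),
                                                c("KEN", "ETH", "NOR"),
                                                rep("national", 3)))
  p0 <- profile_genus(w0, "Zea")
  expect_equal(c(p0$n_in_sgsv, p0$n_under_sda), c(0L, 0L))
})

test_that("profile counts are monotone non-decreasing in added deposits", {
  hold <- tibble::tibble(institute_code = c("A", "B"), genus = "Zea",
                         n_total = c(10L, 10L), n_indigenous = NA_integer_)
  reg <- make_registry(c("A", "B"), c("KEN", "ETH"), rep("national", 2))
  w1 <- assemble_world(holdings = hold, registry = reg,
                       deposits = tibble::tibble(depositor_code = "A",
                                                 genus = "Zea", n_deposited = 1L))
  w2 <- assemble_world(holdings = hold, registry = reg,
                       deposits = tibble::tibble(depositor_code = c("A", "B"),
                                                 genus = "Zea",
                                                 n_deposited = c(1L, 2L)))
  p1 <- profile_genus(w1, "Zea"); p2 <- profile_genus(w2, "Zea")
  expect_gte(p2$n_in_sgsv, p1$n_in_sgsv)
  expect_gte(p2$n_under_sda, p1$n_under_sda)
})

test_that("profile averages match a full-precision mean oracle and round to one decimal", {
  set.seed(9)
  counts <- tibble::tibble(n_in_sgsv = sample(0:10, 29, replace = TRUE),
                           n_under_sda = sample(0:10, 29, replace = TRUE))
  s <- summarize_profiles(counts)
  expect_equal(s$avg_in_sgsv, round_half_up(sum(counts$n_in_sgsv) / 29, 1))
  expect_equal(s$avg_under_sda, round_half_up(sum(counts$n_under_sda) / 29, 1))

  one <- summarize_profiles(tibble::tibble(n_in_sgsv = 4, n_under_sda = 5))
  expect_equal(c(one$avg_in_sgsv, one$avg_under_sda), c(4.0, 5.0))
  expect_error(summarize_profiles(list()), class = "vaultgap_value_error")
})

test_that("plot builders return ggplot objects", {
  rows <- fixture_table1()
  expect_s3_class(plot_group_shares(rows), "ggplot")
  expect_s3_class(plot_backup_share(rows), "ggplot")
})
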