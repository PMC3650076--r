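# synthetic_world: seeded collection-world generator with known ground
# truth, for estimator validation and bias experiments.
#
# Duplication decisions are made by comparing pre-drawn uniforms against the
# probability knobs (inversion sampling), and every random quantity is drawn
# for every founder whether or not it ends up used. Two consequences, both
# deliberate: generation is exactly reproducible from (config, seed), and at
# a fixed seed the set of duplicates grows monotonically with each knob, so
# bias curves from bias_experiment() are monotone pathwise, not merely in
# expectation.

#' Default genus catalog for synthetic worlds
#'
#' Mirrors the relative abundance structure of the major seed-crop genera in
#' global holdings registries: the shipped benchmark genera with founder
#' counts proportional to their distinct-accession estimates, scaled down to
#' simulation size (about 5 to 450 founders per genus at the default scale).
#'
#' @param scale Founders per distinct accession (default 1e-3).
#' @return Tibble `genus`, `crop_group`, `seed_behavior`, `n_founders`.
#' @export
default_genus_catalog <- function(scale = 1e-3) {
  t1 <- fixture_table1()
  tibble(
    genus = t1$genus,
    crop_group = t1$crop_group,
    seed_behavior = "orthodox",
    n_founders = pmax(5L, as.integer(round(t1$distinct * scale)))
  )
}

#' Synthetic world configuration
#'
#' Knobs encode the duplication and reporting mechanisms that bias the
#' distinct-accession estimator: cross-country duplication (foreign-origin
#' copies, invisible to the estimator), IARC duplication and within-country
#' duplication (both counted again, hence overcount), and missing origins
#' (indigenous records that stop counting, hence undercount).
#'
#' @param genus_catalog Tibble `genus`, `crop_group`, `seed_behavior`,
#'   `n_founders`.
#' @param n_countries Number of countries hosting national genebanks.
#' @param institutes_per_country National institutes per country.
#' @param n_iarcs Number of international (IARC) institutes; all are
#'   Article 15 institutes in the synthetic registry.
#' @param p_cross_country_dup Probability a founder is duplicated in a
#'   foreign national genebank (origin preserved).
#' @param p_iarc_dup Probability a founder is also held by an IARC.
#' @param p_within_country_dup Probability of a second domestic copy.
#' @param p_missing_origin Probability the home record's origin is reported
#'   `UNKNOWN`.
#' @param p_wrong_origin Probability a duplicate's origin is corrupted to a
#'   random other country (off by default; duplicates normally inherit the
#'   founder's origin, which is the passport semantics the estimator relies
#'   on).
#' @param p_contracting_party Probability a country is a Treaty Contracting
#'   Party.
#' @param p_depositor Probability an institute deposits in the vault at all.
#' @param backup_fraction_range Interval from which a depositing
#'   institute's per-collection backup fraction is drawn.
#' @return A `vaultgap_world_config` list.
#' @export
world_config <- function(genus_catalog = default_genus_catalog(),
                         n_countries = 20,
                         institutes_per_country = 2,
                         n_iarcs = 3,
                         p_cross_country_dup = 0,
                         p_iarc_dup = 0,
                         p_within_country_dup = 0,
                         p_missing_origin = 0,
                         p_wrong_origin = 0,
                         p_contracting_party = 0.7,
                         p_depositor = 0.6,
                         backup_fraction_range = c(0.2, 0.8)) {
  probs <- c(p_cross_country_dup, p_iarc_dup, p_within_country_dup,
             p_missing_origin, p_wrong_origin, p_contracting_party, p_depositor)
  if (any(probs < 0 | probs > 1)) {
    abort_value("world_config: probabilities must lie in [0, 1]")
  }
  stopifnot(n_countries >= 1, institutes_per_country >= 1, n_iarcs >= 0,
            length(backup_fraction_range) == 2,
            all(backup_fraction_range >= 0), all(backup_fraction_range <= 1),
            backup_fraction_range[1] <= backup_fraction_range[2])
  catalog <- as_tibble(genus_catalog)
  if (nrow(catalog) && any(catalog$n_founders < 0)) {
    abort_value("world_config: n_founders must be nonnegative")
  }
  structure(
    list(genus_catalog = catalog, n_countries = as.integer(n_countries),
         institutes_per_country = as.integer(institutes_per_country),
         n_iarcs = as.integer(n_iarcs),
         p_cross_country_dup = p_cross_country_dup, p_iarc_dup = p_iarc_dup,
         p_within_country_dup = p_within_country_dup,
         p_missing_origin = p_missing_origin, p_wrong_origin = p_wrong_origin,
         p_contracting_party = p_contracting_party, p_depositor = p_depositor,
         backup_fraction_range = backup_fraction_range),
    class = "vaultgap_world_config"
  )
}

# synthetic alpha-3 codes XAA, XAB, ... (X prefix avoids collision with real
# ISO assignments for small n)
synthetic_country_codes <- function(n) {
  stopifnot(n <= 26 * 26)
  first <- rep(LETTERS, each = 26)[seq_len(n)]
  second <- rep(LETTERS, times = 26)[seq_len(n)]
  paste0("X", first, second)
}

#' Generate a synthetic collection world with known ground truth
#'
#' Founders are assigned an origin country and an indigenous home institute
#' there; duplicates are copied abroad, domestically and to IARCs per the
#' probability knobs, inheriting the founder's origin; per-institute vault
#' deposits are drawn from the backup-fraction interval. The result is fully
#' reproducible from `(config, seed)`.
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @return A `vaultgap_sim` list: `world` (a `vaultgap_world`), `truth`
#'   (founder table, per-record lineage, per-institute backup fractions,
#'   Contracting-Party set) and `config`.
#' @examples
#' sim <- generate_world(world_config(default_genus_catalog(5e-4)), seed = 1)
#' sim$world
#' @export
generate_world <- function(config, seed) {
  stopifnot(inherits(config, "vaultgap_world_config"))
  catalog <- config$genus_catalog
  if (!nrow(catalog)) abort_value("generate_world: empty genus catalog")
  withr::local_seed(as.integer(seed))

  countries <- synthetic_country_codes(config$n_countries)
  national <- tibble(
    country = rep(countries, each = config$institutes_per_country),
    idx = rep(seq_len(config$institutes_per_country), times = config$n_countries)
  ) |>
    mutate(institute_code = sprintf("%s%02d", .data$country, .data$idx),
           inst_type = "national", article15 = FALSE)
  iarcs <- tibble(
    institute_code = sprintf("IARC%02d", seq_len(config$n_iarcs)),
    country = sample(countries, config$n_iarcs, replace = TRUE),
    inst_type = "international_IARC", article15 = TRUE
  )
  registry <- bind_rows(select(national, "institute_code", "country",
                               "inst_type", "article15"),
                        select(iarcs, "institute_code", "country",
                               "inst_type", "article15"))

  n_founders <- sum(catalog$n_founders)
  founders <- tibble(
    founder_id = sprintf("F%06d", seq_len(n_founders)),
    genus = rep(catalog$genus, times = catalog$n_founders)
  )
  founders$origin <- sample(countries, n_founders, replace = TRUE)
  founders$home_idx <- sample.int(config$institutes_per_country, n_founders,
                                  replace = TRUE)
  founders$home_institute <- sprintf("%s%02d", founders$origin, founders$home_idx)

  # pre-drawn uniforms: inversion keeps duplicate sets monotone in the knobs
  u_within <- runif(n_founders)
  u_cross <- runif(n_founders)
  u_iarc <- runif(n_founders)
  u_missing <- runif(n_founders)
  u_wrong <- runif(n_founders)
  # partner choices, drawn unconditionally
  within_partner <- sample.int(max(config$institutes_per_country - 1L, 1L),
                               n_founders, replace = TRUE)
  cross_country_step <- sample.int(max(config$n_countries - 1L, 1L),
                                   n_founders, replace = TRUE)
  cross_idx <- sample.int(config$institutes_per_country, n_founders,
                          replace = TRUE)
  iarc_pick <- sample.int(max(config$n_iarcs, 1L), n_founders, replace = TRUE)
  wrong_step <- sample.int(max(config$n_countries - 1L, 1L),
                           n_founders, replace = TRUE)

  home <- founders |>
    mutate(
      institute_code = .data$home_institute,
      origin_country = if_else(u_missing < config$p_missing_origin,
                               UNKNOWN_COUNTRY, .data$origin),
      kind = "founder"
    )

  do_within <- u_within < config$p_within_country_dup &
    config$institutes_per_country > 1L
  within <- founders[do_within, ] |>
    mutate(
      partner = ((.data$home_idx - 1L + within_partner[do_within]) %%
                   config$institutes_per_country) + 1L,
      institute_code = sprintf("%s%02d", .data$origin, .data$partner),
      origin_country = .data$origin,
      kind = "within_country_dup"
    )

  do_cross <- u_cross < config$p_cross_country_dup & config$n_countries > 1L
  cross <- founders[do_cross, ] |>
    mutate(
      ci = match(.data$origin, countries),
      cj = ((.data$ci - 1L + cross_country_step[do_cross]) %%
              config$n_countries) + 1L,
      institute_code = sprintf("%s%02d", countries[.data$cj],
                               cross_idx[do_cross]),
      origin_country = .data$origin,
      kind = "cross_country_dup"
    )

  do_iarc <- u_iarc < config$p_iarc_dup & config$n_iarcs > 0L
  iarc_dup <- founders[do_iarc, ] |>
    mutate(
      institute_code = iarcs$institute_code[iarc_pick[do_iarc]],
      origin_country = .data$origin,
      kind = "iarc_dup"
    )

  records <- bind_rows(
    select(home, "founder_id", "genus", "institute_code", "origin_country", "kind"),
    select(within, "founder_id", "genus", "institute_code", "origin_country", "kind"),
    select(cross, "founder_id", "genus", "institute_code", "origin_country", "kind"),
    select(iarc_dup, "founder_id", "genus", "institute_code", "origin_country", "kind")
  )

  # optional origin corruption of duplicates
  if (config$p_wrong_origin > 0) {
    is_dup <- records$kind != "founder"
    u_w <- u_wrong[match(records$founder_id, founders$founder_id)]
    corrupt <- is_dup & u_w < config$p_wrong_origin
    if (any(corrupt)) {
      ci <- match(records$origin_country[corrupt], countries)
      step <- wrong_step[match(records$founder_id[corrupt], founders$founder_id)]
      records$origin_country[corrupt] <-
        countries[((ci - 1L + step) %% config$n_countries) + 1L]
    }
  }

  records <- records |>
    group_by(.data$institute_code) |>
    mutate(accession_id = sprintf("%s-%04d", .data$founder_id, row_number())) |>
    ungroup() |>
    mutate(species_epithet = "")

  accessions <- select(records, "institute_code", "accession_id", "genus",
                       "species_epithet", "origin_country")
  lineage <- select(records, "institute_code", "accession_id", "founder_id",
                    "kind")

  holdings <- accessions |>
    left_join(select(registry, "institute_code", "country"),
              by = "institute_code") |>
    group_by(.data$institute_code, .data$genus) |>
    summarise(
      n_total = n(),
      n_indigenous = sum(.data$origin_country == .data$country),
      .groups = "drop"
    ) |>
    mutate(n_total = as.integer(.data$n_total),
           n_indigenous = as.integer(.data$n_indigenous))

  n_inst <- nrow(registry)
  is_depositor <- runif(n_inst) < config$p_depositor
  fractions <- runif(n_inst, config$backup_fraction_range[1],
                     config$backup_fraction_range[2])
  fractions[!is_depositor] <- 0
  backup <- tibble(institute_code = registry$institute_code,
                   backup_fraction = fractions)

  deposits <- holdings |>
    left_join(backup, by = "institute_code") |>
    mutate(n_deposited = as.integer(round_half_up(.data$backup_fraction *
                                                    .data$n_total))) |>
    filter(.data$n_deposited > 0) |>
    select(depositor_code = "institute_code", "genus", "n_deposited")

  registry <- registry |>
    mutate(
      sgsv_depositor = .data$institute_code %in% deposits$depositor_code,
      sda_signed = .data$sgsv_depositor
    ) |>
    select("institute_code", "country", "inst_type", "article15",
           "sda_signed", "sgsv_depositor")

  cp <- countries[runif(config$n_countries) < config$p_contracting_party]

  world <- assemble_world(accessions = accessions, holdings = holdings,
                          registry = registry, deposits = deposits)
  truth <- list(
    founders = select(founders, "founder_id", "genus", "origin",
                      "home_institute"),
    founder_counts = founders |> count(.data$genus, name = "true_founder_count"),
    lineage = lineage,
    backup_fractions = backup,
    contracting_parties = cp
  )
  structure(list(world = world, truth = truth, config = config, seed = seed),
            class = "vaultgap_sim")
}

#' @export
print.vaultgap_sim <- function(x, ...) {
  cat(sprintf("<vaultgap_sim> seed %s: %d founders -> %d records\n",
              format(x$seed), nrow(x$truth$founders), nrow(x$world$accessions)))
  print(x$world)
  invisible(x)
}

#' Bias experiment over a grid of generator knobs
#'
#' For each grid point, generates `n_reps` worlds (the same replicate seeds
#' at every grid point, so knob effects are coupled), runs
#' [estimate_distinct()] and reports the mean and SD of the total estimate
#' minus the true founder count. Duplication at IARCs and within countries
#' inflates the estimate; missing origins deflate it; cross-country
#' duplication is invisible to it.
#'
#' @param config Base [world_config()].
#' @param grid Tibble whose columns are knob names (any of the `p_*`
#'   probabilities); one row per experimental condition.
#' @param n_reps Replicate worlds per grid point.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A `vaultgap_bias` tibble: the grid columns plus `mean_bias`,
#'   `sd_bias`, `n_reps`, `true_total`. Has [autoplot()], [tidy()] and
#'   [glance()] methods.
#' @export
bias_experiment <- function(config, grid, n_reps = 20, seed = 1) {
  stopifnot(inherits(config, "vaultgap_world_config"), n_reps >= 1)
  grid <- as_tibble(grid)
  knob_cols <- names(grid)
  allowed <- c("p_cross_country_dup", "p_iarc_dup", "p_within_country_dup",
               "p_missing_origin", "p_wrong_origin")
  bad <- setdiff(knob_cols, allowed)
  if (length(bad)) {
    abort_value(paste0("bias_experiment: unknown knob column(s): ",
                       fmt_items(bad)))
  }

  results <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- config
    for (k in knob_cols) cfg[[k]] <- grid[[k]][i]
    biases <- vapply(seq_len(n_reps), function(r) {
      sim <- generate_world(cfg, seed = as.integer(seed) + r)
      est <- estimate_distinct(sim$world, check_summary = FALSE)
      sum(est$n_distinct) - sum(sim$truth$founder_counts$true_founder_count)
    }, numeric(1))
    true_total <- sum(cfg$genus_catalog$n_founders)
    bind_cols(grid[i, , drop = FALSE],
              tibble(mean_bias = mean(biases),
                     sd_bias = if (n_reps > 1) sd(biases) else NA_real_,
                     n_reps = n_reps, true_total = true_total))
  })
  class(results) <- c("vaultgap_bias", class(results))
  results
}

#' @rdname bias_experiment
#' @param x A `vaultgap_bias` result.
#' @param ... Unused.
#' @export
tidy.vaultgap_bias <- function(x, ...) as_tibble(unclass(x))

#' @rdname bias_experiment
#' @export
glance.vaultgap_bias <- function(x, ...) {
  tibble(n_conditions = nrow(x), n_reps = x$n_reps[1],
         max_abs_bias = max(abs(x$mean_bias)))
}
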