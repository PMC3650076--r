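# pipeline: end-to-end orchestration producing the TSV report bundle.

#' Run configuration for the full pipeline
#'
#' Either `world` (an in-memory `vaultgap_world`) or `paths` (named list
#' with `accessions`, `holdings`, `registry`, `deposits` files) must be
#' given. A YAML file with the same field names can be loaded with
#' [read_run_config()].
#'
#' @param world Optional `vaultgap_world`.
#' @param paths Optional named list of input file paths.
#' @param delim Delimiter for input files.
#' @param contracting_parties Country codes for the Treaty context; when
#'   empty, Treaty coverage is skipped (`NA` column).
#' @param annex1_rules Annex 1 rule tibble.
#' @param params [selection_params()].
#' @param opts [reporting_options()].
#' @param profile_genera How many of the largest selected genera to
#'   profile (by total holdings).
#' @param out_dir Output directory for the report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(world = NULL, paths = NULL, delim = ",",
                       contracting_parties = character(),
                       annex1_rules = default_annex1_rules(),
                       params = selection_params(),
                       opts = reporting_options(),
                       profile_genera = 10,
                       out_dir = tempfile("vaultgap-report-")) {
  if (is.null(world) && is.null(paths)) {
    abort_value("run_config: supply either `world` or `paths`")
  }
  structure(
    list(world = world, paths = paths, delim = delim,
         contracting_parties = toupper(contracting_parties),
         annex1_rules = annex1_rules, params = params, opts = opts,
         profile_genera = as.integer(profile_genera), out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Recognised fields: `accessions`, `holdings`, `registry`, `deposits`
#' (paths, resolved relative to the YAML file), `delim`,
#' `contracting_parties`, `annex1_rules` (path), `min_accessions`,
#' `require_sgsv_presence`, `top_n`, `profile_genera`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  run_config(
    paths = list(accessions = resolve(y$accessions),
                 holdings = resolve(y$holdings),
                 registry = resolve(y$registry),
                 deposits = resolve(y$deposits)),
    delim = y$delim %||% ",",
    contracting_parties = unlist(y$contracting_parties) %||% character(),
    annex1_rules = if (!is.null(y$annex1_rules))
      read_annex1_rules(resolve(y$annex1_rules)) else default_annex1_rules(),
    params = selection_params(
      min_accessions = y$min_accessions %||% 1000,
      require_sgsv_presence = y$require_sgsv_presence %||% TRUE),
    opts = reporting_options(top_n = y$top_n %||% 10),
    profile_genera = y$profile_genera %||% 10,
    out_dir = y$out_dir %||% tempfile("vaultgap-report-")
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    vg_abort(paste0("pipeline stage '", stage, "' failed: ",
                    conditionMessage(e)),
             class = "vaultgap_pipeline_error", parent = e)
  })
}

#' Run the full gap-analysis pipeline
#'
#' Reads (or takes) the collection world, runs the study-genus selection
#' cascade, the distinct-accession and Treaty-coverage estimators, builds
#' the per-genus and per-group benchmark tables and the top-N institutional
#' profiles, and writes the report bundle as TSV files plus a plain-text run
#' log. Outputs are written to a temporary directory and moved into place
#' only on success, so a failing run leaves no partial bundle; every output
#' carries a header comment with the package version and a configuration
#' hash, and reruns on identical inputs produce identical files.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with the computed tables and `files` (paths of
#'   the written bundle: `coverage.tsv`, `groups.tsv`, `profiles.tsv`,
#'   `selection_audit.tsv`, `run.log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  world <- pipeline_stage("read", {
    if (!is.null(config$world)) config$world
    else assemble_world(
      accessions = if (!is.null(config$paths$accessions))
        read_passport_table(config$paths$accessions, config$delim),
      holdings = if (!is.null(config$paths$holdings))
        read_holdings_summary(config$paths$holdings, config$delim),
      registry = read_institution_registry(config$paths$registry, config$delim),
      deposits = if (!is.null(config$paths$deposits))
        read_deposit_table(config$paths$deposits, config$delim)
    )
  })
  say("read: %d accessions, %d holdings rows, %d institutes, %d deposit rows",
      world$report$n_records[1], world$report$n_records[2],
      world$report$n_records[3], world$report$n_records[4])

  sel <- pipeline_stage("select", {
    select_study_genera(world$holdings, world$deposits, config$params)
  })
  for (i in seq_len(nrow(sel$audit))) {
    say("select: %-22s %d genera", sel$audit$stage[i], sel$audit$n_retained[i])
  }

  ctx <- if (length(config$contracting_parties)) {
    treaty_context_from_world(world, config$contracting_parties,
                              config$annex1_rules)
  }
  est <- pipeline_stage("estimate", estimate_distinct(world, sel$genera))
  tc <- if (!is.null(ctx)) {
    pipeline_stage("treaty", treaty_coverage(world, sel$genera, ctx))
  }
  rows <- pipeline_stage("coverage", {
    build_coverage_rows(world, sel$genera, distinct_estimates = est,
                        treaty_coverages = tc, ctx = ctx)
  })
  groups <- pipeline_stage("coverage", aggregate_groups(rows))
  say("coverage: %d genus rows, %d group rows", nrow(rows), nrow(groups))

  prof_genera <- rows |>
    arrange(desc(.data$wiews_total)) |>
    slice_head(n = config$profile_genera) |>
    pull(.data$genus)
  profiles <- pipeline_stage("profile", {
    purrr::map(prof_genera, \(g) profile_genus(world, g, config$opts))
  })
  prof_tbl <- purrr::map_dfr(profiles, tidy)
  prof_sum <- if (length(profiles)) summarize_profiles(profiles)
  if (!is.null(prof_sum)) {
    say("profile: %d genera, average %.1f of top %d collections in vault, %.1f under agreement",
        prof_sum$n_genera, prof_sum$avg_in_sgsv, config$opts$top_n,
        prof_sum$avg_under_sda)
  }

  files <- pipeline_stage("write", {
    write_report_bundle(config, rows, groups, prof_tbl, sel, log_lines)
  })
  invisible(list(world = world, selection = sel, coverage = rows,
                 groups = groups, profiles = profiles,
                 profile_summary = prof_sum, files = files))
}

config_hash <- function(config) {
  key <- list(
    paths = config$paths, delim = config$delim,
    cp = config$contracting_parties,
    params = unclass(config$params), top_n = config$opts$top_n,
    profile_genera = config$profile_genera,
    has_world = !is.null(config$world)
  )
  rlang::hash(key)
}

write_report_bundle <- function(config, rows, groups, prof_tbl, sel,
                                log_lines) {
  header <- sprintf("# vaultgap %s | config %s",
                    as.character(utils::packageVersion("vaultgap")),
                    config_hash(config))
  staging <- tempfile("vaultgap-staging-")
  dir.create(staging, recursive = TRUE)
  emit <- function(df, file) {
    path <- file.path(staging, file)
    writeLines(header, path)
    int_cols <- names(df)[vapply(df, is.integer, logical(1))]
    df <- mutate(df, across(all_of(int_cols),
                            \(x) if_else(is.na(x), "na", as.character(x))))
    suppressWarnings(readr::write_tsv(df, path, append = TRUE,
                                      col_names = TRUE))
    file
  }
  names <- c(
    emit(rows, "coverage.tsv"),
    emit(groups, "groups.tsv"),
    emit(prof_tbl, "profiles.tsv"),
    emit(sel$audit, "selection_audit.tsv")
  )
  writeLines(c(header, log_lines), file.path(staging, "run.log"))
  names <- c(names, "run.log")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_paths <- file.path(config$out_dir, names)
  ok <- file.copy(file.path(staging, names), out_paths, overwrite = TRUE)
  unlink(staging, recursive = TRUE)
  if (!all(ok)) vg_abort("failed to move report bundle into place",
                         class = "vaultgap_pipeline_error")
  setNames(out_paths, names)
}
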