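# collection model: the five table kinds and the merged world view.
#
# Internal column names (MCPD v2 aliases accepted on read):
#   accessions: institute_code (INSTCODE), accession_id (ACCENUMB),
#               genus (GENUS), species_epithet (SPECIES),
#               origin_country (ORIGCTY)
#   registry:   institute_code, country, inst_type, article15, sda_signed,
#               sgsv_depositor
#   holdings:   institute_code, genus, n_total, n_indigenous
#   deposits:   depositor_code, genus, n_deposited

PASSPORT_ALIASES <- c(
  INSTCODE = "institute_code", ACCENUMB = "accession_id", GENUS = "genus",
  SPECIES = "species_epithet", ORIGCTY = "origin_country"
)

INST_TYPES <- c("national", "subnational", "regional", "international_IARC", "other")

apply_aliases <- function(df, aliases) {
  hits <- intersect(names(df), names(aliases))
  names(df)[match(hits, names(df))] <- unname(aliases[hits])
  df
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_schema(paste0(what, " is missing mandatory column(s): ",
                        fmt_items(missing)))
  }
  invisible(df)
}

parse_flag <- function(x, column) {
  raw <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(raw))
  out[raw %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[raw %in% c("0", "false", "no", "f", "n")] <- FALSE
  bad <- is.na(out) & !is.na(raw) & raw != "" & raw != "na"
  if (any(bad)) {
    abort_schema(paste0("Column '", column, "' has unparseable boolean tokens: ",
                        fmt_items(raw[bad])))
  }
  as.logical(out)
}

parse_count <- function(x, column, allow_na = FALSE) {
  raw <- trimws(as.character(x))
  blank <- is.na(raw) | raw == "" | toupper(raw) == "NA"
  val <- suppressWarnings(as.numeric(raw))
  bad <- !blank & (is.na(val) | val %% 1 != 0)
  if (any(bad)) {
    abort_value(paste0("Column '", column, "' has non-integer values: ",
                       fmt_items(raw[bad])))
  }
  if (any(val < 0, na.rm = TRUE)) {
    abort_value(paste0("Column '", column, "' has negative counts: ",
                       fmt_items(raw[!blank & val < 0])))
  }
  if (any(blank) && !allow_na) {
    abort_value(paste0("Column '", column, "' has missing values"))
  }
  out <- as.integer(val)
  out[blank] <- NA_integer_
  out
}

#' Read an accession-level passport table
#'
#' Reads MCPD-style passport records (one row per accession). Standard MCPD
#' descriptor names (`INSTCODE`, `ACCENUMB`, `GENUS`, `SPECIES`, `ORIGCTY`)
#' are accepted as aliases for the internal column names. Origin-country
#' codes are normalized with [normalize_country()]; an empty origin becomes
#' the `"UNKNOWN"` sentinel. The species epithet column is optional.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (explicit by design; no auto-detection).
#' @return A tibble of accession records with columns `institute_code`,
#'   `accession_id`, `genus`, `species_epithet`, `origin_country`.
#' @export
read_passport_table <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(.default = "c"))
  df <- apply_aliases(df, PASSPORT_ALIASES)
  require_columns(df, c("institute_code", "accession_id", "genus", "origin_country"),
                  "passport table")
  if (!"species_epithet" %in% names(df)) df$species_epithet <- ""
  df <- as_tibble(df)[, c("institute_code", "accession_id", "genus",
                          "species_epithet", "origin_country")]
  df$species_epithet <- coalesce(trimws(df$species_epithet), "")
  df$origin_country <- normalize_country(df$origin_country)
  validate_accessions(df)
}

validate_accessions <- function(df) {
  if (any(is.na(df$genus) | trimws(df$genus) == "")) {
    abort_integrity("Accession records with empty genus are not allowed")
  }
  key <- paste(df$institute_code, df$accession_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort_integrity(paste0(
      "Duplicate (institute_code, accession_id) pairs: ",
      fmt_items(paste0(df$institute_code[dup], ":", df$accession_id[dup]))))
  }
  df
}

#' Read an institution registry table
#'
#' One row per genebank or collection-holding institution, with its host
#' country, type, and Treaty/Seed-Vault flags. Boolean columns accept
#' `0/1`, `true/false`, `yes/no`. An `article15` flag on a non-IARC
#' institute is accepted with a warning: Article 15 agreements are made with
#' International Agricultural Research Centers, but registries in the wild
#' occasionally mark successor or hosted collections this way.
#'
#' @inheritParams read_passport_table
#' @return A tibble with columns `institute_code`, `country`, `inst_type`,
#'   `article15`, `sda_signed`, `sgsv_depositor`.
#' @export
read_institution_registry <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(.default = "c"))
  require_columns(df, c("institute_code", "country", "inst_type", "article15",
                        "sda_signed", "sgsv_depositor"), "institution registry")
  df <- as_tibble(df)[, c("institute_code", "country", "inst_type", "article15",
                          "sda_signed", "sgsv_depositor")]
  df$country <- normalize_country(df$country)
  df$article15 <- parse_flag(df$article15, "article15")
  df$sda_signed <- parse_flag(df$sda_signed, "sda_signed")
  df$sgsv_depositor <- parse_flag(df$sgsv_depositor, "sgsv_depositor")
  validate_registry(df)
}

validate_registry <- function(df) {
  dup <- duplicated(df$institute_code)
  if (any(dup)) {
    abort_integrity(paste0("Duplicate institute codes in registry: ",
                           fmt_items(df$institute_code[dup])))
  }
  bad_type <- !df$inst_type %in% INST_TYPES
  if (any(bad_type)) {
    abort_schema(paste0("Unknown inst_type token(s): ",
                        fmt_items(df$inst_type[bad_type]),
                        " (expected one of: ", paste(INST_TYPES, collapse = ", "), ")"))
  }
  odd <- df$article15 & df$inst_type != "international_IARC"
  if (any(odd, na.rm = TRUE)) {
    warn(paste0("article15 flag on non-IARC institute(s), accepted as-is: ",
                fmt_items(df$institute_code[which(odd)])))
  }
  df
}

#' Read an institution-by-genus holdings summary
#'
#' WIEWS-style summary: how many accessions of each genus an institution
#' reports, and optionally how many of those have a recorded origin equal to
#' the institution's own country (`n_indigenous`). A blank `n_indigenous` is
#' preserved as `NA` — "not reported" is not the same as zero.
#'
#' @inheritParams read_passport_table
#' @return A tibble with columns `institute_code`, `genus`, `n_total`,
#'   `n_indigenous`.
#' @export
read_holdings_summary <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(.default = "c"))
  require_columns(df, c("institute_code", "genus", "n_total"), "holdings summary")
  if (!"n_indigenous" %in% names(df)) df$n_indigenous <- NA_character_
  df <- as_tibble(df)[, c("institute_code", "genus", "n_total", "n_indigenous")]
  df$n_total <- parse_count(df$n_total, "n_total")
  df$n_indigenous <- parse_count(df$n_indigenous, "n_indigenous", allow_na = TRUE)
  validate_holdings(df)
}

validate_holdings <- function(df) {
  bad <- !is.na(df$n_indigenous) & df$n_indigenous > df$n_total
  if (any(bad)) {
    abort_integrity(paste0(
      "n_indigenous exceeds n_total for: ",
      fmt_items(paste0(df$institute_code[bad], ":", df$genus[bad]))))
  }
  df
}

#' Read a safety-deposit table
#'
#' One row per (depositor institute, genus): the number of safety-duplicate
#' seed samples that institute has deposited in the backup vault.
#'
#' @inheritParams read_passport_table
#' @return A tibble with columns `depositor_code`, `genus`, `n_deposited`.
#' @export
read_deposit_table <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(.default = "c"))
  require_columns(df, c("depositor_code", "genus", "n_deposited"), "deposit table")
  df <- as_tibble(df)[, c("depositor_code", "genus", "n_deposited")]
  df$n_deposited <- parse_count(df$n_deposited, "n_deposited")
  validate_deposits(df)
}

validate_deposits <- function(df) {
  key <- paste(df$depositor_code, df$genus, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort_integrity(paste0("Duplicate (depositor_code, genus) pairs: ",
                           fmt_items(paste0(df$depositor_code[dup], ":", df$genus[dup]))))
  }
  df
}

empty_accessions <- function() {
  tibble(institute_code = character(), accession_id = character(),
         genus = character(), species_epithet = character(),
         origin_country = character())
}

empty_holdings <- function() {
  tibble(institute_code = character(), genus = character(),
         n_total = integer(), n_indigenous = integer())
}

empty_registry <- function() {
  tibble(institute_code = character(), country = character(),
         inst_type = character(), article15 = logical(),
         sda_signed = logical(), sgsv_depositor = logical())
}

empty_deposits <- function() {
  tibble(depositor_code = character(), genus = character(),
         n_deposited = integer())
}

#' Assemble the merged collection world
#'
#' Joins the four record tables into a single queryable view, enforcing
#' referential integrity: every institute code referenced by accessions,
#' holdings or deposits must resolve in the registry. The returned object
#' carries an integrity report with per-source record counts; assembly
#' never drops or fabricates records.
#'
#' @param accessions Accession-level passport tibble (see
#'   [read_passport_table()]); `NULL` for none.
#' @param holdings Institution-by-genus holdings tibble; `NULL` for none.
#' @param registry Institution registry tibble.
#' @param deposits Safety-deposit tibble; `NULL` for none.
#' @return A `vaultgap_world` object: a list with elements `accessions`,
#'   `holdings`, `registry`, `deposits` and `report` (a tibble of per-source
#'   record counts).
#' @examples
#' w <- assemble_world(registry = tibble::tibble(
#'   institute_code = "NOR001", country = "NOR", inst_type = "national",
#'   article15 = FALSE, sda_signed = TRUE, sgsv_depositor = TRUE))
#' w$report
#' @export
assemble_world <- function(accessions = NULL, holdings = NULL,
                           registry = empty_registry(), deposits = NULL) {
  accessions <- validate_accessions(as_tibble(accessions %||% empty_accessions()))
  holdings <- validate_holdings(as_tibble(holdings %||% empty_holdings()))
  registry <- validate_registry(as_tibble(registry))
  deposits <- validate_deposits(as_tibble(deposits %||% empty_deposits()))

  referenced <- unique(c(accessions$institute_code, holdings$institute_code,
                         deposits$depositor_code))
  unresolved <- setdiff(referenced, registry$institute_code)
  if (length(unresolved)) {
    abort_integrity(paste0("Institute code(s) not in registry: ",
                           fmt_items(unresolved)))
  }

  report <- tibble(
    source = c("accessions", "holdings", "registry", "deposits"),
    n_records = c(nrow(accessions), nrow(holdings), nrow(registry), nrow(deposits))
  )
  structure(
    list(accessions = accessions, holdings = holdings, registry = registry,
         deposits = deposits, report = report),
    class = "vaultgap_world"
  )
}

#' @export
print.vaultgap_world <- function(x, ...) {
  cat("<vaultgap_world>\n")
  cat(sprintf("  accessions: %d records, %d genera\n",
              nrow(x$accessions), dplyr::n_distinct(x$accessions$genus)))
  cat(sprintf("  holdings:   %d rows, %d genera\n",
              nrow(x$holdings), dplyr::n_distinct(x$holdings$genus)))
  cat(sprintf("  registry:   %d institutes (%d IARC)\n",
              nrow(x$registry), sum(x$registry$inst_type == "international_IARC")))
  cat(sprintf("  deposits:   %d rows, %s samples\n",
              nrow(x$deposits), format(sum(x$deposits$n_deposited), big.mark = ",")))
  invisible(x)
}

#' Write world tables to delimited files
#'
#' Writes the four component tables of a world as delimited text, the same
#' schema the `read_*` functions consume, so a write/read cycle is the
#' identity on records.
#'
#' @param world A `vaultgap_world`.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return Invisibly, the paths of the four files written.
#' @export
write_world <- function(world, dir, delim = ",") {
  stopifnot(inherits(world, "vaultgap_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    accessions = file.path(dir, "accessions.csv"),
    holdings = file.path(dir, "holdings.csv"),
    registry = file.path(dir, "registry.csv"),
    deposits = file.path(dir, "deposits.csv")
  )
  readr::write_delim(world$accessions, paths["accessions"], delim = delim)
  readr::write_delim(world$holdings, paths["holdings"], delim = delim)
  reg <- world$registry
  reg$article15 <- as.integer(reg$article15)
  reg$sda_signed <- as.integer(reg$sda_signed)
  reg$sgsv_depositor <- as.integer(reg$sgsv_depositor)
  readr::write_delim(reg, paths["registry"], delim = delim)
  readr::write_delim(world$deposits, paths["deposits"], delim = delim)
  invisible(paths)
}

#' Read a world previously written with [write_world()]
#'
#' @param dir Directory containing `accessions.csv`, `holdings.csv`,
#'   `registry.csv`, `deposits.csv`.
#' @param delim Field delimiter.
#' @return A `vaultgap_world`.
#' @export
read_world <- function(dir, delim = ",") {
  assemble_world(
    accessions = read_passport_table(file.path(dir, "accessions.csv"), delim),
    holdings = read_holdings_summary(file.path(dir, "holdings.csv"), delim),
    registry = read_institution_registry(file.path(dir, "registry.csv"), delim),
    deposits = read_deposit_table(file.path(dir, "deposits.csv"), delim)
  )
}
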