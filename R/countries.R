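#' Country code reference table
#'
#' A small ISO 3166-1 lookup (alpha-2, alpha-3, English name) shipped with
#' the package and used to translate alpha-2 passport codes to the alpha-3
#' codes used internally. It covers the countries appearing in the shipped
#' fixtures plus other common genebank host countries; it is not the full
#' ISO registry. Any syntactically valid alpha-3 token (three ASCII letters)
#' is accepted as a country code even when absent from this table.
#'
#' @return A tibble with columns `alpha2`, `alpha3`, `name`.
#' @export
country_codes <- function() {
  if (is.null(the$country_codes)) {
    the$country_codes <- vg_read_csv(vg_extdata("country_codes.csv"),
                                     col_types = "ccc")
  }
  the$country_codes
}

#' Sentinel for a missing or unmappable origin country
#' @export
UNKNOWN_COUNTRY <- "UNKNOWN"

#' Normalize origin-country codes to ISO 3166-1 alpha-3
#'
#' Trims and upper-cases, translates alpha-2 codes through [country_codes()],
#' keeps any three-letter token as-is, and maps empty, `NA` or unmappable
#' values to the `"UNKNOWN"` sentinel (with a warning for unmappable
#' tokens). The sentinel is deliberately distinct from any host country so
#' that a missing origin can never be silently counted as indigenous.
#'
#' @param x Character vector of raw country codes.
#' @param quiet Suppress the unmappable-token warning.
#' @return Character vector of alpha-3 codes or `"UNKNOWN"`.
#' @examples
#' normalize_country(c("no", " ETH ", "", NA, "US"))
#' @export
normalize_country <- function(x, quiet = FALSE) {
  out <- toupper(trimws(as.character(x)))
  out[is.na(out) | out == ""] <- UNKNOWN_COUNTRY

  two <- nchar(out) == 2L
  if (any(two)) {
    cc <- country_codes()
    idx <- match(out[two], cc$alpha2)
    mapped <- cc$alpha3[idx]
    bad <- is.na(mapped)
    if (any(bad) && !quiet) {
      warn(paste0("Unmappable alpha-2 country codes set to UNKNOWN: ",
                  fmt_items(out[two][bad])))
    }
    mapped[bad] <- UNKNOWN_COUNTRY
    out[two] <- mapped
  }

  valid3 <- grepl("^[A-Z]{3}$", out)
  bad_rest <- !valid3 & out != UNKNOWN_COUNTRY
  if (any(bad_rest)) {
    if (!quiet) {
      warn(paste0("Unrecognized country tokens set to UNKNOWN: ",
                  fmt_items(out[bad_rest])))
    }
    out[bad_rest] <- UNKNOWN_COUNTRY
  }
  out
}
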