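#' Round half away from zero
#'
#' Commercial rounding: halves move away from zero, so `round_half_up(0.5)`
#' is 1 and `round_half_up(-0.5)` is -1. Base R's [round()] rounds halves to
#' even, which does not reproduce the percentage columns of published
#' genebank benchmark tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))   # 1 2 3 (round() gives 0 2 2)
#' round_half_up(53.91)              # 54
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

vg_abort <- function(message, class, ...) {
  abort(message, class = c(class, "vaultgap_error"), ...)
}

abort_schema <- function(message, ...) vg_abort(message, "vaultgap_schema_error", ...)
abort_integrity <- function(message, ...) vg_abort(message, "vaultgap_integrity_error", ...)
abort_value <- function(message, ...) vg_abort(message, "vaultgap_value_error", ...)

# collapse a character vector for an error message, capped
fmt_items <- function(x, max = 10) {
  x <- unique(x)
  shown <- head(x, max)
  out <- paste(shown, collapse = ", ")
  if (length(x) > max) out <- paste0(out, ", ... (", length(x) - max, " more)")
  out
}
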