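# ggplot2 views of the coverage results.

#' Crop-group share comparison plot
#'
#' Side-by-side shares of each crop group in two benchmark columns
#' (default: total registered holdings vs vault deposits), the usual way to
#' show that seed-bankable staple groups dominate the backup collection.
#'
#' @param rows Coverage tibble ([build_coverage_rows()] or the group rows
#'   from [aggregate_groups()] minus the total row).
#' @param columns Two count columns to compare as shares.
#' @return A ggplot object.
#' @export
plot_group_shares <- function(rows, columns = c("wiews_total", "sgsv")) {
  stopifnot(length(columns) == 2, all(columns %in% names(rows)))
  rows <- filter(rows, .data$crop_group != "Total")
  long <- rows |>
    group_by(.data$crop_group) |>
    summarise(across(all_of(columns), \(x) sum(x, na.rm = TRUE)),
              .groups = "drop") |>
    tidyr::pivot_longer(all_of(columns), names_to = "benchmark",
                        values_to = "n") |>
    group_by(.data$benchmark) |>
    mutate(share = .data$n / sum(.data$n)) |>
    ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$crop_group, y = .data$share,
                                     fill = .data$benchmark)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "Share of benchmark total", fill = NULL,
                  title = "Crop-group representation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Backup-share bar chart per genus
#'
#' Vault deposits as a percentage of a chosen denominator column
#' (default the distinct-accession estimate), per genus.
#'
#' @param rows Coverage tibble from [build_coverage_rows()].
#' @param denominator Column used as the denominator.
#' @return A ggplot object.
#' @export
plot_backup_share <- function(rows, denominator = "distinct") {
  stopifnot(denominator %in% names(rows), "sgsv" %in% names(rows))
  df <- rows |>
    mutate(pct = backup_share(.data$sgsv, .data[[denominator]])) |>
    filter(!is.na(.data$pct)) |>
    arrange(desc(.data$pct))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$genus, .data$pct),
                                   y = .data$pct)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("Vault deposits as % of ", denominator),
                  title = "Safety-duplication coverage by genus") +
    ggplot2::theme_minimal()
}

#' @rdname bias_experiment
#' @param object A `vaultgap_bias` result.
#' @export
autoplot.vaultgap_bias <- function(object, ...) {
  knobs <- setdiff(names(object), c("mean_bias", "sd_bias", "n_reps",
                                    "true_total"))
  varying <- knobs[vapply(knobs, function(k) dplyr::n_distinct(object[[k]]) > 1,
                          logical(1))]
  x <- if (length(varying)) varying[1] else knobs[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data$mean_bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_bias - .data$sd_bias,
      ymax = .data$mean_bias + .data$sd_bias)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = x, y = "Estimate - truth (accessions)",
                  title = "Distinct-accession estimator bias") +
    ggplot2::theme_minimal()
}
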