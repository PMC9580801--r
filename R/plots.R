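#' Stacked-bar chart of a CT frequency table
#'
#' @param object A [ct_frequency_table()] result.
#' @param ... Unused.
#' @return A ggplot: CT composition (percent) per grouping stratum.
#' @export
autoplot.vmb_ct_table <- function(object, ...) {
  group_cols <- setdiff(names(object),
                        c("ct_label", "n", "row_total", "percent"))
  object$stratum <- do.call(paste, c(object[group_cols], sep = " / "))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$stratum, y = .data$percent,
                               fill = .data$ct_label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of samples",
                  fill = "Community type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Average community composition per CT
#'
#' Proportional bar chart of the mean relative abundance of each taxon
#' within each assigned community type, restricted to the most abundant
#' taxa for readability.
#'
#' @param profiles Long profile tibble (see [compute_profiles()]).
#' @param labels CT assignments (see [assign_ct()]).
#' @param top_n Number of taxa shown individually; the rest pool into
#'   "other".
#' @return A ggplot.
#' @export
plot_ct_composition <- function(profiles, labels, top_n = 10) {
  df <- profiles |>
    dplyr::inner_join(dplyr::select(labels, "sample_id", "ct_label"),
                      by = "sample_id") |>
    dplyr::group_by(.data$ct_label, .data$taxon) |>
    dplyr::summarise(mean_ra = mean(.data$rel_abundance),
                     .groups = "drop")
  keep <- df |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(m = max(.data$mean_ra), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::pull("taxon")
  df <- df |>
    dplyr::mutate(taxon = ifelse(.data$taxon %in% keep, .data$taxon,
                                 "other")) |>
    dplyr::group_by(.data$ct_label, .data$taxon) |>
    dplyr::summarise(mean_ra = sum(.data$mean_ra), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ct_label, y = .data$mean_ra,
                                   fill = .data$taxon)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = "Community type", y = "Mean relative abundance",
                  fill = "Taxon") +
    ggplot2::theme_minimal()
}

#' Group-mean fold-change trajectories
#'
#' Plots the per-day group mean log10 fold change from baseline with
#' +/- 1 SD ribbons, one line per treatment group.
#'
#' @param fc A [log_fold_change()] result.
#' @return A ggplot.
#' @export
plot_fold_change <- function(fc) {
  summ <- fc_group_summary(fc)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$study_day,
                                     y = .data$mean_fc,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_fc - .data$sd_fc,
                                      ymax = .data$mean_fc + .data$sd_fc),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Study day",
                  y = expression(log[10] ~ "fold change vs baseline"),
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}
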