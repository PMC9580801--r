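sample_meta_cols <- c("sample_id", "animal_id", "group", "study_day",
                      "period")

#' Read a qPCR sample table
#'
#' Reads a tab-separated sample table (UTF-8, decimal point): one row per
#' swab with metadata columns (`sample_id`, `animal_id`, `group`,
#' `study_day`, `period`), the control targets `shgapdh` and `univ16s`, and
#' one copies/ul column per taxon target. Column order is free. Rows with
#' unparseable numeric cells are rejected with their line numbers; a
#' missing mandatory column is a schema error naming the column.
#'
#' @param path TSV file path.
#' @param taxa Taxon columns expected (default: intersect with
#'   [vmb_taxa()]).
#' @return Tibble of typed sample records.
#' @export
read_samples <- function(path, taxa = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(df, c(sample_meta_cols, "shgapdh", "univ16s"),
                basename(path))
  taxa <- resolve_taxa(df, taxa)
  numeric_cols <- c("study_day", "shgapdh", "univ16s", taxa)
  for (col in numeric_cols) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
    }
  }
  bad <- which(rowSums(is.na(df[numeric_cols])) > 0)
  if (length(bad) > 0) {
    warning("rejecting ", length(bad), " unparseable row(s) at line(s): ",
            paste(bad + 1, collapse = ", "), call. = FALSE)
    df <- df[-bad, ]
  }
  if (nrow(df) == 0) warning("no data rows in ", basename(path),
                             call. = FALSE)
  df
}

#' Read a cytokine ELISA table
#'
#' Long TSV with columns `sample_id`, `cytokine`, `od` (and optionally
#' `detected`). Rows with unparseable OD values are rejected with their
#' line numbers.
#'
#' @param path TSV file path.
#' @return Tibble of typed cytokine records.
#' @export
read_cytokines <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(df, c("sample_id", "cytokine", "od"), basename(path))
  if (!is.numeric(df$od)) suppressWarnings(df$od <- as.numeric(df$od))
  bad <- which(is.na(df$od))
  if (length(bad) > 0) {
    warning("rejecting ", length(bad), " unparseable row(s) at line(s): ",
            paste(bad + 1, collapse = ", "), call. = FALSE)
    df <- df[-bad, ]
  }
  if ("detected" %in% names(df)) df$detected <- as.logical(df$detected)
  if (nrow(df) == 0) warning("no data rows in ", basename(path),
                             call. = FALSE)
  df
}

#' Reference count tables from the characterization study
#'
#' Published summary counts shipped with the package for worked examples
#' and arithmetic checks:
#' * `"ct_main"` — main-period (days 1-9) CT counts per group, including
#'   the pre-dose and sham arms.
#' * `"ct_period"` — main vs recovery CT counts for the three treated
#'   groups.
#' * `"inflammation"` — inflamed/total call counts under the three
#'   inflammation models.
#' * `"qc"` — collected/failed swab counts of the phase-3 QC ledger.
#'
#' @param name One of `"ct_main"`, `"ct_period"`, `"inflammation"`, `"qc"`.
#' @return Tibble of counts.
#' @export
#' @examples
#' vmb_reference_counts("ct_main")
vmb_reference_counts <- function(name = c("ct_main", "ct_period",
                                          "inflammation", "qc")) {
  name <- match.arg(name)
  file <- c(
    ct_main = "ct_counts_main.tsv",
    ct_period = "ct_counts_period.tsv",
    inflammation = "inflammation_model_counts.tsv",
    qc = "qc_exclusion_counts.tsv"
  )[[name]]
  path <- system.file("extdata", file, package = "ovmb", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}
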