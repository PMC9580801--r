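#' Sample-inclusion thresholds
#'
#' Quality gates for vaginal swab samples: extracted DNA must carry at least
#' `min_shgapdh` copies/ul of the single-copy sheep GAPDH gene and at least
#' `min_16s` copies/ul of the universal bacterial 16S target, and a
#' post-thaw retest of both controls must agree with the original values
#' within `max_integrity_delta` log10 units.
#'
#' @param min_shgapdh,min_16s Minimum copies/ul (inclusive), default 1e4.
#' @param max_integrity_delta Maximum |log10 retest - log10 original|
#'   (inclusive), default 0.5.
#' @return A list of class `vmb_qc_thresholds`.
#' @export
qc_thresholds <- function(min_shgapdh = 1e4, min_16s = 1e4,
                          max_integrity_delta = 0.5) {
  if (min_shgapdh <= 0 || min_16s <= 0 || max_integrity_delta <= 0) {
    abort_ovmb("QC thresholds must be strictly positive")
  }
  structure(
    list(min_shgapdh = min_shgapdh, min_16s = min_16s,
         max_integrity_delta = max_integrity_delta),
    class = "vmb_qc_thresholds"
  )
}

#' Apply the sample-inclusion gates
#'
#' Adds a `qc_status` column to a sample table: `"pass"` when both control
#' targets meet their (inclusive) minimums, otherwise the first violated
#' gate (`"fail_shgapdh"` is checked before `"fail_16s"`, a fixed precedence
#' so exclusion reports are reproducible).
#'
#' @param samples Tibble with numeric `shgapdh` and `univ16s` columns
#'   (copies/ul).
#' @param thresholds A [qc_thresholds()].
#' @return `samples` with a `qc_status` character column.
#' @export
#' @examples
#' assess_quality(tibble::tibble(shgapdh = c(2e5, 9e3), univ16s = c(3e6, 1e6)))
assess_quality <- function(samples, thresholds = qc_thresholds()) {
  check_columns(samples, c("shgapdh", "univ16s"), "sample table")
  if (any(samples$shgapdh < 0, na.rm = TRUE) ||
      any(samples$univ16s < 0, na.rm = TRUE)) {
    abort_ovmb("control copy numbers must be non-negative")
  }
  samples |>
    dplyr::mutate(qc_status = dplyr::case_when(
      .data$shgapdh < thresholds$min_shgapdh ~ "fail_shgapdh",
      .data$univ16s < thresholds$min_16s ~ "fail_16s",
      TRUE ~ "pass"
    ))
}

#' Post-thaw integrity check
#'
#' A sample retains integrity when the retested shGAPDH and universal 16S
#' values are each within `max_integrity_delta` log10 (inclusive) of the
#' original measurements.
#'
#' @param original,retest Tibbles (or lists) with `shgapdh` and `univ16s`
#'   columns of equal length, all values strictly positive.
#' @param thresholds A [qc_thresholds()].
#' @return Tibble with the two per-target log10 deltas and a logical `pass`.
#' @export
#' @examples
#' check_integrity(list(shgapdh = 1e5, univ16s = 1e5),
#'                 list(shgapdh = 10^4.4, univ16s = 1e5))
check_integrity <- function(original, retest, thresholds = qc_thresholds()) {
  original <- tibble::as_tibble(original)
  retest <- tibble::as_tibble(retest)
  check_columns(original, c("shgapdh", "univ16s"), "original")
  check_columns(retest, c("shgapdh", "univ16s"), "retest")
  vals <- c(original$shgapdh, original$univ16s, retest$shgapdh, retest$univ16s)
  if (any(vals <= 0)) {
    abort_ovmb("integrity check requires strictly positive copy numbers")
  }
  d_sh <- abs(log10(retest$shgapdh) - log10(original$shgapdh))
  d_16 <- abs(log10(retest$univ16s) - log10(original$univ16s))
  tol <- thresholds$max_integrity_delta + 1e-12 # inclusive boundary
  tibble::tibble(
    delta_shgapdh = d_sh, delta_16s = d_16,
    pass = d_sh <= tol & d_16 <= tol
  )
}

#' Exclusion report
#'
#' Summarizes how many collected swabs failed the inclusion gates, with the
#' failure percentage rounded half-up to one decimal (the reporting style
#' used for study quality metrics).
#'
#' @param samples Tibble with a `qc_status` column (see [assess_quality()]).
#' @return One-row tibble: `n_collected`, `n_failed`, `percent_failed`.
#' @export
#' @examples
#' samples <- tibble::tibble(qc_status = c(rep("pass", 261), rep("fail_shgapdh", 6)))
#' summarize_exclusions(samples)
summarize_exclusions <- function(samples) {
  check_columns(samples, "qc_status", "sample table")
  n <- nrow(samples)
  if (n == 0) abort_ovmb("empty cohort: no samples to summarize")
  n_failed <- sum(samples$qc_status != "pass")
  tibble::tibble(
    n_collected = n,
    n_failed = n_failed,
    percent_failed = round_half_up(100 * n_failed / n, 1)
  )
}
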