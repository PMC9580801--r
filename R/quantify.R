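#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of quantification cycle against log10 template
#' copies from a plasmid dilution series, `Cq = slope * log10(copies) +
#' intercept`. A 100%-efficient assay has slope -1/log10(2) = -3.3219.
#'
#' @param dilution_series Tibble with numeric columns `log10_copies` and
#'   `cq`; at least three distinct dilution points are required.
#' @param taxon Optional target name carried on the result.
#' @return Object of class `vmb_std_curve` with `slope`, `intercept`,
#'   `r_squared`, `n` and `taxon`.
#' @export
#' @examples
#' ds <- tibble::tibble(log10_copies = 2:7, cq = 38 - 3.32 * (2:7))
#' fit_standard_curve(ds)
fit_standard_curve <- function(dilution_series, taxon = NA_character_) {
  check_columns(dilution_series, c("log10_copies", "cq"), "dilution series")
  x <- dilution_series$log10_copies
  y <- dilution_series$cq
  if (length(unique(x)) < 3) {
    abort_ovmb("standard curve needs >= 3 distinct dilution points")
  }
  fit <- lm(y ~ x)
  # direct R^2 avoids summary.lm()'s perfect-fit warning on exact series
  r2 <- if (var(y) == 0) 1 else {
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  structure(
    list(taxon = taxon, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), r_squared = r2, n = length(x)),
    class = "vmb_std_curve"
  )
}

#' @export
print.vmb_std_curve <- function(x, ...) {
  cat(sprintf("<vmb_std_curve%s> Cq = %.4f * log10(copies) + %.4f (R^2 = %.4f, n = %d)\n",
              if (is.na(x$taxon)) "" else paste0(": ", x$taxon),
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Convert Cq values to genome copies
#'
#' Inverts a standard curve: `copies = 10^((cq - intercept) / slope)`.
#' Non-detected wells (missing Cq) follow the array's convention and map to
#' zero copies.
#'
#' @param cq Numeric vector of quantification cycles (NA = no amplification).
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric vector of copies/ul.
#' @export
#' @examples
#' curve <- fit_standard_curve(
#'   tibble::tibble(log10_copies = 2:7, cq = 38 - 3.3219 * (2:7)))
#' cq_to_copies(c(31.356, NA), curve)
cq_to_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "vmb_std_curve"))
  if (curve$slope == 0) abort_ovmb("standard curve has zero slope")
  out <- 10^((cq - curve$intercept) / curve$slope)
  out[is.na(cq)] <- 0
  out
}

#' Relative-abundance profiles
#'
#' Converts a wide qPCR sample table into long per-taxon relative abundances.
#' The denominator is the sum of the 46 taxon targets (total detected
#' bacteria on the array); the universal 16S control is used only for the
#' coverage check, not for normalization.
#'
#' @param samples Wide sample tibble with one column per taxon plus
#'   `sample_id` (metadata columns `animal_id`, `group`, `study_day` and
#'   `period` are carried through when present).
#' @param taxa Taxon panel; defaults to the panel columns found in
#'   `samples` intersected with [vmb_taxa()] or, if none match, every
#'   numeric column that is not metadata/control.
#' @return Long tibble: metadata, `taxon`, `copies`, `rel_abundance`.
#' @export
compute_profiles <- function(samples, taxa = NULL) {
  check_columns(samples, "sample_id", "sample table")
  taxa <- resolve_taxa(samples, taxa)
  meta <- intersect(c("sample_id", "animal_id", "group", "study_day",
                      "period"), names(samples))
  long <- samples |>
    dplyr::select(dplyr::all_of(c(meta, taxa))) |>
    tidyr::pivot_longer(dplyr::all_of(taxa), names_to = "taxon",
                        values_to = "copies") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$copies)) |>
    dplyr::ungroup()
  if (any(long$copies < 0)) abort_ovmb("copy numbers must be non-negative")
  if (any(long$total == 0)) {
    abort_ovmb("profile undefined: sample(s) with all-zero taxon vector")
  }
  long |>
    dplyr::mutate(rel_abundance = .data$copies / .data$total) |>
    dplyr::select(-"total")
}

resolve_taxa <- function(samples, taxa) {
  if (!is.null(taxa)) {
    check_columns(samples, taxa, "sample table")
    return(taxa)
  }
  hit <- intersect(vmb_taxa(), names(samples))
  if (length(hit) > 0) return(hit)
  reserved <- c("sample_id", "animal_id", "group", "study_day", "period",
                "shgapdh", "univ16s", "qc_status")
  candidates <- setdiff(names(samples), reserved)
  candidates[vapply(samples[candidates], is.numeric, logical(1))]
}

#' Per-sample profile statistics: coverage and Shannon diversity
#'
#' Coverage is the fraction of the universal 16S load accounted for by the
#' summed taxon targets; values below `coverage_flag` are flagged as a cue
#' that the panel misses community members (flag only, never an exclusion).
#' The Shannon Diversity Index (SDI) is computed in nats over the non-zero
#' relative abundances, so a single-taxon community has SDI 0 and a uniform
#' 46-taxon community has SDI ln(46).
#'
#' @param samples Wide sample tibble with taxon columns and `univ16s`.
#' @param taxa Taxon panel (see [compute_profiles()]).
#' @param coverage_flag Coverage below which `low_coverage` is set
#'   (default 0.90).
#' @return Tibble: `sample_id`, `total_detected`, `univ16s`, `coverage`,
#'   `low_coverage`, `sdi`.
#' @export
profile_stats <- function(samples, taxa = NULL, coverage_flag = 0.90) {
  check_columns(samples, c("sample_id", "univ16s"), "sample table")
  taxa <- resolve_taxa(samples, taxa)
  mat <- as.matrix(samples[taxa])
  total <- rowSums(mat)
  if (any(total == 0)) {
    abort_ovmb("profile undefined: sample(s) with all-zero taxon vector")
  }
  tibble::tibble(
    sample_id = samples$sample_id,
    total_detected = total,
    univ16s = samples$univ16s,
    coverage = total / samples$univ16s,
    low_coverage = total / samples$univ16s < coverage_flag,
    sdi = unname(vegan::diversity(mat, index = "shannon"))
  )
}

#' Shannon diversity of a single abundance vector
#'
#' @param x Non-negative abundance or relative-abundance vector.
#' @return SDI in nats, `-sum(p * log(p))` over `p > 0`.
#' @export
#' @examples
#' shannon_index(rep(1, 46)) # ln(46)
shannon_index <- function(x) {
  if (any(x < 0)) abort_ovmb("abundances must be non-negative")
  if (sum(x) == 0) abort_ovmb("SDI undefined for an all-zero vector")
  unname(vegan::diversity(matrix(x, nrow = 1), index = "shannon"))
}
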