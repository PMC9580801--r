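#' Tidy a two-part test result
#'
#' @param x A [two_part_test()] result.
#' @param ... Unused.
#' @return One-row tibble with the component statistics and the combined
#'   chi-square p value.
#' @export
tidy.vmb_two_part <- function(x, ...) {
  tibble::tibble(
    z_zero = x$z_zero,
    w_nonzero = x$w_nonzero,
    statistic = x$chi2,
    df = x$df,
    p.value = x$p_value,
    method = "two-part zero/Wilcoxon chi-square"
  )
}

#' @rdname tidy.vmb_two_part
#' @export
glance.vmb_two_part <- function(x, ...) {
  tibble::tibble(
    statistic = x$chi2, p.value = x$p_value,
    n_x = x$n_x, n_y = x$n_y,
    nonzero_degenerate = x$nonzero_degenerate
  )
}

#' Tidy a standard curve
#'
#' @param x A [fit_standard_curve()] result.
#' @param ... Unused.
#' @return One-row tibble with slope, intercept, fit R^2, the implied
#'   amplification efficiency `10^(-1/slope) - 1`, and n.
#' @export
tidy.vmb_std_curve <- function(x, ...) {
  tibble::tibble(
    taxon = x$taxon,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    efficiency = 10^(-1 / x$slope) - 1,
    n = x$n
  )
}

#' Tidy a normality-gated group comparison
#'
#' @param x A [group_compare_fc()] result.
#' @param ... Unused.
#' @return The pairwise comparison tibble with the branch recorded.
#' @export
tidy.vmb_group_test <- function(x, ...) {
  dplyr::mutate(x$pairwise, branch = x$branch)
}

#' @rdname tidy.vmb_group_test
#' @export
glance.vmb_group_test <- function(x, ...) {
  tibble::tibble(
    branch = x$branch,
    method = x$omnibus$method,
    statistic = x$omnibus$statistic,
    p.value = x$omnibus$p_value,
    n_groups = nrow(x$normality)
  )
}
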