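#' Kolmogorov-Smirnov comparison of CT frequency distributions
#'
#' Compares two community-type count vectors with the asymptotic two-sample
#' KS test: `D` is the maximum absolute difference between the cumulative
#' distributions taken over a fixed CT ordering. Because the CT axis is
#' categorical, the result depends on that ordering; the catalog order is
#' used and echoed in the result. `D` is invariant to rescaling either
#' count vector.
#'
#' @param freq_a,freq_b Named (or equally ordered) non-negative count
#'   vectors over the same CTs.
#' @param ct_order Optional explicit CT ordering; defaults to the names of
#'   `freq_a` (or positional order).
#' @return One-row tibble: `statistic` (D), `p_value` (asymptotic),
#'   `n_a`, `n_b`, plus the ordering in attribute `"ct_order"`.
#' @export
#' @examples
#' a <- c("A-H" = 30, Ps = 1, Ec = 0, H = 17, Cy = 5, U = 1)
#' b <- c("A-H" = 37, Ps = 9, Ec = 5, H = 0, Cy = 0, U = 0)
#' ks_ct_distribution(a, b)
ks_ct_distribution <- function(freq_a, freq_b, ct_order = NULL) {
  if (is.null(ct_order)) {
    ct_order <- names(freq_a) %||% as.character(seq_along(freq_a))
  }
  if (!is.null(names(freq_a))) {
    if (!setequal(names(freq_a), names(freq_b)) ||
        !setequal(names(freq_a), ct_order)) {
      abort_ovmb("freq_a, freq_b and ct_order must share one CT set")
    }
    freq_a <- freq_a[ct_order]
    freq_b <- freq_b[ct_order]
  }
  if (length(freq_a) != length(freq_b)) {
    abort_ovmb("count vectors must have equal length")
  }
  if (sum(freq_a) < 1 || sum(freq_b) < 1) {
    abort_ovmb("both distributions need at least one count")
  }
  # expand counts over the ordered category axis; ties carry the
  # categorical CDF, and the asymptotic two-sample test applies as-is
  xa <- rep(seq_along(freq_a), times = round(freq_a))
  xb <- rep(seq_along(freq_b), times = round(freq_b))
  kt <- suppressWarnings(ks.test(xa, xb, exact = FALSE))
  out <- tibble::tibble(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    n_a = length(xa), n_b = length(xb)
  )
  attr(out, "ct_order") <- ct_order
  out
}

#' Per-CT Fisher exact tests with Benjamini-Hochberg correction
#'
#' For each community type and each pair of treatment groups, forms the
#' 2x2 table (samples in the CT vs not) x (group pair) and runs a
#' two-sided Fisher exact test (sum of hypergeometric table probabilities
#' at most that of the observed table). All (CT x pair) p values within the
#' call — one period's family — are then adjusted by the BH step-up rule.
#' Tables with a zero margin (a CT absent from both groups) get p = 1 by
#' convention and are flagged.
#'
#' @param counts Tibble with columns `group`, `ct_label`, `n` (counts), such
#'   as the output of [ct_frequency_table()] — or any per-group CT count
#'   table.
#' @param pairs Optional list of 2-vectors of group names; defaults to all
#'   pairs.
#' @return Tibble: `ct_label`, `group_a`, `group_b`, the 2x2 cells,
#'   `p_value`, `q_value` (BH), `degenerate`.
#' @export
fisher_per_ct <- function(counts, pairs = NULL) {
  check_columns(counts, c("group", "ct_label", "n"), "counts")
  groups <- unique(counts$group)
  if (is.null(pairs)) {
    pairs <- utils::combn(as.character(groups), 2, simplify = FALSE)
  }
  cts <- unique(counts$ct_label)
  totals <- counts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  get_n <- function(g, ct) {
    v <- counts$n[counts$group == g & counts$ct_label == ct]
    if (length(v) == 0) 0 else sum(v)
  }
  rows <- purrr::map_dfr(pairs, function(p) {
    purrr::map_dfr(cts, function(ct) {
      a <- get_n(p[1], ct)
      b <- totals$total[totals$group == p[1]] - a
      c_ <- get_n(p[2], ct)
      d <- totals$total[totals$group == p[2]] - c_
      tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
      degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
      p_val <- if (degenerate) 1 else {
        fisher.test(tab, alternative = "two.sided")$p.value
      }
      tibble::tibble(
        ct_label = ct, group_a = p[1], group_b = p[2],
        in_ct_a = a, not_ct_a = b, in_ct_b = c_, not_ct_b = d,
        p_value = p_val, degenerate = degenerate
      )
    })
  })
  rows |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH"))
}
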