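#' Per-CT majority category for one cytokine
#'
#' Within a community type, a cytokine is categorized `"H"` when at least
#' `majority_fraction` of the CT's samples carry a high call, `"L"` when at
#' least that fraction are low, and `"mixed"` otherwise. The default 0.67 is
#' a strict decimal threshold: 2 high of 3 (0.667) is mixed; pass
#' `majority_fraction = 2/3` to use the exact fraction instead.
#'
#' @param calls Character vector of `"H"`/`"L"` calls for one cytokine over
#'   the samples of one CT.
#' @param majority_fraction Consensus fraction (default 0.67).
#' @return `"H"`, `"L"` or `"mixed"`.
#' @export
#' @examples
#' majority_category(rep(c("H", "L"), c(7, 3))) # "H"
#' majority_category(rep(c("H", "L"), c(2, 1))) # "mixed": 0.667 < 0.67
majority_category <- function(calls, majority_fraction = 0.67) {
  if (length(calls) == 0) abort_ovmb("empty CT: no calls to categorize")
  frac_h <- mean(calls == "H")
  tol <- 1e-12
  if (frac_h >= majority_fraction - tol) return("H")
  if (1 - frac_h >= majority_fraction - tol) return("L")
  "mixed"
}

#' Consensus eubiosis/dysbiosis call from cytokine categories
#'
#' A CT is dysbiotic when at least 3 of its 4 cytokine categories are high,
#' eubiotic when at least 3 are low; anything else (mixed categories never
#' count toward either side) is indeterminate.
#'
#' @param categories Named character vector/list of `"H"`/`"L"`/`"mixed"`
#'   for the four analyzable cytokines.
#' @param consistency_required Same-direction categories needed (default 3).
#' @return `"dysbiotic"`, `"eubiotic"` or `"indeterminate"`.
#' @export
#' @examples
#' consensus_biosis(c(IL8 = "H", IL1B = "H", TNFA = "H", CXCL10 = "L"))
consensus_biosis <- function(categories, consistency_required = 3L) {
  categories <- unlist(categories)
  missing <- setdiff(vmb_cytokines_analyzable(), names(categories))
  if (length(missing) > 0) {
    abort_ovmb(sprintf("missing cytokine categories: %s",
                       paste(missing, collapse = ", ")))
  }
  categories <- categories[vmb_cytokines_analyzable()]
  if (sum(categories == "H") >= consistency_required) return("dysbiotic")
  if (sum(categories == "L") >= consistency_required) return("eubiotic")
  "indeterminate"
}

#' Per-CT biosis consensus calls
#'
#' Joins CT labels to per-cytokine high/low calls and applies the
#' 67%-majority / 3-of-4 consensus rule to associate every community type
#' with eubiosis, dysbiosis, or an indeterminate state.
#'
#' @param labels Tibble with `sample_id` and `ct_label` (see [assign_ct()]).
#' @param calls Long per-cytokine call tibble with `sample_id`, `cytokine`,
#'   `call` (see [cytokine_calls()]), restricted to (or filtered here to)
#'   the four analyzable cytokines.
#' @param majority_fraction Consensus fraction per cytokine (default 0.67).
#' @param consistency_required Same-direction cytokines needed (default 3).
#' @return Tibble of class `vmb_biosis`: `ct_label`, `n_samples`, one
#'   category column per cytokine, and `consensus`.
#' @export
call_biosis <- function(labels, calls, majority_fraction = 0.67,
                        consistency_required = 3L) {
  check_columns(labels, c("sample_id", "ct_label"), "labels")
  check_columns(calls, c("sample_id", "cytokine", "call"), "calls")
  calls <- dplyr::filter(calls,
                         .data$cytokine %in% vmb_cytokines_analyzable())
  joined <- dplyr::inner_join(
    dplyr::select(labels, "sample_id", "ct_label"),
    calls, by = "sample_id"
  )
  if (nrow(joined) == 0) abort_ovmb("no samples shared by labels and calls")
  categories <- joined |>
    dplyr::group_by(.data$ct_label, .data$cytokine) |>
    dplyr::summarise(
      category = majority_category(.data$call, majority_fraction),
      .groups = "drop"
    )
  n_samples <- joined |>
    dplyr::distinct(.data$ct_label, .data$sample_id) |>
    dplyr::count(.data$ct_label, name = "n_samples")
  wide <- categories |>
    tidyr::pivot_wider(names_from = "cytokine", values_from = "category")
  out <- wide |>
    dplyr::left_join(n_samples, by = "ct_label") |>
    dplyr::rowwise() |>
    dplyr::mutate(consensus = consensus_biosis(
      setNames(
        c(.data$IL8, .data$IL1B, .data$TNFA, .data$CXCL10),
        c("IL8", "IL1B", "TNFA", "CXCL10")
      ),
      consistency_required
    )) |>
    dplyr::ungroup() |>
    dplyr::relocate("n_samples", .after = "ct_label")
  class(out) <- c("vmb_biosis", class(out))
  out
}
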