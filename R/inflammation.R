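#' Flag cytokine detection against a blank-derived threshold
#'
#' A cytokine is "detected" when its OD490 exceeds the detection threshold.
#' The threshold is either supplied directly or derived from negative
#' reagent blanks as `mean(blanks) + 2 * sd(blanks)`.
#'
#' @param panels Long cytokine tibble: `sample_id`, `cytokine`, `od`.
#' @param blanks Optional numeric vector of reagent-blank ODs.
#' @param threshold Explicit OD threshold (used when `blanks` is NULL).
#' @return `panels` with a logical `detected` column.
#' @export
flag_detection <- function(panels, blanks = NULL, threshold = 0.05) {
  check_columns(panels, c("sample_id", "cytokine", "od"), "cytokine table")
  if (!is.null(blanks)) {
    if (length(blanks) < 2) abort_ovmb("need >= 2 blank wells")
    threshold <- mean(blanks) + 2 * sd(blanks)
  }
  dplyr::mutate(panels, detected = .data$od > threshold)
}

#' Per-cytokine detection frequency
#'
#' Fraction of samples in which each cytokine is detected. Cytokines whose
#' frequency falls below `analyzable_floor` are marked non-analyzable and
#' should be dropped from inflammation models (in ovine vaginal fluid this
#' removes IL-6 and IL-17A, which are rarely detected).
#'
#' @param panels Long cytokine tibble with a `detected` column.
#' @param analyzable_floor Minimum detection frequency (default 0.20).
#' @return Tibble: `cytokine`, `n_detected`, `n`, `frequency`, `analyzable`.
#' @export
detection_frequency <- function(panels, analyzable_floor = 0.20) {
  check_columns(panels, c("cytokine", "detected"), "cytokine table")
  if (nrow(panels) == 0) abort_ovmb("empty cytokine table")
  panels |>
    dplyr::group_by(.data$cytokine) |>
    dplyr::summarise(
      n_detected = sum(.data$detected),
      n = dplyr::n(),
      frequency = .data$n_detected / .data$n,
      .groups = "drop"
    ) |>
    dplyr::mutate(analyzable = .data$frequency >= analyzable_floor)
}

#' Inflammation classification models
#'
#' The two categorization models used to call a swab inflamed from its
#' cytokine ODs:
#' * `Infl1` votes over the four analyzable cytokines (IL-8, IL-1B, TNF-A,
#'   CXCL10) and declares inflamed when at least 3 of 4 are high. Its
#'   `scheme` may be `"tertile"` (high = top tertile), `"percentile"`
#'   (high = above the 59th percentile by default) or `"mean"` (high =
#'   above the arithmetic mean).
#' * `Infl4` uses only IL-8 and IL-1B (the most frequently detected
#'   targets) with a binary percentile split; a single high call suffices
#'   (1-of-2), the only vote rule under which it calls more samples
#'   inflamed than the binary Infl1.
#'
#' @param name `"Infl1"` or `"Infl4"` (anything else builds a custom model).
#' @param scheme Threshold scheme: `"percentile"`, `"tertile"` or `"mean"`.
#' @param percentile Percentile for the binary split (default 0.59).
#' @param cytokines Cytokines the model votes over.
#' @param votes_required High calls needed to declare a sample inflamed.
#' @return A list of class `vmb_infl_model`.
#' @export
#' @examples
#' infl_model("Infl4")
#' infl_model("Infl1", scheme = "tertile")
infl_model <- function(name = c("Infl1", "Infl4"),
                       scheme = NULL, percentile = 0.59,
                       cytokines = NULL, votes_required = NULL) {
  name <- name[1]
  if (name == "Infl1") {
    scheme <- scheme %||% "percentile"
    cytokines <- cytokines %||% vmb_cytokines_analyzable()
    votes_required <- votes_required %||% 3L
  } else if (name == "Infl4") {
    scheme <- scheme %||% "percentile"
    cytokines <- cytokines %||% c("IL8", "IL1B")
    votes_required <- votes_required %||% 1L
  } else {
    if (is.null(scheme) || is.null(cytokines) || is.null(votes_required)) {
      abort_ovmb("custom models need scheme, cytokines and votes_required")
    }
  }
  scheme <- match.arg(scheme, c("percentile", "tertile", "mean"))
  if (votes_required < 1 || votes_required > length(cytokines)) {
    abort_ovmb("votes_required must be between 1 and the number of cytokines")
  }
  structure(
    list(name = name, scheme = scheme, percentile = percentile,
         cytokines = cytokines, votes_required = as.integer(votes_required)),
    class = "vmb_infl_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive per-cytokine high/low cutoffs
#'
#' Cutoffs are computed per cytokine over ALL pooled study samples:
#' `"percentile"` takes the stated percentile (linear-interpolation
#' definition, quantile type 7), `"tertile"` the 33.3/66.7 percentiles, and
#' `"mean"` the arithmetic mean. Raw ODs are used throughout — no
#' standard-curve conversion enters the classification path.
#'
#' @param panels Long cytokine tibble: `sample_id`, `cytokine`, `od`.
#' @param scheme `"percentile"`, `"tertile"` or `"mean"`.
#' @param percentile Percentile for the binary split (default 0.59).
#' @return Tibble: `cytokine`, `cutoff` (and `cutoff_low` for tertiles),
#'   `scheme`. Constant OD vectors trigger a degenerate-threshold warning.
#' @export
#' @examples
#' panels <- tibble::tibble(sample_id = 1:100, cytokine = "IL8", od = 1:100)
#' derive_thresholds(panels, "percentile") # 59.41
derive_thresholds <- function(panels,
                              scheme = c("percentile", "tertile", "mean"),
                              percentile = 0.59) {
  scheme <- match.arg(scheme)
  check_columns(panels, c("cytokine", "od"), "cytokine table")
  counts <- table(panels$cytokine)
  if (any(counts < 3)) {
    abort_ovmb("need >= 3 OD values per cytokine to derive thresholds")
  }
  out <- panels |>
    dplyr::group_by(.data$cytokine) |>
    dplyr::summarise(
      cutoff_low = unname(quantile(.data$od, 1 / 3, type = 7)),
      cutoff = switch(scheme,
        percentile = unname(quantile(.data$od, percentile, type = 7)),
        tertile = unname(quantile(.data$od, 2 / 3, type = 7)),
        mean = mean(.data$od)
      ),
      constant = sd(.data$od) == 0,
      .groups = "drop"
    )
  if (any(out$constant)) {
    warning("degenerate threshold: constant OD vector for ",
            paste(out$cytokine[out$constant], collapse = ", "),
            "; all its samples will be called low", call. = FALSE)
  }
  if (scheme != "tertile") out$cutoff_low <- NULL
  out |>
    dplyr::select(-"constant") |>
    dplyr::mutate(scheme = scheme)
}

#' Classify samples as inflamed or normal
#'
#' Applies a model's vote rule to per-cytokine high/low calls: a cytokine is
#' high when its OD strictly exceeds the cutoff (for the tertile scheme, the
#' upper-tertile cutoff), and a sample is inflamed when at least
#' `votes_required` of the model's cytokines are high. Increasing any OD
#' can therefore never flip an inflamed sample back to normal.
#'
#' @param panels Long cytokine tibble: `sample_id`, `cytokine`, `od`.
#' @param model A [infl_model()].
#' @param cutoffs Optional [derive_thresholds()] output; derived from
#'   `panels` under the model's scheme when omitted.
#' @return Tibble: `sample_id`, `n_high`, `n_votes`, `inflamed` (logical),
#'   with the long per-cytokine calls in attribute `"calls"` (also
#'   retrievable via [cytokine_calls()]).
#' @export
classify_inflammation <- function(panels, model = infl_model("Infl4"),
                                  cutoffs = NULL) {
  stopifnot(inherits(model, "vmb_infl_model"))
  check_columns(panels, c("sample_id", "cytokine", "od"), "cytokine table")
  if (is.null(cutoffs)) {
    cutoffs <- derive_thresholds(panels, model$scheme, model$percentile)
  }
  missing <- setdiff(model$cytokines, unique(panels$cytokine))
  if (length(missing) > 0) {
    abort_ovmb(sprintf("cytokine(s) required by %s missing from panels: %s",
                       model$name, paste(missing, collapse = ", ")))
  }
  calls <- cytokine_calls(panels, cutoffs) |>
    dplyr::filter(.data$cytokine %in% model$cytokines)
  incomplete <- calls |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n < length(model$cytokines))
  if (nrow(incomplete) > 0) {
    abort_ovmb("some samples lack OD values for the model's cytokines")
  }
  out <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_high = sum(.data$call == "H"), .groups = "drop") |>
    dplyr::mutate(
      n_votes = length(model$cytokines),
      inflamed = .data$n_high >= model$votes_required
    )
  attr(out, "calls") <- calls
  attr(out, "model") <- model
  out
}

#' Per-cytokine high/low calls
#'
#' @param panels Long cytokine tibble: `sample_id`, `cytokine`, `od`.
#' @param cutoffs A [derive_thresholds()] output.
#' @return `panels` restricted to cytokines with cutoffs, plus a `call`
#'   column (`"H"` when `od > cutoff`, else `"L"`).
#' @export
cytokine_calls <- function(panels, cutoffs) {
  check_columns(cutoffs, c("cytokine", "cutoff"), "cutoffs")
  panels |>
    dplyr::inner_join(cutoffs, by = "cytokine") |>
    dplyr::mutate(call = ifelse(.data$od > .data$cutoff, "H", "L")) |>
    dplyr::select(dplyr::any_of(c("sample_id", "cytokine", "od", "detected",
                                  "cutoff", "call")))
}

#' Inflammation summary
#'
#' Counts inflamed samples and reports the percentage rounded half-up to
#' the nearest integer (the reporting style for study-level inflammation
#' rates, e.g. 174/264 prints as 66).
#'
#' @param calls Tibble with a logical `inflamed` column, or a logical
#'   vector.
#' @return One-row tibble: `n_inflamed`, `n_total`, `percent`.
#' @export
#' @examples
#' summarize_inflammation(rep(c(TRUE, FALSE), c(174, 90)))
summarize_inflammation <- function(calls) {
  inflamed <- if (is.logical(calls)) calls else {
    check_columns(calls, "inflamed", "calls")
    calls$inflamed
  }
  if (length(inflamed) == 0) abort_ovmb("no inflammation calls to summarize")
  tibble::tibble(
    n_inflamed = sum(inflamed),
    n_total = length(inflamed),
    percent = round_half_up(100 * sum(inflamed) / length(inflamed), 0)
  )
}
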