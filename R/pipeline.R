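#' Run the full VMB analysis pipeline
#'
#' Ties the stages together in study order: QC gating, relative-abundance
#' quantification (with coverage and Shannon diversity), community-type
#' assignment, inflammation classification, per-CT biosis consensus, and
#' the CT frequency table by group and period. Only QC-passing samples flow
#' past the first stage; an empty post-QC cohort halts the run. Reruns on
#' identical inputs are deterministic — the manifest records per-stage row
#' counts and the package version.
#'
#' @param samples Wide qPCR sample tibble (see [read_samples()] or
#'   [simulate_vmb_dataset()]).
#' @param cytokines Long cytokine tibble (`sample_id`, `cytokine`, `od`).
#' @param catalog CT catalog (default [ct_catalog()]).
#' @param thresholds QC thresholds (default [qc_thresholds()]).
#' @param model Inflammation model (default `Infl4`).
#' @param detection_threshold OD490 detection threshold for the
#'   detection-frequency report.
#' @param dominance_threshold,combination_threshold CT assignment
#'   thresholds (see [assign_ct()]).
#' @return Object of class `vmb_pipeline`: `qc_report`, `samples` (QC
#'   annotated), `profiles`, `profile_stats`, `ct_labels`, `ct_table`,
#'   `detection`, `inflammation_calls`, `inflammation_summary`, `biosis`,
#'   `manifest`.
#' @export
run_vmb_pipeline <- function(samples, cytokines,
                             catalog = ct_catalog(),
                             thresholds = qc_thresholds(),
                             model = infl_model("Infl4"),
                             detection_threshold = 0.05,
                             dominance_threshold = 0.40,
                             combination_threshold = 0.20) {
  unknown <- setdiff(unique(unlist(catalog$biomarkers)), names(samples))
  if (length(unknown) > 0) {
    abort_ovmb(sprintf(
      "catalog biomarker(s) not present in the sample table: %s",
      paste(unknown, collapse = ", ")
    ))
  }

  samples <- assess_quality(samples, thresholds)
  qc_report <- summarize_exclusions(samples)
  passing <- dplyr::filter(samples, .data$qc_status == "pass")
  if (nrow(passing) == 0) {
    abort_ovmb("pipeline halted after qc: no samples passed the gates")
  }

  profiles <- compute_profiles(passing)
  stats <- profile_stats(passing)

  labels <- assign_ct(profiles, catalog,
                      dominance_threshold = dominance_threshold,
                      combination_threshold = combination_threshold)
  grouping <- intersect(c("group", "period"), names(labels))
  ct_table <- ct_frequency_table(labels,
                                 dplyr::all_of(grouping))

  cytokines <- dplyr::semi_join(cytokines, passing, by = "sample_id")
  if (!"detected" %in% names(cytokines)) {
    cytokines <- flag_detection(cytokines, threshold = detection_threshold)
  }
  detection <- detection_frequency(cytokines)
  analyzable <- detection$cytokine[detection$analyzable]
  model_ok <- all(model$cytokines %in% analyzable)
  if (!model_ok) {
    warning("model uses cytokine(s) below the detection-frequency floor",
            call. = FALSE)
  }
  infl <- classify_inflammation(cytokines, model)
  infl_summary <- summarize_inflammation(infl)

  # biosis consensus is built from binary percentile calls over the four
  # analyzable targets, independent of the chosen inflammation model
  binary_cutoffs <- derive_thresholds(
    dplyr::filter(cytokines,
                  .data$cytokine %in% vmb_cytokines_analyzable()),
    scheme = "percentile"
  )
  calls <- cytokine_calls(cytokines, binary_cutoffs)
  biosis <- call_biosis(labels, calls)

  manifest <- tibble::tibble(
    stage = c("qc", "quantify", "assign_ct", "inflammation", "biosis"),
    n_in = c(nrow(samples), nrow(passing), nrow(passing),
             length(unique(cytokines$sample_id)), nrow(labels)),
    n_out = c(nrow(passing), nrow(stats), nrow(labels), nrow(infl),
              nrow(biosis)),
    package_version = as.character(utils::packageVersion("ovmb"))
  )

  structure(
    list(
      qc_report = qc_report, samples = samples, profiles = profiles,
      profile_stats = stats, ct_labels = labels, ct_table = ct_table,
      detection = detection, inflammation_calls = infl,
      inflammation_summary = infl_summary, biosis = biosis,
      manifest = manifest
    ),
    class = "vmb_pipeline"
  )
}

#' @export
print.vmb_pipeline <- function(x, ...) {
  cat("<vmb_pipeline>\n")
  cat(sprintf("  qc: %d collected, %d failed (%.1f%%)\n",
              x$qc_report$n_collected, x$qc_report$n_failed,
              x$qc_report$percent_failed))
  cat(sprintf("  community types: %s\n",
              paste(sort(unique(x$ct_labels$ct_label)), collapse = ", ")))
  cat(sprintf("  inflamed: %d/%d (%d%%)\n",
              x$inflammation_summary$n_inflamed,
              x$inflammation_summary$n_total,
              x$inflammation_summary$percent))
  cat(sprintf("  biosis consensus: %s\n",
              paste(sprintf("%s=%s", x$biosis$ct_label, x$biosis$consensus),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname run_vmb_pipeline
#' @param x A `vmb_pipeline` object.
#' @param ... Unused.
#' @export
glance.vmb_pipeline <- function(x, ...) {
  tibble::tibble(
    n_collected = x$qc_report$n_collected,
    n_failed_qc = x$qc_report$n_failed,
    percent_failed_qc = x$qc_report$percent_failed,
    n_cts = length(unique(x$ct_labels$ct_label)),
    n_untypable = sum(x$ct_labels$ct_label == "untypable"),
    percent_inflamed = x$inflammation_summary$percent,
    n_dysbiotic_cts = sum(x$biosis$consensus == "dysbiotic"),
    n_eubiotic_cts = sum(x$biosis$consensus == "eubiotic")
  )
}
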