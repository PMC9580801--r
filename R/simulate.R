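#' Study design for a longitudinal vaginal-irritant safety study
#'
#' Describes the sampling schedule of a three-arm irritant study plus sham
#' controls: a 10-day daily-dosing main period sampled on days 1, 2, 3, 5, 7
#' and 9 (day 1 is the pre-dose baseline) and a post-treatment recovery
#' window sampled on days 11, 13, 15, 17 and 21 in a subset of animals.
#' Recovery samples are collected for the treated groups only.
#'
#' @param groups Character vector of group names.
#' @param animals_per_group Number of animals in each group.
#' @param main_days Integer sampling days of the main (dosing) period;
#'   must include the baseline day 1 and be strictly increasing.
#' @param recovery_days Integer sampling days of the recovery period.
#' @param recovery_animals_per_group Number of animals per group followed
#'   through recovery (must not exceed `animals_per_group`).
#' @param recovery_groups Groups with a recovery arm.
#' @return A list of class `vmb_design`.
#' @export
#' @examples
#' vmb_design()
vmb_design <- function(groups = c("Sham", "HEC", "N9", "BZK"),
                       animals_per_group = 9,
                       main_days = c(1L, 2L, 3L, 5L, 7L, 9L),
                       recovery_days = c(11L, 13L, 15L, 17L, 21L),
                       recovery_animals_per_group = 4,
                       recovery_groups = c("HEC", "N9", "BZK")) {
  main_days <- as.integer(main_days)
  recovery_days <- as.integer(recovery_days)
  if (is.unsorted(main_days, strictly = TRUE) ||
      (length(recovery_days) && is.unsorted(recovery_days, strictly = TRUE))) {
    abort_ovmb("day lists must be strictly increasing")
  }
  if (!1L %in% main_days) {
    abort_ovmb("main_days must include the baseline day 1")
  }
  if (length(recovery_days) && min(recovery_days) <= max(main_days)) {
    abort_ovmb("recovery days must follow the main period")
  }
  if (recovery_animals_per_group > animals_per_group) {
    abort_ovmb("recovery_animals_per_group cannot exceed animals_per_group")
  }
  if (!all(recovery_groups %in% groups)) {
    abort_ovmb("recovery_groups must be a subset of groups")
  }
  structure(
    list(
      groups = groups,
      animals_per_group = as.integer(animals_per_group),
      main_days = main_days,
      recovery_days = recovery_days,
      recovery_animals_per_group = as.integer(recovery_animals_per_group),
      recovery_groups = recovery_groups
    ),
    class = "vmb_design"
  )
}

default_treatment_effects <- function() {
  list(
    Sham = list(load_shift_log10 = 0, enriched_taxa = character(),
                enrichment_fold = 1, persist_recovery = FALSE),
    HEC = list(load_shift_log10 = 0, enriched_taxa = character(),
               enrichment_fold = 1, persist_recovery = FALSE),
    N9 = list(load_shift_log10 = 0.3, enriched_taxa = "Haemophilus",
              enrichment_fold = 8, persist_recovery = FALSE),
    BZK = list(load_shift_log10 = -1, enriched_taxa = "Corynebacterium",
               enrichment_fold = 150, persist_recovery = TRUE)
  )
}

default_cytokine_params <- function() {
  list(
    IL8 = list(baseline_od_mean = 0.40, baseline_od_sd = 0.15,
               inflamed_od_shift = 0.6, detection_dropout_prob = 0.08),
    IL1B = list(baseline_od_mean = 0.35, baseline_od_sd = 0.15,
                inflamed_od_shift = 0.6, detection_dropout_prob = 0.24),
    TNFA = list(baseline_od_mean = 0.30, baseline_od_sd = 0.12,
                inflamed_od_shift = 0.6, detection_dropout_prob = 0.40),
    CXCL10 = list(baseline_od_mean = 0.30, baseline_od_sd = 0.12,
                  inflamed_od_shift = 0.6, detection_dropout_prob = 0.45),
    IL6 = list(baseline_od_mean = 0.20, baseline_od_sd = 0.10,
               inflamed_od_shift = 0, detection_dropout_prob = 0.95),
    IL17A = list(baseline_od_mean = 0.20, baseline_od_sd = 0.10,
                 inflamed_od_shift = 0, detection_dropout_prob = 0.90)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' conditions the pipeline was designed for: a vaginal microbiome dominated
#' by the Actinobacillus/Haemophilus community type with Pseudomonas- and
#' E. coli-dominant minorities (pre-dose distribution roughly 70/16/14),
#' log-normal total bacterial loads around 10^6 copies/ul, benzalkonium
#' chloride (BZK) suppressing total load one log while enriching
#' Corynebacterium, nonoxynol-9 (N9) enriching Haemophilus with mild
#' overgrowth, and ELISA optical densities in which IL-6/IL-17A suffer heavy
#' detection dropout while IL-8 is detected in about 92% of samples.
#'
#' @param seed Integer seed; all per-sample draws use counter-based
#'   substreams derived from it, so subsetting a design never shifts other
#'   samples' values.
#' @param ct_priors Named probabilities over catalog CT labels used to draw
#'   each animal's resident community type; must sum to 1.
#' @param dominance_mass Fraction of the community assigned jointly to a
#'   CT's biomarker taxa (split evenly in combination CTs), in (0, 1).
#' @param total_load_log10_mean,total_load_log10_sd Log10 copies/ul of the
#'   total community load.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for the
#'   non-biomarker remainder of the community.
#' @param treatment_effects Per-group list with `load_shift_log10`,
#'   `enriched_taxa`, `enrichment_fold` (>= 1) and `persist_recovery`.
#'   Effects apply on post-baseline main-period days; `persist_recovery`
#'   extends the enrichment into the recovery window.
#' @param cytokine_params Per-cytokine list with `baseline_od_mean`,
#'   `baseline_od_sd`, `inflamed_od_shift` and `detection_dropout_prob`.
#' @param detection_threshold OD490 above which a cytokine is called
#'   detected.
#' @param qc_fail_prob Probability that a swab fails collection (simulated
#'   as a below-threshold shGAPDH yield).
#' @param inflamed_prob Named probabilities that a sample drawn from an
#'   eubiotic / dysbiotic / indeterminate CT is in an inflamed state.
#' @param shgapdh_log10_mean,shgapdh_log10_sd Log10 copies/ul of the host
#'   cell control target.
#' @param coverage_range Range of the fraction of universal 16S copies
#'   accounted for by the 46 panel targets.
#' @param taxa Taxon panel (defaults to [vmb_taxa()]).
#' @param catalog CT catalog (defaults to [ct_catalog()]).
#' @return A list of class `vmb_sim_config`.
#' @export
#' @examples
#' cfg <- vmb_sim_config(seed = 42)
#' cfg$dominance_mass
vmb_sim_config <- function(seed = 1L,
                           ct_priors = c("A-H" = 0.70, "Ps" = 0.16,
                                         "Ec" = 0.14),
                           dominance_mass = 0.7,
                           total_load_log10_mean = 6.0,
                           total_load_log10_sd = 0.5,
                           dirichlet_alpha = 1.0,
                           treatment_effects = default_treatment_effects(),
                           cytokine_params = default_cytokine_params(),
                           detection_threshold = 0.05,
                           qc_fail_prob = 0.02,
                           inflamed_prob = c(eubiotic = 0.1,
                                             dysbiotic = 0.9,
                                             indeterminate = 0.5),
                           shgapdh_log10_mean = 5.5,
                           shgapdh_log10_sd = 0.3,
                           coverage_range = c(0.92, 0.99),
                           taxa = vmb_taxa(),
                           catalog = ct_catalog()) {
  if (abs(sum(ct_priors) - 1) > 1e-8) {
    abort_ovmb("ct_priors must sum to 1")
  }
  if (any(ct_priors < 0) || any(ct_priors > 1)) {
    abort_ovmb("ct_priors must be probabilities in [0, 1]")
  }
  if (dominance_mass <= 0 || dominance_mass >= 1) {
    abort_ovmb("dominance_mass must be in (0, 1)")
  }
  if (qc_fail_prob < 0 || qc_fail_prob > 1) {
    abort_ovmb("qc_fail_prob must be a probability")
  }
  if (!all(names(ct_priors) %in% catalog$label)) {
    abort_ovmb("ct_priors names must be catalog CT labels")
  }
  folds <- vapply(treatment_effects, function(e) e$enrichment_fold, 1)
  if (any(folds < 1)) abort_ovmb("enrichment_fold must be >= 1")
  structure(
    list(
      seed = as.integer(seed), ct_priors = ct_priors,
      dominance_mass = dominance_mass,
      total_load_log10_mean = total_load_log10_mean,
      total_load_log10_sd = total_load_log10_sd,
      dirichlet_alpha = dirichlet_alpha,
      treatment_effects = treatment_effects,
      cytokine_params = cytokine_params,
      detection_threshold = detection_threshold,
      qc_fail_prob = qc_fail_prob,
      inflamed_prob = inflamed_prob,
      shgapdh_log10_mean = shgapdh_log10_mean,
      shgapdh_log10_sd = shgapdh_log10_sd,
      coverage_range = coverage_range,
      taxa = taxa, catalog = catalog
    ),
    class = "vmb_sim_config"
  )
}

#' Simulate one bacterial community
#'
#' Draws a copies/ul vector for the 46-taxon panel given a community type:
#' the CT's biomarker taxa jointly receive `dominance_mass` of the community
#' (split evenly among the biomarkers of a combination CT), the remainder is
#' spread over the other taxa by a symmetric Dirichlet draw, and the whole
#' vector is scaled to a log-normal total load.
#'
#' @param ct_label A CT label present in `config$catalog`.
#' @param config A [vmb_sim_config()].
#' @param seed Integer seed for this draw.
#' @return Named numeric vector of copies/ul over `config$taxa`.
#' @export
#' @examples
#' copies <- simulate_community("Cy", vmb_sim_config(), seed = 7)
#' copies[["Corynebacterium"]] / sum(copies)
simulate_community <- function(ct_label, config, seed) {
  taxa <- config$taxa
  row <- which(config$catalog$label == ct_label)
  if (length(row) != 1) {
    abort_ovmb(sprintf("unknown CT label '%s'", ct_label))
  }
  biomarkers <- config$catalog$biomarkers[[row]]
  if (!all(biomarkers %in% taxa)) {
    abort_ovmb(sprintf(
      "CT '%s' has biomarker(s) outside the taxon panel", ct_label
    ))
  }
  with_seed(seed, {
    ra <- setNames(numeric(length(taxa)), taxa)
    ra[biomarkers] <- config$dominance_mass / length(biomarkers)
    others <- setdiff(taxa, biomarkers)
    w <- rgamma(length(others), shape = config$dirichlet_alpha, rate = 1)
    ra[others] <- (1 - config$dominance_mass) * w / sum(w)
    total <- 10^rnorm(1, config$total_load_log10_mean,
                      config$total_load_log10_sd)
    ra * total
  })
}

#' Simulate one ELISA cytokine panel
#'
#' Draws OD490 absorbances for the six-cytokine panel. An inflamed state
#' shifts the mean OD of the four analyzable targets upward by each
#' cytokine's `inflamed_od_shift`. Detection dropout emulates cytokine
#' concentrations below the assay threshold in quiescent vaginal fluid:
#' with probability `detection_dropout_prob` the OD is replaced by
#' sub-threshold noise and the `detected` flag cleared. Because an inflamed
#' mucosa secretes the shifted cytokines at readily detectable levels,
#' dropout does not apply to a cytokine whose inflamed shift is acting
#' (IL-6 and IL-17A carry no shift, so their heavy dropout applies in
#' every state).
#'
#' @param inflamed Logical, the generating inflammation state.
#' @param config A [vmb_sim_config()].
#' @param seed Integer seed for this draw.
#' @return Tibble with columns `cytokine`, `od`, `detected`.
#' @export
#' @examples
#' simulate_cytokines(TRUE, vmb_sim_config(), seed = 3)
simulate_cytokines <- function(inflamed, config, seed) {
  params <- config$cytokine_params
  thr <- config$detection_threshold
  with_seed(seed, {
    rows <- purrr::imap(params, function(p, name) {
      mu <- p$baseline_od_mean + if (inflamed) p$inflamed_od_shift else 0
      od <- max(rnorm(1, mu, p$baseline_od_sd), 0)
      dropout <- runif(1) < p$detection_dropout_prob &&
        !(inflamed && p$inflamed_od_shift > 0)
      if (dropout) od <- runif(1, 0, thr)
      tibble::tibble(cytokine = name, od = od, detected = od > thr)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a complete synthetic study dataset
#'
#' Produces one sample per animal x sampling day under a study design: a
#' wide qPCR sample table (46 taxon targets + shGAPDH + universal 16S, all
#' copies/ul), a long cytokine table, and a truth table recording each
#' sample's generating CT and inflamed state. Each animal keeps a resident
#' CT drawn from `ct_priors`; treatment effects multiply the enriched taxa
#' and shift total load on post-baseline dosing days (and through recovery
#' when `persist_recovery` is set). Identical `(design, config)` input
#' yields byte-identical output.
#'
#' @param design A [vmb_design()].
#' @param config A [vmb_sim_config()]; its `seed` drives all randomness.
#' @return List of class `vmb_dataset` with tibbles `samples`, `cytokines`,
#'   `truth` and the echoed `design`/`config`.
#' @export
#' @examples
#' ds <- simulate_vmb_dataset(vmb_design(animals_per_group = 2),
#'                            vmb_sim_config(seed = 1))
#' nrow(ds$samples)
simulate_vmb_dataset <- function(design, config = vmb_sim_config()) {
  stopifnot(inherits(design, "vmb_design"), inherits(config, "vmb_sim_config"))
  seed <- config$seed
  catalog <- config$catalog

  schedule <- purrr::map_dfr(design$groups, function(g) {
    animals <- sprintf("%s-%02d", g, seq_len(design$animals_per_group))
    main <- tidyr::expand_grid(animal_id = animals,
                               study_day = design$main_days) |>
      dplyr::mutate(period = "main")
    rec <- NULL
    if (g %in% design$recovery_groups && length(design$recovery_days)) {
      rec_animals <- animals[seq_len(design$recovery_animals_per_group)]
      rec <- tidyr::expand_grid(animal_id = rec_animals,
                                study_day = design$recovery_days) |>
        dplyr::mutate(period = "recovery")
    }
    dplyr::bind_rows(main, rec) |> dplyr::mutate(group = g)
  })
  schedule <- schedule |>
    dplyr::arrange(.data$group, .data$animal_id, .data$study_day) |>
    dplyr::mutate(
      sample_id = sprintf("%s-D%02d", .data$animal_id, .data$study_day),
      sample_index = dplyr::row_number()
    )

  # one resident CT and a per-day inflamed flag per animal
  animals <- unique(schedule$animal_id)
  animal_ct <- setNames(character(length(animals)), animals)
  for (i in seq_along(animals)) {
    animal_ct[i] <- with_seed(
      child_seed(seed, i, stage = 1L),
      sample(names(config$ct_priors), 1, prob = config$ct_priors)
    )
  }

  biosis_of <- setNames(catalog$biosis, catalog$label)

  per_sample <- purrr::pmap(schedule, function(animal_id, study_day, period,
                                               group, sample_id,
                                               sample_index) {
    ct <- animal_ct[[animal_id]]
    copies <- simulate_community(ct, config,
                                 child_seed(seed, sample_index, stage = 2L))

    eff <- config$treatment_effects[[group]]
    dosing_day <- period == "main" && study_day > 1L
    effect_on <- !is.null(eff) &&
      (dosing_day || (period == "recovery" && isTRUE(eff$persist_recovery)))
    if (effect_on) {
      total0 <- sum(copies)
      hit <- intersect(eff$enriched_taxa, names(copies))
      copies[hit] <- copies[hit] * eff$enrichment_fold
      copies <- copies * (total0 / sum(copies)) # renormalize composition
      copies <- copies * 10^eff$load_shift_log10
    }

    aux <- with_seed(child_seed(seed, sample_index, stage = 3L), {
      qc_fail <- runif(1) < config$qc_fail_prob
      shgapdh <- if (qc_fail) {
        10^runif(1, 2.5, 3.9) # below the 1e4 copies/ul inclusion gate
      } else {
        10^rnorm(1, config$shgapdh_log10_mean, config$shgapdh_log10_sd)
      }
      coverage <- runif(1, config$coverage_range[1], config$coverage_range[2])
      p_infl <- config$inflamed_prob[[biosis_of[[ct]]]]
      inflamed <- runif(1) < p_infl
      list(shgapdh = shgapdh, coverage = coverage, inflamed = inflamed)
    })

    cyt <- simulate_cytokines(aux$inflamed, config,
                              child_seed(seed, sample_index, stage = 4L)) |>
      dplyr::mutate(sample_id = sample_id, .before = 1)

    sample_row <- tibble::tibble(
      sample_id = sample_id, animal_id = animal_id, group = group,
      study_day = study_day, period = period,
      shgapdh = aux$shgapdh, univ16s = sum(copies) / aux$coverage
    )
    sample_row[names(copies)] <- as.list(copies)

    truth_row <- tibble::tibble(
      sample_id = sample_id, true_ct = ct,
      true_biosis = biosis_of[[ct]], inflamed = aux$inflamed
    )
    list(sample = sample_row, cyt = cyt, truth = truth_row)
  })

  structure(
    list(
      samples = dplyr::bind_rows(purrr::map(per_sample, "sample")),
      cytokines = dplyr::bind_rows(purrr::map(per_sample, "cyt")),
      truth = dplyr::bind_rows(purrr::map(per_sample, "truth")),
      design = design, config = config
    ),
    class = "vmb_dataset"
  )
}

#' @export
print.vmb_dataset <- function(x, ...) {
  cat("<vmb_dataset>\n")
  cat(sprintf("  samples:   %d (%d taxa + 2 controls)\n",
              nrow(x$samples), length(x$config$taxa)))
  cat(sprintf("  cytokines: %d rows (%d panels)\n",
              nrow(x$cytokines), length(unique(x$cytokines$sample_id))))
  cat(sprintf("  groups:    %s\n", paste(x$design$groups, collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to TSV files
#'
#' @param dataset A `vmb_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`samples.tsv`, `cytokines.tsv`,
#'   `truth.tsv`).
#' @export
write_vmb_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "vmb_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("samples.tsv", "cytokines.tsv", "truth.tsv"))
  readr::write_tsv(dataset$samples, paths[1])
  readr::write_tsv(dataset$cytokines, paths[2])
  readr::write_tsv(dataset$truth, paths[3])
  invisible(paths)
}
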