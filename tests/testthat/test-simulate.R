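test_that("a fixed seed reproduces the dataset byte for byte", {
  ds1 <- small_dataset(seed = 7)
  ds2 <- small_dataset(seed = 7)
  expect_identical(
    serialize(ds1[c("samples", "cytokines", "truth")], NULL),
    serialize(ds2[c("samples", "cytokines", "truth")], NULL)
  )
  ds3 <- small_dataset(seed = 8)
  expect_false(identical(ds1$samples, ds3$samples))
})

test_that("sample counts follow the design: one sample per animal x day", {
  ds <- simulate_vmb_dataset(vmb_design(), vmb_sim_config(seed = 3))
  main <- dplyr::filter(ds$samples, period == "main")
  expect_equal(nrow(main), 4 * 9 * 6) # 216 main-period samples
  rec <- dplyr::filter(ds$samples, period == "recovery")
  expect_equal(nrow(rec), 3 * 4 * 5) # treated groups only
  expect_equal(anyDuplicated(ds$samples$sample_id), 0)
  # every sample carries all 48 targets
  expect_true(all(c(vmb_taxa(), "shgapdh", "univ16s") %in%
                    names(ds$samples)))
  expect_equal(nrow(ds$truth), nrow(ds$samples))
})

test_that("qc_fail_prob = 0 yields no samples below the inclusion gates", {
  # untreated arms only: a strong load-suppressing treatment can push 16S
  # below the gate on its own, which is a treatment effect, not a
  # collection failure
  ds <- simulate_vmb_dataset(
    vmb_design(groups = c("Sham", "HEC"), animals_per_group = 3,
               recovery_animals_per_group = 1,
               recovery_groups = "HEC"),
    vmb_sim_config(seed = 5, qc_fail_prob = 0)
  )
  qc <- assess_quality(ds$samples)
  expect_true(all(qc$qc_status == "pass"))
})

test_that("biomarkers receive the configured dominance mass", {
  cfg <- vmb_sim_config(seed = 1, dominance_mass = 0.8)
  ras <- vapply(1:1000, function(i) {
    copies <- simulate_community("Cy", cfg, seed = i)
    copies[["Corynebacterium"]] / sum(copies)
  }, numeric(1))
  se <- sd(ras) / sqrt(length(ras))
  expect_lt(abs(mean(ras) - 0.8), 3 * se + 1e-12)

  # two-biomarker CT splits the mass evenly
  cfg7 <- vmb_sim_config(seed = 1, dominance_mass = 0.7)
  copies <- simulate_community("A-H", cfg7, seed = 42)
  ra <- copies / sum(copies)
  expect_equal(unname(ra["Actinobacillus"]), 0.35, tolerance = 1e-12)
  expect_equal(unname(ra["Haemophilus"]), 0.35, tolerance = 1e-12)
})

test_that("dominance_mass near 1 starves the non-biomarker taxa", {
  cfg <- vmb_sim_config(seed = 2, dominance_mass = 0.999)
  copies <- simulate_community("Ps", cfg, seed = 9)
  ra <- copies / sum(copies)
  expect_lt(max(ra[setdiff(names(ra), "Pseudomonas")]), 0.002)
  expect_true(all(copies >= 0))
})

test_that("unknown CT or off-panel biomarker is rejected", {
  cfg <- vmb_sim_config(seed = 1)
  expect_error(simulate_community("nope", cfg, seed = 1), "unknown CT")
  cat_bad <- ct_catalog()
  cat_bad$biomarkers[[1]] <- c("NotATaxon")
  cfg_bad <- vmb_sim_config(seed = 1, catalog = cat_bad,
                            ct_priors = c("A-H-Ps" = 1))
  expect_error(simulate_community("A-H-Ps", cfg_bad, seed = 1),
               "outside the taxon panel")
})

test_that("detection dropout calibrates the detection frequency", {
  cfg <- vmb_sim_config(seed = 4)
  panels <- purrr::map_dfr(1:1000, function(i) {
    simulate_cytokines(FALSE, cfg, seed = i)
  })
  freq <- panels |>
    dplyr::group_by(cytokine) |>
    dplyr::summarise(f = mean(detected))
  il6 <- freq$f[freq$cytokine == "IL6"]
  il8 <- freq$f[freq$cytokine == "IL8"]
  # binomial 3-SE bands around the configured dropout rates
  expect_lt(abs(il6 - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(abs(il8 - 0.92), 3 * sqrt(0.92 * 0.08 / 1000))
})

test_that("a zero inflamed shift leaves the OD law unchanged", {
  cfg <- vmb_sim_config(seed = 6)
  cfg$cytokine_params <- lapply(cfg$cytokine_params, function(p) {
    p$inflamed_od_shift <- 0
    p
  })
  a <- simulate_cytokines(TRUE, cfg, seed = 11)
  b <- simulate_cytokines(FALSE, cfg, seed = 11)
  expect_equal(a$od, b$od)
  expect_equal(a$detected, b$detected)
})

test_that("invalid configurations are rejected before any generation", {
  expect_error(vmb_sim_config(ct_priors = c("A-H" = 0.5, Ps = 0.2)),
               "sum to 1")
  expect_error(vmb_sim_config(dominance_mass = 1), "dominance_mass")
  expect_error(vmb_sim_config(qc_fail_prob = 1.5), "probability")
  expect_error(vmb_design(main_days = c(2, 3)), "baseline day 1")
  expect_error(vmb_design(main_days = c(1, 3, 2)), "strictly increasing")
  expect_error(
    vmb_design(animals_per_group = 2, recovery_animals_per_group = 3),
    "cannot exceed"
  )
})

test_that("a negative BZK load shift depresses post-dose 16S fold change", {
  signs <- vapply(1:20, function(s) {
    ds <- simulate_vmb_dataset(
      vmb_design(groups = c("Sham", "BZK"), animals_per_group = 4,
                 recovery_days = integer(),
                 recovery_animals_per_group = 0,
                 recovery_groups = character()),
      vmb_sim_config(seed = 4000 + s, qc_fail_prob = 0)
    )
    fc <- log_fold_change(ds$samples, target = "univ16s")
    post <- dplyr::filter(fc, group == "BZK", study_day > 1,
                          period == "main")
    mean(post$log10_fc)
  }, numeric(1))
  expect_true(all(signs < 0))
})
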