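test_that("detection frequency gates non-analyzable cytokines", {
  panels <- tibble::tibble(
    sample_id = rep(1:264, 2),
    cytokine = rep(c("IL8", "IL6"), each = 264),
    detected = c(rep(c(TRUE, FALSE), c(243, 21)),
                 rep(c(TRUE, FALSE), c(40, 224)))
  )
  freq <- detection_frequency(panels)
  il8 <- freq[freq$cytokine == "IL8", ]
  expect_equal(il8$frequency, 243 / 264, tolerance = 1e-12)
  expect_equal(round_half_up(100 * il8$frequency, 0), 92)
  expect_true(il8$analyzable)
  expect_false(freq$analyzable[freq$cytokine == "IL6"])

  all_det <- tibble::tibble(sample_id = 1:5, cytokine = "TNFA",
                            detected = TRUE)
  expect_equal(detection_frequency(all_det)$frequency, 1)
  expect_error(detection_frequency(panels[0, ]), "empty")
})

test_that("threshold schemes match their order-statistics oracles", {
  p <- tibble::tibble(sample_id = 1:100, cytokine = "IL8",
                      od = as.numeric(1:100))
  expect_equal(derive_thresholds(p, "percentile")$cutoff, 59.41,
               tolerance = 1e-9)
  expect_equal(derive_thresholds(p, "mean")$cutoff, 50.5)

  set.seed(8)
  u <- tibble::tibble(sample_id = 1:999, cytokine = "IL8",
                      od = runif(999))
  tert <- derive_thresholds(u, "tertile")
  expect_equal(tert$cutoff_low, 1 / 3, tolerance = 0.05)
  expect_equal(tert$cutoff, 2 / 3, tolerance = 0.05)

  # symmetric data under the mean split: half the samples are high
  sym <- tibble::tibble(sample_id = 1:101, cytokine = "IL8",
                        od = seq(0, 1, length.out = 101))
  calls <- cytokine_calls(sym, derive_thresholds(sym, "mean"))
  expect_equal(sum(calls$call == "H"), 50)

  const <- tibble::tibble(sample_id = 1:5, cytokine = "IL8", od = 2)
  expect_warning(cuts <- derive_thresholds(const, "percentile"),
                 "degenerate")
  expect_equal(cytokine_calls(const, cuts)$call, rep("L", 5))
})

test_that("vote rules classify according to the model", {
  four <- vmb_cytokines_analyzable()
  cuts <- tibble::tibble(cytokine = four, cutoff = 0.5,
                         scheme = "percentile")
  hi4 <- make_panel(setNames(rep(0.9, 4), four))
  lo2 <- make_panel(setNames(c(0.9, 0.9, 0.1, 0.1), four))
  infl1 <- infl_model("Infl1")
  expect_true(classify_inflammation(hi4, infl1, cuts)$inflamed)
  expect_false(classify_inflammation(lo2, infl1, cuts)$inflamed) # 2 < 3

  infl4 <- infl_model("Infl4")
  mixed <- make_panel(c(IL8 = 0.9, IL1B = 0.1))
  expect_true(classify_inflammation(mixed, infl4,
                                    cuts[cuts$cytokine %in%
                                           c("IL8", "IL1B"), ])$inflamed)

  expect_error(
    classify_inflammation(make_panel(c(IL8 = 0.9)), infl1, cuts),
    "missing"
  )
  expect_error(infl_model("Infl4", votes_required = 3), "votes_required")
})

test_that("raising an OD never flips inflamed to normal", {
  four <- vmb_cytokines_analyzable()
  cuts <- tibble::tibble(cytokine = four, cutoff = 0.5,
                         scheme = "percentile")
  set.seed(5)
  model <- infl_model("Infl1")
  for (i in 1:30) {
    od <- setNames(runif(4), four)
    before <- classify_inflammation(make_panel(od), model, cuts)$inflamed
    od[sample(4, 1)] <- od[sample(4, 1)] + runif(1, 0, 2)
    after <- classify_inflammation(make_panel(od), model, cuts)$inflamed
    if (before) expect_true(after)
  }
})

test_that("affine OD rescaling moves cutoffs equivariantly, calls unchanged", {
  set.seed(6)
  p <- tibble::tibble(sample_id = 1:60, cytokine = "IL8",
                      od = rlnorm(60))
  a <- 3.7
  b <- 0.2
  p2 <- dplyr::mutate(p, od = a * od + b)
  c1 <- derive_thresholds(p, "percentile")
  c2 <- derive_thresholds(p2, "percentile")
  expect_equal(c2$cutoff, a * c1$cutoff + b, tolerance = 1e-9)
  expect_equal(cytokine_calls(p, c1)$call, cytokine_calls(p2, c2)$call)
})

test_that("inflammation percentages use half-up integer rounding", {
  expect_equal(summarize_inflammation(rep(c(TRUE, FALSE), c(174, 90)))$percent, 66)
  expect_equal(summarize_inflammation(rep(c(TRUE, FALSE), c(95, 169)))$percent, 36)
  expect_equal(summarize_inflammation(rep(c(TRUE, FALSE), c(163, 101)))$percent, 62)
  expect_equal(summarize_inflammation(rep(FALSE, 20))$percent, 0)
  expect_error(summarize_inflammation(logical(0)), "no inflammation calls")
})

test_that("a strong OD shift makes the generating state recoverable", {
  cfg <- vmb_sim_config(seed = 5)
  set.seed(5)
  truth <- rep(c(TRUE, FALSE), 200)
  panels <- purrr::map_dfr(seq_along(truth), function(i) {
    dplyr::mutate(simulate_cytokines(truth[i], cfg, seed = i),
                  sample_id = paste0("s", i))
  })
  res <- classify_inflammation(panels, infl_model("Infl4"))
  t_res <- truth[match(res$sample_id, paste0("s", seq_along(truth)))]
  expect_gte(mean(res$inflamed[t_res]), 0.9)      # sensitivity
  expect_gte(mean(!res$inflamed[!t_res]), 0.9)    # specificity
})
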