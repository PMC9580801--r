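make_fc_samples <- function(values_by_day, animal = "a1", group = "g") {
  tibble::tibble(
    animal_id = animal, group = group,
    study_day = as.integer(names(values_by_day)),
    period = ifelse(as.integer(names(values_by_day)) <= 10,
                    "main", "recovery"),
    univ16s = unname(values_by_day)
  )
}

test_that("fold change is per-animal log10 relative to the day-1 baseline", {
  s <- make_fc_samples(c(`1` = 1e5, `3` = 1e5, `5` = 1e6, `7` = 10^4.5))
  fc <- log_fold_change(s, "univ16s")
  expect_equal(fc$log10_fc[fc$study_day == 1], 0)
  expect_equal(fc$log10_fc[fc$study_day == 3], 0)
  expect_equal(fc$log10_fc[fc$study_day == 5], 1)
  expect_equal(fc$log10_fc[fc$study_day == 7], -0.5)
  mx <- fc_period_max(fc)
  expect_equal(mx$max_fc[mx$period == "main"], 1)

  # zero values are floored at one copy, keeping the change finite
  z <- make_fc_samples(c(`1` = 1e3, `2` = 0))
  expect_equal(log_fold_change(z, "univ16s")$log10_fc[2], -3)

  nb <- dplyr::bind_rows(
    make_fc_samples(c(`2` = 1e5), animal = "nobase"),
    make_fc_samples(c(`1` = 1e5, `2` = 1e5), animal = "ok")
  )
  expect_warning(fc2 <- log_fold_change(nb, "univ16s"), "nobase")
  expect_false("nobase" %in% fc2$animal_id)
})

test_that("group comparison gates on normality and takes the right branch", {
  set.seed(2)
  null_df <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 9),
    log10_fc = rep(c(1, 2, 3), 9)
  )
  res <- group_compare_fc(null_df)
  expect_gt(res$omnibus$p_value, 0.9)
  expect_true(all(tidy(res)$p_adjusted > 0.9))

  shifted <- tibble::tibble(
    group = rep(c("a", "b"), each = 9),
    log10_fc = c(rnorm(9, 0, 1), rnorm(9, 3, 1))
  )
  res2 <- group_compare_fc(shifted)
  expect_equal(res2$branch, "parametric")
  expect_equal(glance(res2)$method, "one-way ANOVA")
  expect_lt(res2$omnibus$p_value, 0.01)
  expect_true(all(tidy(res2)$p_adjusted < 0.05))

  heavy <- tibble::tibble(
    group = rep(c("a", "b"), each = 30),
    log10_fc = rcauchy(60)
  )
  res3 <- group_compare_fc(heavy)
  expect_equal(res3$branch, "nonparametric")
  expect_match(tidy(res3)$adjustment[1], "Holm")

  expect_error(group_compare_fc(null_df[1:9, ]), ">= 2 groups")
})

test_that("KS on CT counts matches the cumulative-difference oracle", {
  a <- c("A-H" = 5, Ps = 5)
  same <- ks_ct_distribution(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  extreme <- ks_ct_distribution(c(x = 10, y = 0), c(x = 0, y = 10))
  expect_equal(extreme$statistic, 1)

  n9 <- c("A-H" = 30, Ps = 1, Ec = 0, H = 17, Cy = 5, U = 1)
  notx <- c("A-H" = 37, Ps = 9, Ec = 5, H = 0, Cy = 0, U = 0)
  ks <- ks_ct_distribution(n9, notx)
  expect_equal(ks$statistic, ks_d_oracle(n9, notx), tolerance = 1e-12)
  # D is invariant to rescaling either count vector
  ks3 <- ks_ct_distribution(n9 * 3, notx)
  expect_equal(ks3$statistic, ks$statistic, tolerance = 1e-12)

  expect_error(ks_ct_distribution(c(a = 1), c(b = 1)), "share one CT set")
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  balanced <- tibble::tibble(group = rep(c("g1", "g2"), each = 2),
                             ct_label = rep(c("X", "other"), 2),
                             n = c(5, 5, 5, 5))
  expect_equal(fisher_per_ct(balanced)$p_value, c(1, 1))

  crossed <- matrix(c(3, 7, 7, 3), nrow = 2, byrow = TRUE)
  counts <- tibble::tibble(group = rep(c("g1", "g2"), each = 2),
                           ct_label = rep(c("X", "other"), 2),
                           n = c(3, 7, 7, 3))
  got <- fisher_per_ct(counts)
  expect_equal(got$p_value[got$ct_label == "X"],
               fisher_enumeration_oracle(crossed), tolerance = 1e-12)

  # random 2x2 tables with margins <= 60 agree with brute force
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), nrow = 2)
    cnt <- tibble::tibble(group = rep(c("a", "b"), each = 2),
                          ct_label = rep(c("X", "other"), 2),
                          n = c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_per_ct(cnt)$p_value[1],
                 fisher_enumeration_oracle(tab), tolerance = 1e-12)
  }

  # zero-margin tables take p = 1 by convention and are flagged
  degen <- tibble::tibble(group = rep(c("a", "b"), each = 2),
                          ct_label = rep(c("X", "other"), 2),
                          n = c(0, 10, 0, 12))
  out <- fisher_per_ct(degen)
  expect_true(out$degenerate[out$ct_label == "X"])
  expect_equal(out$p_value[out$ct_label == "X"], 1)
})

test_that("BH adjustment is monotone and bounded below by the smallest p", {
  set.seed(12)
  p <- runif(40)^2
  q <- p.adjust(p, method = "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_gte(min(q), min(p))
})

test_that("two-part statistic combines zero and rank information", {
  x <- c(0, 0, 1, 2, 3)
  same <- two_part_test(x, x)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  # zero proportions 0.8 vs 0.2 at n = 50 with identical nonzero values:
  # the chi-square reduces to the two-proportion Z part
  nz <- seq(0.1, 1, length.out = 10)
  a <- c(rep(0, 40), nz)
  b <- c(rep(0, 10), rep(nz, 4))
  res <- two_part_test(a, b)
  z_expected <- (0.8 - 0.2) / sqrt(0.5 * 0.5 * (2 / 50))
  expect_equal(res$z_zero, z_expected, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)

  zz <- two_part_test(rep(0, 5), rep(0, 6))
  expect_equal(zz$chi2, 0)
  expect_equal(zz$p_value, 1)
  expect_true(zz$nonzero_degenerate)

  td <- tidy(res)
  expect_equal(td$statistic, res$chi2)
  expect_equal(td$df, 2L)
})

test_that("relative-abundance comparisons flag directed shifts only", {
  set.seed(31)
  taxa <- c("Corynebacterium", "Pseudomonas", "Haemophilus")
  base <- tidyr::expand_grid(
    group = c("HEC", "BZK"), rep = 1:10, taxon = taxa
  ) |>
    dplyr::mutate(
      sample_id = paste(group, rep, sep = "-"),
      study_day = 7L,
      rel_abundance = runif(dplyr::n(), 0.1, 0.4)
    )
  null_res <- ra_comparison(base)
  expect_false(any(null_res$significant_wilcoxon))

  shifted <- base |>
    dplyr::mutate(rel_abundance = ifelse(
      group == "BZK" & taxon == "Corynebacterium",
      rel_abundance + 0.5, rel_abundance
    ))
  res <- ra_comparison(shifted)
  hit <- res[res$taxon == "Corynebacterium", ]
  expect_true(hit$significant_wilcoxon)
  expect_true(hit$significant_two_part)
  expect_equal(hit$higher_in, "BZK")
  expect_false(any(res$significant_wilcoxon[res$taxon != "Corynebacterium"]))
})

test_that("Welch comparison of diversity matches the closed form", {
  eq <- sdi_compare(rep(2, 5), rep(2, 7))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  x <- as.numeric(scale(rnorm(10))) + 2 # mean 2, sd 1 exactly
  y <- as.numeric(scale(rnorm(10)))     # mean 0, sd 1 exactly
  res <- sdi_compare(x, y)
  expect_equal(res$statistic, 2 / sqrt(2 / 10), tolerance = 1e-9)

  set.seed(77)
  a <- rnorm(8, sd = 3)
  b <- rnorm(15, sd = 0.5)
  df <- sdi_compare(a, b)$df
  expect_gte(df, min(8, 15) - 1)
  expect_lte(df, 8 + 15 - 2)
})
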