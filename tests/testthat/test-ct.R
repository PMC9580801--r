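test_that("uncentered-correlation clustering separates dominance groups", {
  # identical profiles sit at distance zero
  p <- dplyr::bind_rows(make_profile("Pseudomonas", 0.7, "a"),
                        make_profile("Pseudomonas", 0.7, "b"))
  cl <- cluster_profiles(p, k = 1)
  expect_equal(max(cl$dist), 0, tolerance = 1e-12)

  # profiles on orthogonal taxa are at the maximal distance 1
  ortho <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 2),
    taxon = c("Pseudomonas", "Corynebacterium",
              "Haemophilus", "Ureaplasma"),
    rel_abundance = c(0.5, 0.5, 0.5, 0.5)
  )
  expect_equal(max(cluster_profiles(ortho)$dist), 1, tolerance = 1e-12)

  # 3 Corynebacterium- + 3 Pseudomonas-dominant profiles cut at k = 2
  cfg <- vmb_sim_config(seed = 21)
  wide <- purrr::map_dfr(1:6, function(i) {
    ct <- if (i <= 3) "Cy" else "Ps"
    copies <- simulate_community(ct, cfg, seed = i)
    row <- tibble::tibble(sample_id = paste0("s", i), shgapdh = 1e5,
                          univ16s = sum(copies) / 0.95)
    row[names(copies)] <- as.list(copies)
    row
  })
  cl2 <- cluster_profiles(compute_profiles(wide), k = 2)
  groups <- cl2$membership$cluster
  expect_equal(length(unique(groups[1:3])), 1)
  expect_equal(length(unique(groups[4:6])), 1)
  expect_false(groups[1] == groups[4])

  expect_error(cluster_profiles(make_profile("Ps", 0.5)), "at least 2")
})

test_that("newick export writes a tree ape can parse", {
  p <- dplyr::bind_rows(make_profile("Pseudomonas", 0.7, "a"),
                        make_profile("Corynebacterium", 0.7, "b"),
                        make_profile("Haemophilus", 0.7, "c"))
  cl <- cluster_profiles(p)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})

test_that("CT assignment follows the dominance rules in catalog order", {
  # single-biomarker dominance
  expect_equal(assign_ct(make_profile("Corynebacterium", 0.70))$ct_label,
               "Cy")
  # nothing dominant: a uniform profile is untypable
  uniform <- tibble::tibble(sample_id = "u", taxon = vmb_taxa(),
                            rel_abundance = rep(1 / 46, 46))
  expect_equal(assign_ct(uniform)$ct_label, "untypable")
  # combination CT wins over its singleton components
  combo <- make_profile(c("Pasteurella", "Actinobacillus"), c(0.35, 0.30))
  expect_equal(assign_ct(combo)$ct_label, "Pa-Ac")
  # three-biomarker combination is evaluated before the two-biomarker one
  trip <- make_profile(c("Actinobacillus", "Haemophilus", "Pseudomonas"),
                       c(0.25, 0.25, 0.25))
  expect_equal(assign_ct(trip)$ct_label, "A-H-Ps")
  ah <- make_profile(c("Actinobacillus", "Haemophilus"), c(0.35, 0.30))
  expect_equal(assign_ct(ah)$ct_label, "A-H")
  # a 0.45 biomarker beats the 0.40 threshold only if it's the top biomarker
  shaded <- make_profile(c("Pseudomonas", "Corynebacterium"),
                         c(0.45, 0.50))
  expect_equal(assign_ct(shaded)$ct_label, "Cy")

  expect_error(assign_ct(make_profile("Ps", 0.5), ct_catalog()[0, ]),
               "empty")
})

test_that("CT assignment is scale invariant", {
  cfg <- vmb_sim_config(seed = 33)
  copies <- simulate_community("U", cfg, seed = 2)
  wide <- tibble::tibble(sample_id = "s", shgapdh = 1e5,
                         univ16s = sum(copies) / 0.95)
  wide[names(copies)] <- as.list(copies)
  big <- wide
  big[names(copies)] <- as.list(copies * 1e3)
  expect_equal(assign_ct(compute_profiles(wide))$ct_label,
               assign_ct(compute_profiles(big))$ct_label)
})

test_that("frequency tables print half-up percentages that sum to ~100", {
  labels <- tibble::tibble(
    group = rep("Pre-Dose", 37),
    ct_label = rep(c("A-H", "Ps", "Ec"), c(26, 6, 5))
  )
  tab <- ct_frequency_table(labels, group)
  expect_equal(tab$percent[tab$ct_label == "A-H"], 70.3)
  expect_equal(tab$percent[tab$ct_label == "Ps"], 16.2)
  expect_equal(tab$percent[tab$ct_label == "Ec"], 13.5)
  expect_equal(unique(tab$row_total), 37)

  single <- ct_frequency_table(
    tibble::tibble(group = "g", ct_label = rep("Cy", 12)), group
  )
  expect_equal(single$percent, 100.0)

  set.seed(3)
  rand <- tibble::tibble(
    group = sample(c("a", "b"), 200, replace = TRUE),
    ct_label = sample(ct_catalog()$label, 200, replace = TRUE)
  )
  sums <- ct_frequency_table(rand, group) |>
    dplyr::group_by(group) |>
    dplyr::summarise(s = sum(percent))
  expect_true(all(abs(sums$s - 100) <= 0.3))
})

test_that("pooled no-treatment counts are additive over their source rows", {
  counts <- vmb_reference_counts("ct_main")
  pooled <- counts |>
    dplyr::filter(group %in% c("Pre-Dose", "Sham")) |>
    dplyr::group_by(ct_label) |>
    dplyr::summarise(n = sum(n))
  expect_equal(pooled$n[pooled$ct_label == "A-H"], 37)
  expect_equal(pooled$n[pooled$ct_label == "Ps"], 9)
  expect_equal(sum(pooled$n), 51)
})
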