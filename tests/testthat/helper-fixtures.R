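# Shared fixtures and independent oracles used across the suite.

# A profile tibble with one sample dominated by `dominant` at `ra` and the
# remainder spread evenly over the other panel taxa.
make_profile <- function(dominant, ra, sample_id = "s1",
                         taxa = vmb_taxa()) {
  others <- setdiff(taxa, dominant)
  tibble::tibble(
    sample_id = sample_id,
    taxon = c(dominant, others),
    rel_abundance = c(ra, rep((1 - sum(ra)) / length(others),
                              length(others)))
  ) |>
    dplyr::mutate(copies = rel_abundance * 1e6)
}

# Long cytokine panel tibble from a named OD list for one sample.
make_panel <- function(od, sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, cytokine = names(od),
                 od = unname(unlist(od)))
}

# Brute-force two-sided Fisher exact p for a 2x2 table: enumerate every
# table with the observed margins and sum hypergeometric probabilities at
# most that of the observed table.
fisher_enumeration_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form OLS slope/intercept through the normal equations.
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

# Max absolute difference between the CDFs of two count vectors.
ks_d_oracle <- function(a, b) {
  max(abs(cumsum(a) / sum(a) - cumsum(b) / sum(b)))
}

# Small all-default simulated study shared by pipeline-level tests.
small_dataset <- function(seed = 101) {
  simulate_vmb_dataset(
    vmb_design(animals_per_group = 4, recovery_animals_per_group = 2),
    vmb_sim_config(seed = seed)
  )
}
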