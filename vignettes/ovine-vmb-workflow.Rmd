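---
title: "Characterizing the ovine vaginal microbiome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing the ovine vaginal microbiome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovmb)
library(dplyr)
```

## The problem

Sheep are an attractive large-animal model for testing vaginally applied
drugs and devices, and regulatory guidance asks that safety studies assess
impact on the vaginal microbiome (VMB). The ovine VMB, unlike the
Lactobacillus-dominated human one, is organized around genera such as
*Pasteurella*, *Actinobacillus*, *Pseudomonas* and *E. coli*, with
*Haemophilus*, *Corynebacterium* and *Ureaplasma* marking inflamed,
dysbiotic states. `ovmb` implements the analysis workflow for studies that
measure this community with a 48-target qPCR array (46 taxa plus two
controls: the single-copy sheep GAPDH gene, shGAPDH, and a pan-bacterial
16S target) and vaginal inflammation with a six-cytokine ELISA panel, in a
longitudinal irritant design: four arms (Sham swab-only, HEC placebo gel,
nonoxynol-9 gel, benzalkonium chloride solution), ten daily doses with
swabs on days 1, 2, 3, 5, 7 and 9, and a recovery window sampled on days
11, 13, 15, 17 and 21 in a subset of treated animals.

## Pipeline stages and their models

**Quality gating.** A swab is analyzable when extracted DNA carries at
least 1e4 copies/ul of both shGAPDH and universal 16S (inclusive
thresholds), and a post-thaw retest of both controls agrees with the
original values within 0.5 log10 (inclusive). When both gates fail, the
shGAPDH reason is recorded first — an arbitrary but fixed precedence so
exclusion reports are reproducible. Reported failure percentages use
half-up rounding to one decimal, matching the convention of the summary
tables this package reproduces (base R's `round()` is half-to-even and
would print some of them differently).

**Quantification.** Cq values convert to genome copies through
per-target OLS standard curves, `copies = 10^((cq - intercept)/slope)`;
non-detected wells are true zeros (no pseudocount). Relative abundance is
each taxon's share of the *summed 46 taxon targets*, not of universal 16S:
the 16S control serves only the coverage check, `coverage =
total_detected/univ16s`, flagged (never excluded) below 0.90, since low
coverage is a cue that the panel misses community members. The Shannon
index uses natural logs over nonzero proportions, so it ranges from 0 to
ln 46 ≈ 3.829 on this panel.

**Community types.** Profiles cluster under the uncentered-correlation
distance (one minus cosine similarity, no mean centering) with average
linkage — the dissimilarity under which communities are close when the
same taxa dominate regardless of load. Discovery by clustering proposes
types; assignment is rule-based against an editable 16-entry catalog.
Because the source material never states a numeric dominance rule, the
defaults are package choices: a single-biomarker CT requires its biomarker
at ≥ 0.40 relative abundance *and* top rank among catalog biomarkers; a
combination CT requires every member at ≥ 0.20; combinations are evaluated
before singletons (so an Actinobacillus–Haemophilus community is not
collapsed into either singleton), first catalog match wins, and profiles
matching nothing are `untypable`. Both thresholds are arguments. The
composition of the "A-H" label is itself provisional — the label is read
literally as Actinobacillus + Haemophilus — and users can re-map it by
editing `ct_catalog()`.

**Inflammation.** ELISA OD490 values are used raw; no conversion to
concentration enters the classification path. Cutoffs are derived per
cytokine over all pooled study samples: a 59th-percentile binary split
(linear-interpolation percentile), tertiles, or the mean. Only four
targets are analyzable — IL-8, IL-1B, TNF-A, CXCL10 — because IL-6 and
IL-17A fall below the 20% detection-frequency floor in ovine vaginal
fluid. `Infl1` calls a sample inflamed when ≥ 3 of the 4 targets are high;
`Infl4` uses only IL-8 and IL-1B with a 1-of-2 rule. The 1-of-2 choice is
a reconstruction: no vote rule is stated for Infl4, but it is the only one
consistent with Infl4 calling *more* samples inflamed (66%) than the
binary Infl1 (36%) on the same data. Both the mean-based and
percentile-based splits are implemented; percentile is the default since
it defines the named models.

**Biosis consensus.** Within each CT, a cytokine is categorized H (or L)
when at least 67% of the CT's samples share that call — interpreted as a
strict decimal threshold, so 2 of 3 (66.7%) is `mixed`; pass
`majority_fraction = 2/3` for the exact fraction. A CT is dysbiotic with
≥ 3 of 4 cytokines H, eubiotic with ≥ 3 L; `mixed` never counts toward
either side.

**Treatment statistics.** Control-target trajectories are summarized as
per-animal log10 fold change from that animal's day-1 baseline (zeros
floored at 1 copy so the change stays finite; the floor is an argument).
Group comparisons gate on per-group Shapiro–Wilk at 0.05: all normal →
one-way ANOVA with Tukey HSD; otherwise Kruskal–Wallis with pairwise
Wilcoxon. Tukey's procedure is defined for the parametric branch only, so
the nonparametric branch substitutes Holm and records the substitution in
the report. CT distributions are compared by the asymptotic two-sample
Kolmogorov–Smirnov test over the categorical CT axis; that statistic
depends on the category ordering, so the catalog order is fixed and echoed
in the result. Per-CT contingency shifts use two-sided Fisher exact tests
with Benjamini–Hochberg correction over all (CT × pair) tests in a period.
Per-taxon relative abundances are compared by Wilcoxon and by the two-part
statistic — a two-proportion Z on zero frequencies plus a tie-corrected
standardized rank-sum on the positive values, summed as a chi-square with
2 df — which restores power lost to the mass of tied 0% ranks. Shannon
diversity is compared by Welch t.

## The synthetic-data generator

The study's per-sample qPCR and ELISA measurements are not publicly
deposited (only raw sequencing reads are), so the package ships a
generator that emulates the *statistical structure* the analysis assumes,
making every stage testable end to end:

* Each animal carries a resident CT drawn from `ct_priors` (default
  70/16/14 over A-H, Ps and Ec, mirroring the pre-dose distribution).
  Communities give the CT's biomarkers jointly a fixed `dominance_mass`
  (0.7 by default, split evenly in combinations) with the remainder spread
  by a symmetric Dirichlet (alpha = 1) — a minimal-assumption law chosen
  because the source reports only average profiles. Total load is
  log10-normal (mean 6.0, SD 0.5 log10 copies/ul), scaled so the 1e4 gate
  is rarely breached except through the explicit `qc_fail_prob` mechanism
  or a strong load-suppressing treatment.
* Treatment effects multiply enriched taxa and then renormalize the
  composition (matching the relative-abundance framing of the observed
  shifts) before shifting total load: BZK suppresses load one log and
  enriches *Corynebacterium*; N9 enriches *Haemophilus* with mild
  overgrowth. Effects act on post-baseline dosing days; the BZK enrichment
  persists through recovery, mirroring the reported persistence of the
  Cy type versus the quick resolution of the H type.
* Cytokine ODs are Gaussian around per-target baselines, with the
  inflamed state shifting the four analyzable targets upward. Detection
  dropout models sub-threshold concentrations in quiescent fluid (IL-6 at
  0.95, IL-17A at 0.90, IL-8 at 0.08 — calibrated to the reported 92%
  IL-8 detection — IL-1B at 0.24); an acting inflamed shift overrides
  dropout, since an inflamed mucosa secretes those cytokines at readily
  detectable levels. Inflamed states are drawn from the resident CT's
  biosis (0.9 for dysbiotic, 0.1 for eubiotic CTs).
* One global seed drives counter-based per-sample substreams, so a fixed
  seed reproduces a dataset byte for byte and subsetting a design never
  shifts other samples' draws.

What the generator does *not* emulate: estrus-cycle dynamics, plate and
batch effects, spatial swab variability, taxon–taxon ecological
interactions, and overdispersion beyond the Dirichlet. Passing recovery
tests therefore demonstrate internal consistency of the pipeline under
its own assumptions, not field performance on real swabs.

## A property worth knowing: percentile cutoffs and prevalence

The binary 59th-percentile split pins the marginal rate of "high" calls at
41% no matter what the data look like. Consensus biosis calls are
therefore sharpest when true inflammation prevalence sits near that
complement: with prevalence well above 41% the cutoff moves into the
inflamed OD mode and dysbiotic CTs drift toward `mixed`; well below it,
excess high calls land on quiescent samples and erode eubiotic
majorities. The study cohort — eubiotic-majority with irritant arms —
sits in the workable range, and the package's consensus-recovery test
generates its data at ≈ 41% prevalence for the same reason. Users applying
the workflow to cohorts with very different inflammation rates should
prefer the mean-based split or adjust the percentile.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for
desk-scale runs: label recovery at n = 500 communities, consensus
recovery over 20 seeds × 135 samples, two-part test calibration at 10,000
null replicates of n = 50 per arm, and the end-to-end treatment pipeline
at the design's natural 276 samples. Percentile cutoffs use the
linear-interpolation definition (R's quantile type 7). Boundary decisions
are inclusive throughout (QC gates, 0.5-log integrity band); the 67%
majority is strict; ties in clustering and assignment break by fixed
input/catalog order. Zero-margin Fisher tables take p = 1 by convention
and are flagged; an all-zero two-part comparison returns chi-square 0,
p = 1, flagged degenerate.

## Worked example

```{r example}
design <- vmb_design(animals_per_group = 4, recovery_animals_per_group = 2)
dataset <- simulate_vmb_dataset(design, vmb_sim_config(seed = 20))
pipeline <- run_vmb_pipeline(dataset$samples, dataset$cytokines)
pipeline
glance(pipeline)

fc <- log_fold_change(
  dplyr::filter(pipeline$samples, qc_status == "pass"), "univ16s")
tidy(group_compare_fc(dplyr::filter(fc, study_day == 5)))
```

## Known limitations

* The 46-taxon panel beyond the named biomarker and treatment-responsive
  organisms is a synthetic default; swap in your own target list.
* The A-H (and A-H-Ps) biomarker mapping is provisional.
* The KS comparison of CT distributions is ordering-dependent by
  construction; treat its p values as descriptive unless the ordering is
  pre-registered.
* No mixed-effects repeated-measures modeling: comparisons are day-wise,
  as in the source workflow.
* Real-data irregularities (plate effects, partial panels, freeze–thaw
  drift) are out of scope for the generator; the integrity check exists
  to catch the last of these in real inputs.
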