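#' Default 46-taxon qPCR array panel
#'
#' The taxon targets quantified by the custom ovine VMB qPCR array. Ten of
#' these are the biomarker organisms that anchor the community-type catalog
#' (Pasteurella, Actinobacillus, Pseudomonas, Bacteroides, Leptotrichia,
#' Escherichia_coli, Haemophilus, Ureaplasma, Corynebacterium, Helcococcus);
#' the remainder are genera commonly recovered from the ovine vaginal cavity.
#' Only the biomarker and treatment-responsive organisms are fixed by the
#' analysis; the rest of this default panel is a synthetic stand-in and can
#' be replaced by the user's own target list wherever a `taxa` argument is
#' accepted. The two array control targets (shGAPDH, universal 16S) are not
#' part of the panel: they are carried as separate columns of a sample table.
#'
#' @return Character vector of 46 taxon names.
#' @export
#' @examples
#' length(vmb_taxa())
vmb_taxa <- function() {
  c(
    # biomarker organisms behind the CT catalog
    "Pasteurella", "Actinobacillus", "Pseudomonas", "Bacteroides",
    "Leptotrichia", "Escherichia_coli", "Haemophilus", "Ureaplasma",
    "Corynebacterium", "Helcococcus",
    # treatment-responsive minor community members
    "Actinomyces", "Acidovorax", "Rhodococcus", "Cloacibacterium",
    # other panel members (default synthetic panel, user replaceable)
    "Streptococcus", "Staphylococcus", "Enterococcus", "Aerococcus",
    "Facklamia", "Trueperella", "Arcanobacterium", "Fusobacterium",
    "Prevotella", "Porphyromonas", "Peptostreptococcus", "Finegoldia",
    "Anaerococcus", "Peptoniphilus", "Veillonella", "Mannheimia",
    "Moraxella", "Acinetobacter", "Psychrobacter", "Micrococcus",
    "Bacillus", "Clostridium", "Lactobacillus", "Bifidobacterium",
    "Campylobacter", "Ruminococcus", "Blautia", "Oscillibacter",
    "Stenotrophomonas", "Sphingomonas", "Delftia", "Comamonas"
  )
}

#' Community-type (CT) catalog
#'
#' The categorical system used to label vaginal microbiome profiles by their
#' dominant (biomarker) organisms. Multi-biomarker ("combination") types are
#' listed before single-biomarker types because assignment evaluates the
#' catalog in order. Each CT carries its inflammation association
#' (`biosis`): Haemophilus-, Corynebacterium-, Ureaplasma- and
#' Helcococcus-dominant communities are dysbiotic (high cytokine levels);
#' Pasteurella, Actinobacillus, Pseudomonas, Bacteroides, Leptotrichia and
#' E. coli dominance marks eubiosis. The composition of the "A-H" label is
#' provisional (taken literally as Actinobacillus + Haemophilus); edit the
#' returned tibble to change it.
#'
#' @return A tibble with columns `label` (character), `biomarkers`
#'   (list-column of character vectors) and `biosis`
#'   (`"eubiotic"`, `"dysbiotic"` or `"indeterminate"`).
#' @export
#' @examples
#' ct_catalog()
ct_catalog <- function() {
  tibble::tibble(
    label = c(
      "A-H-Ps", "A-H", "Pa-Ac", "Pa-H", "Ba-Le", "Ps-Ec",
      "Pa", "Ac", "Ps", "Ba", "Le", "Ec", "H", "Cy", "U", "Hc"
    ),
    biomarkers = list(
      c("Actinobacillus", "Haemophilus", "Pseudomonas"),
      c("Actinobacillus", "Haemophilus"),
      c("Pasteurella", "Actinobacillus"),
      c("Pasteurella", "Haemophilus"),
      c("Bacteroides", "Leptotrichia"),
      c("Pseudomonas", "Escherichia_coli"),
      "Pasteurella", "Actinobacillus", "Pseudomonas", "Bacteroides",
      "Leptotrichia", "Escherichia_coli", "Haemophilus", "Corynebacterium",
      "Ureaplasma", "Helcococcus"
    ),
    biosis = c(
      "indeterminate", "eubiotic", "eubiotic", "dysbiotic", "eubiotic",
      "eubiotic",
      "eubiotic", "eubiotic", "eubiotic", "eubiotic", "eubiotic", "eubiotic",
      "dysbiotic", "dysbiotic", "dysbiotic", "dysbiotic"
    )
  )
}

#' Cytokine panel membership
#'
#' Names of the six ELISA targets and the four-analyte subset retained for
#' inflammation modelling (IL-6 and IL-17A are rarely detected in ovine
#' vaginal fluid and are dropped by the detection-frequency gate).
#'
#' @return Character vector of cytokine names.
#' @export
vmb_cytokines <- function() {
  c("IL8", "IL1B", "TNFA", "CXCL10", "IL6", "IL17A")
}

#' @rdname vmb_cytokines
#' @export
vmb_cytokines_analyzable <- function() {
  c("IL8", "IL1B", "TNFA", "CXCL10")
}
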