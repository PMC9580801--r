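#' Cluster community profiles by uncentered correlation
#'
#' Hierarchical agglomerative clustering of relative-abundance profiles with
#' the uncentered-correlation distance `1 - sum(x*y) / (||x|| * ||y||)`
#' (i.e. one minus cosine similarity, no mean centering) and average
#' linkage. This is the dissimilarity under which two communities count as
#' close when the same taxa dominate, regardless of total load.
#'
#' @param profiles Long profile tibble from [compute_profiles()] (or any
#'   tibble with `sample_id`, `taxon` and an abundance column named
#'   `rel_abundance` or `copies`).
#' @param k Optional number of flat clusters to cut.
#' @return Object of class `vmb_clustering`: the `hclust` tree, the
#'   distance matrix and, when `k` is given, a `membership` tibble.
#' @export
cluster_profiles <- function(profiles, k = NULL) {
  check_columns(profiles, c("sample_id", "taxon"), "profiles")
  value_col <- if ("rel_abundance" %in% names(profiles)) {
    "rel_abundance"
  } else if ("copies" %in% names(profiles)) {
    "copies"
  } else {
    abort_ovmb("profiles need a rel_abundance or copies column")
  }
  wide <- profiles |>
    dplyr::select("sample_id", "taxon", dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "taxon",
                       values_from = dplyr::all_of(value_col),
                       values_fill = 0)
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$sample_id
  if (nrow(mat) < 2) abort_ovmb("clustering requires at least 2 profiles")
  d <- uncentered_cor_dist(mat)
  tree <- hclust(as.dist(d), method = "average")
  membership <- NULL
  if (!is.null(k)) {
    cl <- cutree(tree, k = k)
    membership <- tibble::tibble(sample_id = names(cl),
                                 cluster = unname(cl))
  }
  structure(
    list(tree = tree, dist = d, membership = membership, k = k),
    class = "vmb_clustering"
  )
}

# 1 - cosine similarity between rows; all-zero rows are rejected upstream.
uncentered_cor_dist <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) abort_ovmb("cannot cluster an all-zero profile")
  xn <- mat / norms
  d <- 1 - tcrossprod(xn)
  d[d < 0] <- 0 # clip numeric noise
  diag(d) <- 0
  d
}

#' @export
print.vmb_clustering <- function(x, ...) {
  cat(sprintf("<vmb_clustering> %d profiles, average linkage, uncentered correlation\n",
              length(x$tree$order)))
  if (!is.null(x$membership)) {
    cat(sprintf("  flat cut at k = %d\n", x$k))
  }
  invisible(x)
}

#' Export a clustering dendrogram in Newick format
#'
#' @param clustering A [cluster_profiles()] result.
#' @param path File path to write.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "vmb_clustering"))
  ape::write.tree(ape::as.phylo(clustering$tree), file = path)
  invisible(path)
}

#' Assign community types by biomarker dominance
#'
#' Labels each profile against a CT catalog. Combination CTs are evaluated
#' first (every biomarker must reach `combination_threshold` relative
#' abundance), then single-biomarker CTs (the biomarker must reach
#' `dominance_threshold` and be the most abundant of all catalog biomarker
#' taxa). The first matching catalog entry wins; profiles matching nothing
#' are `"untypable"`. Assignment depends only on relative abundances, so it
#' is invariant to rescaling all copies.
#'
#' @param profiles Long profile tibble from [compute_profiles()].
#' @param catalog A [ct_catalog()]-shaped tibble.
#' @param dominance_threshold Minimum relative abundance for a
#'   single-biomarker CT (default 0.40).
#' @param combination_threshold Minimum per-biomarker relative abundance in
#'   a combination CT (default 0.20).
#' @return Tibble: sample metadata plus `ct_label`.
#' @export
assign_ct <- function(profiles, catalog = ct_catalog(),
                      dominance_threshold = 0.40,
                      combination_threshold = 0.20) {
  if (nrow(catalog) == 0) abort_ovmb("empty CT catalog")
  if (dominance_threshold < combination_threshold) {
    abort_ovmb("dominance_threshold must be >= combination_threshold")
  }
  check_columns(profiles, c("sample_id", "taxon", "rel_abundance"),
                "profiles")
  all_biomarkers <- unique(unlist(catalog$biomarkers))
  missing <- setdiff(all_biomarkers, unique(profiles$taxon))
  if (length(missing) > 0) {
    abort_ovmb(sprintf("profiles do not cover catalog biomarker(s): %s",
                       paste(missing, collapse = ", ")))
  }

  wide <- profiles |>
    dplyr::select("sample_id", "taxon", "rel_abundance") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "rel_abundance",
                       values_fill = 0)
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$sample_id

  n_bio <- lengths(catalog$biomarkers)
  combos <- which(n_bio > 1)
  singles <- which(n_bio == 1)
  bio_mat <- mat[, all_biomarkers, drop = FALSE]
  top_biomarker <- all_biomarkers[max.col(bio_mat, ties.method = "first")]

  labels <- rep("untypable", nrow(mat))
  unset <- rep(TRUE, nrow(mat))
  for (i in combos) {
    bm <- catalog$biomarkers[[i]]
    hit <- unset &
      rowSums(mat[, bm, drop = FALSE] >= combination_threshold) == length(bm)
    labels[hit] <- catalog$label[i]
    unset[hit] <- FALSE
  }
  for (i in singles) {
    bm <- catalog$biomarkers[[i]]
    hit <- unset & mat[, bm] >= dominance_threshold & top_biomarker == bm
    labels[hit] <- catalog$label[i]
    unset[hit] <- FALSE
  }

  meta <- profiles |>
    dplyr::select(dplyr::any_of(c("sample_id", "animal_id", "group",
                                  "study_day", "period"))) |>
    dplyr::distinct()
  tibble::tibble(sample_id = rownames(mat), ct_label = labels) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::relocate("ct_label", .after = dplyr::last_col())
}

#' Community-type frequency table
#'
#' Tabulates CT labels within grouping strata (e.g. treatment group, study
#' period), reporting counts and row percentages rounded half-up to one
#' decimal, plus row totals — the layout used to summarize CT distributions
#' across treatment arms.
#'
#' @param labels Tibble with a `ct_label` column (see [assign_ct()]).
#' @param ... Grouping columns (tidy-select), e.g. `group, period`.
#' @return Tibble of class `vmb_ct_table`: grouping columns, `ct_label`,
#'   `n`, `row_total`, `percent`.
#' @export
#' @examples
#' labels <- tibble::tibble(
#'   group = rep("Pre-Dose", 37),
#'   ct_label = rep(c("A-H", "Ps", "Ec"), c(26, 6, 5)))
#' ct_frequency_table(labels, group)
ct_frequency_table <- function(labels, ...) {
  check_columns(labels, "ct_label", "labels")
  out <- labels |>
    dplyr::count(dplyr::across(c(...)), .data$ct_label, name = "n") |>
    dplyr::group_by(dplyr::across(c(...))) |>
    dplyr::mutate(
      row_total = sum(.data$n),
      percent = round_half_up(100 * .data$n / .data$row_total, 1)
    ) |>
    dplyr::ungroup()
  class(out) <- c("vmb_ct_table", class(out))
  out
}
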