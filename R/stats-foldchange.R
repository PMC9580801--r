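#' Log10 fold change from each animal's baseline
#'
#' For a control target (shGAPDH or universal 16S), computes per animal and
#' day `log10(value_day) - log10(value_baseline)` against that animal's
#' day-1 pre-dose measurement. Zero copy values are floored at
#' `zero_floor` (1 copy by default) before taking logs so the fold change
#' stays finite; animals without a baseline measurement are dropped with a
#' warning.
#'
#' @param samples Tibble with `animal_id`, `group`, `study_day`, `period`
#'   and the target column.
#' @param target Column name to analyze (`"shgapdh"` or `"univ16s"`).
#' @param baseline_day Baseline day (default 1).
#' @param zero_floor Floor applied before log10 (default 1 copy).
#' @return Tibble: `animal_id`, `group`, `study_day`, `period`, `target`,
#'   `log10_fc` (exactly 0 on the baseline day).
#' @export
log_fold_change <- function(samples, target = "univ16s", baseline_day = 1L,
                            zero_floor = 1) {
  check_columns(samples, c("animal_id", "group", "study_day", "period",
                           target), "sample table")
  df <- samples |>
    dplyr::transmute(
      .data$animal_id, .data$group, .data$study_day, .data$period,
      value = pmax(.data[[target]], zero_floor)
    )
  baselines <- df |>
    dplyr::filter(.data$study_day == baseline_day) |>
    dplyr::select("animal_id", baseline = "value")
  no_base <- setdiff(unique(df$animal_id), baselines$animal_id)
  if (length(no_base) > 0) {
    warning("excluding animal(s) without a day-", baseline_day,
            " baseline: ", paste(no_base, collapse = ", "), call. = FALSE)
  }
  df |>
    dplyr::inner_join(baselines, by = "animal_id") |>
    dplyr::mutate(
      target = target,
      log10_fc = log10(.data$value) - log10(.data$baseline)
    ) |>
    dplyr::select("animal_id", "group", "study_day", "period", "target",
                  "log10_fc")
}

#' Per-group daily fold-change summaries
#'
#' @param fc A [log_fold_change()] result.
#' @return Tibble: `group`, `study_day`, `period`, `n`, `mean_fc`, `sd_fc`,
#'   `median_fc`.
#' @export
fc_group_summary <- function(fc) {
  check_columns(fc, c("group", "study_day", "period", "log10_fc"), "fc")
  fc |>
    dplyr::group_by(.data$group, .data$study_day, .data$period) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fc = mean(.data$log10_fc),
      sd_fc = sd(.data$log10_fc),
      median_fc = median(.data$log10_fc),
      .groups = "drop"
    )
}

#' Per-animal maximal fold change within each period
#'
#' The maximum departure from baseline an animal reached during the main
#' (dosing) and recovery windows; the baseline day itself is excluded so
#' the main-period maximum reflects post-dose days.
#'
#' @param fc A [log_fold_change()] result.
#' @param baseline_day Day excluded from the main-period maximum.
#' @return Tibble: `animal_id`, `group`, `period`, `max_fc`.
#' @export
fc_period_max <- function(fc, baseline_day = 1L) {
  check_columns(fc, c("animal_id", "group", "period", "study_day",
                      "log10_fc"), "fc")
  fc |>
    dplyr::filter(.data$study_day != baseline_day) |>
    dplyr::group_by(.data$animal_id, .data$group, .data$period) |>
    dplyr::summarise(max_fc = max(.data$log10_fc), .groups = "drop")
}

#' Normality-gated group comparison
#'
#' Compares a response across treatment groups with the branch rule used
#' for fold-change endpoints: Shapiro-Wilk per group at `alpha_normality`;
#' if every group looks normal, one-way ANOVA with Tukey HSD pairwise
#' contrasts; otherwise Kruskal-Wallis with pairwise Wilcoxon rank-sum
#' tests, Holm-adjusted (Tukey's procedure is defined for the parametric
#' branch only, so the nonparametric branch substitutes Holm and records
#' it). Groups with fewer than 3 observations cannot be tested for
#' normality and send the comparison down the nonparametric branch.
#'
#' @param df Tibble with a grouping column and a numeric response.
#' @param value Response column name (default `"log10_fc"`).
#' @param group Grouping column name (default `"group"`).
#' @param alpha_normality Shapiro-Wilk gate (default 0.05).
#' @return Object of class `vmb_group_test`: branch, omnibus statistic and
#'   p value, pairwise tibble, per-group normality results.
#' @export
group_compare_fc <- function(df, value = "log10_fc", group = "group",
                             alpha_normality = 0.05) {
  check_columns(df, c(value, group), "comparison input")
  df <- tibble::tibble(g = as.character(df[[group]]), y = df[[value]])
  sizes <- table(df$g)
  if (length(sizes) < 2) abort_ovmb("need >= 2 groups to compare")
  if (any(sizes < 2)) abort_ovmb("every group needs >= 2 observations")

  normality <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(
      n = dplyr::n(),
      shapiro_p = if (dplyr::n() >= 3 && sd(.data$y) > 0) {
        shapiro.test(.data$y)$p.value
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  all_normal <- all(!is.na(normality$shapiro_p) &
                      normality$shapiro_p >= alpha_normality)

  if (all_normal) {
    fit <- aov(y ~ g, data = df)
    sm <- summary(fit)[[1]]
    omnibus <- tibble::tibble(
      method = "one-way ANOVA",
      statistic = sm$`F value`[1], p_value = sm$`Pr(>F)`[1]
    )
    tk <- TukeyHSD(fit)$g
    pairwise <- tibble::tibble(
      comparison = rownames(tk),
      estimate = tk[, "diff"],
      p_adjusted = tk[, "p adj"],
      adjustment = "Tukey HSD"
    )
    branch <- "parametric"
  } else {
    kw <- kruskal.test(df$y, factor(df$g))
    omnibus <- tibble::tibble(
      method = "Kruskal-Wallis",
      statistic = unname(kw$statistic), p_value = kw$p.value
    )
    gs <- sort(unique(df$g))
    pairs <- utils::combn(gs, 2, simplify = FALSE)
    pw <- purrr::map_dfr(pairs, function(p) {
      w <- suppressWarnings(wilcox.test(df$y[df$g == p[1]],
                                        df$y[df$g == p[2]],
                                        exact = FALSE))
      tibble::tibble(
        comparison = paste(p[2], p[1], sep = "-"),
        estimate = median(df$y[df$g == p[2]]) - median(df$y[df$g == p[1]]),
        p_raw = w$p.value
      )
    })
    pairwise <- pw |>
      dplyr::mutate(
        p_adjusted = p.adjust(.data$p_raw, method = "holm"),
        adjustment = "Holm (nonparametric branch)"
      ) |>
      dplyr::select(-"p_raw")
    branch <- "nonparametric"
  }
  structure(
    list(branch = branch, omnibus = omnibus, pairwise = pairwise,
         normality = normality, alpha_normality = alpha_normality),
    class = "vmb_group_test"
  )
}

#' @export
print.vmb_group_test <- function(x, ...) {
  cat(sprintf("<vmb_group_test> branch: %s\n", x$branch))
  cat(sprintf("  omnibus %s: statistic = %.4g, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  print(x$pairwise)
  invisible(x)
}

#' Welch t comparison of Shannon diversity
#'
#' Compares SDI between two groups with a Welch (unequal-variance) t-test
#' and Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric SDI vectors for the two groups.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
#' @examples
#' sdi_compare(rnorm(10, 3), rnorm(10, 2.5))
sdi_compare <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort_ovmb("need >= 2 SDI values per group")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1,
                            mean_x = mean(x), mean_y = mean(y)))
    }
    abort_ovmb("zero variance in both groups with unequal means")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_x = mean(x), mean_y = mean(y)
  )
}
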