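# Identification of beat-responsive units (per-window rank-sum tests with a
# Bonferroni-corrected threshold) and population-level count statistics.

stop_insufficient <- function(msg) abort(msg, class = "beatmem_insufficient_data")
stop_degenerate <- function(msg) abort(msg, class = "beatmem_degenerate_error")

#' Two-sided rank-sum (Mann-Whitney) test on two trial sets
#'
#' Trials of the two beat conditions are unpaired, so the "Wilcoxon test" on
#' per-trial firing rates is the two-sample rank-sum test. The exact null
#' distribution is used when both samples have at most 10 values and there
#' are no ties; otherwise the normal approximation with tie correction (no
#' continuity correction) is used.
#'
#' @param a,b Numeric vectors of per-trial rates (each of length >= 2).
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   `NULL` selects automatically as above.
#' @return A list with `p` (two-sided), `statistic` (Mann-Whitney U of `a`),
#'   and `direction` (+1 if `mean(a) > mean(b)`, -1 if smaller, `NA` if
#'   equal).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p # exact, 0.1
rank_sum_test <- function(a, b, exact = NULL) {
  if (length(a) < 2 || length(b) < 2) {
    stop_insufficient("rank_sum_test needs at least 2 values per sample")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- length(a) <= 10 && length(b) <= 10 && !ties
  if (all(c(a, b) == a[1])) {
    return(list(p = 1, statistic = length(a) * length(b) / 2, direction = NA_real_))
  }
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  p <- w$p.value
  if (!is.finite(p)) p <- 1
  dir <- sign(mean(a) - mean(b))
  if (dir == 0) dir <- NA_real_
  list(p = min(p, 1), statistic = unname(w$statistic),
       direction = if (is.na(dir)) NA_real_ else dir)
}

#' Select beat-responsive units
#'
#' For each unit, per-trial firing rates on binaural vs monaural trials of
#' the requested phase (stimulated runs only) are compared with
#' [rank_sum_test()] in each of the four 500 ms post-stimulus windows. A unit
#' is selected when its minimum p-value is at or below the
#' Bonferroni-corrected threshold (`alpha`, default 0.05/4 = 0.0125). The
#' response direction (increase/decrease of binaural relative to monaural) is
#' taken from the most significant window, earliest window on ties.
#'
#' @param rates Per-trial rates from [trial_window_rates()].
#' @param trials Trial table.
#' @param units Unit metadata tibble (the dataset's `units`).
#' @param phase `"encoding"` or `"retrieval"`.
#' @param hemisphere Restrict to `"left"` or `"right"` (`NULL`: both).
#' @param alpha Per-window selection threshold.
#' @param kept_units Unit ids that passed the inclusion filter (`NULL`: all).
#' @return A tibble with one row per unit: `p_w1`..`p_w4`, `min_p`,
#'   `best_window`, `direction` (`"increase"`/`"decrease"`), `selected`.
#' @export
select_beat_responsive <- function(rates, trials, units, phase,
                                   hemisphere = NULL, alpha = 0.0125,
                                   kept_units = NULL) {
  stopifnot(phase %in% task_phases())
  if (!is.null(hemisphere)) stopifnot(hemisphere %in% hemispheres())
  u <- units
  if (!is.null(hemisphere)) u <- u |> filter(.data$hemisphere == !!hemisphere)
  if (!is.null(kept_units)) u <- u |> filter(.data$unit_id %in% kept_units)
  if (nrow(u) == 0) {
    return(tibble::tibble(
      unit_id = character(), subject_id = character(), region = character(),
      hemisphere = character(), phase = character(),
      p_w1 = numeric(), p_w2 = numeric(), p_w3 = numeric(), p_w4 = numeric(),
      min_p = numeric(), best_window = character(), direction = character(),
      selected = logical()
    ))
  }

  stim <- trials |>
    filter(.data$phase == !!phase, .data$stimulation_delivered,
           .data$beat_condition %in% c("binaural", "monaural"))
  dat <- rates |>
    filter(.data$window %in% analysis_windows(),
           .data$unit_id %in% u$unit_id) |>
    inner_join(stim |> select(dplyr::all_of(c("trial_id", "beat_condition"))),
               by = "trial_id")
  by_unit <- split(dat, factor(dat$unit_id, levels = u$unit_id))

  rows <- lapply(u$unit_id, function(id) {
    d <- by_unit[[id]]
    ps <- rep(NA_real_, 4)
    dirs <- rep(NA_real_, 4)
    for (w in seq_along(analysis_windows())) {
      dw <- d[d$window == analysis_windows()[w], ]
      res <- rank_sum_test(dw$rate[dw$beat_condition == "binaural"],
                           dw$rate[dw$beat_condition == "monaural"])
      ps[w] <- res$p
      dirs[w] <- res$direction
    }
    best <- which.min(ps) # earliest window on ties
    tibble::tibble(
      p_w1 = ps[1], p_w2 = ps[2], p_w3 = ps[3], p_w4 = ps[4],
      min_p = ps[best], best_window = analysis_windows()[best],
      direction_sign = dirs[best]
    )
  })
  res <- bind_cols(
    u |> select(dplyr::all_of(c("unit_id", "subject_id", "region", "hemisphere"))),
    bind_rows(rows)
  ) |>
    mutate(
      phase = !!phase, .after = "hemisphere"
    ) |>
    mutate(
      selected = .data$min_p <= alpha,
      direction = dplyr::case_when(
        !.data$selected ~ NA_character_,
        .data$direction_sign > 0 ~ "increase",
        .data$direction_sign < 0 ~ "decrease",
        TRUE ~ NA_character_
      )
    ) |>
    select(-"direction_sign")
  res
}

#' Exact one-sided binomial proportion test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, by exact
#' summation of the probability mass. Used to test whether the number of
#' units showing a significant contrast exceeds the chance expectation
#' (`p0 = 0.05` at the 5% alpha level).
#'
#' @param k Observed count of significant units (0 <= k <= n).
#' @param n Number of units tested.
#' @param p0 Chance probability, in (0, 1).
#' @return The one-sided p-value.
#' @export
#' @examples
#' binomial_proportion_test(52, 112, 0.05) # ~3e-37
binomial_proportion_test <- function(k, n, p0 = 0.05) {
  if (any(k < 0) || any(k > n)) abort("k must satisfy 0 <= k <= n",
                                      class = "beatmem_domain_error")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie in (0, 1)",
                                class = "beatmem_domain_error")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Overlap test between two unit classes
#'
#' Tests whether the number of units significant in both of two contrasts
#' exceeds chance, with the chance probability taken as the product of the
#' two class proportions (instead of 5% for single classes).
#'
#' @param k_overlap Units significant in both contrasts.
#' @param n Units tested.
#' @param portion1,portion2 Observed proportions of the two classes, in
#'   (0, 1].
#' @return One-sided binomial p-value.
#' @export
#' @examples
#' overlap_test(17, 112, 30 / 112, 52 / 112) # 0.226
overlap_test <- function(k_overlap, n, portion1, portion2) {
  if (portion1 <= 0 || portion1 > 1 || portion2 <= 0 || portion2 > 1) {
    abort("portions must lie in (0, 1]", class = "beatmem_domain_error")
  }
  binomial_proportion_test(k_overlap, n, portion1 * portion2)
}

#' Pearson chi-square test for two proportions
#'
#' 1-df Pearson chi-square on the 2x2 table (significant/not x group), with
#' no continuity correction.
#'
#' @param k1,n1 Significant count and total in group 1.
#' @param k2,n2 Significant count and total in group 2.
#' @return A list with `statistic`, `p`, `df = 1`.
#' @export
#' @examples
#' proportion_chi_square(30, 112, 11, 68)$statistic # ~2.71
proportion_chi_square <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) abort("group sizes must be >= 1",
                              class = "beatmem_domain_error")
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop_degenerate("degenerate 2x2 table: a row or column sums to zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, df = 1)
}

#' Population-level summary of a selection result
#'
#' Counts selected units and runs [binomial_proportion_test()] per grouping
#' cell (e.g. hemisphere, or region within hemisphere).
#'
#' @param selection Output of [select_beat_responsive()].
#' @param by Grouping columns (character), e.g. `"hemisphere"` or
#'   `c("hemisphere", "region")`.
#' @param p0 Chance probability per unit.
#' @return A tibble with `n`, `k`, `proportion` and `p_binom` per cell.
#' @export
population_summary <- function(selection, by = "hemisphere", p0 = 0.05) {
  selection |>
    group_by(dplyr::across(dplyr::all_of(c("phase", by)))) |>
    summarise(n = dplyr::n(), k = sum(.data$selected), .groups = "drop") |>
    mutate(
      proportion = .data$k / .data$n,
      p_binom = binomial_proportion_test(.data$k, .data$n, p0)
    )
}
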