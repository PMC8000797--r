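# Correlations between beat-related and memory-related normalized firing
# rate differences: post-stimulus (matched-window) and pre-stimulus
# (baseline-shift) analyses, the sign-adjusted pre-stimulus t-test, and the
# exploratory homeostatic correlation scheme.

#' Pearson correlation with a significance threshold
#'
#' Sample Pearson correlation with a two-sided p-value from the t-transform
#' with `n - 2` degrees of freedom, flagged significant when `p < alpha`
#' (default 0.0125, Bonferroni correction for four time windows).
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @param alpha Significance threshold.
#' @return A one-row tibble with `r`, `p`, `n`, `significant`.
#' @export
pearson_with_threshold <- function(x, y, alpha = 0.0125) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "beatmem_domain_error")
  }
  if (length(x) < 3) {
    stop_insufficient("need at least 3 observations for a correlation")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_degenerate("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate), p = ct$p.value, n = length(x),
    significant = ct$p.value < alpha
  )
}

#' Correlation between beat-related and memory-related differences
#'
#' Across units, correlates the normalized beat difference with the
#' normalized memory difference in one post-stimulus window. With
#' `beat_window = "matched_post"` the beat difference comes from the same
#' window as the memory difference (post-stimulus analysis); with
#' `beat_window = "pre"` it comes from the pre-stimulus window
#' (baseline-shift analysis). Units with an undefined difference in either
#' statistic are dropped and counted.
#'
#' @param beat_diff Output of [beat_diffs()] for one phase.
#' @param memory_diff Output of [memory_diffs()] for the same phase.
#' @param memory_window One of `w1`..`w4`.
#' @param beat_window `"matched_post"` or `"pre"`.
#' @param alpha Significance threshold.
#' @return A one-row tibble with the analysis labels, `r`, `p`, `n_units`,
#'   `n_dropped`, `significant`.
#' @export
beat_memory_correlation <- function(beat_diff, memory_diff, memory_window,
                                    beat_window = c("matched_post", "pre"),
                                    alpha = 0.0125) {
  beat_window <- match.arg(beat_window)
  stopifnot(memory_window %in% analysis_windows())
  bw <- if (beat_window == "pre") "pre" else memory_window
  b <- beat_diff |>
    filter(.data$window == bw) |>
    select("unit_id", beat = "diff")
  m <- memory_diff |>
    filter(.data$window == memory_window) |>
    select("unit_id", mem = "diff")
  joined <- inner_join(b, m, by = "unit_id")
  usable <- joined |> filter(!is.na(.data$beat), !is.na(.data$mem))
  res <- pearson_with_threshold(usable$beat, usable$mem, alpha = alpha)
  tibble::tibble(
    phase = memory_diff$phase[1],
    memory_type = memory_diff$memory_type[1],
    run_scope = memory_diff$run_scope[1],
    beat_window = beat_window,
    memory_window = memory_window,
    r = res$r, p = res$p, n_units = res$n,
    n_dropped = nrow(joined) - nrow(usable),
    significant = res$significant
  )
}

#' Correlation table over the four post-stimulus windows
#'
#' Convenience wrapper running [beat_memory_correlation()] for `w1`..`w4`,
#' producing one row per window (one quadrant of the published-style
#' correlation tables). Windows with fewer than 3 usable units are reported
#' with `NA` correlation rather than an error.
#'
#' @inheritParams beat_memory_correlation
#' @return A four-row tibble.
#' @export
correlation_table <- function(beat_diff, memory_diff,
                              beat_window = c("matched_post", "pre"),
                              alpha = 0.0125) {
  beat_window <- match.arg(beat_window)
  rows <- lapply(analysis_windows(), function(w) {
    tryCatch(
      beat_memory_correlation(beat_diff, memory_diff, w, beat_window, alpha),
      beatmem_insufficient_data = function(e) tibble::tibble(
        phase = memory_diff$phase[1], memory_type = memory_diff$memory_type[1],
        run_scope = memory_diff$run_scope[1], beat_window = beat_window,
        memory_window = w, r = NA_real_, p = NA_real_, n_units = 0L,
        n_dropped = NA_integer_, significant = NA
      ),
      beatmem_degenerate_error = function(e) tibble::tibble(
        phase = memory_diff$phase[1], memory_type = memory_diff$memory_type[1],
        run_scope = memory_diff$run_scope[1], beat_window = beat_window,
        memory_window = w, r = NA_real_, p = NA_real_, n_units = NA_integer_,
        n_dropped = NA_integer_, significant = NA
      )
    )
  })
  bind_rows(rows)
}

#' Sign-adjusted pre-stimulus t-test
#'
#' Multiplies each selected unit's binaural-minus-monaural difference in the
#' pre-stimulus window by the sign (+1/-1) of its post-stimulus beat effect
#' and tests the products against zero with a two-sided one-sample t-test. A
#' significant positive shift confirms that the beat effect was already
#' present before stimulus onset (a baseline shift rather than an evoked
#' response).
#'
#' @param beat_diff Output of [beat_diffs()] for one phase.
#' @param selection Output of [select_beat_responsive()] for the same phase;
#'   only selected units (which have a defined direction) are used.
#' @param normalized Use the normalized pre-stimulus difference (default) or
#'   the raw difference in Hz.
#' @return A list with `t`, `p`, `df`, `n`, `mean_product`.
#' @export
prestim_sign_adjusted_test <- function(beat_diff, selection, normalized = TRUE) {
  sel <- selection |> filter(.data$selected)
  if (nrow(sel) < 2) {
    stop_insufficient("need at least 2 selected units with directions")
  }
  pre <- beat_diff |>
    filter(.data$window == "pre") |>
    inner_join(sel |> select("unit_id", "direction"), by = "unit_id")
  value <- if (normalized) pre$diff else pre$raw_diff
  sgn <- ifelse(pre$direction == "increase", 1, -1)
  products <- value * sgn
  products <- products[!is.na(products)]
  if (length(products) < 2) {
    stop_insufficient("need at least 2 defined pre-stimulus differences")
  }
  if (sd(products) == 0) {
    stop_degenerate("sign-adjusted products have zero variance")
  }
  tt <- stats::t.test(products, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(products),
       mean_product = mean(products))
}

#' Exploratory homeostatic correlation scheme
#'
#' Correlates firing-rate *levels* with memory-related differences across
#' beat-responsive units, as suggested by homeostatic plasticity: high-rate
#' units are expected to show smaller (or negative) remembered-vs-forgotten
#' differences. For each combination of analysis
#' (i, `pre_activity`: mean rate in the pre-stimulus window; ii,
#' `post_activity`: mean rate in the analyzed post-stimulus window), beat
#' condition (monaural/binaural), post-stimulus window, memory type and
#' phase, the units are split by the sign of their memory difference in the
#' analyzed window (zero joins the positive stratum) and a Pearson
#' correlation between activity and the signed difference is computed per
#' stratum: 2 x 2 x 2 x 4 x 2 x 2 = 128 correlations. A second variant
#' correlates activity with the absolute memory difference across all units
#' (64 correlations). Cells with fewer than 3 units are kept as `NA` rows.
#'
#' @param rates Per-trial rates from [trial_window_rates()].
#' @param trials Trial table.
#' @param selection Combined selection results for both phases (rows where
#'   `selected` is `TRUE` define the unit pool per phase).
#' @param run_scope Run scope for the memory differences.
#' @return A list with `main` (128-row tibble), `absolute` (64-row tibble),
#'   and `p_bands` (counts of p-values in [0, 0.05) and [0.05, 0.1) per
#'   table).
#' @export
homeostatic_exploration <- function(rates, trials, selection,
                                    run_scope = "all_runs") {
  act <- condition_window_rates(rates, trials, stimulated_only = TRUE) |>
    filter(.data$beat_condition %in% c("monaural", "binaural"))
  grid <- tidyr::expand_grid(
    phase = task_phases(),
    memory_type = c("item", "source"),
    analysis = c("pre_activity", "post_activity"),
    condition = c("monaural", "binaural"),
    window = analysis_windows()
  )
  mem_cache <- list()
  for (ph in task_phases()) {
    for (mt in c("item", "source")) {
      mem_cache[[paste(ph, mt)]] <-
        memory_diffs(rates, trials, ph, mt, run_scope = run_scope)
    }
  }
  sel <- selection |> filter(.data$selected)
  sel_by_phase <- split(sel, sel$phase)

  cell_cor <- function(a, d) {
    ok <- !is.na(a) & !is.na(d)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(d[ok]) == 0) {
      return(tibble::tibble(r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- stats::cor.test(a[ok], d[ok])
    tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }

  main_rows <- list()
  abs_rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    units <- sel_by_phase[[g$phase]]$unit_id
    md <- mem_cache[[paste(g$phase, g$memory_type)]] |>
      filter(.data$window == g$window, .data$unit_id %in% units) |>
      select("unit_id", mem = "diff")
    act_window <- if (g$analysis == "pre_activity") "pre" else g$window
    av <- act |>
      filter(.data$phase == g$phase, .data$beat_condition == g$condition,
             .data$window == act_window, .data$unit_id %in% units) |>
      select("unit_id", activity = "mean_rate")
    cell <- inner_join(md, av, by = "unit_id")
    # sign split; zero differences join the positive stratum
    pos <- cell |> filter(!is.na(.data$mem) & .data$mem >= 0)
    neg <- cell |> filter(!is.na(.data$mem) & .data$mem < 0)
    main_rows[[length(main_rows) + 1]] <- bind_cols(
      g, tibble::tibble(stratum = "positive"), cell_cor(pos$activity, pos$mem)
    )
    main_rows[[length(main_rows) + 1]] <- bind_cols(
      g, tibble::tibble(stratum = "negative"), cell_cor(neg$activity, neg$mem)
    )
    ok <- cell |> filter(!is.na(.data$mem))
    abs_rows[[length(abs_rows) + 1]] <- bind_cols(
      g, cell_cor(ok$activity, abs(ok$mem))
    )
  }
  main <- bind_rows(main_rows)
  absolute <- bind_rows(abs_rows)
  band <- function(tab) {
    p <- tab$p[!is.na(tab$p)]
    tibble::tibble(
      n_defined = length(p),
      n_p_lt_05 = sum(p < 0.05),
      n_p_05_to_10 = sum(p >= 0.05 & p < 0.1)
    )
  }
  list(
    main = main,
    absolute = absolute,
    p_bands = bind_rows(
      band(main) |> mutate(table = "main", .before = 1),
      band(absolute) |> mutate(table = "absolute", .before = 1)
    )
  )
}
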