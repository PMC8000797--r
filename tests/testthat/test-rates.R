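test_that("window_rate counts spikes in half-open windows", {
  ts <- c(0.1, 0.2, 0.3, 0.5, 1.9)
  expect_equal(window_rate(ts, onset = 0, start = 0, end = 0.5), 6) # 3 spikes / 0.5 s
  expect_equal(window_rate(numeric(0), onset = 0, start = 0, end = 0.5), 0)
  # spike exactly at onset+end is not counted; at onset+start it is
  expect_equal(window_rate(c(0.5), onset = 0, start = 0, end = 0.5), 0)
  expect_equal(window_rate(c(0.5), onset = 0, start = 0.5, end = 1), 2)
  # vectorized over onsets
  expect_equal(window_rate(ts, onset = c(0, 1.5), start = 0, end = 0.5), c(6, 2))
  expect_error(window_rate(c(2, 1), onset = 0, start = 0, end = 1),
               class = "beatmem_integrity_error")
  expect_error(window_rate(ts, onset = 0, start = 1, end = 1),
               class = "beatmem_config_error")
})

test_that("window spike counts partition the 0-2 s interval", {
  ds <- simulate_cohort(tiny_config(), seed = 5)
  rates <- trial_window_rates(ds)
  wide <- tidyr::pivot_wider(rates, names_from = "window", values_from = "rate")
  # counts: rate * length; w1..w4 (0.5 s each) must sum to full (2 s)
  expect_equal(0.5 * (wide$w1 + wide$w2 + wide$w3 + wide$w4), 2 * wide$full)
})

test_that("normalized difference matches its definition and symmetries", {
  expect_equal(normalized_difference(4, 2, 6, 6), 2 / 12)
  expect_equal(normalized_difference(3, 3, 5, 7), 0)
  # antisymmetric under swapping conditions
  expect_equal(normalized_difference(4, 2, 6, 6),
               -normalized_difference(2, 4, 6, 6))
  # invariant to common positive rescaling (the purpose of normalization)
  set.seed(1)
  for (i in 1:20) {
    x <- runif(4, 0, 10)
    k <- runif(1, 0.1, 50)
    expect_equal(normalized_difference(x[1], x[2], x[3], x[4]),
                 normalized_difference(k * x[1], k * x[2], k * x[3], k * x[4]))
  }
  # undefined when the denominator is zero; negative rates rejected
  expect_true(is.na(normalized_difference(0, 0, 0, 0)))
  expect_error(normalized_difference(-1, 0, 1, 1), class = "beatmem_config_error")
})

test_that("inclusion filter keeps units reaching 2 Hz in any condition window", {
  cell <- function(unit, rate) {
    tidyr::expand_grid(
      unit_id = unit, phase = c("encoding", "retrieval"),
      beat_condition = c("binaural", "monaural", "control"),
      window = analysis_windows()
    ) |> dplyr::mutate(mean_rate = rate, n_trials = 50)
  }
  low <- cell("low", 1.9)
  edge <- cell("edge", 1.0)
  edge$mean_rate[7] <- 2.0 # single cell exactly at threshold
  high <- cell("high", 3.5)
  kept <- inclusion_filter(dplyr::bind_rows(low, edge, high))
  expect_setequal(kept, c("edge", "high"))

  # pre-stimulus window rates do not count toward inclusion
  pre_only <- cell("pre_only", 0.5) |>
    dplyr::bind_rows(tibble::tibble(unit_id = "pre_only", phase = "encoding",
                                    beat_condition = "control", window = "pre",
                                    mean_rate = 10, n_trials = 50))
  expect_length(inclusion_filter(pre_only), 0)
})

test_that("a cohort of constructed rates reproduces the 346 -> 180 bookkeeping", {
  # 346 units, 166 with all condition-window means below 2 Hz
  set.seed(42)
  n_below <- 166
  n_above <- 180
  mk <- function(ids, rates) {
    tidyr::expand_grid(unit_id = ids, phase = c("encoding", "retrieval"),
                       beat_condition = c("binaural", "monaural", "control"),
                       window = analysis_windows()) |>
      dplyr::group_by(unit_id) |>
      dplyr::mutate(mean_rate = sample(rates, dplyr::n(), replace = TRUE),
                    n_trials = 50) |>
      dplyr::ungroup()
  }
  below <- mk(sprintf("b%03d", seq_len(n_below)), seq(0.05, 1.95, by = 0.05))
  above <- mk(sprintf("a%03d", seq_len(n_above)), seq(0.5, 6, by = 0.25))
  # guarantee each "above" unit one qualifying cell
  above$mean_rate[match(sprintf("a%03d", seq_len(n_above)), above$unit_id)] <- 2.5
  kept <- inclusion_filter(dplyr::bind_rows(below, above))
  expect_equal(length(kept), 180)
  expect_true(all(startsWith(kept, "a")))
})

test_that("condition-level beat differences use stimulated trials and the full-window denominator", {
  ds <- simulate_cohort(tiny_config(p_beat_responsive = 1), seed = 9)
  rates <- trial_window_rates(ds)
  bd <- beat_diffs(rates, ds$trials, "retrieval")
  expect_setequal(unique(bd$window), c("pre", analysis_windows()))
  # hand-recompute one unit/window from per-trial rates
  u <- bd$unit_id[1]
  stim <- ds$trials |>
    dplyr::filter(phase == "retrieval", stimulation_delivered)
  mean_rate <- function(cond, win) {
    ids <- stim$trial_id[stim$beat_condition == cond]
    r <- rates |> dplyr::filter(unit_id == u, window == win, trial_id %in% ids)
    mean(r$rate)
  }
  expected <- (mean_rate("binaural", "w2") - mean_rate("monaural", "w2")) /
    (mean_rate("binaural", "full") + mean_rate("monaural", "full"))
  expect_equal(bd$diff[bd$unit_id == u & bd$window == "w2"], expected)
  # trial counts: retrieval stimulation happens in scene runs, 75 + 75 trials
  expect_equal(nrow(stim |> dplyr::filter(beat_condition == "binaural")), 75)
})

test_that("memory differences respect run scope and outcome labels", {
  ds <- simulate_cohort(tiny_config(), seed = 13)
  rates <- trial_window_rates(ds)
  md_all <- memory_diffs(rates, ds$trials, "retrieval", "item", "all_runs")
  md_stim <- memory_diffs(rates, ds$trials, "retrieval", "item", "stimulated_runs")
  n_all <- ds$trials |>
    dplyr::filter(phase == "retrieval", item_outcome == "remembered") |> nrow()
  n_stim <- ds$trials |>
    dplyr::filter(phase == "retrieval", stimulation_delivered,
                  item_outcome == "remembered") |> nrow()
  expect_gt(n_all, n_stim)
  expect_false(identical(md_all$diff, md_stim$diff))
  expect_setequal(unique(md_all$window), c("pre", analysis_windows()))
})
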