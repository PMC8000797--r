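test_that("identical config and seed give identical datasets", {
  cfg <- tiny_config()
  d1 <- simulate_cohort(cfg, seed = 21)
  d2 <- simulate_cohort(cfg, seed = 21)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$units$timestamps, d2$units$timestamps)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_cohort(cfg, seed = 22)
  expect_false(identical(d1$units$timestamps, d3$units$timestamps))
})

test_that("paradigm structure matches the study design", {
  ds <- simulate_cohort(tiny_config(), seed = 2)
  tr <- ds$trials
  per_run <- tr |> dplyr::count(run_id, phase)
  expect_true(all(per_run$n[per_run$phase == "encoding"] == 50))
  expect_true(all(per_run$n[per_run$phase == "retrieval"] == 75))
  expect_equal(length(unique(tr$run_id)), 6)
  # 3 color runs stimulated at encoding, 3 scene runs at retrieval,
  # each beat condition exactly once per category
  runs <- tr |> dplyr::distinct(run_id, source_category, beat_condition)
  expect_equal(sort(runs$beat_condition[runs$source_category == "color"]),
               sort(beat_conditions()))
  expect_equal(sort(runs$beat_condition[runs$source_category == "scene"]),
               sort(beat_conditions()))
  stim <- tr |> dplyr::distinct(source_category, phase, stimulation_delivered)
  expect_true(all(stim$stimulation_delivered ==
                    (stim$source_category == "color" & stim$phase == "encoding" |
                     stim$source_category == "scene" & stim$phase == "retrieval")))
  # trial onsets ordered and within the recorded span
  expect_false(is.unsorted(tr$onset))
  for (i in seq_len(nrow(ds$units))) {
    ts <- ds$units$timestamps[[i]]
    expect_false(is.unsorted(ts))
    expect_true(all(ts >= 0))
  }
})

test_that("effective_rate implements the baseline-shift model", {
  # no coupling: memory gain applies regardless of the beat shift
  expect_equal(effective_rate(4, 1.8, 1.3, "binaural", "remembered", "w2"),
               4 * 1.8 * 1.3)
  expect_equal(effective_rate(4, 1.8, 1.3, "monaural", "remembered", "w2"), 4 * 1.3)
  expect_equal(effective_rate(4, 1.8, 1.3, "control", "forgotten", "w2"), 4)
  # the shift is present pre-stimulus but memory modulation is not
  expect_equal(effective_rate(4, 1.8, 1.3, "binaural", "remembered", "pre"), 4 * 1.8)
  # memory modulation restricted to the configured windows
  expect_equal(effective_rate(4, 1, 1.3, "control", "remembered", "w1",
                              memory_windows = "w3"), 4)
  expect_error(effective_rate(4, 1, 1.3, "control", "remembered", "w9"),
               class = "beatmem_config_error")
})

test_that("memory gains decrease with the signed baseline shift", {
  cfg <- simulation_config(n_subjects = 2, units_per_region_hemisphere = 4,
                           p_beat_responsive = 1, memory_gain_sd = 1e-9,
                           coupling = 0.5)
  ds <- simulate_cohort(cfg, seed = 31)
  tru <- ds$truth
  up <- tru$memory_gain[tru$beat_shift > 0]
  down <- tru$memory_gain[tru$beat_shift < 0]
  expect_lt(max(up), min(down)) # sign algebra of the homeostatic coupling
  # kappa = 0 removes the coupling entirely
  cfg0 <- simulation_config(n_subjects = 1, units_per_region_hemisphere = 4,
                            coupling = 0, memory_gain_sd = 1e-9)
  t0 <- simulate_cohort(cfg0, seed = 31)$truth
  expect_equal(t0$memory_gain, rep(cfg0$memory_gain_base, nrow(t0)),
               tolerance = 1e-6)
})

test_that("a null config yields zero true normalized differences", {
  cfg <- simulation_config(n_subjects = 1, units_per_region_hemisphere = 2,
                           beat_gain = 1, p_beat_responsive = 0, coupling = 0,
                           memory_gain_base = 1, memory_gain_sd = 0)
  tru <- simulate_cohort(cfg, seed = 8)$truth
  expect_true(all(tru$true_diff_beat == 0))
  expect_true(all(tru$true_diff_memory_w2 == 0))
  expect_true(all(tru$true_diff_memory_w3 == 0))
})

test_that("window spike counts follow the configured Poisson law", {
  # 4 Hz baseline, 0.5 s windows: mean count 2.0 per window
  cfg <- simulation_config(n_subjects = 1, units_per_region_hemisphere = 1,
                           baseline_median_hz = 4, baseline_log_sd = 0,
                           p_beat_responsive = 0, memory_gain_base = 1,
                           memory_gain_sd = 0, coupling = 0)
  ds <- simulate_cohort(cfg, seed = 17)
  rates <- trial_window_rates(ds)
  # one unit, one stimulated retrieval run: 75 trials at the baseline rate
  run1 <- ds$trials |>
    dplyr::filter(phase == "retrieval", stimulation_delivered,
                  beat_condition == "control")
  u1 <- ds$units$unit_id[1]
  counts <- 0.5 * rates$rate[rates$window == "w1" & rates$unit_id == u1 &
                               rates$trial_id %in% run1$trial_id]
  n <- length(counts)
  expect_equal(n, 75)
  se <- sqrt(2.0 / n) # Poisson variance equals the mean
  expect_lt(abs(mean(counts) - 2.0), 3 * se)
})

test_that("empirical per-window rates track the effective rate model", {
  cfg <- simulation_config(n_subjects = 1, units_per_region_hemisphere = 2,
                           p_beat_responsive = 1, baseline_log_sd = 0.2)
  ds <- simulate_cohort(cfg, seed = 23)
  rates <- trial_window_rates(ds)
  tr <- ds$trials |>
    dplyr::filter(phase == "retrieval", stimulation_delivered,
                  beat_condition == "binaural")
  tru <- ds$truth
  for (i in seq_len(4)) { # spot-check a few units
    u <- tru$unit_id[i]
    lam <- effective_rate(tru$baseline_hz[i], tru$beat_gain_factor[i],
                          tru$memory_gain[i], "binaural", "forgotten", "w1")
    obs <- rates |>
      dplyr::filter(unit_id == u, window == "w1",
                    trial_id %in% tr$trial_id[tr$item_outcome == "forgotten"])
    n <- nrow(obs)
    if (n >= 5) {
      se <- sqrt(lam / (0.5 * n)) # var of a per-trial rate is lam/0.5
      expect_lt(abs(mean(obs$rate) - lam), 4 * se)
    }
  }
})

test_that("coupling calibration places the true shift/gain correlation near target", {
  cfg <- simulation_config(n_subjects = 5, units_per_region_hemisphere = 3,
                           p_beat_responsive = 1, memory_windows = "w3")
  in_band <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    tru <- simulate_cohort(cfg, seed = 300 + s)$truth
    left <- tru[tru$hemisphere == "left", ]
    r <- cor(left$beat_shift, left$true_diff_memory_w3)
    if (r >= -0.75 && r <= -0.45) in_band <- in_band + 1
  }
  expect_gte(in_band, 16) # ~92% expected at n=60 units from the Fisher-z width
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(p_hit = 1.2), class = "beatmem_config_error")
  expect_error(simulation_config(beat_gain = -1), class = "beatmem_config_error")
  expect_error(simulation_config(coupling = -0.5), class = "beatmem_config_error")
  expect_error(simulation_config(memory_windows = "w7"),
               class = "beatmem_config_error")
  expect_error(simulation_config(condition_offset = 0.5),
               class = "beatmem_config_error")
  expect_error(coupling_for_correlation(0.6, 1.8, 0.45),
               class = "beatmem_config_error")
})
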