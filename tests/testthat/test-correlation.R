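test_that("pearson_with_threshold matches hand computation and guards input", {
  perfect <- pearson_with_threshold(1:10, -(1:10))
  expect_equal(perfect$r, -1)
  # hand-computed covariance/variance ratio for a 3-point example
  res <- pearson_with_threshold(c(1, 2, 3), c(1, 2, 4))
  # cov = 3/2, var(x) = 1, var(y) = 7/3
  expect_equal(res$r, (3 / 2) / sqrt(7 / 3), tolerance = 1e-9)
  expect_equal(round(res$r, 4), 0.982)
  expect_error(pearson_with_threshold(1:2, 1:2),
               class = "beatmem_insufficient_data")
  expect_error(pearson_with_threshold(rep(1, 5), 1:5),
               class = "beatmem_degenerate_error")
  expect_error(pearson_with_threshold(1:4, 1:5), class = "beatmem_domain_error")
})

test_that("correlation p-values are uniform under independence", {
  set.seed(2024)
  ps <- replicate(500, pearson_with_threshold(rnorm(30), rnorm(30))$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(ps < 0.0125), 0.04)
})

test_that("beat_memory_correlation joins diffs by unit and window", {
  mk_diff <- function(units, window, values, phase = "retrieval") {
    tibble::tibble(phase = phase, unit_id = units, window = window,
                   diff = values, raw_diff = values)
  }
  units <- sprintf("u%02d", 1:12)
  set.seed(5)
  beat <- rnorm(12)
  bd <- dplyr::bind_rows(mk_diff(units, "w2", beat), mk_diff(units, "pre", beat / 2))
  md <- dplyr::bind_rows(
    mk_diff(units, "w2", -2 * beat + 3),      # exact negative affine map
    mk_diff(units, "w3", rnorm(12))
  )
  md$memory_type <- "item"
  md$run_scope <- "all_runs"

  exact <- beat_memory_correlation(bd, md, "w2", "matched_post")
  expect_equal(exact$r, -1)
  expect_true(exact$significant)
  expect_equal(exact$n_units, 12)

  # pre window beat diffs are an exact positive multiple of the post ones
  pre <- beat_memory_correlation(bd, md, "w2", "pre")
  expect_equal(pre$r, -1)

  # dropping NA units does not perturb r on the remainder
  bd_na <- bd
  bd_na$diff[bd_na$unit_id == "u01"] <- NA
  dropped <- beat_memory_correlation(bd_na, md, "w2", "matched_post")
  keep <- units[-1]
  expect_equal(dropped$n_dropped, 1)
  expect_equal(dropped$r, cor(beat[-1], (-2 * beat + 3)[-1]))

  # constant diffs across units are a degenerate-variance error
  md_const <- md
  md_const$diff <- 0.2
  expect_error(beat_memory_correlation(bd, md_const, "w2"),
               class = "beatmem_degenerate_error")
})

test_that("sign-adjusted pre-stimulus test behaves per contract", {
  sel <- tibble::tibble(
    unit_id = sprintf("u%02d", 1:10), phase = "encoding",
    selected = TRUE,
    direction = rep(c("increase", "decrease"), 5)
  )
  mk_bd <- function(pre_vals) {
    tibble::tibble(phase = "encoding", unit_id = sprintf("u%02d", 1:10),
                   window = "pre", diff = pre_vals, raw_diff = pre_vals * 2)
  }
  # products symmetric around zero -> t ~ 0, p ~ 1
  sel_inc <- sel |> dplyr::mutate(direction = "increase")
  vals <- rep(c(0.1, -0.1), 5)
  res <- prestim_sign_adjusted_test(mk_bd(vals), sel_inc)
  expect_lt(abs(res$t), 1e-8)
  expect_equal(res$p, 1)

  # consistent baseline shift: strongly positive products
  set.seed(3)
  shift <- 0.2 + rnorm(10, 0, 0.02)
  res2 <- prestim_sign_adjusted_test(mk_bd(shift * rep(c(1, -1), 5)), sel)
  expect_lt(res2$p, 1e-6)
  expect_gt(res2$mean_product, 0)

  # raw variant uses the Hz difference
  res3 <- prestim_sign_adjusted_test(mk_bd(shift * rep(c(1, -1), 5)), sel,
                                     normalized = FALSE)
  expect_equal(res3$mean_product, 2 * res2$mean_product, tolerance = 1e-9)

  # identical products have zero variance
  expect_error(
    prestim_sign_adjusted_test(mk_bd(0.1 * rep(c(1, -1), 5)), sel),
    class = "beatmem_degenerate_error"
  )
  expect_error(prestim_sign_adjusted_test(mk_bd(vals), sel[0, ]),
               class = "beatmem_insufficient_data")
})

test_that("the exploratory homeostatic table has the full factorization", {
  cfg <- tiny_config(p_beat_responsive = 1)
  ds <- simulate_cohort(cfg, seed = 41)
  rates <- trial_window_rates(ds)
  sel <- dplyr::bind_rows(
    select_beat_responsive(rates, ds$trials, ds$units, "encoding", hemisphere = "left"),
    select_beat_responsive(rates, ds$trials, ds$units, "retrieval", hemisphere = "left")
  )
  ex <- homeostatic_exploration(rates, ds$trials, sel)
  expect_equal(nrow(ex$main), 128)
  expect_equal(nrow(ex$absolute), 64)
  # the factorization: 2 strata x 2 analyses x 2 conditions x 4 windows x
  # 2 memory types x 2 phases
  expect_equal(nrow(dplyr::distinct(
    ex$main, phase, memory_type, analysis, condition, window, stratum)), 128)
  expect_true(all(c("n_defined", "n_p_lt_05", "n_p_05_to_10") %in%
                    names(ex$p_bands)))
  # cells with < 3 units stay in the table as NA rows
  sel_none <- sel |> dplyr::mutate(selected = FALSE)
  ex0 <- homeostatic_exploration(rates, ds$trials, sel_none)
  expect_equal(nrow(ex0$main), 128)
  expect_true(all(is.na(ex0$main$r)))
})

test_that("strong rate-level homeostatic coupling makes activity anticorrelate with memory effects", {
  # memory-effect magnitude shrinks with the unit's firing level; with a
  # wide baseline-rate spread the absolute-value variant is negative in
  # every defined cell for essentially all seeds. (The activity measured in
  # a memory window contains the memory gain itself, a positive
  # contamination; a wide rate spread keeps it subordinate.)
  cfg <- simulation_config(
    n_subjects = 2, units_per_region_hemisphere = 10,
    p_beat_responsive = 1, coupling = 0, rate_coupling = 3,
    memory_gain_base = 1, memory_gain_sd = 0.4, baseline_log_sd = 0.8,
    memory_windows = analysis_windows()
  )
  all_neg <- vapply(1:8, function(s) {
    ds <- simulate_cohort(cfg, seed = 600 + s)
    rates <- trial_window_rates(ds)
    sel <- dplyr::bind_rows(
      select_beat_responsive(rates, ds$trials, ds$units, "encoding", hemisphere = "left"),
      select_beat_responsive(rates, ds$trials, ds$units, "retrieval", hemisphere = "left")
    )
    ex <- homeostatic_exploration(rates, ds$trials, sel)
    r <- ex$absolute$r
    all(r[!is.na(r)] < 0)
  }, logical(1))
  expect_gte(mean(all_neg), 0.9)
})

test_that("pre- and post-window beat diffs estimate the same baseline shift", {
  # the simulated shift is identical pre- and post-stimulus, so measured
  # pre-window and post-window beat diffs agree up to trial sampling noise
  cfg <- simulation_config(n_subjects = 1, units_per_region_hemisphere = 6,
                           p_beat_responsive = 1)
  ds <- simulate_cohort(cfg, seed = 55)
  rates <- trial_window_rates(ds)
  bd <- beat_diffs(rates, ds$trials, "retrieval")
  wide <- tidyr::pivot_wider(bd |> dplyr::select(unit_id, window, diff),
                             names_from = "window", values_from = "diff")
  expect_gt(cor(wide$pre, wide$w1), 0.7)
  expect_equal(mean(wide$pre), mean(wide$w1), tolerance = 0.15)
})
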