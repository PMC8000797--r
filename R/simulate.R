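# Synthetic cohort generator: homogeneous-Poisson spike trains whose
# window-wise rates follow a homeostatic baseline-shift model, plus a
# behavioral response model producing the associative recognition paradigm
# (6 runs x 50 encoding / 75 retrieval trials, three beat conditions).

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. The defaults reproduce the paradigm
#' scale of the recorded study population: 5 subjects, 6 runs each (3 color
#' runs stimulated at encoding, 3 scene runs stimulated at retrieval, beat
#' condition counterbalanced by a seeded Latin square), 50 encoding and 75
#' retrieval trials per run, and unit baseline rates log-normal around a
#' median of 3 Hz so that condition means of kept units fall in the 3-5 Hz
#' range typical of human MTL units.
#'
#' The firing model is multiplicative on the Poisson rate. A beat-responsive
#' unit carries a gain `beat_gain^s` (`s = +/-1` drawn per unit) on binaural
#' relative to monaural trials, applied in the pre-stimulus and all
#' post-stimulus windows of trials whose phase was actually stimulated: the
#' "baseline shift". Remembered trials carry a memory gain
#' `exp((log(memory_gain_base) + e) * h(b) - coupling * shift)` with
#' `e ~ N(0, memory_gain_sd)`, `shift = beat_gain^s - 1`, and
#' `h(b) = 2 / (1 + (b/median)^rate_coupling)` a bounded decreasing function
#' of the unit's baseline rate (1 at the median rate, at most 2): the memory
#' modulation decreases with the signed baseline shift (homeostatic
#' coupling, strength `coupling`) and optionally with the unit's overall
#' firing level (`rate_coupling`; 0 makes `h` identically 1). The
#' exponential form is the positive-rate realization of the linear gain
#' `m0 - coupling * shift`.
#'
#' @param n_subjects Number of subjects.
#' @param units_per_region_hemisphere Units simulated in each of the 8
#'   region x hemisphere cells, per subject.
#' @param baseline_median_hz,baseline_log_sd Median (Hz) and log-sd of the
#'   log-normal unit baseline rate law.
#' @param p_beat_responsive Probability that a unit carries a beat effect.
#' @param beat_gain Multiplicative binaural/monaural gain magnitude (> 1);
#'   the sign of the exponent is drawn per unit.
#' @param memory_gain_base Median remembered/forgotten gain `m0` (> 0).
#' @param memory_gain_sd Log-scale sd of the unit-specific memory gain;
#'   this heterogeneity is what makes the coupling a correlation rather than
#'   a deterministic relation.
#' @param coupling Homeostatic coupling strength `kappa >= 0` between the
#'   signed beat shift and the log memory gain. The default is calibrated
#'   with [coupling_for_correlation()] to a true shift/gain correlation of
#'   -0.6 among responsive units.
#' @param rate_coupling Exponent `>= 0` of the bounded shrink `h(b)` that
#'   damps the memory modulation of high-rate units (0 disables; used to
#'   emulate rate-level homeostasis).
#' @param memory_windows Post-stimulus windows (subset of `w1`..`w4`)
#'   carrying the memory modulation.
#' @param p_hit,p_false_alarm Item recognition probabilities for old and new
#'   words.
#' @param p_source_correct,p_source_unsure Source response probabilities,
#'   conditional on a hit; the wrong-source probability is the remainder.
#' @param condition_offset Behavioral offset `delta`: `p_hit` and
#'   `p_source_correct` are shifted by `+delta` on binaural and `-delta` on
#'   monaural runs.
#' @param p_single_unit Probability a unit is labeled a single unit (vs
#'   multi-unit).
#' @param encoding_trial_s,retrieval_trial_s,intertrial_s,interphase_gap_s
#'   Timing of the paradigm (seconds).
#' @return A validated list with class `simulation_config`.
#' @export
simulation_config <- function(
    n_subjects = 5,
    units_per_region_hemisphere = 9,
    baseline_median_hz = 3,
    baseline_log_sd = 0.4,
    p_beat_responsive = 0.4,
    beat_gain = 1.8,
    memory_gain_base = 1.1,
    memory_gain_sd = 0.45,
    coupling = coupling_for_correlation(-0.6, beat_gain, memory_gain_sd),
    rate_coupling = 0,
    memory_windows = c("w2", "w3"),
    p_hit = 0.85,
    p_false_alarm = 0.19,
    p_source_correct = 0.63,
    p_source_unsure = 0.12,
    condition_offset = 0.04,
    p_single_unit = 0.5,
    encoding_trial_s = 3.5,
    retrieval_trial_s = 5,
    intertrial_s = 1,
    interphase_gap_s = 60) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

stop_config <- function(msg) abort(msg, class = "beatmem_config_error")

validate_simulation_config <- function(cfg) {
  probs <- c("p_beat_responsive", "p_hit", "p_false_alarm", "p_source_correct",
             "p_source_unsure", "p_single_unit")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_config(sprintf("%s must be a probability in [0, 1]", p))
    }
  }
  if (cfg$p_source_correct + cfg$p_source_unsure > 1) {
    stop_config("p_source_correct + p_source_unsure must not exceed 1")
  }
  d <- cfg$condition_offset
  if (d < 0 || cfg$p_hit + d > 1 || cfg$p_hit - d < 0 ||
      cfg$p_source_correct + d + cfg$p_source_unsure > 1 || cfg$p_source_correct - d < 0) {
    stop_config("condition_offset drives a behavioral probability outside [0, 1]")
  }
  pos <- c("baseline_median_hz", "beat_gain", "memory_gain_base",
           "encoding_trial_s", "retrieval_trial_s")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) stop_config(sprintf("%s must be > 0", p))
  }
  nonneg <- c("baseline_log_sd", "memory_gain_sd", "coupling", "rate_coupling",
              "intertrial_s", "interphase_gap_s")
  for (p in nonneg) {
    if (!is.numeric(cfg[[p]]) || is.na(cfg[[p]]) || cfg[[p]] < 0) {
      stop_config(sprintf("%s must be >= 0", p))
    }
  }
  if (cfg$n_subjects < 1 || cfg$units_per_region_hemisphere < 1) {
    stop_config("n_subjects and units_per_region_hemisphere must be >= 1")
  }
  bad_w <- setdiff(cfg$memory_windows, analysis_windows())
  if (length(bad_w) > 0) {
    stop_config(sprintf("memory_windows must be a subset of w1..w4 (got %s)",
                        paste(bad_w, collapse = ", ")))
  }
  cfg
}

#' Coupling strength yielding a target shift/gain correlation
#'
#' Among beat-responsive units the signed baseline shift takes the two
#' values `g - 1` and `1/g - 1` with equal probability, and the memory gain
#' is `m = L * exp(-kappa * shift)` with `L` log-normal
#' (`log L ~ N(log m0, memory_gain_sd^2)`). The Pearson correlation between
#' shift and gain follows in closed form from the log-normal moments; this
#' function inverts it numerically (uniroot) to find the `kappa` giving a
#' target correlation `rho`.
#'
#' @param rho Target correlation, in (-1, 0).
#' @param beat_gain Beat gain magnitude `g > 1`.
#' @param memory_gain_sd Log-scale memory gain sd (> 0).
#' @param memory_gain_base Median memory gain `m0` (scale factor; it does
#'   not affect the correlation, kept for completeness).
#' @return The coupling strength `kappa >= 0`.
#' @export
#' @examples
#' coupling_for_correlation(-0.6, beat_gain = 1.8, memory_gain_sd = 0.45)
coupling_for_correlation <- function(rho, beat_gain, memory_gain_sd,
                                     memory_gain_base = 1.1) {
  if (!is.numeric(rho) || rho <= -1 || rho >= 0) {
    stop_config("rho must lie in (-1, 0)")
  }
  if (memory_gain_sd <= 0) stop_config("memory_gain_sd must be > 0")
  if (beat_gain <= 1) stop_config("beat_gain must exceed 1 to carry a shift")
  s <- c(beat_gain - 1, 1 / beat_gain - 1)
  var_s <- ((s[1] - s[2]) / 2)^2
  mu_l <- memory_gain_base * exp(memory_gain_sd^2 / 2)
  var_l <- mu_l^2 * (exp(memory_gain_sd^2) - 1)
  cor_at <- function(kappa) {
    a <- exp(-kappa * s)
    e_m <- mu_l * mean(a)
    cov_sm <- mu_l * mean(s * a) - mean(s) * e_m
    var_m <- (mu_l^2 + var_l) * mean(a^2) - e_m^2
    cov_sm / sqrt(var_s * var_m)
  }
  stats::uniroot(function(k) cor_at(k) - rho, lower = 0, upper = 100,
                 tol = 1e-10)$root
}

#' Window-wise Poisson rate of a simulated unit
#'
#' The rate is `baseline * beat_factor * memory_factor` (Hz): the beat factor
#' applies on binaural trials in the pre-stimulus and all post-stimulus
#' windows (the baseline shift; monaural and control trials sit at baseline),
#' and the memory factor applies on remembered trials in the configured
#' memory windows.
#'
#' @param baseline_hz Unit baseline rate (Hz).
#' @param beat_gain_factor The unit's binaural gain factor (`beat_gain^s`; 1
#'   for non-responsive units).
#' @param memory_gain The unit's remembered/forgotten gain.
#' @param condition `"binaural"`, `"monaural"` or `"control"`.
#' @param outcome `"remembered"`, `"forgotten"` or `"excluded"`.
#' @param window One of `pre`, `w1`..`w4`.
#' @param memory_windows Windows carrying the memory modulation.
#' @return Rate in Hz (vectorized over the first five arguments).
#' @export
effective_rate <- function(baseline_hz, beat_gain_factor, memory_gain,
                           condition, outcome, window,
                           memory_windows = c("w2", "w3")) {
  ok_w <- window %in% c("pre", analysis_windows())
  if (any(!ok_w)) stop_config(sprintf("unknown window: %s", window[!ok_w][1]))
  beat <- ifelse(condition == "binaural", beat_gain_factor, 1)
  mem <- ifelse(outcome == "remembered" & window %in% memory_windows, memory_gain, 1)
  lambda <- baseline_hz * beat * mem
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop_config("effective rate is not a positive finite number; check gains")
  }
  lambda
}

# --- trial table ------------------------------------------------------------

# Latin square over the three beat conditions; each subject gets one row per
# source category so every (category, condition) pair occurs exactly once
condition_square <- function() {
  base <- beat_conditions()
  rbind(base, base[c(2, 3, 1)], base[c(3, 1, 2)], deparse.level = 0)
}

simulate_subject_trials <- function(cfg, subject_id, color_row, scene_row) {
  square <- condition_square()
  # runs 1,3,5 are color (encoding-stimulated); 2,4,6 scene (retrieval-stimulated)
  run_category <- rep(c("color", "scene"), 3)
  run_condition <- character(6)
  run_condition[run_category == "color"] <- square[color_row, ]
  run_condition[run_category == "scene"] <- square[scene_row, ]

  t_cursor <- 0
  rows <- vector("list", 6)
  for (r in seq_len(6)) {
    run_id <- sprintf("%s_r%d", subject_id, r)
    cond <- run_condition[r]
    category <- run_category[r]
    stim_phase <- if (category == "color") "encoding" else "retrieval"

    old_words <- sprintf("%s_w%03d", run_id, seq_len(50))
    truth <- sample(c("source_a", "source_b"), 50, replace = TRUE)
    enc_onsets <- t_cursor + (seq_len(50) - 1) * (cfg$encoding_trial_s + cfg$intertrial_s) + 0.5
    enc <- tibble::tibble(
      trial_id = sprintf("%s_enc%03d", run_id, seq_len(50)),
      subject_id = subject_id, run_id = run_id, phase = "encoding",
      onset = enc_onsets, beat_condition = cond,
      stimulation_delivered = stim_phase == "encoding",
      source_category = category, word = old_words, novelty = "na",
      response = "none", source_truth = truth
    )
    t_cursor <- max(enc_onsets) + cfg$encoding_trial_s + cfg$interphase_gap_s

    new_words <- sprintf("%s_new%03d", run_id, seq_len(25))
    order <- sample.int(75)
    ret_word <- c(old_words, new_words)[order]
    ret_truth <- c(truth, rep("na", 25))[order]
    ret_novelty <- c(rep("old", 50), rep("new", 25))[order]
    ret_onsets <- t_cursor + (seq_len(75) - 1) * (cfg$retrieval_trial_s + cfg$intertrial_s) + 0.5

    # behavioral model with per-run condition offsets on hits and source accuracy
    delta <- switch(cond, binaural = cfg$condition_offset,
                    monaural = -cfg$condition_offset, 0)
    p_hit <- cfg$p_hit + delta
    p_src <- cfg$p_source_correct + delta
    n_ret <- 75
    is_old <- ret_novelty == "old"
    response <- rep("new", n_ret)
    hit <- is_old & runif(n_ret) < p_hit
    u <- runif(n_ret)
    src_resp <- ifelse(u < p_src, "correct",
                       ifelse(u < p_src + cfg$p_source_unsure, "unsure", "wrong"))
    other <- ifelse(ret_truth == "source_a", "source_b", "source_a")
    response[hit] <- ifelse(src_resp == "correct", ret_truth,
                            ifelse(src_resp == "unsure", "unsure", other))[hit]
    fa <- !is_old & runif(n_ret) < cfg$p_false_alarm
    response[fa] <- sample(c("source_a", "source_b", "unsure"), sum(fa), replace = TRUE)

    ret <- tibble::tibble(
      trial_id = sprintf("%s_ret%03d", run_id, seq_len(75)),
      subject_id = subject_id, run_id = run_id, phase = "retrieval",
      onset = ret_onsets, beat_condition = cond,
      stimulation_delivered = stim_phase == "retrieval",
      source_category = category, word = ret_word, novelty = ret_novelty,
      response = response, source_truth = ret_truth
    )
    t_cursor <- max(ret_onsets) + cfg$retrieval_trial_s + cfg$interphase_gap_s
    rows[[r]] <- bind_rows(enc, ret)
  }
  bind_rows(rows)
}

# --- units and spikes -------------------------------------------------------

simulate_subject_units <- function(cfg, subject_id) {
  grid <- tidyr::expand_grid(
    region = mtl_regions(), hemisphere = hemispheres(),
    idx = seq_len(cfg$units_per_region_hemisphere)
  )
  n <- nrow(grid)
  baseline <- rlnorm(n, meanlog = log(cfg$baseline_median_hz), sdlog = cfg$baseline_log_sd)
  responsive <- runif(n) < cfg$p_beat_responsive
  sign <- ifelse(runif(n) < 0.5, 1, -1)
  gain_factor <- ifelse(responsive, cfg$beat_gain^sign, 1)
  shift <- gain_factor - 1
  # bounded homeostatic shrink: 1 at the median rate, -> 2 for sparse units,
  # -> 0 for high-rate units (keeps rates finite for any coupling strength)
  shrink <- 2 / (1 + (baseline / cfg$baseline_median_hz)^cfg$rate_coupling)
  log_gain <- (log(cfg$memory_gain_base) + rnorm(n, 0, cfg$memory_gain_sd)) * shrink -
    cfg$coupling * shift
  memory_gain <- exp(log_gain)
  tibble::tibble(
    unit_id = sprintf("%s_%s_%s_u%02d", subject_id,
                      ifelse(grid$hemisphere == "left", "L", "R"),
                      grid$region, grid$idx),
    subject_id = subject_id,
    region = grid$region,
    hemisphere = grid$hemisphere,
    unit_class = ifelse(runif(n) < cfg$p_single_unit, "single", "multi"),
    baseline_hz = baseline,
    responsive = responsive,
    beat_gain_factor = gain_factor,
    beat_shift = shift,
    memory_gain = memory_gain
  )
}

# Poisson spikes for one unit over one subject's session: piecewise-constant
# rate over the six 500 ms peristimulus windows of every trial, uniform
# background at baseline elsewhere
simulate_unit_spikes <- function(unit, trials, cfg) {
  wd <- window_defs() |> filter(.data$window != "full")
  onsets <- trials$onset
  cond <- ifelse(trials$stimulation_delivered, trials$beat_condition, "control")
  outcome <- trials$item_outcome
  n_tr <- length(onsets)

  spikes <- vector("list", nrow(wd) + 1)
  for (i in seq_len(nrow(wd))) {
    lambda <- effective_rate(unit$baseline_hz, unit$beat_gain_factor,
                             unit$memory_gain, cond, outcome, wd$window[i],
                             cfg$memory_windows)
    len <- wd$end[i] - wd$start[i]
    counts <- rpois(n_tr, lambda * len)
    spikes[[i]] <- rep(onsets + wd$start[i], counts) + runif(sum(counts)) * len
  }
  # background between peristimulus windows (trials are in onset order)
  gap_start <- c(0, onsets + 2.0)
  gap_end <- c(onsets - 0.5, max(onsets) + 2.0 + cfg$interphase_gap_s)
  gap_len <- pmax(gap_end - gap_start, 0)
  counts <- rpois(length(gap_len), unit$baseline_hz * gap_len)
  spikes[[nrow(wd) + 1]] <- rep(gap_start, counts) + runif(sum(counts)) * rep(gap_len, counts)

  sort(unlist(spikes, use.names = FALSE))
}

# --- cohort -----------------------------------------------------------------

#' Simulate a cohort of subjects with ground truth
#'
#' Generates the full paradigm (trial tables with behavioral responses and
#' derived memory outcomes) and homogeneous-Poisson spike trains for every
#' unit, following the baseline-shift model described in
#' [simulation_config()]. Identical `config` and `seed` yield identical
#' datasets.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A [beat_dataset()] whose `truth` element records, per unit, the
#'   drawn baseline rate, responsiveness, signed beat shift, memory gain, and
#'   the true (noise-free) normalized beat and memory differences per window.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  validate_simulation_config(config)
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  # seeded counterbalancing: rotate the Latin square rows across subjects
  offset <- sample.int(3, 2, replace = TRUE)
  all_units <- vector("list", length(subjects))
  all_trials <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    color_row <- 1 + (i - 1 + offset[1]) %% 3
    scene_row <- 1 + (i - 1 + offset[2]) %% 3
    trials <- simulate_subject_trials(config, subjects[i], color_row, scene_row)
    trials <- derive_memory_outcomes(trials, quiet = TRUE)
    units <- simulate_subject_units(config, subjects[i])
    units$timestamps <- lapply(seq_len(nrow(units)), function(j) {
      simulate_unit_spikes(units[j, ], trials, config)
    })
    units$n_spikes <- lengths(units$timestamps)
    all_units[[i]] <- units
    all_trials[[i]] <- trials
  }
  units <- bind_rows(all_units) |> arrange(.data$unit_id)
  trials <- bind_rows(all_trials)
  truth <- ground_truth(units, config)
  dataset_units <- units |>
    select(dplyr::all_of(c("unit_id", "subject_id", "region", "hemisphere",
                           "unit_class", "n_spikes", "timestamps")))
  beat_dataset(dataset_units, trials, truth = truth)
}

# true (noise-free) normalized differences implied by the rate model,
# evaluated at the forgotten-outcome margin
ground_truth <- function(units, cfg) {
  k <- length(cfg$memory_windows)
  m <- units$memory_gain
  diff_mem <- 4 * (m - 1) / (8 - k + k * m)
  g <- units$beat_gain_factor
  truth <- units |>
    select(dplyr::all_of(c("unit_id", "subject_id", "region", "hemisphere",
                           "baseline_hz", "responsive", "beat_gain_factor",
                           "beat_shift", "memory_gain")))
  truth$true_diff_beat <- (g - 1) / (g + 1)
  for (w in analysis_windows()) {
    truth[[paste0("true_diff_memory_", w)]] <-
      if (w %in% cfg$memory_windows) diff_mem else 0
  }
  truth$condition_offset <- cfg$condition_offset
  truth
}
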