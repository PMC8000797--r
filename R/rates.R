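# Window-based firing-rate extraction, the 2 Hz inclusion filter, and the
# normalized firing-rate difference statistics.

#' Firing rate of a spike train in one peristimulus window
#'
#' Counts spikes with `onset + start <= t < onset + end` (half-open window)
#' and divides by the window length. Vectorized over `onset`.
#'
#' @param timestamps Sorted spike times (seconds, session clock).
#' @param onset Trial onset(s) in seconds.
#' @param start,end Window bounds in seconds relative to onset (`end > start`).
#' @return Rate(s) in Hz, one per onset.
#' @export
#' @examples
#' window_rate(c(0.1, 0.2, 0.3), onset = 0, start = 0, end = 0.5) # 6 Hz
window_rate <- function(timestamps, onset, start, end) {
  if (end <= start) stop_config("window end must exceed start")
  if (is.unsorted(timestamps)) {
    stop_integrity("timestamps must be nondecreasing")
  }
  n_before <- function(y) findInterval(y, timestamps, left.open = TRUE)
  (n_before(onset + end) - n_before(onset + start)) / (end - start)
}

#' Per-trial firing rates in every analysis window
#'
#' Computes, for every unit and every trial of its subject, the firing rate
#' in the `pre`, `w1`..`w4` and `full` windows (see [window_defs()]).
#'
#' @param dataset A [beat_dataset()].
#' @return A long tibble with columns `unit_id`, `trial_id`, `window`,
#'   `rate` (Hz).
#' @export
trial_window_rates <- function(dataset) {
  wd <- window_defs()
  trials_by_subject <- split(dataset$trials, dataset$trials$subject_id)
  units <- dataset$units
  out <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    tr <- trials_by_subject[[units$subject_id[i]]]
    ts <- units$timestamps[[i]]
    if (is.unsorted(ts)) stop_integrity("timestamps must be nondecreasing")
    n_tr <- nrow(tr)
    rates <- matrix(0, n_tr, nrow(wd))
    nlt <- function(y) findInterval(y, ts, left.open = TRUE)
    for (w in seq_len(nrow(wd))) {
      rates[, w] <- (nlt(tr$onset + wd$end[w]) - nlt(tr$onset + wd$start[w])) /
        (wd$end[w] - wd$start[w])
    }
    out[[i]] <- tibble::tibble(
      unit_id = units$unit_id[i],
      trial_id = rep(tr$trial_id, nrow(wd)),
      window = rep(wd$window, each = n_tr),
      rate = as.vector(rates)
    )
  }
  bind_rows(out)
}

#' Mean firing rate per unit, phase, beat condition and window
#'
#' Averages per-trial rates across all trials of each phase, split by the
#' run's beat condition. This is the table the 2 Hz inclusion filter and the
#' exploratory activity analyses operate on.
#'
#' @param rates Per-trial rates from [trial_window_rates()].
#' @param trials The trial table of the same dataset.
#' @param stimulated_only Keep only trials whose phase was stimulated
#'   (used for condition contrasts; the inclusion filter uses all trials).
#' @return A tibble `unit_id`, `phase`, `beat_condition`, `window`,
#'   `mean_rate`, `n_trials`.
#' @export
condition_window_rates <- function(rates, trials, stimulated_only = FALSE) {
  tr <- trials
  if (stimulated_only) tr <- tr |> filter(.data$stimulation_delivered)
  rates |>
    inner_join(tr |> select(dplyr::all_of(c("trial_id", "phase", "beat_condition"))),
               by = "trial_id") |>
    group_by(.data$unit_id, .data$phase, .data$beat_condition, .data$window) |>
    summarise(mean_rate = mean(.data$rate), n_trials = dplyr::n(), .groups = "drop")
}

#' The 2 Hz inclusion filter
#'
#' A unit is kept when its mean firing rate across trials reaches at least
#' `min_rate_hz` in at least one 500 ms post-stimulus window (`w1`..`w4`) in
#' one of the three stimulation conditions, during encoding or retrieval
#' (inclusive threshold). Sparsely firing units below the cutoff are removed
#' because rank statistics on near-empty windows are unstable.
#'
#' @param mean_rates Output of [condition_window_rates()] (all trials).
#' @param min_rate_hz Inclusion threshold in Hz.
#' @return Character vector of kept `unit_id`s.
#' @export
inclusion_filter <- function(mean_rates, min_rate_hz = 2) {
  per_unit <- mean_rates |>
    filter(.data$window %in% analysis_windows()) |>
    group_by(.data$unit_id) |>
    summarise(max_rate = max(.data$mean_rate), .groups = "drop")
  per_unit$unit_id[per_unit$max_rate >= min_rate_hz]
}

#' Apply the inclusion filter to a dataset
#'
#' @param dataset A [beat_dataset()].
#' @param rates Optional precomputed [trial_window_rates()] table.
#' @param min_rate_hz Inclusion threshold in Hz.
#' @return A list with `kept` (unit ids), `n_total`, `n_removed`.
#' @export
apply_inclusion_filter <- function(dataset, rates = NULL, min_rate_hz = 2) {
  rates <- rates %||% trial_window_rates(dataset)
  kept <- inclusion_filter(condition_window_rates(rates, dataset$trials),
                           min_rate_hz = min_rate_hz)
  silent <- setdiff(dataset$units$unit_id, unique(rates$unit_id))
  if (length(silent) > 0) {
    warn(sprintf("%d unit(s) had no trials and were excluded", length(silent)),
         class = "beatmem_empty_unit")
  }
  list(kept = kept, n_total = nrow(dataset$units),
       n_removed = nrow(dataset$units) - length(kept))
}

#' Normalized firing-rate difference
#'
#' `(fr_w_a - fr_w_b) / (fr_full_a + fr_full_b)`: the window-rate difference
#' between two conditions divided by the sum of the two conditions' full
#' 0--2 s rates, removing trivial influences of firing-rate magnitude (the
#' statistic is invariant to scaling all four inputs by a common positive
#' constant). A zero denominator yields `NA` (undefined, the unit is dropped
#' from correlations downstream).
#'
#' @param fr_w_a,fr_w_b Window rates (Hz) of conditions A and B.
#' @param fr_full_a,fr_full_b Full-interval rates (Hz) of conditions A and B.
#' @return Dimensionless difference(s) in `[-4, 4]`, `NA` where undefined.
#' @export
#' @examples
#' normalized_difference(4, 2, 6, 6) # 2/12
normalized_difference <- function(fr_w_a, fr_w_b, fr_full_a, fr_full_b) {
  inputs <- cbind(fr_w_a, fr_w_b, fr_full_a, fr_full_b)
  if (any(inputs < 0, na.rm = TRUE)) {
    stop_config("firing rates must be >= 0")
  }
  denom <- fr_full_a + fr_full_b
  ifelse(denom > 0, (fr_w_a - fr_w_b) / denom, NA_real_)
}

# mean rate per unit x window for a trial subset, wide over a 2-level label;
# returns unit_id, window, rate_a, rate_b, full_a, full_b, diff, raw_diff
diff_from_subsets <- function(rates, trials_a, trials_b) {
  mean_by <- function(tr, nm) {
    rates |>
      inner_join(tr |> select("trial_id"), by = "trial_id") |>
      group_by(.data$unit_id, .data$window) |>
      summarise("{nm}" := mean(.data$rate), .groups = "drop")
  }
  a <- mean_by(trials_a, "rate_a")
  b <- mean_by(trials_b, "rate_b")
  ab <- full_join(a, b, by = c("unit_id", "window"))
  full <- ab |>
    filter(.data$window == "full") |>
    select("unit_id", full_a = "rate_a", full_b = "rate_b")
  ab |>
    filter(.data$window != "full") |>
    left_join(full, by = "unit_id") |>
    mutate(
      diff = normalized_difference(.data$rate_a, .data$rate_b,
                                   .data$full_a, .data$full_b),
      raw_diff = .data$rate_a - .data$rate_b
    ) |>
    arrange(.data$unit_id, match(.data$window, window_defs()$window))
}

#' Normalized beat-stimulation differences per unit and window
#'
#' For every unit, the normalized difference between binaural (A) and
#' monaural (B) mean firing rates in the `pre` and `w1`..`w4` windows. Only
#' trials of the requested phase in which stimulation was actually delivered
#' enter the contrast (encoding: color runs, 50 + 50 trials; retrieval: scene
#' runs, 75 + 75 trials). The pre-stimulus difference uses the same 0--2 s
#' denominator as the post-stimulus windows for cross-window comparability.
#'
#' @param rates Per-trial rates from [trial_window_rates()].
#' @param trials Trial table.
#' @param phase `"encoding"` or `"retrieval"`.
#' @return A tibble `unit_id`, `window`, mean rates per condition, `diff`
#'   (normalized binaural - monaural) and `raw_diff` (Hz).
#' @export
beat_diffs <- function(rates, trials, phase) {
  stopifnot(phase %in% task_phases())
  stim <- trials |> filter(.data$phase == !!phase, .data$stimulation_delivered)
  diff_from_subsets(
    rates,
    stim |> filter(.data$beat_condition == "binaural"),
    stim |> filter(.data$beat_condition == "monaural")
  ) |>
    mutate(phase = !!phase, .before = 1)
}

#' Normalized memory-related differences per unit and window
#'
#' For every unit, the normalized difference between remembered (A) and
#' forgotten (B) mean firing rates per window, for the item or source
#' contrast. By default the contrast pools all experimental runs for robust
#' estimates; `run_scope = "stimulated_runs"` restricts it to runs in which
#' beats were delivered during the analyzed phase.
#'
#' @inheritParams beat_diffs
#' @param memory_type `"item"` or `"source"`.
#' @param run_scope `"all_runs"` (default) or `"stimulated_runs"`.
#' @return A tibble like [beat_diffs()], with `memory_type` and `run_scope`.
#' @export
memory_diffs <- function(rates, trials, phase, memory_type = c("item", "source"),
                         run_scope = c("all_runs", "stimulated_runs")) {
  memory_type <- match.arg(memory_type)
  run_scope <- match.arg(run_scope)
  stopifnot(phase %in% task_phases())
  outcome_col <- paste0(memory_type, "_outcome")
  tr <- trials |> filter(.data$phase == !!phase)
  if (run_scope == "stimulated_runs") tr <- tr |> filter(.data$stimulation_delivered)
  diff_from_subsets(
    rates,
    tr |> filter(.data[[outcome_col]] == "remembered"),
    tr |> filter(.data[[outcome_col]] == "forgotten")
  ) |>
    mutate(phase = !!phase, memory_type = memory_type, run_scope = run_scope,
           .before = 1)
}
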