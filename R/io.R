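# Readers/writers for the two tab-separated input tables and derivation of
# memory outcomes from raw responses.
#
# File dialect: UTF-8, tab-separated, mandatory header, decimal point.

SPIKE_COLS <- c("unit_id", "subject_id", "region", "hemisphere", "unit_class", "timestamp")
TRIAL_COLS <- c(
  "trial_id", "subject_id", "run_id", "phase", "onset", "beat_condition",
  "stimulation_delivered", "source_category", "word", "novelty", "response",
  "source_truth"
)
OUTCOME_COLS <- c("item_outcome", "source_outcome")

stop_format <- function(msg) abort(msg, class = "beatmem_format_error")
stop_parse <- function(msg) abort(msg, class = "beatmem_parse_error")
stop_integrity <- function(msg) abort(msg, class = "beatmem_integrity_error")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf(
      "%s: missing required column(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
}

check_enum <- function(values, allowed, column, path = "input") {
  bad <- setdiff(unique(values[!is.na(values)]), allowed)
  if (length(bad) > 0) {
    stop_format(sprintf(
      "%s: column '%s' contains unknown value(s): %s (allowed: %s)",
      path, column, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  invisible(values)
}

# parse a character column to double, reporting 1-based data file line numbers
# (header is line 1) for unparseable entries
parse_numeric_col <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "%s: non-numeric value '%s' in column '%s' at line %d",
      path, x[bad[1]], column, bad[1] + 1L
    ))
  }
  if (anyNA(out)) {
    stop_parse(sprintf("%s: missing value in column '%s' at line %d",
                       path, column, which(is.na(out))[1] + 1L))
  }
  out
}

#' Read a spike timestamp table
#'
#' Reads a tab-separated file with one row per spike (columns `unit_id`,
#' `subject_id`, `region`, `hemisphere`, `unit_class`, `timestamp` in seconds
#' on the session clock) and returns one row per unit with its sorted spike
#' train in a list-column. The total spike count is conserved: every input
#' row becomes exactly one timestamp.
#'
#' @param path Path to a spikes TSV file.
#' @return A tibble with columns `unit_id`, `subject_id`, `region`,
#'   `hemisphere`, `unit_class`, `n_spikes`, and list-column `timestamps`
#'   (sorted, non-negative seconds).
#' @seealso [write_spike_trains()], [read_trial_table()]
#' @export
read_spike_trains <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("spike file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, SPIKE_COLS, path)
  check_enum(raw$region, mtl_regions(), "region", path)
  check_enum(raw$hemisphere, hemispheres(), "hemisphere", path)
  check_enum(raw$unit_class, unit_classes(), "unit_class", path)
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      unit_id = character(), subject_id = character(), region = character(),
      hemisphere = character(), unit_class = character(),
      n_spikes = integer(), timestamps = list()
    ))
  }
  raw$timestamp <- parse_numeric_col(raw$timestamp, "timestamp", path)
  if (any(!is.finite(raw$timestamp)) || any(raw$timestamp < 0)) {
    stop_integrity(sprintf("%s: timestamps must be finite and >= 0", path))
  }
  meta <- raw |>
    distinct(.data$unit_id, .data$subject_id, .data$region, .data$hemisphere,
             .data$unit_class)
  dup <- meta$unit_id[duplicated(meta$unit_id)]
  if (length(dup) > 0) {
    stop_integrity(sprintf(
      "%s: unit(s) with inconsistent metadata across rows: %s",
      path, paste(unique(dup), collapse = ", ")
    ))
  }
  ts <- split(raw$timestamp, raw$unit_id)
  meta |>
    mutate(
      n_spikes = unname(lengths(ts)[.data$unit_id]),
      timestamps = unname(lapply(ts[.data$unit_id], sort))
    ) |>
    arrange(.data$unit_id)
}

#' Write spike trains to a TSV file
#'
#' Inverse of [read_spike_trains()]: expands the `timestamps` list-column to
#' one row per spike. Doubles are written with round-trip precision.
#'
#' @param units A unit tibble as returned by [read_spike_trains()] or found in
#'   a simulated dataset.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(units, path) {
  long <- units |>
    select(dplyr::all_of(c("unit_id", "subject_id", "region", "hemisphere",
                           "unit_class", "timestamps"))) |>
    tidyr::unnest(cols = "timestamps") |>
    rename(timestamp = "timestamps")
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Read a trial/event table
#'
#' Reads the per-trial paradigm metadata (one row per trial) and returns
#' trials sorted by onset. Memory outcome columns, if absent, are initialized
#' to `"excluded"` pending [derive_memory_outcomes()].
#'
#' Required columns: `trial_id`, `subject_id`, `run_id`, `phase`, `onset`
#' (seconds), `beat_condition`, `stimulation_delivered` (logical: were beats
#' playing during this phase of this run), `source_category`, `word`,
#' `novelty` (`old`/`new`, `na` for encoding), `response`, `source_truth`.
#'
#' @param path Path to a trials TSV file.
#' @return A tibble of trials in onset order with `item_outcome` and
#'   `source_outcome` columns.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("trial file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, TRIAL_COLS, path)
  if (nrow(raw) > 0) {
    raw$onset <- parse_numeric_col(raw$onset, "onset", path)
    raw$stimulation_delivered <- as.logical(raw$stimulation_delivered)
  } else {
    raw$onset <- numeric(0)
    raw$stimulation_delivered <- logical(0)
  }
  for (col in OUTCOME_COLS) {
    if (!col %in% names(raw)) raw[[col]] <- rep("excluded", nrow(raw))
  }
  validate_trials(raw, path)
  raw |> arrange(.data$onset)
}

validate_trials <- function(trials, path = "trials") {
  dup <- trials$trial_id[duplicated(trials$trial_id)]
  if (length(dup) > 0) {
    stop_integrity(sprintf("%s: duplicated trial_id: %s", path,
                           paste(unique(dup), collapse = ", ")))
  }
  check_enum(trials$phase, task_phases(), "phase", path)
  check_enum(trials$beat_condition, beat_conditions(), "beat_condition", path)
  check_enum(trials$source_category, c("color", "scene"), "source_category", path)
  check_enum(trials$novelty, novelty_levels(), "novelty", path)
  check_enum(trials$response, response_levels(), "response", path)
  check_enum(trials$source_truth, source_levels(), "source_truth", path)
  check_enum(trials$item_outcome, outcome_levels(), "item_outcome", path)
  check_enum(trials$source_outcome, outcome_levels(), "source_outcome", path)
  bad_nov <- trials$phase == "retrieval" & (is.na(trials$novelty) | trials$novelty == "na")
  if (any(bad_nov)) {
    stop_format(sprintf("%s: retrieval trial(s) lacking novelty: %s", path,
                        paste(head(trials$trial_id[bad_nov], 3), collapse = ", ")))
  }
  enc_nov <- trials$phase == "encoding" & !trials$novelty %in% "na"
  if (any(enc_nov)) {
    stop_format(sprintf("%s: encoding trial(s) must have novelty 'na': %s", path,
                        paste(head(trials$trial_id[enc_nov], 3), collapse = ", ")))
  }
  # a run uses exactly one source category
  mixed <- trials |>
    distinct(.data$run_id, .data$source_category) |>
    count(.data$run_id) |>
    filter(.data$n > 1)
  if (nrow(mixed) > 0) {
    stop_integrity(sprintf("%s: run(s) with more than one source category: %s",
                           path, paste(mixed$run_id, collapse = ", ")))
  }
  invisible(trials)
}

#' Write a trial table to a TSV file
#'
#' @param trials A trial tibble (see [read_trial_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path, progress = FALSE)
  invisible(path)
}

#' Derive item and source memory outcomes from raw responses
#'
#' Classifies every trial as `remembered`, `forgotten` or `excluded` for the
#' item and the source contrast:
#'
#' * Retrieval, old word: item `remembered` if the response was one of the two
#'   sources or "unsure" (an "old" response), `forgotten` if the word was
#'   wrongly judged "new". Source `remembered` if the response names the
#'   correct source, `forgotten` if it names the wrong source or is "unsure".
#'   When the word itself was judged "new", no source decision was made and
#'   the source outcome is `excluded`.
#' * Retrieval, new word: both outcomes `excluded` (these trials only enter
#'   the false-alarm rate).
#' * No-response trials: both outcomes `excluded`.
#' * Encoding trials inherit the outcomes of the retrieval trial presenting
#'   the same word (subsequent-memory coding). Words are unique within a
#'   subject, so the mapping is unambiguous. Encoding trials whose word has
#'   no retrieval counterpart are excluded with a warning.
#'
#' @param trials A trial tibble with raw responses populated.
#' @param quiet Suppress the unmatched-encoding-word warning.
#' @return The trial tibble with `item_outcome` and `source_outcome` set.
#' @export
derive_memory_outcomes <- function(trials, quiet = FALSE) {
  check_columns(trials, TRIAL_COLS, "trials")
  n <- nrow(trials)
  item <- rep("excluded", n)
  src <- rep("excluded", n)

  is_ret <- trials$phase == "retrieval"
  old <- is_ret & trials$novelty == "old"
  resp <- trials$response
  judged_old <- old & resp %in% c("source_a", "source_b", "unsure")

  item[judged_old] <- "remembered"
  item[old & resp == "new"] <- "forgotten"

  src[judged_old & resp == trials$source_truth] <- "remembered"
  wrong_src <- judged_old &
    (resp == "unsure" | (resp %in% c("source_a", "source_b") & resp != trials$source_truth))
  src[wrong_src] <- "forgotten"

  # subsequent-memory linkage: encoding trials inherit their word's retrieval
  # outcome within subject
  enc <- which(trials$phase == "encoding")
  ret_old <- which(old)
  key <- paste(trials$subject_id, trials$word, sep = "\r")
  hit <- match(key[enc], key[ret_old])
  matched <- !is.na(hit)
  item[enc[matched]] <- item[ret_old][hit[matched]]
  src[enc[matched]] <- src[ret_old][hit[matched]]
  if (any(!matched) && !quiet) {
    warn(sprintf(
      "%d encoding trial(s) have no matching retrieval trial and were excluded",
      sum(!matched)
    ), class = "beatmem_unmatched_word")
  }

  trials$item_outcome <- item
  trials$source_outcome <- src
  trials
}

#' Bundle units and trials into a validated dataset
#'
#' A `beat_dataset` holds the spike trains and the trial table for one or
#' several subjects and is the input to every analysis stage.
#'
#' @param units Unit tibble as from [read_spike_trains()].
#' @param trials Trial tibble as from [read_trial_table()].
#' @param truth Optional simulation ground truth (see [simulate_cohort()]).
#' @return A list with class `beat_dataset` and elements `units`, `trials`,
#'   and (optionally) `truth`.
#' @export
beat_dataset <- function(units, trials, truth = NULL) {
  validate_trials(trials)
  if (anyDuplicated(units$unit_id)) {
    stop_integrity("unit_id values must be globally unique")
  }
  check_enum(units$region, mtl_regions(), "region", "units")
  check_enum(units$hemisphere, hemispheres(), "hemisphere", "units")
  orphan <- setdiff(units$subject_id, trials$subject_id)
  if (length(orphan) > 0) {
    stop_integrity(sprintf("unit subject(s) with no trials: %s",
                           paste(orphan, collapse = ", ")))
  }
  structure(list(units = units, trials = trials, truth = truth),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf(
    "<beat_dataset> %d units, %d trials, %d subject(s)%s\n",
    nrow(x$units), nrow(x$trials), length(unique(x$trials$subject_id)),
    if (!is.null(x$truth)) ", with simulation ground truth" else ""
  ))
  invisible(x)
}

#' Read a dataset from a directory containing spikes.tsv and trials.tsv
#'
#' @param dir Directory holding `spikes.tsv` and `trials.tsv` (and optionally
#'   `truth.json`).
#' @param derive_outcomes Run [derive_memory_outcomes()] after loading.
#' @return A [beat_dataset()].
#' @export
read_beat_dataset <- function(dir, derive_outcomes = TRUE) {
  units <- read_spike_trains(file.path(dir, "spikes.tsv"))
  trials <- read_trial_table(file.path(dir, "trials.tsv"))
  if (derive_outcomes) trials <- derive_memory_outcomes(trials, quiet = TRUE)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    as_tibble(jsonlite::fromJSON(truth_path))
  }
  beat_dataset(units, trials, truth = truth)
}

#' Write a dataset to a directory
#'
#' Writes `spikes.tsv`, `trials.tsv` and, when simulation ground truth is
#' present, `truth.json`.
#'
#' @param dataset A [beat_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_beat_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spike_trains(dataset$units, file.path(dir, "spikes.tsv"))
  write_trial_table(dataset$trials, file.path(dir, "trials.tsv"))
  if (!is.null(dataset$truth)) {
    jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
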