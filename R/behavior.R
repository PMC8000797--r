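# Behavioral performance summaries and group-level tests.

#' Behavioral performance summary
#'
#' Per subject and source category (color/scene): hit percentage (old words
#' judged old), false-alarm percentage (new words judged old), hits minus
#' false alarms, and the source-decision percentages (correct / incorrect /
#' unsure, computed over old words judged old, so the three sum to 100
#' within rounding) with correct minus incorrect. No-response trials are
#' excluded from all denominators. Also returns the per-subject x beat
#' condition x stimulated-phase cell means used by the repeated-measures
#' ANOVA (stimulation occurred at encoding for color runs and at retrieval
#' for scene runs, so the phase factor coincides with source category), and
#' group means with standard errors.
#'
#' @param trials Trial table with raw responses (memory outcomes need not be
#'   derived; the summary works from responses directly).
#' @return A list with class `behavioral_summary`: `per_subject`, `group`,
#'   `anova_input`.
#' @export
behavioral_summary <- function(trials) {
  ret <- trials |>
    filter(.data$phase == "retrieval", .data$response != "none") |>
    mutate(
      judged_old = .data$response %in% c("source_a", "source_b", "unsure"),
      src_correct = .data$judged_old & .data$response == .data$source_truth,
      src_unsure = .data$judged_old & .data$response == "unsure",
      src_incorrect = .data$judged_old & !.data$src_correct & !.data$src_unsure
    )

  summarise_cells <- function(grouped) {
    grouped |>
      summarise(
        n_old = sum(.data$novelty == "old"),
        n_new = sum(.data$novelty == "new"),
        n_hits = sum(.data$novelty == "old" & .data$judged_old),
        hit_pct = 100 * n_hits / n_old,
        fa_pct = 100 * sum(.data$novelty == "new" & .data$judged_old) / n_new,
        hits_minus_fa = hit_pct - fa_pct,
        source_correct_pct =
          100 * sum(.data$novelty == "old" & .data$src_correct) / n_hits,
        source_incorrect_pct =
          100 * sum(.data$novelty == "old" & .data$src_incorrect) / n_hits,
        source_unsure_pct =
          100 * sum(.data$novelty == "old" & .data$src_unsure) / n_hits,
        source_correct_minus_incorrect =
          source_correct_pct - source_incorrect_pct,
        .groups = "drop"
      )
  }

  per_subject <- summarise_cells(
    ret |> group_by(.data$subject_id, .data$source_category)
  )
  measures <- c("hit_pct", "fa_pct", "hits_minus_fa", "source_correct_pct",
                "source_incorrect_pct", "source_unsure_pct",
                "source_correct_minus_incorrect")
  group <- per_subject |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure") |>
    group_by(.data$source_category, .data$measure) |>
    summarise(
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()),
      n_subjects = dplyr::n(),
      .groups = "drop"
    )

  # ANOVA cells: runs grouped by beat condition; the stimulated phase of a
  # run is encoding for color runs and retrieval for scene runs
  anova_input <- summarise_cells(
    ret |>
      mutate(stimulated_phase =
               ifelse(.data$source_category == "color", "encoding", "retrieval")) |>
      group_by(.data$subject_id, .data$beat_condition, .data$stimulated_phase)
  ) |>
    select(dplyr::all_of(c("subject_id", "beat_condition", "stimulated_phase",
                           "hit_pct", "source_correct_pct")))

  structure(list(per_subject = per_subject, group = group,
                 anova_input = anova_input),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat("<behavioral_summary>\n")
  print(x$group, n = Inf)
  invisible(x)
}

#' One-sample t-test
#'
#' Two-sided one-sample t-test of `values` against `mu` (used e.g. to test
#' hits-minus-false-alarms against chance level 0).
#'
#' @param values Numeric vector, length >= 2, nonzero variance.
#' @param mu Null hypothesis mean.
#' @return A list with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2) {
    stop_insufficient("one_sample_t needs at least 2 values")
  }
  if (sd(values) == 0) {
    stop_degenerate("one_sample_t: zero variance")
  }
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(values))
}

#' Two-way repeated-measures ANOVA (2 x 2 within-subject)
#'
#' Within-subject ANOVA with two 2-level factors (beat condition and task
#' phase). Each effect is tested against its own subject-by-effect
#' interaction stratum with (1, n-1) degrees of freedom; with 2-level
#' factors no sphericity correction is needed. Effects with zero sum of
#' squares are reported as `F = 0`, `p = 1`.
#'
#' @param data A data frame with columns `subject`, `condition`, `phase`,
#'   `value`: exactly one value per subject x condition x phase cell, both
#'   factors with exactly 2 levels, >= 2 subjects.
#' @return A tibble with one row per effect (`condition`, `phase`,
#'   `condition:phase`): `df1`, `df2`, `statistic` (F), `p`.
#' @export
rm_anova_2x2 <- function(data) {
  required <- c("subject", "condition", "phase", "value")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(sprintf("rm_anova_2x2: missing column(s) %s",
                  paste(missing, collapse = ", ")),
          class = "beatmem_design_error")
  }
  data <- data |>
    mutate(subject = factor(.data$subject), condition = factor(.data$condition),
           phase = factor(.data$phase))
  n_sub <- nlevels(data$subject)
  if (nlevels(data$condition) != 2 || nlevels(data$phase) != 2) {
    abort("rm_anova_2x2: both factors must have exactly 2 levels",
          class = "beatmem_design_error")
  }
  if (n_sub < 2) {
    abort("rm_anova_2x2: need at least 2 subjects", class = "beatmem_design_error")
  }
  cells <- data |> count(.data$subject, .data$condition, .data$phase)
  if (nrow(cells) != n_sub * 4 || any(cells$n != 1)) {
    abort("rm_anova_2x2: design must have exactly one value per subject x condition x phase cell",
          class = "beatmem_design_error")
  }

  fit <- stats::aov(value ~ condition * phase + Error(subject / (condition * phase)),
                    data = data)
  s <- summary(fit)
  effects <- c("condition", "phase", "condition:phase")
  rows <- lapply(effects, function(eff) {
    stratum <- s[[paste0("Error: subject:", eff)]][[1]]
    idx <- match(eff, trimws(rownames(stratum)))
    ss_eff <- stratum[idx, "Sum Sq"]
    f <- stratum[idx, "F value"]
    p <- stratum[idx, "Pr(>F)"]
    if (ss_eff < .Machine$double.eps * 100) {
      f <- 0; p <- 1
    } else if (!is.finite(f)) { # zero error stratum, nonzero effect
      f <- Inf; p <- 0
    }
    tibble::tibble(effect = eff, df1 = stratum[idx, "Df"],
                   df2 = stratum[nrow(stratum), "Df"], statistic = f, p = p)
  })
  bind_rows(rows)
}
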