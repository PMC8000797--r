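# Orchestration: run every analysis stage on a dataset and emit the tabular
# report bundle plus a machine-readable summary.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)),
          class = c("beatmem_stage_error", class(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes io -> rates -> selection -> correlation -> behavior on a dataset
#' and returns a report bundle. The stages are: per-trial window rates; the
#' 2 Hz inclusion filter; beat-responsive unit selection per phase and
#' hemisphere with population-level binomial, overlap and chi-square tests;
#' normalized beat and memory difference correlations (post-stimulus
#' matched-window and pre-stimulus analyses, plus the run-restricted
#' variant) for the correlation hemisphere; the sign-adjusted pre-stimulus
#' t-test; the exploratory homeostatic correlation scheme; and the
#' behavioral summary with two 2x2 repeated-measures ANOVAs. The pipeline is
#' deterministic given its inputs.
#'
#' @param dataset A [beat_dataset()], e.g. from [read_beat_dataset()] or
#'   [simulate_cohort()].
#' @param alpha_unit Per-window unit-level threshold (Bonferroni 0.05/4).
#' @param alpha_population Population-level alpha for the binomial tests.
#' @param min_rate_hz Inclusion filter threshold.
#' @param run_scope Run scope for the primary memory contrasts.
#' @param corr_hemisphere Hemisphere analyzed in the correlation stage.
#' @return A list with class `beat_report`; see the elements written by
#'   [write_report()].
#' @export
analyze_dataset <- function(dataset, alpha_unit = 0.0125,
                            alpha_population = 0.05, min_rate_hz = 2,
                            run_scope = "all_runs",
                            corr_hemisphere = "left") {
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    invisible(NULL)
  }

  trials <- dataset$trials
  units <- dataset$units

  rates <- stage("rates", trial_window_rates(dataset))
  incl <- stage("rates", apply_inclusion_filter(dataset, rates = rates,
                                                min_rate_hz = min_rate_hz))
  note("inclusion filter (%g Hz): kept %d of %d units (%d removed)",
       min_rate_hz, length(incl$kept), incl$n_total, incl$n_removed)

  selection <- stage("selection", bind_rows(lapply(task_phases(), function(ph) {
    select_beat_responsive(rates, trials, units, ph, hemisphere = NULL,
                           alpha = alpha_unit, kept_units = incl$kept)
  })))
  for (ph in task_phases()) {
    sel_ph <- selection |> filter(.data$phase == ph)
    note("selection (%s): %d of %d units selected (%d increase, %d decrease)",
         ph, sum(sel_ph$selected), nrow(sel_ph),
         sum(sel_ph$direction == "increase", na.rm = TRUE),
         sum(sel_ph$direction == "decrease", na.rm = TRUE))
  }

  population <- stage("selection", {
    by_hemi <- population_summary(selection, by = "hemisphere", p0 = alpha_population)
    by_region <- population_summary(selection, by = c("hemisphere", "region"),
                                    p0 = alpha_population)
    chisq <- bind_rows(lapply(task_phases(), function(ph) {
      h <- by_hemi |> filter(.data$phase == ph)
      left <- h |> filter(.data$hemisphere == "left")
      right <- h |> filter(.data$hemisphere == "right")
      cs <- tryCatch(
        proportion_chi_square(left$k, left$n, right$k, right$n),
        beatmem_degenerate_error = function(e) {
          note("chi-square (%s) undefined: %s", ph, conditionMessage(e))
          list(statistic = NA_real_, p = NA_real_, df = 1)
        }
      )
      tibble::tibble(phase = ph, statistic = cs$statistic, p = cs$p, df = cs$df)
    }))
    overlap <- bind_rows(lapply(hemispheres(), function(hm) {
      sel_h <- selection |> filter(.data$hemisphere == hm)
      wide <- sel_h |>
        select(dplyr::all_of(c("unit_id", "phase", "selected"))) |>
        tidyr::pivot_wider(names_from = "phase", values_from = "selected")
      n <- nrow(wide)
      k_enc <- sum(wide$encoding)
      k_ret <- sum(wide$retrieval)
      k_both <- sum(wide$encoding & wide$retrieval)
      p <- if (k_enc > 0 && k_ret > 0 && k_enc < n) {
        # chance probability is the product of the class portions; if every
        # unit belongs to a class the test is vacuous (p = 1)
        if ((k_enc / n) * (k_ret / n) < 1) {
          overlap_test(k_both, n, k_enc / n, k_ret / n)
        } else 1
      } else NA_real_
      tibble::tibble(hemisphere = hm, n = n, k_encoding = k_enc,
                     k_retrieval = k_ret, k_overlap = k_both, p_binom = p)
    }))
    list(by_hemisphere = by_hemi, by_region = by_region, chi_square = chisq,
         overlap = overlap)
  })

  corr <- stage("correlation", {
    sel_corr <- selection |>
      filter(.data$hemisphere == corr_hemisphere, .data$selected)
    tables <- list()
    prestim <- list()
    for (ph in task_phases()) {
      ids <- sel_corr$unit_id[sel_corr$phase == ph]
      bd <- beat_diffs(rates, trials, ph) |> filter(.data$unit_id %in% ids)
      note("correlation (%s, %s): %d selected units", ph, corr_hemisphere,
           length(ids))
      for (mt in c("item", "source")) {
        for (scope in unique(c(run_scope, "stimulated_runs"))) {
          md <- memory_diffs(rates, trials, ph, mt, run_scope = scope) |>
            filter(.data$unit_id %in% ids)
          if (length(ids) >= 3) {
            for (bw in c("matched_post", "pre")) {
              tables[[length(tables) + 1]] <-
                correlation_table(bd, md, beat_window = bw, alpha = alpha_unit)
            }
          }
        }
      }
      prestim[[ph]] <- tryCatch(
        prestim_sign_adjusted_test(bd, selection |>
                                     filter(.data$phase == ph,
                                            .data$hemisphere == corr_hemisphere)),
        error = function(e) {
          note("prestim test (%s) unavailable: %s", ph, conditionMessage(e))
          NULL
        }
      )
    }
    list(tables = bind_rows(tables), prestim = prestim)
  })

  exploration <- stage("correlation", homeostatic_exploration(
    rates, trials,
    selection |> filter(.data$hemisphere == corr_hemisphere),
    run_scope = run_scope
  ))
  dropped <- sum(is.na(corr$tables$r))
  if (dropped > 0) note("correlation: %d undefined cells", dropped)

  behavior <- stage("behavior", {
    summ <- behavioral_summary(trials)
    anova <- list()
    an_in <- summ$anova_input |>
      filter(.data$beat_condition %in% c("binaural", "monaural"))
    n_subj <- length(unique(an_in$subject_id))
    for (measure in c("hit_pct", "source_correct_pct")) {
      anova[[measure]] <- if (n_subj >= 2) {
        rm_anova_2x2(an_in |>
                       select(subject = "subject_id", condition = "beat_condition",
                              phase = "stimulated_phase",
                              value = dplyr::all_of(measure)))
      }
    }
    list(summary = summ, anova = anova)
  })

  report <- list(
    inclusion = incl,
    selection = selection,
    population = population,
    correlations = corr$tables,
    prestim = corr$prestim,
    exploration = exploration,
    behavior = behavior,
    params = list(alpha_unit = alpha_unit, alpha_population = alpha_population,
                  min_rate_hz = min_rate_hz, run_scope = run_scope,
                  corr_hemisphere = corr_hemisphere),
    log = log_lines
  )
  class(report) <- "beat_report"
  report
}

#' @export
print.beat_report <- function(x, ...) {
  cat("<beat_report>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  sig <- x$correlations |> filter(.data$significant %in% TRUE)
  cat(sprintf("  significant correlation cells: %d of %d\n",
              nrow(sig), nrow(x$correlations)))
  invisible(x)
}

report_summary <- function(report) {
  sel_counts <- report$selection |>
    group_by(.data$phase, .data$hemisphere) |>
    summarise(n = dplyr::n(), k = sum(.data$selected), .groups = "drop")
  list(
    n_units_total = report$inclusion$n_total,
    n_units_kept = length(report$inclusion$kept),
    n_units_removed = report$inclusion$n_removed,
    selection = sel_counts,
    population = report$population$by_hemisphere,
    chi_square = report$population$chi_square,
    overlap = report$population$overlap,
    correlations = report$correlations,
    prestim = lapply(report$prestim, function(x) x[c("t", "p", "n")]),
    exploration_rows = nrow(report$exploration$main),
    exploration_abs_rows = nrow(report$exploration$absolute),
    exploration_p_bands = report$exploration$p_bands,
    behavior_group = report$behavior$summary$group,
    anova = report$behavior$anova,
    params = report$params
  )
}

#' Write a report bundle to a directory
#'
#' Writes `selection.tsv`, `population.tsv`, `correlations.tsv`,
#' `exploration.tsv`, `behavior.tsv`, `summary.json` and `pipeline.log`.
#'
#' @param report A `beat_report` from [analyze_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$selection, file.path(dir, "selection.tsv"), progress = FALSE)
  readr::write_tsv(report$population$by_region, file.path(dir, "population.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$correlations, file.path(dir, "correlations.tsv"),
                   progress = FALSE)
  expl <- bind_rows(
    report$exploration$main |> mutate(variant = "signed", .before = 1),
    report$exploration$absolute |>
      mutate(variant = "absolute", stratum = "all", .before = 1)
  )
  readr::write_tsv(expl, file.path(dir, "exploration.tsv"), progress = FALSE)
  readr::write_tsv(report$behavior$summary$per_subject,
                   file.path(dir, "behavior.tsv"), progress = FALSE)
  jsonlite::write_json(report_summary(report), file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE, null = "null")
  writeLines(report$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' Run the pipeline from files or a simulation config
#'
#' Thin orchestration wrapper: loads (or simulates) a dataset, analyzes it,
#' and optionally writes the report bundle. Stage failures abort with a
#' stage-tagged message.
#'
#' @param spikes,trials Paths to `spikes.tsv` and `trials.tsv` (ignored when
#'   `sim_config` is given).
#' @param sim_config A [simulation_config()] to generate the dataset instead
#'   of reading files.
#' @param seed Seed for the simulation.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param ... Passed to [analyze_dataset()].
#' @return The `beat_report`, invisibly.
#' @export
run_pipeline <- function(spikes = NULL, trials = NULL, sim_config = NULL,
                         seed = 1, out_dir = NULL, ...) {
  dataset <- stage("io", {
    if (!is.null(sim_config)) {
      simulate_cohort(sim_config, seed = seed)
    } else {
      if (is.null(spikes) || is.null(trials)) {
        abort("provide either sim_config or both spikes and trials paths",
              class = "beatmem_config_error")
      }
      u <- read_spike_trains(spikes)
      t <- derive_memory_outcomes(read_trial_table(trials), quiet = TRUE)
      beat_dataset(u, t)
    }
  })
  report <- analyze_dataset(dataset, ...)
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}
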