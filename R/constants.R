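# Controlled vocabularies and the window grid shared by all modules.

#' Peristimulus analysis windows
#'
#' The analysis grid uses four non-overlapping 500 ms post-stimulus windows
#' covering 0--2 s after stimulus onset (`w1`..`w4`), one 500 ms pre-stimulus
#' window (`pre`, -0.5--0 s), and the `full` 0--2 s interval whose rate is
#' used as the normalization denominator. All windows are half-open
#' `[start, end)` in seconds relative to trial onset.
#'
#' @return A tibble with columns `window`, `start`, `end` (seconds).
#' @export
#' @examples
#' window_defs()
window_defs <- function() {
  tibble::tibble(
    window = c("pre", "w1", "w2", "w3", "w4", "full"),
    start  = c(-0.5, 0.0, 0.5, 1.0, 1.5, 0.0),
    end    = c(0.0, 0.5, 1.0, 1.5, 2.0, 2.0)
  )
}

#' @rdname window_defs
#' @details `analysis_windows()` returns the four post-stimulus window labels
#'   used for unit selection and the Bonferroni family (alpha 0.05 / 4 =
#'   0.0125).
#' @export
analysis_windows <- function() c("w1", "w2", "w3", "w4")

mtl_regions <- function() c("amygdala", "hippocampus", "entorhinal", "parahippocampal")
hemispheres <- function() c("left", "right")
unit_classes <- function() c("single", "multi")
task_phases <- function() c("encoding", "retrieval")
beat_conditions <- function() c("binaural", "monaural", "control")
response_levels <- function() c("new", "source_a", "source_b", "unsure", "none")
novelty_levels <- function() c("old", "new", "na")
source_levels <- function() c("source_a", "source_b", "na")
outcome_levels <- function() c("remembered", "forgotten", "excluded")

# default Bonferroni-corrected per-window threshold (0.05 over 4 windows)
ALPHA_UNIT <- 0.0125
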