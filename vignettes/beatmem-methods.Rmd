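---
title: "Beat stimulation and memory-related single-unit firing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat stimulation and memory-related single-unit firing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatmem)
library(dplyr)
```

## The scientific problem

Auditory beats — amplitude-modulated tones (monaural beats) or dichotic tone
pairs whose modulation is constructed neurally (binaural beats) — modulate
long-term memory performance, and binaural versus monaural 5 Hz beats do so
in opposite directions. `beatmem` implements the single-unit analysis chain
that links this behavioral effect to the firing of neurons in the human
medial temporal lobe (MTL: amygdala, hippocampus, entorhinal and
parahippocampal cortex), recorded from microwires while patients perform an
associative recognition task.

The guiding hypothesis is *homeostatic*: beat stimulation shifts a neuron's
baseline firing level, and because plasticity operates relative to baseline
(as in the Bienenstock–Cooper–Munro rule, where high prior activity favors
depression and low prior activity favors potentiation), an upward baseline
shift should *reduce* the neuron's memory-related firing modulation and a
downward shift should *increase* it. The observable signature is a
**negative correlation across neurons** between beat-related and
memory-related firing-rate differences — including when the beat-related
difference is measured *before* stimulus onset.

## The paradigm

Each subject completes 6 runs. A run has an encoding phase (50 nouns, each
paired with a color or scene source) and a retrieval phase (the 50 old nouns
plus 25 new ones; responses: "new", one of the two sources, or "unsure" =
old without source memory). A run uses exactly one source category. Beats
(binaural 5 Hz, monaural 5 Hz, or a no-beat control tone) play during the
encoding phase of color runs and the retrieval phase of scene runs; each
category sees each condition exactly once, counterbalanced by a seeded Latin
square across subjects.

Memory outcomes are derived per trial (`derive_memory_outcomes()`):

* **item**: old word judged old ("source" or "unsure" response) = remembered;
  judged "new" = forgotten;
* **source**: correct source = remembered; wrong source or "unsure" =
  forgotten; item misses carry no source decision and are excluded from the
  source contrast (this avoids conflating item and source forgetting);
* new words and no-response trials are excluded; encoding trials inherit
  their word's retrieval outcome (subsequent-memory coding — words are
  unique within subject, so the mapping is unambiguous).

## The analysis chain

1. **Window rates** (`trial_window_rates()`). Per-trial firing rates in four
   non-overlapping 500 ms post-stimulus windows (`w1`..`w4`, 0–2 s), one
   pre-stimulus window (`pre`, −0.5–0 s) and the full 0–2 s interval. All
   windows are half-open `[start, end)`; time is double-precision seconds.
2. **Inclusion filter** (`inclusion_filter()`). A unit is kept when its mean
   rate across trials reaches **2 Hz** (inclusive) in at least one
   post-stimulus window in at least one stimulation condition in either
   phase. Sparsely firing units make rank statistics unstable.
3. **Selection** (`select_beat_responsive()`). Per unit and 500 ms window,
   binaural and monaural per-trial rates (stimulated runs only: 50+50 trials
   at encoding, 75+75 at retrieval) are compared with a two-sided rank-sum
   test; because trials are unpaired, the two-sample Mann–Whitney form is
   the correct "Wilcoxon" variant. A unit is beat-responsive when its
   minimum p across the four windows is ≤ **0.0125** (Bonferroni, 0.05/4).
   The response direction comes from the most significant window (earliest
   window on ties) — the pre-stimulus sign analysis needs it.
4. **Population statistics**. One-sided exact binomial tests ask whether
   the count of responsive units exceeds the 5% chance level
   (`binomial_proportion_test()`); overlap between encoding- and
   retrieval-responsive classes uses the product of the class portions as
   its chance level (`overlap_test()`); the left/right comparison is a 1-df
   Pearson chi-square without continuity correction
   (`proportion_chi_square()` — the uncorrected statistic is what the
   published 2.71/2.77 values reproduce).
5. **Normalized differences** (`normalized_difference()`). For window rates
   `fr` of two conditions A, B:
   `Diff = (fr_w(A) − fr_w(B)) / (fr_[0,2s](A) + fr_[0,2s](B))`.
   Dividing by the summed full-interval rates removes trivial
   firing-rate-magnitude effects (the statistic is invariant to common
   rescaling). A zero denominator marks the unit's statistic undefined; such
   units are dropped from correlations and counted. Condition-level rates
   are means across trials of per-trial rates, matching the trialwise rank
   tests. Beat contrasts (binaural − monaural) use stimulated trials;
   memory contrasts (remembered − forgotten) pool **all runs** by default
   for robustness, with `run_scope = "stimulated_runs"` as the documented
   variant. The pre-stimulus beat difference uses the same 0–2 s
   denominator as the post-stimulus windows for cross-window comparability
   (the alternative — a pre-window denominator — changes only the scale,
   not the sign or ordering, of the statistic).
6. **Correlations** (`beat_memory_correlation()`, `correlation_table()`).
   Across selected units of one hemisphere, Pearson correlations between
   beat and memory differences, per memory window; `matched_post` pairs
   same-window differences, `pre` pairs the pre-stimulus beat difference
   with each post-stimulus memory window. Significance is `p < 0.0125`
   (Bonferroni over the four windows per analysis family); a stricter
   all-tests correction is reported as a flag, not a second threshold.
7. **Pre-stimulus sign test** (`prestim_sign_adjusted_test()`). Each
   selected unit's pre-stimulus binaural−monaural difference is multiplied
   by the sign of its post-stimulus effect; a two-sided one-sample t-test
   against zero asks whether the beat effect was already present before
   onset. Normalized differences are the default; a raw-Hz variant is
   available by flag (the choice affects scale, not sign).
8. **Exploratory homeostatic scheme** (`homeostatic_exploration()`).
   Correlates firing-rate *levels* ("activity": mean Hz in a window and
   condition, stimulated trials) with memory differences:
   2 sign strata (units split by the sign of the memory difference in the
   analyzed window; zero joins the positive stratum) × 2 analyses
   (pre-stimulus vs post-stimulus activity) × 2 conditions × 4 windows ×
   2 memory types × 2 phases = **128 correlations**, plus an absolute-value
   variant across all units (64), with counts of p-values below 0.05 and in
   [0.05, 0.1). Cells with fewer than 3 units stay in the table as
   undefined rows so the factorization is always complete.
9. **Behavior** (`behavioral_summary()`, `rm_anova_2x2()`). Hits, false
   alarms, hits−FA, and source correct/incorrect/unsure percentages — the
   source percentages are computed over old words judged old, which is the
   only denominator under which the three sum to 100. The 2×2
   repeated-measures ANOVA (beat condition × stimulated phase) uses
   `stats::aov` with within-subject error strata; with 2-level factors each
   effect has (1, n−1) df and needs no sphericity correction. Because
   stimulation occurred at encoding for color runs and retrieval for scene
   runs, the phase factor coincides with source category by design.

`run_pipeline()` chains all stages, logs every exclusion (the unit
bookkeeping is part of the result), and writes `selection.tsv`,
`population.tsv`, `correlations.tsv`, `exploration.tsv`, `behavior.tsv` and
`summary.json`.

## The synthetic cohort generator

Real microwire data cannot ship with the package, so every stage is
validated against `simulate_cohort()`, which generates the full paradigm
with a known ground truth.

**Firing model.** Spikes are homogeneous Poisson with a piecewise-constant
rate over the six peristimulus windows of every trial and a uniform
background at baseline elsewhere — the simplest process matching a windowed
analysis; renewal or bursting structure is deliberately out of scope. Unit
baseline rates are log-normal (default median 3 Hz, log-sd 0.4), placing
kept-unit condition means in the 3–5 Hz range typical of human MTL
recordings. The rate of unit *i* on a trial is

`lambda = b_i × beat_i(trial, window) × mem_i(trial, window)`

* `beat_i = g^(s_i)` (default g = 1.8, sign `s_i = ±1` per responsive unit,
  responsive with probability 0.4) on binaural trials whose phase was
  stimulated, **in the pre-stimulus and all post-stimulus windows** — beats
  play continuously through a stimulated phase, so the induced shift is a
  *baseline* shift, visible between trials. Monaural and control trials sit
  at baseline.
* `mem_i = m_i` on remembered trials in the configured memory windows
  (default `w2`, `w3`, where the recorded data showed effects), with

  `m_i = exp((log m0 + e_i) · h(b_i) − kappa · shift_i)`,

  `e_i ~ N(0, sigma_m)`, `shift_i = g^(s_i) − 1`. The `− kappa · shift`
  term is the homeostatic coupling: units whose baseline was shifted up
  carry a smaller memory gain. The exponential form is the positive-rate
  realization of the linear gain `m0 − kappa·shift`; it never produces a
  non-positive rate, for any coupling strength, which a clamped linear form
  cannot guarantee once unit heterogeneity `sigma_m` is present. That
  heterogeneity is essential: without it the two-point shift would make the
  shift/gain correlation exactly ±1, and no intermediate target correlation
  could exist. `h(b) = 2/(1 + (b/median)^rate_coupling)` is a bounded
  rate-level homeostatic term (1 at the median rate, → 2 for sparse units,
  → 0 for high-rate units) used by the exploratory analyses; its default
  exponent is 0 (disabled). The bounded form was chosen over a power law
  because an unbounded low-rate amplification produces arbitrarily large
  Poisson rates.

`coupling_for_correlation(rho, g, sigma_m)` inverts the closed-form moments
of this model to find the `kappa` that yields a target Pearson correlation
`rho` between the signed shift and the memory gain — the default `kappa`
targets −0.6.

**Behavior model.** Old words are hits with probability 0.85, new words
false alarms with probability 0.19; hits split into correct source (0.63),
"unsure" (0.12) and wrong source (rest) — matching the recognition rates of
the recorded subject group. Binaural/monaural runs shift the hit and
source-correct probabilities by ±0.04, reproducing the behavioral beat
effect at a size that leaves the subgroup-scale ANOVA near its published
significance. Firing and behavior are coupled only through the outcome
labels; there is no trial-level latent variable.

**What the generator does not emulate.** Oscillatory phase locking, bursting
and refractoriness, spike-sorting artifacts, region-specific effect
profiles, inter-subject effect heterogeneity, and any LFP/iEEG signal. A
passing synthetic suite therefore validates the *statistical machinery*
(selection calibration, correlation recovery, bookkeeping), not the
neurophysiological claims themselves.

## Calibration properties worth knowing

* **Selection under the null.** With no beat effect, the per-phase
  selection rate is the family-wise error of four Bonferroni-corrected
  tests, `1 − 0.9875^4 ≈ 4.9%`; the suite checks it against 99% binomial
  bounds on a 500-unit cohort.
* **A clean correlation null needs δ = 0.** With the behavioral offset
  active, beat condition genuinely influences memory outcomes, so
  remembered pools contain more beat-gain trials and the correlation stage
  detects a *real* (composition-mediated) beat–memory association,
  concentrated in windows without a true memory modulation. The type-I
  suite therefore sets both `coupling = 0` and `condition_offset = 0`.
  For the same reason, single-subject cohorts show a subject-common
  composition fluctuation; the type-I check uses 5 subjects, which averages
  it away.
* **Recovery attenuation.** The measured beat×memory correlation is
  attenuated by trial-sampling noise in the normalized differences
  (~4% under default settings) and slightly reshaped by the concave
  gain→difference transform; with 60 units the sampling sd of r near −0.6
  is ≈ 0.10–0.13, so recovered values at the paradigm's own scale scatter
  across roughly [−0.8, −0.4]. The recovery suite asserts the band
  [−0.75, −0.45] over 50 seeded replicates.
* **Exploration contamination.** "Post-stimulus activity" measured in a
  memory window contains the memory modulation itself — a positive
  contamination of the activity–memory-difference correlation. The
  homeostatic signature (all absolute-variant correlations negative)
  emerges robustly when the baseline-rate spread is wide relative to the
  memory-gain spread, which is the regime the corresponding property test
  simulates.

## Numerical and design choices

* Rank-sum tests use the exact null distribution when both samples have at
  most 10 values and no ties, otherwise the normal approximation with tie
  correction and no continuity correction. All-constant inputs return
  p = 1 with an undefined direction.
* Binomial tails are exact pmf summations (`pbinom`), one-sided upper tail
  ("more units than chance").
* Degenerate inputs raise classed conditions
  (`beatmem_insufficient_data`, `beatmem_degenerate_error`,
  `beatmem_config_error`, ...) rather than returning silent NAs, except
  where the factorized exploration table deliberately keeps undefined rows.
* In `rm_anova_2x2`, effects with zero sum of squares are reported as
  F = 0, p = 1 (the 0/0 case arises for constant designs).
* Zero memory differences join the positive stratum in the exploration
  sign split (logged choice; zeros are rare with continuous rates).
* Problem sizes in the test suite: the null-selection check uses one
  504-unit cohort; type-I control uses 200 seeds of 5-subject, 40-unit
  cohorts; recovery uses 50 seeds of 5-subject cohorts with 60
  left-hemisphere responsive units. These sizes put the binomial and
  Fisher-z bounds asserted by the tests within reach of a few minutes of
  computation while matching the paradigm's own trial counts exactly.

## Known limitations

* Selecting units by a beat contrast and then correlating a statistic of
  the same trials can bias correlations (circular-selection); like the
  original analysis, the package reports the selection-conditional
  correlations and leaves bias correction out of scope.
* The generator's Poisson assumption understates the variance of real
  spike counts (overdispersion from bursting); calibrated error rates on
  real data may differ.
* The run-restricted memory contrast halves the usable trials and is
  noticeably noisier; it is provided as a variant, not the default.
* With five subjects the behavioral ANOVA has 4 error df; its p-values are
  honest but fragile, exactly as in the recorded subgroup.

## A worked example

```{r example, eval = FALSE}
library(beatmem)

cfg <- simulation_config(p_beat_responsive = 1, memory_windows = "w3",
                         coupling = coupling_for_correlation(-0.6, 1.8, 0.45))
ds <- simulate_cohort(cfg, seed = 7)
report <- analyze_dataset(ds)
print(report)
subset(report$correlations,
       beat_window == "matched_post" & memory_type == "item" &
         run_scope == "all_runs" & phase == "retrieval")
```

The `memory_window == "w3"` row recovers a significantly negative r close
to the injected coupling; `report$prestim` shows the sign-adjusted
pre-stimulus t-tests, and `report$exploration$p_bands` summarizes the
128-correlation exploratory table.
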