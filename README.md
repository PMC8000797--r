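# beatmem

Single-unit analysis of auditory beat stimulation and memory in the human
medial temporal lobe (MTL), plus a seeded spike-train simulator for
validating every stage without patient data.

## The problem

Binaural and monaural 5 Hz auditory beats modulate long-term memory in
opposite directions. In patients with MTL microwire implants performing an
associative recognition task (6 runs × 50 encoding / 75 retrieval trials;
binaural beats, monaural beats, or a no-beat control tone per run), the
question is whether beats act on memory by shifting neurons' *baseline*
firing levels — a homeostatic account in the spirit of the
Bienenstock–Cooper–Munro rule, under which an upward baseline shift reduces
a neuron's memory-related firing modulation.

The observable signature is a negative across-neuron correlation between
the normalized beat-related firing difference and the normalized
memory-related difference,

```
Diff_A,B = (fr_w(A) − fr_w(B)) / (fr_[0,2s](A) + fr_[0,2s](B))
```

computed per 500 ms peristimulus window `w`, with A,B = binaural, monaural
(beat contrast, stimulated runs) or remembered, forgotten (memory contrast,
all runs). The package implements the full chain: per-trial window rates →
2 Hz inclusion filter → beat-responsive unit selection (per-window
two-sided rank-sum tests, Bonferroni threshold p ≤ 0.0125) → population
binomial / overlap / chi-square tests → beat×memory Pearson correlations
(post-stimulus matched-window and pre-stimulus variants, threshold
p < 0.0125) → sign-adjusted pre-stimulus t-test → an exploratory
128-correlation homeostatic scheme → behavioral summaries with a 2×2
repeated-measures ANOVA.

The simulator (`simulate_cohort()`) generates the same paradigm with
Poisson spike trains whose rates follow the baseline-shift model: a
responsive unit carries a multiplicative binaural gain `g^±1` in the
pre-stimulus and all post-stimulus windows, and a remembered-trial memory
gain whose log decreases with the unit's signed beat shift (coupling κ,
calibratable to a target shift/gain correlation with
`coupling_for_correlation()`). See the methods vignette
(`vignettes/beatmem-methods.Rmd`) for the model and its assumptions.

## Input formats

`spikes.tsv` — one row per spike:

```
unit_id             subject_id  region    hemisphere  unit_class  timestamp
s01_L_amygdala_u01  s01         amygdala  left        single      0.3651
s01_L_amygdala_u01  s01         amygdala  left        single      0.9068
s01_L_amygdala_u01  s01         amygdala  left        single      2.633
s01_R_amygdala_u01  s01         amygdala  right       multi       1.204
```

`trials.tsv` — one row per trial (outcome columns optional; derived by
`derive_memory_outcomes()`):

```
trial_id       subject_id  run_id  phase     onset  beat_condition  stimulation_delivered  source_category  word         novelty  response  source_truth
s01_r1_enc001  s01         s01_r1  encoding  0.5    monaural        TRUE                   color            s01_r1_w001  na       none      source_a
s01_r1_enc002  s01         s01_r1  encoding  5      monaural        TRUE                   color            s01_r1_w002  na       none      source_a
s01_r1_ret001  s01         s01_r1  retrieval 300.5  monaural        FALSE                  color            s01_r1_w017  old      source_a  source_a
s01_r1_ret002  s01         s01_r1  retrieval 306.5  monaural        FALSE                  color            s01_r1_w002  old      unsure    source_a
```

Small runnable examples ship in `inst/extdata/`. Files are UTF-8,
tab-separated, header mandatory; times are seconds on the session clock.

## Worked example

Simulate a cohort with a homeostatic coupling injected into window `w3`
(coupling calibrated so the true shift/gain correlation is −0.6), then run
the whole pipeline:

```r
library(beatmem)

cfg <- simulation_config(p_beat_responsive = 1, memory_windows = "w3",
                         coupling = coupling_for_correlation(-0.6, 1.8, 0.45))
ds <- simulate_cohort(cfg, seed = 7)
report <- analyze_dataset(ds)
print(report)
#> <beat_report>
#>   inclusion filter (2 Hz): kept 346 of 360 units (14 removed)
#>   selection (encoding): 339 of 346 units selected (175 increase, 164 decrease)
#>   selection (retrieval): 345 of 346 units selected (175 increase, 170 decrease)
#>   correlation (encoding, left): 169 selected units
#>   correlation (retrieval, left): 174 selected units
#>   significant correlation cells: 34 of 64

subset(report$correlations,
       beat_window == "matched_post" & memory_type == "item" &
         run_scope == "all_runs" & phase == "retrieval")
#>   memory_window       r        p n_units significant
#> 1            w1  0.1589 3.62e-02     174       FALSE
#> 2            w2  0.0507 5.06e-01     174       FALSE
#> 3            w3 -0.5934 6.21e-18     174        TRUE
#> 4            w4  0.2643 4.24e-04     174        TRUE
```

The injected window `w3` recovers r = −0.59 ≈ the −0.6 target. The small
positive correlations in the other windows are real, not artifacts: the
simulated behavioral beat effect makes remembered pools contain slightly
more beat-gain trials, a composition-mediated beat–memory association that
the correlation stage correctly picks up (see the vignette). The
pre-stimulus baseline shift is confirmed by the sign-adjusted t-test:

```r
report$prestim$retrieval[c("t", "p", "n")]
#> t = 49.66, p = 2.7e-104, n = 174
```

`write_report(report, "out/")` writes `selection.tsv`, `population.tsv`,
`correlations.tsv`, `exploration.tsv`, `behavior.tsv`, `summary.json` and
`pipeline.log`. A thin command-line wrapper lives at
`inst/scripts/beatmem.R` (`simulate` and `analyze` subcommands).

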