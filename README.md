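# vissearch

Simulation and analysis of eye-movement strategies in oriented line-segment
visual search.

## The problem

In arrays of oriented line segments, the local variability of distractor
orientations decides whether a target (a segment at 45°) can be found with
peripheral vision. Regions of nearly parallel distractors (*homogeneous*)
make the target pop out; regions of widely varying orientations
(*heterogeneous*) require direct fixation. The optimal search policy is
therefore to fixate the heterogeneous regions and let the periphery handle
the rest — yet observers differ enormously in how closely they follow it,
and the spatial layout of the heterogeneity (one contiguous half vs.
patches scattered by a smooth 1/f² difficulty field) changes how optimal
they are.

`vissearch` is for researchers who study these strategies. It provides:

* **Stimulus generators** — split-half arrays (`make_split_half()`),
  uniformly easy/hard arrays, and "jumbled" arrays (`make_jumbled()`) whose
  per-cell orientation range r(d) = π/6 + d·(2π/3 − π/6) is driven by a
  1/f² random-phase noise field histogram-equalised to the U-shaped
  parabolic density f(x) = 3(2x−1)², plus PNG rendering and JSON metadata.
* **A synthetic-data generator** — parametric observers
  (`observer_params()`, `sample_population()`) that fixate according to a
  heterogeneity weight `w_het`, an upper-field bias and a saccade-amplitude
  penalty, detect targets peripherally within a difficulty-dependent
  radius, give up after a fixation budget, and time out at 60 s; full
  experiment designs via `make_design()` and `simulate_cohort()`.
* **The analysis pipeline** — fixation classification
  (`classify_fixations()`: out-of-bounds rule, split-half midline with a
  30-px unclassified strip, difficulty-threshold rule for jumbled arrays)
  and the search-**efficiency** statistic: the proportion of classified
  fixations 2–6 on correct target-absent trials that land on heterogeneous
  regions, n_het / (n_het + n_homo), with 1 = optimal
  (`efficiency_score()`), plus accuracy/RT tables and exclusion rules.
* **Group-level inference and validation** — hierarchical proportion
  estimates with 95% intervals (participant bootstrap by default, logistic
  mixed model via lme4 as an alternative backend), log₂-median-RT
  correlation matrices with a Fisher-z strategy CI, and the
  parameter-recovery harness (`recovery_experiment()`,
  `coverage_experiment()`) that validates the whole chain on cohorts with
  known parameters.

## Worked example

Simulate a five-observer cohort on the horizontal-split design, run the
pipeline, and compare the recovered strategies with the generating
parameters:

```r
library(vissearch)

design  <- make_design("exp1", seed = 7)        # 10 passive + 5 practice + 160 search
stimuli <- build_stimuli(design, seed = 8)
cohort  <- sample_population(5, seed = 9)       # w_het ~ Beta(2, 2)
report  <- simulate_cohort(design, cohort, stimuli = stimuli, seed = 10)

classified <- classify_fixations(report, experiment = "exp1", stimuli = stimuli)
strategy_summary(classified, experiment = "exp1")
```

```
 participant efficiency n_het n_homo ta_accuracy excluded median_rt_ta_ms
           1      0.320   119    253           1    FALSE            6263
           2      0.265   100    277           1    FALSE            6224
           3      0.424   157    213           1    FALSE            6238
           4      0.415   156    220           1    FALSE            6229
           5      0.643   240    133           1    FALSE            6214
```

The efficiency column is each observer's strategy score; the generating
`w_het` values were 0.291, 0.279, 0.460, 0.422 and 0.622, so the pipeline
recovers the known strategies to within binomial noise. Target-absent
accuracy is at ceiling (no observer is excluded) and median target-absent
RTs sit near the ~6 s give-up time. Group-level estimates by task and
configuration:

```r
est <- hierarchical_proportion(proportion_data(classified), seed = 11)
est$estimates
```

```
              cell estimate lower upper
 passive:hard_down    0.527 0.267 0.787
  search:hard_down    0.419 0.248 0.590
   passive:hard_up    0.797 0.587 1.000
    search:hard_up    0.407 0.246 0.568
```

During passive viewing the cohort strongly prefers the heterogeneous side
when it is the upper half (0.80) — the upper-field and heterogeneity biases
add — while during active search the preference collapses to the cohort's
mean `w_het` (~0.41) regardless of configuration, exactly the structure the
simulator's passive/search parameter split encodes.

Command-line entry points (`inst/cli/`): `generate-stimuli.R`,
`simulate.R`, `analyze.R`, `recover.R`.

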