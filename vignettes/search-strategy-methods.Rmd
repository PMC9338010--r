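---
title: "Models and methods: simulating and scoring visual-search strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and scoring visual-search strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vissearch)
```

## The scientific problem

In search arrays of oriented line segments, the *local variability of
distractor orientations* determines how useful it is to fixate a region. A
45-degree target among nearly parallel distractors (a *homogeneous* region)
pops out in peripheral vision; the same target among widely varying
orientations (a *heterogeneous* region) requires central vision. The optimal
policy is therefore to direct fixations at heterogeneous regions and let the
periphery cover the homogeneous ones. Human observers differ enormously in
how well they do this, and the spatial layout of the heterogeneity — one
contiguous half versus patches scattered across the scene — appears to
change how closely their scanpaths approach the optimum.

`vissearch` packages the computational side of this research programme:

1. **Stimulus generation** (`make_split_half()`, `make_jumbled()`,
   `make_uniform_array()`): arrays whose per-cell orientation range is set by
   a difficulty field.
2. **Synthetic observers** (`observer_params()`, `simulate_session()`): a
   parametric scanpath model producing fixation sequences, responses and
   reaction times with the statistical structure the analysis assumes.
3. **The analysis pipeline** (`classify_fixations()`,
   `efficiency_score()`, `apply_exclusions()`): fixation classification and
   the search-efficiency statistic.
4. **Group-level inference and validation** (`hierarchical_proportion()`,
   `rt_correlations()`, `recovery_experiment()`): interval estimates,
   condition correlations, and the parameter-recovery harness that ties the
   whole chain together.

No claim is made that the observer model matches human oculomotor dynamics;
it is an explicit stand-in whose *known* parameters let us verify that the
pipeline measures what it claims to measure.

## Stimulus model

A search array is a grid of square cells (22 x 16 cells of 32 px for the
split-half geometry on a 1024 x 768 screen; 32 x 24 cells for the dense
arrays on 1280 x 1024), each containing one line segment. The target, when
present, is oriented at $\theta = \pi/4$; distractor orientations are drawn
independently per cell from

$$\mathrm{Uniform}\left(\theta + \tfrac{\pi}{2} - \tfrac{r}{2},\;
\theta + \tfrac{\pi}{2} + \tfrac{r}{2}\right) \bmod \pi,$$

where the *range* $r$ interpolates linearly in the cell's difficulty $d \in
[0,1]$ between $r_{\min} = \pi/6$ ($d=0$, homogeneous) and $r_{\max} =
2\pi/3$ ($d=1$, heterogeneous). Orientations are unoriented line segments,
stored modulo $\pi$, measured counter-clockwise from horizontal-rightward.

* **Split-half arrays**: one half (upper/lower or left/right) at $d=1$, the
  other at $d=0$.
* **Jumbled arrays**: $1/f^2$ noise with independent uniform random phases
  is synthesised at 1024 x 1024 by inverse FFT (Hermitian symmetry is
  guaranteed by normalising the spectrum of real white noise to unit
  amplitude), cropped to the array extent, then *histogram-equalised* to a
  U-shaped parabolic reference density $f(x) = 3(2x-1)^2$ with CDF
  $F(x) = ((2x-1)^3 + 1)/2$. Equalisation is a rank transform (ties broken
  by pixel index) through $F^{-1}$, so the output distribution is parabolic
  regardless of the input — every array has the same difficulty
  distribution, with most pixels pushed toward 0 or 1 to create distinct
  homogeneous and heterogeneous patches. Cell difficulty is the mean of the
  map over the cell's 32 x 32 block (the mean is less noisy than
  centre-pixel sampling; the aggregation rule was an open choice).

Targets are placed uniformly over eligible cells, excluding the outermost
ring and the central cells (the four centre cells on even-by-even grids; 656
eligible cells on the 32 x 24 grid, verified by enumeration in the tests).

Two parameterisation choices were genuinely open and are fixed here: the
reference parabola is the U-shaped $3(2x-1)^2$ (the only parabola that puts
the majority of pixels at the extremes), and the narrow/wide orientation
spreads are treated as the full width of the uniform distribution in both
geometries, with the wide value $2\pi/3$.

## Observer model

Each simulated observer is an `observer_params()` object:

| parameter | default | meaning |
|---|---|---|
| `w_het` | 0.5 | probability that a post-initial fixation targets a heterogeneous cell ($d > 0.5$) |
| `upper_bias` | 1 | multiplicative preference for upper-half cells |
| `amp_scale` | 6 cells | exponential saccade-amplitude penalty scale |
| `detect_radius_easy` | 40 cells | peripheral detection radius at target difficulty 0 (≥ grid diagonal ⇒ ceiling) |
| `detect_radius_hard` | 4 cells | radius at difficulty 1 (small ⇒ periphery near chance; the target must be approached) |
| `fix_dur_median_ms`, `fix_dur_sigma` | 250 ms, 0.3 | log-normal fixation durations |
| `giveup_fix` | 24 | fixations before responding "absent" |
| `w_het_passive`, `upper_bias_passive` | as search | the passive-viewing preferences |

The first fixation of every trial is at the array centre (trials start on a
central fixation cross). Each subsequent fixation is drawn in **two
stages**: first the *class* of the next cell — heterogeneous with
probability $\propto w_{het} \bar U_{het}$ versus homogeneous with
probability $\propto (1 - w_{het}) \bar U_{homo}$, where $\bar U_c$ is the
class's mean upper-half weight — then a *cell within the class* with weight
$\texttt{upper\_bias}^{[\text{upper}]} \exp(-\text{dist}/\texttt{amp\_scale})$,
excluding the currently fixated cell. The two-stage form (rather than one
flat multinomial multiplying class weight by the distance kernel) is a
deliberate design choice: under a flat product the distance kernel couples
with the spatial clustering of heterogeneous cells, so an observer sitting
on the hard half would revisit it more often than `w_het` prescribes and the
recovered efficiency would be biased outward. With the hierarchical sampler
the marginal class probability is *exactly* `w_het` whenever `upper_bias =
1` or the split is left/right — the clean link that the parameter-recovery
validation relies on. For up/down splits with `upper_bias != 1` the class
odds shift to $w_{het} b : (1 - w_{het})$, reproducing the
configuration-dependent efficiency pattern seen with a genuine upper-field
bias.

Peripheral detection is distance-based: a present target is detected from a
fixation iff the fixated cell lies within
$r_e + d_t (r_h - r_e)$ cells of the target cell, with $d_t$ the target
cell's difficulty. Defaults put homogeneous-background detection at ceiling
and heterogeneous-background peripheral detection near chance
(`detect_radius_hard = 4` rather than 0: under the local saccade kernel a
hard target is then found on roughly two thirds of trials once the eyes
wander near it, matching the printed 60–70% regime, whereas a zero radius
would give under 10%; the value was calibrated once against that printed
accuracy and is not revisited).
Responses: "present" on detection, "absent" after `giveup_fix` fixations
(24 fixations x ~260 ms ≈ 6 s, the observed give-up time), "timeout" at
60 s. Reaction time is the cumulative fixation duration at response.

Cohorts come from `sample_population()`: by default `w_het ~ Beta(2, 2)`
(spanning counter-optimal to near-optimal observers), passive-viewing
preferences `w_het_passive ~ Beta(4, 2)` and `upper_bias_passive = 2`
(passive viewing shows both a heterogeneity and an upper-field preference,
while search weakens both), everything else at point values.

### What the generator emulates — and what it does not

The simulator reproduces: centre-start fixation sequences, individual
differences in heterogeneity preference, ceiling/chance peripheral
detection, give-up and timeout behaviour, and RTs on the printed 1–15 s
scale. It does **not** model main-sequence kinematics, landing-site error,
fixation-duration/information coupling, learning across blocks, or response
errors on target-absent trials (simulated TA accuracy is ~1, so the
exclusion rules only bite on degraded parameterisations or real data). A
green recovery test therefore establishes that *the pipeline faithfully
measures the strategy of an observer whose strategy is known*, not that
human data would satisfy any particular value.

## Analysis pipeline

Classification applies, in order: out-of-bounds marking (half-open pixel
intervals — a fixation exactly on the right/bottom array edge is outside);
for split-half trials the midline rule with a 30-px-wide unclassified
central strip (15 px each side, oriented along the split; a fixation exactly
15 px out counts as classified); for jumbled trials a threshold on the
fixated cell's difficulty (strictly greater than 0.5 is heterogeneous; a
cell at exactly 0.5 is homogeneous — a documented tie rule; the threshold is
exposed because the original cut is not public). The four labels partition
the fixations.

The **efficiency score** pools fixations 2–6 of *correct target-absent*
search trials (fixation 1 is the forced central fixation; almost all trials
have ≥ 6 fixations; TA trials avoid target-capture contamination) and
computes $n_{het} / (n_{het} + n_{homo})$ per participant, pooled counts
rather than a mean of per-trial proportions (per-index curves are available
from `strategy_by_index()`). An empty denominator yields a flagged `NA`,
never 0. Exclusions: TA accuracy < 0.75 (both designs), hard-condition
target-present accuracy < 0.25 (dense-array design); thresholds are strict.

## Group-level inference

`hierarchical_proportion()` estimates per-cell (task x configuration)
probabilities of fixating heterogeneous regions with 95% intervals and all
pairwise cell differences. The default backend is a nonparametric bootstrap
over participants of the unweighted mean of per-participant proportions
("average participant"), summarised as a **t interval with bootstrap
standard error** (point ± $t_{n-1,0.975}$ x SE, clipped to the parameter
range). The percentile interval is also available, but at the typical
13-participant scale it undercovers (~80–90% observed), while the boot-t
interval calibrates at ~95–97%; the calibration acceptance test (coverage ≥
90% over 100 replicate cohorts) runs against this default. With a single
participant the bootstrap resamples fixations and converges to the binomial
Wald interval, which the tests assert as a limit check. The alternative
`"glmer"` backend fits a logistic mixed model (maximal random-effect
structure, falling back to a random intercept when the maximal fit fails)
and summarises cells by parametric simulation of the fixed-effect
posterior; it satisfies the same interface. A full MCMC treatment (the
natural analysis for real data) is out of scope here: the estimation
backend is pluggable precisely so the interval contract, not the sampler,
is the specification.

`rt_correlations()` computes Pearson correlations of per-participant
$\log_2$ median RTs across conditions (target-absent and target-present
separately) and the split-half-versus-jumbled strategy correlation with a
Fisher-z CI (`stats::cor.test`).

## Validation harnesses

`recovery_experiment()` is the end-to-end check: for each generating
$w_{het} \in \{0.1, \dots, 0.9\}$, 20 observers x 80 TA trials are
simulated, classified and scored; the cohort-mean efficiency must recover
$w_{het}$ with max |bias| < 0.05 (split-half) and < 0.07 (jumbled). A
single stimulus set per run is shared across observers and grid values (a
fixed item bank) — this only reduces stimulus-sampling noise and does not
couple observers, whose scanpaths are independent. `coverage_experiment()`
replicates 13-participant cohorts at a known truth and checks interval
coverage. Both are deterministic given their seeds; all package randomness
flows through explicit `seed` arguments (restored afterwards via
`withr::with_seed`).

Simulation sizes in the test suite follow the stated validation scales
(9 x 20 x 80 trials; 100 replicate cohorts); a few purely illustrative
distributional checks (e.g. the U-shape of pooled jumbled difficulties) are
scaled down from hypothetical larger runs to keep the suite fast, which is
noted inline where it happens.

## Known limitations

* The observer model is intentionally minimal; its parameters are chosen to
  land summary statistics in the empirically observed regimes, not fitted
  to data. A single detection radius cannot match the printed hard-target
  accuracy of both grid geometries at once: the default is calibrated to
  the dense 32 x 24 arrays (~0.70), so on the sparser 22 x 16 grid the same
  radius over-covers and hard-half accuracy runs higher than the observed
  "a little under half".
* Exact reproduction of published posterior estimates would require the
  original raw eye-tracking data, which the package does not ship.
* The jumbled heterogeneous/homogeneous cut at 0.5 is one defensible choice
  among several; conclusions sensitive to it should vary `threshold`.
* Monitor calibration and visual-angle geometry are recorded as metadata
  only; all geometry is in pixels and cells.
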