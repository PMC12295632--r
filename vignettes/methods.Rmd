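---
title: "Models and methods behind swimprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swimprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimprot)
library(dplyr)
```

swimprot analyses two kinds of data produced by larval zebrafish
neurotoxicity assays, such as the MPP⁺ (1-methyl-4-phenylpyridinium)
Parkinsonism model: tracked swim trajectories recorded under alternating
light/dark illumination, and label-free quantification (LFQ) protein
intensity matrices from pooled-larvae replicates. This vignette explains
the models and procedures the package implements, the parameters that
matter and their defaults, the synthetic-data generators used to validate
the pipeline, and the numerical choices made where the design was
genuinely open.

## The behavioral model

### From positions to velocity

A trajectory is a per-well time series of positions $(x_i, y_i)$ in mm
(origin at the well centre) sampled at a fixed rate (default 25 Hz; the
rate is always an explicit argument and never inferred from the data).
Velocity over interval $i$ is the Euclidean step length divided by the
sampling interval:

$$v_i = \frac{\sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}}{\Delta t}.$$

No smoothing is applied by default. Tracking pipelines differ in whether
they smooth before thresholding and rarely document it, so smoothing is
exposed as an optional centred moving average (odd window) applied before
classification only; the summary metrics always integrate the raw step
lengths, so total distance is unaffected by the smoothing choice.

Sampling must be uniform to within $10^{-6}$ s. A dropped frame is a
validation error, not an interpolation target: every metric below has
exact integral semantics ($\sum v_i \Delta t$ telescopes to the path
length) and silently bridging gaps would quietly break them.

### Activity states, movement phases, and bolts

Two velocity thresholds drive all classification, matching the
conventions of larval locomotor assays:

| parameter | default | meaning |
|---|---|---|
| `theta_active` | 0.1 mm/s | above: *active*; at or below: *inactive* |
| `theta_abrupt` | 1.2 mm/s | splits active time into *normal* (0.1–1.2] and *abrupt* (>1.2) |

A **bolt** is a discrete burst of swimming: a maximal run of active
intervals, after two clean-up rules with config-exposed defaults:

* runs separated by an inactive gap of at most `merge_gap_s` (default
  0.1 s) are merged into one event spanning the gap;
* merged events shorter than `min_duration_s` (default 0.2 s) are
  discarded.

The burst unit itself is standard in this field, but its operational
definition is not; the defaults were chosen so that a single
mis-tracked frame at 10–30 Hz can neither split a burst in two nor
create a spurious one. Both parameters are part of the configuration and
echoed into every run report. A bolt's distance integrates $v\,\Delta t$
over all its intervals, including a merged sub-threshold gap, so the sum
of bolt distances can never exceed the total distance.

One behaviour worth knowing: raising `theta_active` always shrinks
active time, but it can *increase* the bolt count, because a stretch of
mid-range velocity inside one burst can turn into a super-merge-gap
pause and split the event. The test suite pins this down with an
explicit example rather than pretending the count is monotone.

### Per-larva metrics and the light/dark split

For each larva the package reports total distance, mean velocity (total
distance over observed time), active/inactive time fractions, bolt
count, mean bolt duration, mean per-bolt distance, total bolt distance
divided by bolt count, and the mean inter-bolt interval (end of one
event to the start of the next; `NA` with fewer than two events, as are
all bolt means with zero events).

Light/dark epochs come from a schedule object; the standard assay is
`standard_schedule(3, 30, 30)` — 180 s of three 30 s light / 30 s dark
cycles, light first, following a dark acclimation period that is not
part of the recording. Velocity intervals are assigned to the epoch
containing their **midpoint**, and bolts to the epoch containing the
event's temporal midpoint. Midpoint assignment is what makes the
decomposition exact: light and dark distances sum to the total to within
$10^{-9}$, and per-condition bolt counts sum to the overall count. These
conservation identities are asserted in the tests.

The per-second locomotor profile bins each larva's distance into 1 s
bins (again by interval midpoint) and averages within a group, giving
the familiar trace in which responsive larvae show sharp peaks after
each light transition.

### Group statistics

Per-condition distance is analysed with a two-way ANOVA (group ×
condition) followed by Tukey's HSD over the four cells, the standard
design for light/dark assays; overall per-metric group differences use
Welch's *t*-test. These are thin, validated wrappers around
`stats::aov`, `stats::TukeyHSD` and `stats::t.test` — the package's
contribution is the pipeline around them, not a re-derivation of
classical tests. Only balanced designs are accepted for the ANOVA;
under balance the sum-of-squares decomposition is unambiguous. Fully
degenerate inputs (an immobile cohort, hence zero variance everywhere)
are defined to give $F = 0$, $p = 1$ rather than `NaN`, so a null assay
runs to completion and says "nothing happened".

## The proteomics model

The LFQ half follows the conservative contract appropriate for a
two-group design with duplicate pooled replicates:

1. **Detection accounting.** A protein is "detected" in a group when it
   is quantified in both replicates (`both_replicates`, default) or in
   at least one (`any_replicate`, for sensitivity analysis). The shared
   / control-only / treated-only sets partition the union of
   detections.
2. **Replicate-consistency filter.** Only proteins quantified in every
   sample of every group are tested; nothing is imputed anywhere. With
   two replicates per group an imputed value would contribute half of a
   group's information, so exclusion is the defensible choice; the cost
   is coverage, which the run report makes visible.
3. **Transform and normalization.** Intensities are log2-transformed and
   each sample's median log2 intensity is subtracted
   (`median_center`, default) so sample loadings align; `none` is
   available. Median centering is a deliberate, minimal choice —
   upstream pipelines "normalize" in many ways and rarely say how, so
   the method here is explicit and echoed in reports.
4. **Differential expression.** Per protein, the log2 fold change is the
   difference of group means of log2 values (not the log2 of mean
   intensities — means of logs match the transform-then-compare
   contract), Welch's *t*-test supplies the p-value
   (Student's available behind a flag), and Benjamini–Hochberg
   adjustment runs across all tested proteins. A protein is `up` when
   $p_{adj} < 0.05$ and $\log_2 FC > 1$, `down` when
   $p_{adj} < 0.05$ and $\log_2 FC < -1$, else `ns`. Proteins with zero
   variance in both groups have no defined *t* statistic and are
   reported as untested rather than handed $p = 0$ — with $n = 2$ a
   zero-variance row would otherwise always top the list.
5. **Enrichment.** Over-representation of a query gene set (typically
   the `up`/`down` proteins) against a background (all tested proteins)
   is the exact upper-tail hypergeometric probability
   $P[X \ge k]$ per term, BH-adjusted **across terms** — the DE family
   and the enrichment family are corrected separately — and reported at
   $p_{adj} < 0.01$ by default.

### Curated reference sets

Two packaged fixtures transcribe curated protein lists from the MPP⁺
larval model: a 40-protein neurodegeneration-associated set (gene
symbol, protein name, log2 fold change, significance flag, regulation
arrow) and an 8-protein Parkinsonism subset (TCA-cycle enzymes, the
redox chaperone PARK7/DJ-1, 26S proteasome subunits). These are
*inputs*, not computations: membership reflects literature knowledge of
neurobiological relevance, which no desk pipeline can derive. The
8-protein fixture records two symbol spellings that circulate for
several proteasome members (PSMA5 vs PSMA8, PSMB vs PSMB3/5/10, PSMC3
vs PSMC1B, PSMD11 vs PSMD11B); the discrepancy is documented in the
fixture rather than silently resolved either way.

The worked example the package commits to: applying the volcano
classification (adjusted $p < 0.05$, $|\log_2 FC| > 1$) to the
40-protein table yields 40 differentially expressed proteins whose
regulation arrows match the recorded ones row for row — e.g. PARK7 ↑ at
+1.946, VAMP2 ↓ at −4.728.

## The synthetic-data generators

Passing tests on synthetic data show that the pipeline correctly
recovers what the generator put in, under the generator's assumptions.
The generators therefore emulate the statistical structure the analysis
relies on, and nothing more.

### Swim generator

`simulate_larva()` runs a two-state alternating-renewal process:

* **Quiescence** ends with an exponential waiting time whose rate is the
  current bolt-initiation rate — a piecewise-constant hazard that
  switches instantaneously at epoch boundaries. Light-evoked activity
  is modelled purely as this rate multiplier; there is no habituation
  term by default.
* **Bolts** last a Gamma-distributed duration (shape 2, mean 0.5 s by
  default). Within a bolt, per-step speed is normal truncated at zero
  (mean 6, sd 2 mm/s) and the heading performs a random walk (sd 0.5
  rad/step); during quiescence the larva drifts isotropically at a
  sub-threshold jitter speed (0.02 mm/s, below `theta_active` by
  construction).
* Positions are reflected at the wall of a circular well of 10 mm
  diameter — the 24-well-plate scale; arena geometry is otherwise
  unspecified upstream, so a plain reflecting disc is used.

The two preset arms encode the phenotype contrast qualitatively
described for this model: `control_swim_params()` has a dark rate of
0.2 bolts/s tripling to 0.6 under light; `treated_swim_params()`
(the hypokinetic arm) initiates at 0.05 bolts/s with **no** light
modulation, while within-bolt speed is identical to control — movement,
when it occurs, looks normal; initiation is what is suppressed. No
printed effect sizes exist for the behavioral assay, so these values
are a qualitative calibration, chosen once (and checked by simulation
to give the cohort-level ANOVA reasonable power at $n = 12$/group)
before being frozen; the behavioral acceptance checks are accordingly
property-based (directions and contrasts), not numeric reproductions.

Reproducibility: each larva's seed derives from the master seed by a
counter scheme, so any cohort member can be regenerated independently
and cohorts are bit-identical across runs on one platform.

What the swim generator does **not** emulate: tail-beat kinematics,
burst-internal speed profiles, habituation across cycles,
thigmotaxis, inter-larva heterogeneity beyond sampling noise. Tests
passing here say nothing about tracker noise or arena artefacts in real
recordings.

### LFQ generator

`simulate_lfq()` draws protein base abundances normal on the log2 scale
(mean 20, sd 2 — the magnitude range of real LFQ intensities), adds a
fixed-magnitude log2 effect of random sign to a chosen number of
proteins in the treated group, adds per-sample replicate noise (sd 0.25
on the log2 scale), exponentiates, and applies per-cell missingness
with an optional extra probability for the lowest abundance decile
(missing-not-at-random, to exercise the consistency filter the way
detection limits do). The ground truth table accompanies every matrix.

Under the null (no effects), the full pipeline's false discovery
behaviour is checked against the BH guarantee over 200 simulated
matrices of 2000 proteins with 4 replicates/group; with spiked
$|\log_2 FC| = 2$ effects at that design, sensitivity and empirical FDR
are recomputed by the acceptance script. Two replicates per group — the
real design — are supported throughout but give low power by nature;
the operating-characteristics checks use four so that sensitivity is a
meaningful quantity.

## Numerical choices and degenerate inputs

* Comparisons against `merge_gap_s` and `min_duration_s` use a
  $10^{-9}$ s tolerance so exact-multiple gaps (e.g. one 0.1 s frame at
  10 Hz vs a 0.1 s merge gap) behave identically across platforms.
* Threshold comparisons are strict (`v > theta`), so a velocity exactly
  at 0.1 mm/s is inactive and exactly 1.2 mm/s is normal.
* Epoch boundaries belong to the epoch that starts there; the final
  instant belongs to the last epoch.
* Empty cohorts, immobile larvae, all-missing proteins, empty gene
  subsets and zero-overlap enrichment terms all produce well-defined
  outputs (empty tables, `NA` statistics, $p = 1$) rather than errors;
  genuinely contradictory inputs (non-alternating schedules, unbalanced
  ANOVA cells, p-values outside $[0,1]$) raise classed validation
  errors.
* Problem sizes in the test suite are chosen to keep the full run at
  desk scale: the exhaustive bolt-segmentation check enumerates all
  $\sum_{L\le 12} 3^L = 797{,}160$ velocity series against an
  independent run-length-scan oracle; the null-FDR check uses 200
  matrices of 2000 proteins.

## Limitations

* The pipeline starts from trajectories; video decoding, centroid
  tracking and well detection are upstream and out of scope, as are
  spectral search and peptide-to-protein inference on the proteomics
  side.
* With duplicate replicates the Welch test is honest but weak;
  detection of twofold changes at $n = 2$ is unreliable, and the
  package reports that honestly rather than imputing or moderating
  variances.
* Enrichment quality is bounded by the annotation given; the packaged
  annotation builder is synthetic (keyword-matching on protein names)
  and exists to exercise the machinery, not to make biological claims.
* The regulation direction of a protein is reported only when it passes
  both significance and fold-change thresholds; near-threshold proteins
  carry no arrow.
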