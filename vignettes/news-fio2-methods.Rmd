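---
title: "Methods: FiO2-augmented early warning scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FiO2-augmented early warning scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newsfio2)
```

## The problem

Early warning scores (EWS) sum small integer weights assigned to each vital
sign; a rising total triggers escalation of care on general hospital wards.
The National Early Warning Score (NEWS) treats oxygen therapy as a binary
item — 0 on room air, 2 on any supplemental oxygen — so a patient escalated
from 2 L/min nasal oxygen to a reservoir mask at 15 L/min shows *no change
in score*. Because clinicians treat falling SpO2 by raising the inspired
oxygen fraction (FiO2), the oxygen dose itself carries information about
respiratory deterioration that the binary item discards.

This package implements the full pipeline for the FiO2-graded variant,
NEWS-FiO2: estimate FiO2 for every observation set, learn four FiO2 scoring
bands from event-labelled ward data with a single-feature classification
tree, replace the binary oxygen item with the banded weight, and compare the
discrimination of both scores against a composite outcome of in-hospital
death or unplanned ICU admission within 24 hours.

## Estimating FiO2 from the observation chart

Ward charts record the delivery device and the oxygen flow, not FiO2. For
variable-performance devices (nasal cannulae, simple and reservoir masks)
the package uses a dilution model: the patient inspires the supplemental
oxygen flow plus entrained room air at 21%,

$$\mathrm{FiO_2} = \frac{F + 0.21\,(\dot V_E - F)}{\dot V_E},
  \qquad \dot V_E = \mathrm{RR} \times V_T,$$

where $F$ is the oxygen flow (L/min) and minute volume $\dot V_E$ comes
from the charted respiratory rate at a fixed tidal volume $V_T$ of 0.45 L
per breath. Fixed-performance (Venturi-type) masks use the prescribed FiO2
directly; high-flow nasal oxygen and non-invasive ventilation are assigned
the ceiling value 1.0. Room air is 0.21 by definition.

Numerical choices:

* The formula can exceed 1.0 when the flow exceeds the (assumed) minute
  volume; results are clamped to `[0.21, 1.0]` and flagged via
  `fio2_clamped` rather than rejected, matching the ceiling philosophy used
  for high-flow modes.
* The fixed tidal volume is a deliberate simplification — true tidal volume
  is unobserved on the ward. `tidal_volume_sensitivity()` recomputes the
  estimate across a grid (default 0.30–0.70 L in 0.05 L steps) so users can
  see how strongly a given estimate depends on the assumption: the estimate
  falls monotonically as the assumed tidal volume grows, and the dependence
  vanishes for prescribed/ceiling devices.
* The device table is configuration, not code: `default_device_table()`
  ships the behaviour classes above, and deployments must align the device
  list with their local observation chart.

A low-flow, high-RR combination can yield an estimate barely above 0.21;
such observations fall in the lowest scoring band and score zero, the same
as room air. This is intended: the dilution model says these patients
breathe nearly unenriched air.

## Deriving the FiO2 scoring bands

Weights for the graded oxygen item follow the NEWS convention (0–3,
increasing with the concentration). The three cut-points separating the
four bands are learned from data: a binary classification tree restricted
to the single feature `calculated_fio2`, grown greedily by Gini impurity —
at each step the split over any current leaf with the largest impurity-mass
decrease is taken — until three internal splits exist. The sorted split
thresholds become the band edges.

Tunable parameters (`tree_config()`):

* `max_cut_points` (default 3): number of internal splits, hence bands − 1.
* `min_leaf_fraction` (default 0.01): minimum share of observations per
  leaf, a guard against sliver bands supported by a handful of rows.
* `rounding` (default 1): decimal places of the *reported* percent
  thresholds; internal cut-points stay unrounded.

Design decisions that were genuinely open:

* **Weights by concentration, not by event rate.** Weights 0–3 are assigned
  in ascending FiO2 order. If the per-band event rates happen not to be
  monotone (possible in small or unusual cohorts) the fit warns and records
  `monotone_event_rate = FALSE` rather than silently re-ranking bands.
* **Tie-breaking.** Equal impurity gains break toward the lower FiO2 cut,
  making derivation fully deterministic without a seed.
* **Band-edge semantics.** Bands are right-closed:
  `[0.21, c1], (c1, c2], (c2, c3], (c3, 1.0]`. With cut-points 0.22 / 0.37
  / 0.53 this reproduces one-decimal percent banding (21–22, 22.1–37,
  37.1–53, >53) with no gaps.
* **Greedy, not exhaustive.** Greedy CART growth is the field's standard
  and what mainstream tree libraries implement. It is not guaranteed to
  find the globally optimal cut *triple*; on noisy instances of ~200
  observations it matches an exhaustive search over all cut triples in
  most cases and attains at least ~80% (median ~100%) of the optimal
  impurity decrease, while the first split is always the single-cut
  optimum. The test suite checks exactly these properties against
  brute-force oracles and against an independent recursive-partitioning
  implementation.

Statistical caveat on small bands: the lowest band (roughly 21–22%) holds
on the order of 1% of observation sets. Its true impurity gain is small,
so at moderate sample sizes a spurious split inside the large top band can
outcompete it. In simulation with the default step hazards, recovery of
all three planted cuts to ±2 percentage points is reliable from roughly
half a million observation sets, and seed-dependent around 200,000. The
shipped demonstrations use 200,000 (the documented test condition) and
500,000 (the reproduction script) accordingly.

## Scoring

`score_news()` encodes the published RCP NEWS (2012) chart as the default
`news_chart()`; the chart is configuration shipped for convenience and
should be verified against the RCP publication before any clinical use.
`score_news_fio2()` is identical except the binary oxygen item is
*replaced* by the band weight of the calculated FiO2 — the weight-2 band is
by construction the one equivalent to NEWS's flat oxygen score, so a
patient at moderate FiO2 scores the same under both systems, while low
dilute flows score less and high concentrations score more. Replacement
(rather than adding a second oxygen item) follows from that equivalence.
Structural maxima differ slightly: NEWS totals reach 20, NEWS-FiO2 21
(six vitals × 3 plus a 3-weight oxygen item).

Observations in an oxygen-requiring admission that were charted on room
air are scored as charted (oxygen item 0); the package scores the recorded
device, not the admission's oxygen status.

## Cohort construction and labelling

Eligibility (`filter_eligible()`, defaults in `cohort_config()`): adults
(≥16 years at admission), stays of ≥24 h unless ended by death or ICU
admission, at least one complete observation set, and no ward periods that
follow an ICU stay. Exclusions are tallied flowchart-style and conserve
counts. A *complete* set records all of HR, RR, SBP, SpO2, temperature,
consciousness (AVPU, or GCS converted through a configurable map whose
default is 15→A, 9–14→V, 4–8→P, 3→U) and the inhaled-gas fields the device
requires.

Labelling (`tag_events()`): the admission's event is the earlier of
unplanned ICU admission or death (an ICU admission followed by death counts
as ICU). Every complete observation whose timestamp precedes the event by
at most 24 h is a positive with its time-to-event recorded; observations
after the event are dropped (the score is a *prospective* alarm; post-event
ward observations are never analysed); everything else is a negative. The
window boundary is inclusive at exactly 24 h — the more-positive reading —
and configurable (`window_inclusive`).

## Evaluation

All measures are observation-level, matching how ward alerting actually
operates (each observation set either triggers review or not):

* **AUROC** via the Mann–Whitney midrank formulation (exact under the heavy
  ties of integer scores; invariant to increasing transforms). Verified in
  tests against an all-pairs oracle to 1e-12.
* **Confidence intervals** by stratified percentile bootstrap: events and
  non-events resampled separately so every replicate preserves the event
  prevalence exactly. Percentile (not BCa) bounds, matching the simple
  resampling description the method follows; `reps` and `seed` are
  configurable and the caller's RNG stream is left untouched.
* **Operating points** at alert thresholds (default ≥5 and ≥7):
  sensitivity, specificity, PPV, and *efficiency* — the percentage of all
  observation sets alerting, a ward-workload proxy.
* **Precision-recall and efficiency curves**, preferred over ROC display at
  ~1–3% prevalence because they ignore the mass of correct negatives.
* **AUROC versus time-to-event window**: the negative set is fixed (all
  event-free observations) while the positive set shrinks to observations
  within `w` hours of their event, for `w` from 24 down toward 0. The
  shrinking-positive/fixed-negative reading is an assumption (the
  alternative — re-tagging near-window positives as negatives — is not
  used); windows with no positives report `NA`.

An admission-level view (maximum score over the stay against the admission
outcome) can be formed from the scored table with one `dplyr::summarise()`;
the observation level remains primary throughout.

## The synthetic ward generator

Real vital-sign databases of this kind are not openly available, so
`generate_cohort()` provides a synthetic stand-in tuned to published
cohort characteristics: ~38% of admissions on oxygen; truncated-normal
vital marginals (HR 84 (18) /min, RR 18 (4) /min, SBP 125 (23) mmHg,
temperature 36.7 (0.6) °C; oxygen-cohort FiO2 47% (15%)); admission-level
event prevalence ~4% overall and 6–7% in the oxygen cohort
(observation-level positives land near 1–3%). The oxygen cohort's event
probability steps through the planted cut-points 0.22/0.37/0.53 with
per-band probabilities 0.005/0.02/0.05/0.12, so the event hazard genuinely
increases with FiO2; event admissions drift over their final 24 h (rising
RR, HR and FiO2, falling SBP and SpO2, scaled by `drift_strength`).
Devices and flows are assigned by inverting the dilution formula, so
estimated FiO2 round-trips to the intended target. SpO2 is generated as
100 minus a right-skewed deviate floored at 70 (no published marginal
exists to anchor it). Observation cadence uses exponential
inter-observation gaps. A configurable share of admissions is generated
ineligible, and of observation sets incomplete, so the filters are
exercised.

What the generator deliberately does **not** emulate: between-vital
correlation beyond the shared pre-event drift, disease-specific
physiology, ward transfers, measurement artefacts, or the treatment
feedback loop in which a high score triggers intervention that prevents
the event (a structural confounder of all retrospective EWS evaluation).
Tests passing on this generator therefore demonstrate correctness of the
*method* — estimation, banding, scoring, metric computation — not expected
performance on any real cohort; in particular the synthetic AUROC values
and the size of the NEWS-FiO2 gain are properties of the generator, and
only the *direction* of the gain is asserted.

`generate_banded_fio2_labels()` is the minimal fixture for threshold
derivation: FiO2 uniform on `[0.21, 1.0]`, labels Bernoulli through the
planted bands. Uniform (rather than the cohort FiO2 marginal) is used here
because the truncated-normal marginal leaves under 1% of mass below the
lowest planted cut, which the minimum-leaf guard would then exclude from
derivation entirely.

## Problem sizes and reproducibility

The test suite runs cut-point recovery at 200,000 labelled observations,
AUROC oracle equivalence on 100 instances up to 500 observations, a null
simulation at 100,000, bootstrap coverage at 100 outer replications of
20,000 observations (3% prevalence, 200 bootstrap replicates), and
end-to-end studies of 700–2,500 synthetic admissions. The reproduction
script (`scripts/acceptance.R`) derives bands from 500,000 labelled
observations and evaluates a study of 8,000 admissions with 200 bootstrap
replicates; these sizes were chosen so each quantity's sampling
variability sits well inside the comparison tolerances. Every stochastic
step takes an explicit seed, generation is reproducible to the byte, and
seeded routines restore the caller's RNG state.

## Known limitations

* The device table, GCS→AVPU map and NEWS chart defaults are sensible,
  configurable stand-ins; deployments must align them with local charts
  and policies.
* The dilution formula ignores entrainment variability, mask leak and
  rebreathing; the fixed-tidal-volume assumption biases estimates for
  patients far from 0.45 L per breath (explore with
  `tidal_volume_sensitivity()`).
* The ceiling FiO2 of 1.0 for high-flow and non-invasive modes overstates
  delivered FiO2 for some patients; because such observations sit far
  above the top cut-point, their band weight (3) is unaffected.
* Calibration is out of scope: an EWS total is not a probability, so only
  discrimination and workload are assessed.
* Duplicate-timestamp observation sets are kept and flagged, not
  deduplicated; how they arose is a data-quality question the package
  cannot answer.
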