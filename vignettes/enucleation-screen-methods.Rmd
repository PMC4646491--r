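---
title: "Methods: simulating and analysing erythroid enucleation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing erythroid enucleation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythroscreen)
```

## The assay and its statistical model

Orthochromatic erythroblasts are the final nucleated stage of red-blood-cell
differentiation; each one extrudes its nucleus to become a reticulocyte,
leaving a free (extruded) nucleus behind. A phenotypic screen for chemical
inhibitors of this step works as follows: erythroblasts enriched by
fluorescence-activated sorting (Ter119-high, CD44-low, Hoechst-positive,
PI-negative) are seeded at 30,000 cells per well into 96-well plates with
one compound per well at 1 µM, incubated for 5 h, and read out by flow
cytometry. Among live (PI-negative), Ter119-positive events, Hoechst
staining separates enucleated reticulocytes (Hoechst-negative) from
nucleated erythroblasts (Hoechst-positive), and the readout is the **net
enucleation percentage**

$$E = 100 \cdot \frac{n_{\text{enucleated}}}{n_{\text{enucleated}} + n_{\text{nucleated}}}.$$

Each plate carries DMSO (vehicle) negative-control wells and cytochalasin D
positive-control wells (an actin inhibitor that blocks enucleation
essentially completely). Raw compound-well percentages are centred by the
plate median and scaled into z-scores; a compound whose z-score falls
strictly below −1 **in either of two replicate plates** (run on separate
days) is a potential hit, to be confirmed in an independent n = 4 paired
experiment.

This package implements that pipeline — simulator, gating, plate
statistics, hit calling, and the follow-up analyses used to characterise
hits — with every step testable against ground truth.

## The synthetic-data generator: what world it states

`simulate_well_events()` draws one well. Each seeded cell is dead with
probability `dead_fraction`; each live cell enucleates with probability
`true_enucleation_prob`. An enucleation emits **two** particles — a
reticulocyte and a free nucleus — so a well with $n$ cells yields
$n + n_{\text{enucleations}}$ events, and the number of reticulocyte events
equals the number of free-nucleus events exactly. Channel intensities are
single-component Gaussians per population per channel on a transformed
(asinh-like) scale; no spectral spillover is modelled, because gates are
defined in the same transformed space and no channel calibration exists to
emulate. DNA content (7-AAD) is kept on a linear scale, where 2N/4N gating
is conventionally done.

Defaults, and why:

* **Baseline enucleation 0.65 at the 5 h readout.** The control kinetics
  rise roughly linearly from the sort and plateau near 70% at about 6 h;
  0.65 sits between the 5 h point of that curve and the plateau.
* **Cytochalasin D wells at 0.02.** Enucleation is essentially blocked in
  the positive control; the residual 2% represents cells past the point of
  no return at dosing.
* **Noise: between-day sd 4 percentage points (one draw per plate per
  day), within-plate sd 3 points (per well).** These reproduce the
  "highly reproducible" duplicate structure: with 25 genuine inhibitors of
  ≥ 40% relative effect among 324 compounds, the implied replicate Pearson
  r is ≈ 0.85–0.9 (signal variance from true effects ≈ 130, noise
  variance per replicate ≈ 25). Binomial counting error at 30,000
  cells/well (≈ 0.3 points) is negligible by comparison.
* **Control layout: 4 DMSO + 4 cytochalasin D wells per plate** at fixed,
  spread-out positions; the published description states that control
  wells existed but not how many or where, so this is configurable.
* **Library ground truth** (`default_compound_library()`): 324 compounds,
  25 true inhibitors with relative reductions evenly spanning 0.4–0.9
  (mirroring the confirmed-inhibitor count, all at or above a 40% relative
  effect), alternating arrest/delay mechanisms, plus 4 cytotoxic
  compounds; inhibitor EC50s (0.05 µM) sit well below the 1 µM screening
  dose so the screen operates near saturation.
* **Free nuclei are Ter119-low by default**, so they land in neither term
  of the net-enucleation denominator. Their true surface-marker status in
  the analysis gate is not recoverable from the published description
  (which defines the denominator as Ter119+/Hoechst− plus Ter119+/Hoechst+
  without saying where extruded nuclei fall); the alternative convention
  (Ter119-positive nuclei, which then join the nucleated class) is a
  one-argument switch, `default_population_specs(free_nucleus_ter119_positive
  = TRUE)`.
* **Kinetics** (`kinetics_truth()`): control fraction
  $c(t) = 0.70\,\min(t/6, 1)$. Arrest compounds hold the treated culture
  at its suppressed 5 h level through 10 h; delay compounds close the gap
  to control exponentially with half-time `recovery_halftime` after 5 h.
  The default half-time is **0.75 h**: a closed-form power analysis shows
  that with 1 h the treated arm would retain a ~1.5-point residual gap at
  10 h which a paired t-test at n = 3 falsely flags as suppression 5.7% of
  the time, whereas the delay archetype being modelled has *reached*
  vehicle-control levels by 10 h; 0.75 h leaves a 0.5-point gap that is
  statistically indistinguishable at assay noise. With `washout_at` set,
  the treated culture resumes control-rate kinetics from its current
  level — the reversible-inhibitor washout experiment.
* **Seeds.** One master seed; per-plate and per-well streams are derived
  deterministically by hashing (master, plate, well), so outputs are
  byte-identical across runs and wells are reproducible in isolation.

What the generator does **not** emulate: spectral spillover and
compensation, instrument drift within a run, spatial plate effects (edge
wells), doublets/aggregates, autofluorescence tails, or compound
fluorescence. A green end-to-end test therefore establishes that the
statistics recover a known truth under idealised Gaussian channels and
exchangeable wells — not that the gates are robust to instrument
artefacts.

## Gating conventions

Thresholds default to the midpoint, on the transformed scale, between the
two relevant population locations of the simulator's channel model
(published gates are drawn, not numeric, so every threshold is a
configurable parameter). Rectangle gates are half-open, $[\min, \max)$, so
adjacent gates partition without double counting; polygon membership uses
the even-odd rule with boundary points inside. The 4N DNA threshold sits at
1.5× the 2N modal signal, standard cytometry practice. With the default
channel separations (≥ 2.8 sd to each threshold), per-event
misclassification is below 0.002 per gate; the tests allow a conservative
1% floor on top of binomial error.

The per-particle subtlety worth knowing: `gate_live()` reports the dead
fraction over *events*, and enucleation inflates the event count (two
particles per enucleated cell), so in a well with high enucleation the
event-level dead fraction underestimates the cell-level one. The
cytotoxicity readout is comparative (compound versus DMSO wells at similar
enucleation), so this cancels where it is used.

## Plate statistics and hit calling

`normalize_plate()` centres compound wells by the plate median; control
wells are excluded from both the median and the scale, since they are
extreme by construction. The scale convention is a genuine unknown — the
published description says only "normalized using the plate median and
transformed into z-scores" — so both are provided: the sample standard
deviation of the centred compound wells (default) and the robust
1.4826·MAD. With strong hits present, SD-scaling inflates the denominator
and is conservative; MAD-scaling is sharper but calls more borderline
wells. A plate whose compound wells are all identical has no scale and
raises a named degenerate-plate error. Missing wells (empty denominator or
a low-event QC void) propagate as missing and never enter plate
statistics; imputation is deliberately avoided.

Hit calling is strictly `z < threshold` (default −1) in **either**
replicate; a tie at exactly −1 is not a hit. Under a null screen with
standard-normal z-scores this rule calls $1-(1-\Phi(-1))^2 \approx 29.2\%$
of compounds — it is a deliberately permissive funnel in front of an
independent n = 4 confirmation, not a false-discovery control. The
Z′-factor, $1 - 3(\sigma_{neg}+\sigma_{pos})/|\mu_{neg}-\mu_{pos}|$, is
computed on raw control percentages; coincident control means yield
Z′ = −∞ and a failing flag rather than an error, and a failing plate still
produces a hit list (flagged), matching screening practice.

## Follow-up analyses

* **Validation** (`paired_ttest()`, `validate_compounds()`): two-sided
  paired Student's t per compound against vehicle, starred
  \*
  p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001, \*\*\*\* p < 0.0001,
  uncorrected (per-compound stars are the field's reporting convention
  here); Benjamini–Hochberg adjustment is available but off by default.
  Zero-variance differences at tiny n are reachable, so they are reported
  as the degenerate limit (p = 1 for identically zero differences, p = 0
  otherwise) with a flag instead of erroring.
* **Mechanism** (`classify_mechanism()`): paired tests at 5 h and 10 h;
  "suppressed" means two-sided p < α **and** a negative treated−control
  mean difference. Delay = suppressed at 5 h only; arrest = suppressed at
  both. The directional requirement matters: a one-sided test would double
  the false "still suppressed at 10 h" rate for fully recovered delay
  compounds, capping delay-classification accuracy below the 95% the
  design targets.
* **Dose trend** (`dose_trend()`): one-sided Spearman test for a
  decreasing response in concentration. No four-parameter logistic is
  fitted — the question answered is "is inhibition concentration
  dependent?", and no EC50s are reported for the assay being modelled.
  A constant response short-circuits to ρ = 0, verdict negative.
* **Washout** (`washout_recovery()`): recovered when treated comes within
  10 percentage points (configurable) of control by the final post-washout
  timepoint; the margin is roughly the control arm's own between-experiment
  spread at the plateau.
* **Morphology** (`morphology_proportions()`): cytospin class counts are
  proportions per experiment first, then mean ± sd across experiments, so
  experiments with different enumeration depths (112–541 cells) weigh
  equally. Classes are manual-microscopy categories; the taxonomy is
  configurable because it is defined pictorially in the source material.

## Numerical and degenerate-input choices

* `net_enucleation(0, 0)` is missing, not zero and not an error: an empty
  denominator is an uninformative well.
* Polygon boundary tolerance is 1e−12 in transformed units; vertices must
  be non-collinear.
* Medians of even-length centred vectors are exact to floating point
  (two-value average); tests assert exactness only for odd n.
* All fractions are clamped to [0, 1] after noise; the clamp matters only
  for cytochalasin D wells (near 0) and high-baseline wells.

## What the tests establish

The unit suites verify each operation against independent oracles (scalar
point-in-polygon, textbook paired-t arithmetic, binomial/multinomial
standard errors, closed-form null hit rates). The end-to-end checks verify
that, in the stated world above, the full pipeline recovers true inhibitor
status with sensitivity ≥ 0.9 at replicate r > 0.8, recovers per-well
enucleation probabilities within binomial error plus a 1% gating floor,
and classifies delay/arrest/washout mechanisms correctly in ≥ 95% of
simulations. They do not — cannot — establish anything about wet-lab
biology: the published biological measurements (≈ 88.7% non-proliferating
sorted cells, the 70 ± 10.5% plateau, 25 confirmed inhibitors, ≈ 30%
nuclear segmentation under proteasome inhibition) are inputs to the
simulator's design, not outputs the package can reproduce. The one
recomputable published number — 37 potential hits from the raw screen
table under the z < −1 either-replicate rule — requires a transcription of
that table (`recount_hits()` implements the recount under both scale
conventions); the transcription is not redistributable here, and the
corresponding acceptance test fails with an explanatory message rather
than being skipped.
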