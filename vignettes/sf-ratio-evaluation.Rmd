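---
title: "Evaluating the SpO2/FiO2 ratio: models, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating the SpO2/FiO2 ratio: models, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfratio)
```

## What the package computes

`sfratio` evaluates the pulse-oximetric SpO2/FiO2 (SF) ratio as a
surrogate for the arterial PaO2/FiO2 (PF) ratio in grading the acute
respiratory distress syndrome. The analysis unit is the *datapoint*: one
arterial blood-gas (ABG) event time-matched with the SpO2 and FiO2
signals around it. Datapoints are classified on both scales under the
global-definition thresholds (PF: 300/200/100; SF: 315/235/148; each
boundary inclusive on the more severe side), and the package reports

* datapoint- and admission-level agreement (confusion matrix, overall
  accuracy, per-category recall, misclassification direction),
* accuracy binned by FiO2 in 5-percentage-point bins,
* trending: over consecutive datapoint pairs within an admission, the
  correlation of proportional FiO2 changes with proportional PaO2 and
  SpO2 changes under a Respiratory-Index stability gate, and the rate at
  which SF transitions detect PF severity-category transitions,
* oximetry error: bias and precision of SpO2 against co-oximetric SaO2,
  a saturation-binned bias profile with a zero-crossing estimate, and
  RMS deviation of both saturations from the oxyhemoglobin dissociation
  curve,
* SF→PF conversion: a registry of imputation equations evaluated by R²
  and mean absolute error on the PF scale, next to fresh least-squares
  linear and log-linear fits.

## Physiological model and assumptions

**Dissociation curve.** Saturation is tied to oxygen tension by the
Severinghaus form \(S = (P^3 + 150P)/(P^3 + 150P + 23400)\), which has
its half-saturation point at 26.86 mmHg. The inverse solves the cubic in
closed form (Cardano) with one Newton polish step; the forward/inverse
round trip is exact to below 1e-9 over the clinically relevant range.
The curve is used unshifted: pH, PaCO2 and temperature shifts (Bohr
effect) are deliberately ignored. A scalar `shift` hook exists on both
curve functions but defaults to 1 and is outside the validated scope —
in real data those shifts are one reason SpO2- and SaO2-based indices
disagree, so analyses here are, if anything, optimistic about SpO2.

**Alveolar gas equation.** \(P_AO_2 = FiO_2(P_b - P_{H_2O}) -
PaCO_2/RQ\) with sea-level defaults \(P_b = 760\) mmHg, \(P_{H_2O} = 47\)
mmHg, \(RQ = 0.8\). The constants are bundled in
`physiology_constants()` precisely because they are assumptions;
altitude or unusual metabolic states change them.

**Respiratory Index.** \(RI = (P_AO_2 - PaO_2)/PaO_2\) is the
tension-based oxygenation index used as the stability gate for trending
analysis, chosen because it varies less with FiO2 than the PF ratio.
Computing RI requires PaCO2; datapoint pairs lacking it are excluded
from gated analyses and counted separately, never silently dropped.
Slightly negative RI values (measurement noise can put PaO2 above the
computed alveolar tension) are retained and flagged rather than clipped,
since clipping would bias proportional-change gating.

## Matching and validity rules

For each ABG the reference time is, in order of preference: the end of
the latest arterial-pressure gap (≥ 30 s) within 15 min before the
laboratory timestamp (high-resolution data, where the blood draw
interrupts the waveform and the laboratory stamp lags the draw); else
the nominal timestamp. SpO2 and FiO2 are summarised as the median over
[reference − 300 s, reference − 120 s], both endpoints closed
(deterministic and testable); hourly-resolution data instead use the
nearest sample within 30 min, ties resolved to the earlier sample.
Because FiO2 is a *setting* rather than a measurement, an empty FiO2
median window falls back to the last recorded setting at or before the
reference time — the last value of a setting is exact, while a stale
SpO2 measurement is not, so SpO2 gets no such fallback and the datapoint
becomes incomplete instead.

A datapoint is valid iff it is complete (PaO2, SpO2, FiO2 all present),
SpO2 ≤ 97% (inclusive), and it was measured during invasive
ventilation/NIV/CPAP with PEEP ≥ 5 cmH2O or HFNO with flow ≥ 30 L/min
(both inclusive). The first failing rule is recorded, with precedence
completeness → SpO2 → support, and the filter is idempotent.

Two aggregation decisions were genuinely open and are resolved as
follows. The admission-level severity is the most severe category
sustained over two consecutive *valid* datapoints (the maximum over
adjacent pairs of the pairwise minimum); a single-datapoint admission
falls back to that datapoint's category, because dropping such
admissions would silently bias the admission-level comparison.
"Consecutive" means adjacent valid datapoints regardless of the gap
between them; no maximum gap is imposed at this stage (the trending gate
has its own 6-h rule).

## The synthetic cohort generator

The generator exists so that the full pipeline — matching, filtering,
classification, agreement, trending, conversion — runs against data with
the *structure* of high-resolution ICU databases: per-second / per-minute
/ hourly signal resolutions, clinician FiO2 titration toward an SpO2
target band, gas-exchange drift, heteroscedastic oximeter error,
intermittent ABGs, and waveform gaps at blood draws. It makes no claim
of parameter fidelity to any real unit; every number lives in
`cohort_config()`.

Per admission, minute by minute:

1. **Gas exchange.** log-RI follows a Gaussian random walk (hourly sd
   0.10) with rare upward worsening jumps (probability 0.01/h, magnitude
   log 1.5), folded back at reflecting bounds [log 0.05, log 12]. The
   upper bound encodes that worse gas exchange than RI ≈ 12 — refractory
   hypoxemia on pure oxygen — is managed with extracorporeal support,
   and such patients are excluded from the emulated population. The
   initial state is log-normal with mean 1.2 and sd 0.55, calibrated so
   that under titration the datapoint severity mix spans the four
   categories with moderate dominating, as published ARDS cohorts show.
2. **Truth.** PaO2 follows from RI, the current FiO2 and PaCO2 through
   the alveolar gas equation inverse; saturation follows the
   dissociation curve. PaCO2 is redrawn i.i.d. per ABG from Normal(42,
   5) clamped to [25, 80] mmHg and held between draws.
3. **Observation.** The SpO2 channel is the true saturation passed
   through the oximeter model: bias linear in saturation (slope 0.25 per
   percent, zero at 94%), Gaussian noise (sd 2.0%), rounding to integer
   percent, clamping to ≤ 100. ABG events record exact PaO2, SaO2 with
   co-oximeter noise (sd 0.005 as a fraction), and the current PaCO2.
   The pulse oximeter and the co-oximeter observe the same true
   saturation with *independent* errors; the laboratory error is never
   fed into the finger-probe signal.
4. **Treatment.** Every 15 min the FiO2 setting steps up by 0.10 when
   the observed SpO2 sits below the target band and down by 0.05 when
   above, within [0.21, 1.0]. The review acts on the median of the last
   five minutes of observed SpO2: clinicians respond to sustained
   readings, and a controller driven by single noisy readings chatters.
   The default band is 94–98%, the band most commonly prescribed
   outside conservative-oxygenation protocols; under median review it
   induces a cohort mean saturation near 96%, which is also the level
   implied by a +0.5% mean oximeter bias together with a 94%
   zero-crossing and the 0.25/% slope. The asymmetric steps encode
   escape-hypoxemia-fast / wean-slowly behaviour.
5. **Support.** Admissions run on invasive ventilation with PEEP 8
   by default. A sustained FiO2 requirement ≤ 0.35 for 4 consecutive
   hours liberates the patient from support (mode `none`) until the
   requirement rises again — the standard screening criterion for
   spontaneous-breathing trials. This matters structurally: without
   liberation the generator produces near-room-air datapoints on
   qualifying support that real cohorts do not contain, because such
   patients get extubated and their subsequent measurements fail the
   support criterion.
6. **Sampling.** ABGs occur at uniform random intervals of 2–6 h
   (about 18 per 72-h admission). High-resolution admissions carry a
   1-Hz arterial-pressure channel with a gap ending at each draw (with
   probability 0.9, duration 30–90 s) and laboratory timestamps delayed
   2–10 min after the draw; minute/hourly admissions use the draw time
   as the nominal timestamp.

Determinism: each admission derives its own seed from the master seed,
so cohorts are byte-identical across runs and admissions are mutually
independent (regenerating one never perturbs another).

**What the generator does not emulate** — and hence what passing tests
do not show about real data: motion and low-perfusion artifacts (only
Gaussian error plus the median window), skin-pigmentation and
device-specific oximeter effects, dissociation-curve shifts, hemoglobin
and hemodynamics, support-mode heterogeneity (HFNO/NIV appear only if
configured), correlated PaCO2 dynamics, clinician behaviour beyond the
band policy (e.g. PEEP changes, proning), and any outcome process.
Quantitative results on synthetic cohorts are demonstrations of
mechanism, not estimates of real-world rates.

## Numerical and design choices

* Ratios are carried at full precision and never rounded before
  thresholding; the classifier is a half-open-interval lookup
  (`cut()` with right-closed breaks), cross-checked in the tests against
  an independent if-chain oracle on a 0.1-spaced grid.
* FiO2 bins are [center − 2.5, center + 2.5) percentage points with
  centers at multiples of 5 (lower edge inclusive), so bins partition
  the axis and the pooled accuracy equals the n-weighted bin mean
  exactly.
* The stability gate compares |proportional RI change| to the tolerance
  with an epsilon of 1e-9 so boundary cases constructed through the
  alveolar-gas round trip are not lost to floating-point error. Pairs
  whose first RI is below 0.05 are not gated: a proportional change on
  a near-zero base is meaningless.
* Pearson correlations and R² error out on zero-variance input rather
  than returning NA silently; report-level code catches these and
  reports the quantity as absent.
* The gap detector returns the *latest* qualifying gap end (the draw
  immediately precedes the laboratory result); nearest-sample matching
  breaks ties toward the earlier sample.
* FiO2 ingestion treats values > 1 as percentages, values in
  [0.15, 1] as fractions, and rejects values below 0.15 (neither
  convention); duplicate channel timestamps collapse to their median.
* The conversion registry ships the Rice (SF = 64 + 0.84·PF) and Bilan
  (SF = 57 + 0.61·PF) linear equations as transcribed from the
  literature, plus a log-linear entry fitted by this package to
  noise-free dissociation-curve data and named
  `severinghaus_loglinear_synthetic` to make its synthetic provenance
  explicit. Published log-linear coefficients can be added to the CSV
  registry without code changes. R²/MAE are always computed on the PF
  scale (log-linear predictions exponentiated first) so forms are
  comparable.

## Problem sizes

The default study configuration simulates 200 admissions of 72 h at
minute resolution (about 3,500 datapoints), which the full pipeline
processes in well under a minute; unit tests use 1–6 admissions of
12–48 h, parameter-recovery checks use 10,000 observation pairs, and
oracle-equivalence checks run 500–1,000 randomized cases. These sizes
give stable estimates for the mechanism analyses (correlation and share
estimates at roughly ±0.03) while keeping the whole suite fast.

## Known limitations

The admission-level two-consecutive rule is undefined for
single-datapoint admissions; the fallback (use the single category) is a
choice, and admission-level results on cohorts with many sparse
admissions inherit it. The SF–PF correlation is computed on pooled
datapoints, not averaged per admission. Trending transitions are
direction-only (down/same/up), not full category-pair transitions.
Registry equations other than Rice and Bilan are not transcribed from
primary sources; the synthetic log-linear entry stands in for the cited
log-linear imputations and is labelled accordingly.
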