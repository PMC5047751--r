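---
title: "Cross-environment activation of place-cell patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-environment activation of place-cell patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossact)
```

## The scientific question

When a rat sits in a small box watching another rat run a nearby linear
track, do the hippocampal CA1 ensembles that encode the track also become
active in the box? `crossact` implements the full analysis chain needed to
ask that question of paired box/track recordings: behavioural segmentation
(head-rotation events in the box, laps on the track, immobility, sharp-wave
ripples in the LFP), per-cell tuning estimation, common-cell accounting with
a chance model, and rank-order sequence matching with permutation nulls.
Because the recordings themselves are not public, the package ships a
synthetic-session generator that reproduces the statistical structure the
analysis assumes, so every stage is testable end to end.

## Pipeline overview

A recording day consists of a Track session flanked by box sessions
(Pre-box, Post-box). The stages are:

1. **Event detection.** Laps are end-zone-to-end-zone traversals of the
   200 cm track (10 cm reward zones at both ends). Rotation events are head
   excursions that start and end within ±45° of the box opening and span at
   least 180° of net unwrapped rotation, labelled CW/CCW by the sign of the
   net turn. Stops are >3 s below 2 cm/s. Ripples are 100–250 Hz envelope
   excursions peaking at ≥4 SD with boundaries at 2.5 SD.
2. **Tuning.** Linear rate curves on 2 cm bins (reward zones excluded),
   circular rate curves on 72 × 5° arches, 1 × 1 cm box rate maps; all
   smoothed with a Gaussian kernel of σ = 2 bins. Head-direction tuning is
   tested with the Rayleigh statistic; rotation-consistency z-scores the
   mean pairwise correlation of per-event circular curves against a
   curve-rotation null; spatial information is the Skaggs bits-per-spike
   measure.
3. **Cross-activation.** Cells with mean event rate in 0.5–6 Hz are active;
   cells active both in rotation events and on ≥1 track trajectory are
   common cells. Each box session × trajectory pairing yields an actual and
   a chance common-cell proportion and their normalised difference, the
   proportion difference index (PDI).
4. **Sequence matching.** Common cells with a prominent rate-curve peak
   (≥3 SD above the curve mean) are ordered by peak location into ≤2
   templates per day (≥5 cells each). Rotation sequences (cells ordered by
   within-event peak firing angle) are scored against templates by the
   maximum absolute Spearman correlation over all circular shifts; ripple
   sequences (cells ordered by peak firing time) use the plain correlation.
   A sequence matches when its score beats >95% of 1000 cell-identity
   shuffles; group-level significance compares the match count with 200
   identity-randomized template sets.

## The synthetic generator

The source study describes data, not a generative model, so all
distributional choices here are stand-ins chosen to be standard for the
field; they are documented as such and should not be read as claims about
the biology.

* **Census.** Defaults follow the study's per-day statistics: 45
  simultaneously recorded pyramidal cells, of which ~50% are running-active,
  ~33% rotation-active, and — at the default
  `cross_activation_fraction = 0.5` — about 11 are common. Sessions have 19
  laps per trajectory (5.8 s each) and 19 rotation events (6.67 s each).
* **Track tuning** is a 1-D Gaussian field per trajectory with σ = 7 cm
  (full width ≈ 28 cm, the middle of the 20–50 cm range typical of linear
  tracks) and peak 10 Hz jittered ±20%; every non-silent cell also fires at
  a 0.2 Hz baseline, which keeps "silent" cells below the 0.5 Hz activity
  floor while giving them occasional spikes. With these rates the 3 SD
  template-peak criterion is passed robustly by fielded cells — at much
  wider fields the criterion sits on a knife edge and template membership
  becomes a coin flip of estimation noise, a regime the study's templates
  evidently did not occupy.
* **Box tuning** is von-Mises-shaped over head direction (κ = 4, peak
  10 Hz ± 20%), expressed only during rotation events. The injected
  cross-activation forces a fraction of track-active cells to be box-active
  with preferred angles mapped linearly from their field centres
  (cm → degrees), which preserves the circular order exactly. The remaining
  box-active cells draw angles independently, so at zero injected overlap
  the two active sets are independent and overlap only by chance.
* **Kinematics.** Rotations are constant-angular-speed full turns (duration
  jittered ±20%, CW/CCW at random) starting and ending at the opening;
  they are separated by 2.5–6 s of irregular sub-45° facing-opening wiggle,
  with 25 s immobility epochs at both ends of the session so stop detection
  and ripple placement are exercised.
* **LFP.** An 8 Hz theta sinusoid rides on coloured noise during movement;
  during immobility, 150 Hz Hann-windowed bursts (80–120 ms) are inserted
  at 0.3/s. Burst amplitude is specified in detector units — the ripple-band
  envelope peak in SDs of the session envelope — and solved per burst by a
  short secant iteration, because at realistic signal-to-background ratios
  phase interference makes any closed-form amplitude mapping inaccurate by
  several SD. Optional replay places one spike per template cell, in
  forward or reversed order, inside the middle 40% of a burst.
* **Determinism.** One master seed is expanded into per-component streams;
  identical configurations produce byte-identical sessions.

What the generator does **not** emulate: theta-phase precession and
theta-sequence fine structure, realistic LFP spectra beyond band-limited
surrogates, behavioural idiosyncrasies (grooming, rearing — the detector
instead accepts an exclusion mask), overdispersed (non-Poisson) spiking,
and cross-day cell identity drift. Passing tests therefore demonstrate that
the pipeline recovers the structure it assumes, not that the assumptions
hold in any particular real dataset.

## Statistical and numerical choices

* **"Circular correlation" between per-event curves** is implemented as the
  Pearson correlation across the 72 matched angular bins; the null supplies
  the circular geometry by rotating whole curves a random number of 5° steps
  (in whole bins). A Fisher–Lee style circular–circular coefficient is a
  defensible alternative, but the rotation shuffle is only meaningful for a
  bin-matched statistic, so bin-wise Pearson is the default.
* **PDI scale.** The chance proportion $(n_t/N)(n_b/N)$ is a proportion of
  all $N$ cells, so the actual proportion entering the PDI is
  $n_\mathrm{common}/N$ — the only pairing for which independent random
  activation gives $E[\mathrm{actual}] = \mathrm{chance}$ and the control
  comparison is a null. The descriptive proportion of common cells among
  trajectory-active cells ($n_\mathrm{common}/n_t$) is reported alongside
  in the pairing table. Note the PDI of small counts has a Jensen-type
  negative bias (the ratio is concave in the actual count); with ~45-cell
  days this is about −0.02 to −0.05 at zero overlap, which the calibration
  tests account for explicitly.
* **Identity shuffles.** Per-sequence nulls permute the candidate's own
  cells. After restriction to shared cells, the null score distribution
  depends only on the number of shared cells k (relabelling invariance), so
  null samples are memoised per k; the group-level randomization over 200
  template sets exploits the same fact. The memoised null is verified
  against exhaustive permutation enumeration for k = 5–7 in the tests.
* **Small-k ceiling.** With strict ">95% of shuffles" and circular scoring,
  a 5-cell sequence can never match: even a perfect score of 1 beats only
  110/120 ≈ 91.7% of permutations. Circular matches therefore require ≥6
  shared cells; linear (ripple) scoring admits k = 5 (118/120 ≈ 98.3%).
  This is a property of the published rule, not of this implementation.
* **Degenerate group p.** The group p-value is the proportion of randomized
  template sets with strictly more matches. When the actual count is zero
  the strict rule degenerates (every null set ties at zero), so the
  reported p is 1 — the one-sided exceedance probability with ties — and a
  p of exactly 0 is reported as "<0.005" at 200 sets.
* **Ripple durations.** Event duration is the span of the 2.5 SD boundary
  crossing, which for a Hann-enveloped 80–120 ms burst is only ~30–70 ms;
  the operational duration filter is therefore 20–400 ms. The 400 ms cap
  matches the upper end of reported ripple durations.
* **Occupancy.** Bins with less than 0.1 s occupancy are excluded from
  spatial information and curve correlations; session-level curves easily
  clear this, while single-event circular curves (≈0.09 s per 5° arch) are
  used in full, NA-safe, via pairwise-complete correlations.
* **Kernels.** Gaussian kernels are truncated at ±3σ; circular smoothing
  wraps, linear smoothing renormalises at the edges. Rates are smoothed
  counts over smoothed occupancy, so spike counts are conserved before
  smoothing (a test asserts this).
* **Ties.** Cells tied on peak angle or time are ordered by earlier peak,
  then by cell id. Rank correlations of small permutations are rounded to
  10 decimals so the strict score comparisons are exact.
* **z-scored shuffle tests.** The rotation-consistency statistic (a mean of
  many pair correlations) is close to normal under its null and calibrates
  at the nominal 5% level. The z-scored spatial information against the
  within-lap circular-shift null is slightly conservative-to-nominal
  (the null SI distribution is right-skewed); at the study scale (500
  cells, 1000 shifts, 20 laps, 1 Hz observers) the measured false-positive
  rate is ~5–7%, within binomial error of nominal — consistent with the
  very low empirical rates the z > 1.645 rule produces on real data.

## Problem sizes

The test suite simulates reduced days (60 cells, 10 laps and 10 rotation
events per session) for module tests, and full-census days (45 cells, 19
laps, 19 events, Pre- and Post-box) for the parameter-recovery checks: 20
replicate days per overlap level f ∈ {0, 0.3, 0.6}, with 1000 per-sequence
shuffles and 200 template sets. Null calibrations use 100–150 simulated
cells at 200–300 shuffles in the tests and 500 cells at 1000 shuffles in
`scripts/acceptance.R`. The complete suite runs in roughly five minutes on
one CPU; the acceptance script in under ten.

## Known limitations

* The generator's tuning shapes and rates are conventional stand-ins; PDI
  magnitudes and match rates on synthetic days are not calibrated to match
  the effect sizes of any real dataset, only their direction and null
  behaviour.
* Rotation-event detection assumes tracking-quality head direction (≥95%
  of samples defined) and tolerates only brief (<30°) counter-rotations;
  grooming/rearing interruptions must be supplied as an exclusion mask.
* The rest-box variant of rotation detection (rotations away from an
  opening-free start) is not separately implemented; the same detector with
  a caller-chosen reference direction covers it.
* Group-level inference is per condition/day as in the source design;
  across-animal mixed-model comparisons are out of scope, and the pipeline
  reports descriptive summaries only.
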