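---
title: "Indexing mental workload from EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing mental workload from EEG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Two spectral signatures of mental workload are among the most replicated
findings in EEG research: frontal midline theta power (4--8 Hz) rises with
cognitive demand, and parietal alpha power (8--12 Hz) falls.  The Dual
Frequency Head Map (DFHM) approach turns these two signatures into a
person-independent workload monitor in four steps:

1. **Conditioning.**  The multichannel EEG (25 electrodes in the 10--20
   layout, 500 Hz, Cz reference) is bandpass filtered (0.5--40 Hz,
   linear-phase FIR of order 100), cleaned of artifacts by Infomax ICA
   component rejection, spatially sharpened with a Hjorth-style surface
   Laplacian (each channel minus the unweighted mean of its up-to-eight
   neighbours), and transformed to average reference.  The order of these
   stages is fixed; `preprocess_recording()` applies them in that order and
   tags the result.
2. **Personalized spectral features.**  The signal is cut into 1-s segments
   overlapping by 0.5 s.  Per segment and electrode, theta and alpha band
   power are computed from the rectangular-window periodogram (1 Hz bins at
   500 Hz).  Band powers are z-scored per subject, electrode and scenario
   against the mean and standard deviation of the segments of the first
   minute of that scenario.  This within-scenario standardization is what
   makes the features comparable across people and days: every subject is
   measured against their own quiet settle-in period.  The DFHM of a segment
   is the vector of z-scored theta power at the ten frontal electrodes
   followed by z-scored alpha power at the ten parietal electrodes.
3. **Classification.**  A support-vector machine (one-vs-one multiclass)
   maps each DFHM to a workload class: 1 (low), 2 (moderate) or 3 (high),
   yielding one class every 0.5 s.
4. **The workload index.**  A 30-s moving window (60 class values) is
   summed; subtracting the minimum possible sum (60, all low) and dividing
   by the maximum adjusted sum (120, all high) gives

   index(t) = (sum of the last 60 class values - 60) / 120 x 100,

   a 0--100 score updated every 0.5 s that reads as the percentage position
   between all-low and all-high workload within the window.  The first
   29.5 s of a recording have no full window and are reported as undefined
   (`NA`), as is any window touching a missing class value; we chose
   undefined over zero because the defining sum does not exist there.

## Validation statistics

The surrounding study toolkit reproduces the validation harness of a
simulated arrival-management experiment with 2 x 4 within-subject
conditions (priority-flight request yes/no x 25/35/45/55 aircraft per
hour):

* **ISA workload sensitivity** (`fit_isa_sensitivity()`): each subject's
  5-point ISA ratings, collected every 5 min, are regressed on traffic
  load.  Both axes are normalized by their scale means -- the load-scale
  mean (25+55)/2 = 40 and the subject's own ISA-scale mean taken from the
  fitted line, (yhat(25)+yhat(55))/2 -- giving the dimensionless sensitivity
  s_a with intercept s_b = 1 - s_a (an exact identity).  A median split on
  s_a labels subjects workload-sensitive (at or above the median) or not.
* **Reliability correlations** (`same_load_correlation()`): Pearson r
  between the per-subject first-5-min index means of the two scenarios
  sharing a traffic load.
* **Repeated-measures ANOVA** (`rm_anova_2way()`): textbook within-subject
  sums of squares, each effect tested against its effect-by-subject error;
  Mauchly's test on the orthonormal contrast covariances, with the
  Greenhouse-Geisser epsilon applied to the degrees of freedom when
  sphericity is rejected at 0.05; partial eta squared reported per effect.
  `mixed_anova()` adds a between-subject cluster factor (split-plot design,
  computed on contrast scores, type-III main effects under unequal group
  sizes).  Both implementations are cross-checked against `car::Anova()` in
  the test suite.
* **ATC performance** (`route_distance()`, `detect_separation_losses()`,
  `paired_wilcoxon()`): planar polyline length between initial contact and
  landing; losses of separation as maximal contiguous intervals where the
  lateral wake-vortex minimum (3 NM medium-medium, 5 NM medium behind
  heavy; other pairs from ICAO radar values, configurable) and the 1,000 ft
  vertical minimum are breached simultaneously, evaluated on the union of
  the two time grids; and the Wilcoxon signed-rank test in its normal
  approximation with tie correction and a 0.5 continuity correction, with
  Bonferroni-multiplied p and effect size r = Z / sqrt(N).

## The synthetic-data generator

The study's human data are access-restricted, so the package ships a
generator (`generate_eeg()`, `generate_isa()`, `generate_trajectories()`)
whose defaults define the simulated study conditions:

* **EEG.**  25 channels at 500 Hz: an AR(1) background (sd 6 uV) plus
  per-channel theta (~6 Hz) and alpha (~10 Hz) oscillators whose amplitudes
  wax and wane slowly (log-normal modulation, sd 0.12, ~1.5 s correlation).
  Theta is frontally weighted and its amplitude rises on task by a
  load-independent engagement trait (`task_gain`, cohort mean 0.15, sd
  0.15) plus a per-load-level gain (`theta_gain`, mean 0.05, sd 0.025);
  alpha is parietally weighted and falls on task by half the engagement
  trait plus a per-level loss (`alpha_loss`, mean 0.04, sd 0.02) -- the
  shared trait gives the paired same-load scenarios their subject-level
  test-retest correlation, while the per-level terms carry the load
  effect.  The load effect is gated by an envelope that is zero during the
  first minute and ramps to one by 90 s, so the z-score baseline reflects
  the settle-in period while traffic builds up -- without this ramp the
  within-scenario standardization would remove the load effect entirely.
  Baseline Fz theta power lands in the published 16--27 uV^2 range for face
  validity; the task-period effects are deliberately stronger than the
  published cohort means so that desk-scale recovery tests are well-posed.
  Optional blink artifacts (frontally weighted 0.3--0.5 s half-sines,
  Poisson arrivals) exercise the ICA rejection policy.  A priority event
  adds a transient theta boost for 150 s after the request and writes a
  `PRIORITY_REQUEST` trigger.
* **ISA ratings.**  Every 300 s; expected rating linear in load with the
  subject's true normalized sensitivity mapped around a mid-scale rating of
  3 at the 40 ac/h scale mean; Gaussian noise (sd 0.5), rounded to integers
  and clipped to 1--5.
* **Trajectories.**  Arrivals at the design's rate along a gentle C-shaped
  arc (18-degree turns every 4 NM, ~46 NM contact to landing at 180 kt).
  The gentle curvature keeps the lateral distance between in-trail aircraft
  essentially equal to their along-track spacing (minimum chord 3.23 NM at
  the tightest 55 ac/h spacing), so the nominal stream never breaches the
  3 NM minimum and every detected loss of separation is a planted one.
  A priority request reroutes the aircraft still on its early arc directly
  to the final-approach fix, strictly shortening its route.  Planted
  violations are extra aircraft pairs placed away from the stream, each
  engineered to dip to 2.8 NM at under 1,000 ft for one contiguous
  interval.  The generator does not model post-shortcut resequencing, so
  planted-count recovery is asserted on scenarios without a priority event.

What the generator does *not* emulate: volume conduction and realistic
source topographies (each electrode has an independent oscillator phase, a
deliberate choice so the Laplacian does not cancel the planted band
effects), eye/muscle artifact spectra beyond stylized blinks, non-stationary
drifts, electrode impedance changes, or any behavioural coupling between
EEG and ISA beyond the shared load level.  Passing the end-to-end tests
therefore shows that the pipeline recovers the statistical structure it
assumes, not that it would perform identically on human data.

## Classifier training

The original laboratory-trained SVM weights are not available; the package
retrains instead.  Two routes exist: `generate_training_dfhm()` draws
labelled Gaussian blobs in z-space (used for classifier unit tests), and
`synthesize_training_data()` pushes calibration scenarios at the four loads
through the full pipeline and labels post-baseline segments by load level
(25 to low, 35/45 to moderate, 55 to high), which produces training data on
exactly the feature scale seen at prediction time.  The default kernel is
RBF with a 5-fold stratified cross-validated grid over (C, gamma) and
inverse-frequency class weights; a linear kernel is available via the
training config.  Prediction always runs through the package's own
one-vs-one decision code on arrays extracted at training time, so the JSON
model archive (numbers plus metadata, never code) reproduces predictions
exactly after reloading.

## Numerical choices

* Half-open frequency bands [4, 8) and [8, 12) Hz avoid double-counting the
  8 Hz bin; the upper band edge is inclusive only at the Nyquist frequency
  so the full band satisfies the Parseval identity.
* The baseline uses the segments fully contained in the first 60 s (start
  time <= 59 s: 119 segments), regardless of residual artifacts; a zero
  baseline standard deviation on any electrode is an explicit error.
* Zero-phase filtering is implemented as causal FIR convolution followed by
  group-delay compensation (order/2 samples); edge transients at the very
  start and end of a recording are not reflected away.
* The extended Infomax variant (kurtosis-switching nonlinearity) is used
  because EEG mixtures contain both super-Gaussian artifacts and
  sub-Gaussian oscillations; plain logistic Infomax cannot separate the
  latter.  The learning rate anneals and the fit restarts at half rate on
  numerical blow-up; everything is deterministic given the seed.
* The automatic ICA rejection policy scores components by low-frequency
  (< 3 Hz) power fraction, frontal mixing-weight concentration and
  kurtosis; a component is rejected when it is both slow and frontal (blink
  topography) or extremely heavy-tailed.  Manual index lists are supported
  and take precedence.
* The montage neighbour map uses mutual 8-nearest neighbours (symmetric by
  construction) with a cutoff of 1.5x the median k-nearest-neighbour
  distance so border electrodes do not pair across the scalp edge.
* Wilcoxon: ties receive average ranks with the matching variance
  correction; zero differences are dropped; the continuity-corrected normal
  approximation stays within 0.02 of the exhaustive exact distribution for
  all n <= 10 (verified against full enumeration in the tests).
* Slot intervals are half-open [start, start + duration); times are seconds
  from recording start with 0-based sample indexing.

## Problem sizes in the test suite

Cohort-level simulations run at desk scale, chosen so the suite completes
comfortably on one CPU: 300-s scenarios (baseline minute + 30-s ramp +
3.5 min on task) instead of the study's 20--25 min, cohorts of 20--21
subjects as in the study, calibration from 2 synthetic subjects, and the
ANOVA permutation null with 1,000 replicates.  ISA recovery uses the full
8-scenario design at 25 min (5 ratings per scenario).  These sizes are the
package's simulation design, stated here so results are interpreted at the
scale they were computed.

## Known limitations

* The EDF writer produces a single large data record and plain EDF (events
  travel in a sidecar CSV); EDF+ annotation channels are not parsed.
* The ISA sensitivity estimate has an irreducible standard error of about
  0.1 under the study's own design (40 integer ratings, noise sd 0.5),
  which limits how tightly a per-subject recovery can be asserted; the
  median-split cluster assignment is much more stable (>= 90% recovery).
* The mixed ANOVA assumes complete within-subject tables; missing cells are
  an error, never imputed.
* Real-time/streaming operation and vendor acquisition formats are out of
  scope.
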