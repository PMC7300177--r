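---
title: "Classifying running experience from foot-ankle stance mechanics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying running experience from foot-ankle stance mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(runexp)
```

## The problem

Long-distance runners adapt their foot-ankle mechanics as they accumulate
deliberate practice. `runexp` implements a complete pipeline for asking
whether those adaptations are large and consistent enough to *classify* a
runner's experience level from stance-phase biomechanics alone:

1. **Experience scoring.** A runner's practice structure (weekly training
   frequency and volume, years of practice, race count) is scored 0-10 by a
   two-stage fuzzy decision-support system, and the score `x` is thresholded
   into three classes: less experienced (`x < 5`), moderately experienced
   (`5 <= x <= 7`), experienced (`x > 7`).
2. **Signal preprocessing.** Vertical and anteroposterior ground reaction
   forces (GRF, 1000 Hz) and ten kinematic/kinetic channels (eight
   foot-ankle joint angles plus ankle sagittal moment and power, 200 Hz) are
   low-pass filtered with a zero-lag 4th-order Butterworth filter (corners
   100 Hz and 15 Hz respectively), stance phases are detected with a 10 N
   threshold on the vertical force, each stance is time-normalized to 101
   points (0-100% of stance), and waveforms are averaged over 10 consecutive
   stances per subject.
3. **Features.** The averaged waveforms form a subjects x 1010 matrix
   (10 channels x 101 points), standardized column-wise and decomposed by
   PCA; with *n* subjects this yields *n* - 1 components. The PC scores are
   joined by nine body-weight-normalized discrete GRF variables (two
   vertical peaks, loading rate, two vertical impulses, two anteroposterior
   peaks, braking and propulsion impulses), standardized the same way. A
   78-subject cohort therefore has 77 + 9 = 86 candidate features.
4. **Classification.** For each class, a one-vs-all linear soft-margin SVM
   is built by greedy sequential forward selection: at each step the
   candidate that maximizes the pooled 10-fold cross-validated Matthews
   correlation coefficient (MCC) is added. The search is repeated over the
   C grid (0.1, 1, 10, 100, 1000) and the best final MCC wins. A critical
   binomial test provides the minimum accuracy that a no-information
   classifier would be unlikely (p < 0.05, exact tail) to reach.
5. **Interpretation.** Waveforms are reconstructed from the selected
   components; Cohen's d between the positive class and the rest is
   computed at each stance point, and maximal runs with at least a medium
   effect (d >= 0.5) are flagged per channel. Squared correlations between
   a component's scores and the waveform columns, summed per channel,
   attribute the component to joints and planes.

No public motion-capture data accompanies the design this package
follows, so a first-class synthetic cohort generator reproduces the
reference study conditions end-to-end and doubles as the test bed.

## The synthetic cohort generator

`generate_cohort(cohort_config())` produces three experience groups of
24/23/31 runners (the reference cohort sizes), each with metadata and raw trials at
the native sampling rates.

**Waveform model.** No raw reference waveforms are available, only
group-level discrete statistics and qualitative angle patterns, so the
stance templates are statistical stand-ins: smooth combinations of
half-period sinusoids and Gaussian bumps per channel with physiologically
plausible magnitudes. The vertical GRF template is a main support hump
(about 2.2 BW at mid-stance) plus an impact transient (local maximum of
about 1.1 BW near 15% of stance); the anteroposterior template is a single
braking-then-propulsion sinusoid peaking near ±0.23 BW with exactly one
zero crossing. These match the reference group means of the nine discrete
GRF variables to within their between-subject spreads. Stance durations
are drawn uniformly from 0.25-0.35 s and flight phases from 0.10-0.15 s,
typical of recreational rearfoot running; no reference values exist for
either.

**Planted group effects.** The experience effect is an additive stance-wide
shift of the first-metatarsophalangeal (Met-Hal) and calcaneus-metatarsal
(Cal-Met) sagittal angles — the two channels that carry the
discriminating pattern in the reference study: less experienced runners get `+met_hal_offset_deg` (more toe
dorsiflexion) and `-cal_met_offset_deg` (more arch plantarflexion),
experienced runners the sign-flipped shifts, the moderate group neither.
Defaults are 5° and 4° against a 3° between-subject SD — separations in the
range that reference group-mean curves display. Because three collinear
group means cannot be isolated by a linear classifier, a cohort in which
the moderate group differs in *nothing* would make moderate-vs-all
structurally unclassifiable, contradicting the reference conditions this
generator emulates (all three groups were classifiable, the moderate one
through subtle high-order components only). The moderate group therefore
carries its own low-amplitude (2.5°) mid-stance Gaussian deviation on the
ankle frontal and Cal-Met transverse channels. This keeps the qualitative
signature intact: the moderate model selects only low-variance components
rather than the dominant between-group direction.

**Noise model.** Between-subject and step-to-step deviations are smooth
random curves `sqrt(0.5) z0 + sqrt(0.5)(z1 sin(pi s) + z2 cos(pi s))`,
which have *exactly* unit pointwise SD at every stance fraction `s` — so
`subject_sd_deg` and `step_sd_deg` are calibrated parameters, not nominal
ones. Moment and power channels scale these SDs down to match their units.
GRF noise adds a smooth tapered curve of SD `grf_noise_bw` (body weights)
inside stance plus per-step relative jitter of the template amplitudes;
flight phases stay identically zero so the 10 N threshold semantics are
exact. Metadata are drawn from truncated normals centred on the reference
group means with spreads tightened so that the fuzzy scorer reproduces the
intended label for well over 90% of draws (95.8/99.3/98.5% per group in a
3000-draw check).

**What the generator does not emulate:** real foot-ankle coupling
(channels are generated independently apart from the planted effects),
fatigue drift across steps, heteroscedastic impact noise, marker artifacts
and soft-tissue wobble, or speed-dependent waveform shape changes. Passing
recovery tests therefore demonstrates that the *pipeline* recovers planted
effects of realistic size under realistic noise — not that real cohorts
carry such effects.

## The fuzzy experience scorer

The original decision-support system's membership functions and rule
tables are unpublished; this package ships a documented default rule base
(YAML, `inst/extdata/fuzzy_rules.yaml`) with the reference system's
linguistic levels (frequency/volume: too low, low, medium, high; quality: very
bad to very good; competitions: few, medium, many; practice time: very
short to long). Membership functions are trapezoids forming sum-to-one
(Ruspini) partitions with breakpoints anchored to the reference group
means — e.g. "high" weekly volume centred at 55 km/week — so that the group
means land in their score bands (group-mean inputs score 3.6 / 5.7 /
7.7). Rule consequents follow a weighted additive index (volume and quality
carry double weight), making both rule tables monotone. Users can swap in
their own rule base; no numeric equivalence with the original system is
claimed, only structural and threshold fidelity.

**Inference engine.** The classic Mamdani combination — min conjunction,
max aggregation, centroid of the clipped union — turns out to be
measurably non-monotone near membership breakpoints (score drops of up to
~0.1 on the 0-10 scale in random sweeps), because the centroid of a
clipped *asymmetric* trapezoid migrates as the clip level changes. That
conflicts with the basic contract that more training can never lower an
experience score. The default engine is therefore product conjunction, sum
aggregation and the center-average defuzzifier (each rule contributes its
consequent's centroid, weighted by firing strength). With sum-to-one input
partitions this reduces to multilinear interpolation of the consequent
centroids, which is provably monotone whenever the rule table is monotone
— verified by a 2000-pair random sweep with zero violations. The classic
engine remains available as `method = "mamdani"`; the two agree to a few
tenths of a point everywhere.

## Numerical choices

* **"Zero-lag fourth-order" filtering** is realized as a forward-backward
  pass of a 2nd-order Butterworth design (net order 4, phase cancelled) —
  the dominant biomechanics convention; the alternative reading (dual-pass
  4th order, net 8th) was rejected. The signal is extended by odd
  reflection before the dual pass because a zero-padded `filtfilt` leaves
  DC edge transients; with reflection, constants pass through to 1e-9 and
  the corner gain matches the analytic |H|² = 1/2.
* **Stance intervals** are half-open `[start, end)` in 1-based sample
  indices (R convention; the contact sample is included, the first
  sub-threshold sample is not). Incomplete edge stances are discarded.
  Stance boundaries are quantized to the 1 kHz grid, so two nominally
  identical stances can differ by one sample — tests treat that as part of
  the interpolation tolerance.
* **Vertical impulse split.** The operational definition used is the
  valley after the first peak (`split = "valley"`); the alternative
  mid-stance split at the second peak is available as
  `split = "second_peak"` since the narrative description of the impulses
  admits that reading.
* **Loading rate** is the secant slope between the first crossings of 20%
  and 80% of the first-peak magnitude, crossing times linearly
  interpolated; units are BW/s (forces are body-weight normalized before
  extraction, g = 9.81 m/s²).
* **Stances without an impact transient** degrade gracefully: first peak
  and valley both fall back to the most concave-down point of the rising
  limb and a degeneracy flag is set.
* **Discrete GRF aggregation**: variables are extracted per stance and the
  nine values averaged (`aggregation = "per_stance"`); computing them once
  on the time-normalized mean curve is exposed as `"mean_curve"`. Whether
  the reference analysis averaged before or after extraction is not
  recoverable; the two agree to a few percent on clean data.
* **PCA** is computed by SVD of the standardized matrix; component signs
  are fixed so each component's largest-magnitude loading is positive
  (signs affect nothing downstream except reported loadings).
  Zero-variance columns are an error by default, with an optional
  `sd_floor`. Standardization and PCA are fitted on the full sample before
  cross-validation, replicating the reference analysis order; this leaks
  distributional information into the folds and makes all CV numbers
  optimistic, which is acknowledged rather than silently corrected.
* **Forward selection** stops after `stall_patience = 1` non-improving
  round (no stopping rule is prescribed by the reference design) or at
  `max_features`, and
  returns the best-scoring prefix. When MCC is undefined for every
  candidate (a zero confusion-matrix marginal — no predicted case in one
  class), the step falls back to the candidate with the largest univariate
  Cohen's d, ties broken by CV accuracy, then candidate order. Equal MCCs
  break toward higher accuracy then lower feature index; equal final MCCs
  across the C grid break toward smaller C (less overfit-prone). Fold
  assignment is seeded and recorded: the original fold partition is
  unknowable, so cross-validated numbers are reproducible only under this
  package's seeds.
* **Candidate features are rescaled inside each SVM training fold**
  (libsvm's standard internal scaling): leading and trailing PC scores
  span orders of magnitude and the solver converges poorly without it.
* **The binomial floor** uses the exact upper tail: the smallest `k` with
  `P(X >= k | n, p0) < 0.05`, `p0` being the majority-class share of the
  one-vs-all split (the no-information rate). The strict/non-strict
  convention is switchable. Under this convention the reference
  experienced-vs-all floor (70.5% = 55/78) is reproduced exactly; no
  single convention reproduces all three reference floors, whose exact
  derivation is ambiguous.
* **"Medium effect"** is fixed at Cohen's conventional d = 0.5
  (configurable); effect profiles are computed on the waveforms
  reconstructed from the selected components, with the raw-waveform
  variant available for comparison.

## Problem sizes used in the shipped checks

The test suite exercises full-size cohorts (78 subjects, 10 stances at
native rates) for the recovery checks, three zero-offset cohorts for the
null check with a reduced C grid (1, 100) and a feature cap of 8, and
smaller cohorts (12-24 subjects, reduced grids) for the per-module
behavioral tests. These sizes keep each check's Monte-Carlo error small
relative to its assertion band while the whole suite stays interactive.

## Known limitations

* The fuzzy rule base is an artifact default, not the original system;
  absolute scores should not be compared across rule bases.
* No nested cross-validation: feature selection and performance
  evaluation share one 10-fold partition, following the reference
  design. The pooled CV
  metrics are therefore optimistic — on label-free (zero-offset) cohorts
  the most balanced one-vs-all split can report a cross-validated
  accuracy noticeably above its no-information rate purely through
  selection over 86 candidates. The shipped null-recovery check
  quantifies this; treat reported CV numbers as upper bounds on
  generalization.
* The generator's channels are conditionally independent given the group;
  real foot-ankle channels are mechanically coupled, so real-data PC
  structure will differ.
* No statistical-parametric-mapping inference on the waveform domain;
  effect-size profiles are descriptive.
* The pipeline is strictly one-vs-all binary; no multi-class averaging of
  metrics is provided.

## A worked run

```{r}
library(runexp)
cfg <- pipeline_config(
  cohort = cohort_config(seed = 11),
  selection = selection_config(seed = 11),
  out_dir = "runexp_demo")
manifest <- run_pipeline(cfg)
str(manifest$reports)
```

Each report records the selected features, the winning C, the pooled
confusion matrix, MCC/accuracy/precision/recall/F1, and the binomial
accuracy floor; the interpretation directory holds per-channel effect
profiles and the flagged medium-effect regions.
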