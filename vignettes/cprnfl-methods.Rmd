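---
title: "Measuring circumpapillary RNFL thickness from hand-held OCT rasters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring circumpapillary RNFL thickness from hand-held OCT rasters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprnfl)
```

## Overview

Hand-held OCT acquires rectangular raster volumes rather than the
fixed-radius ring scans of table-mounted devices, because awake infants
cannot hold fixation. The circumpapillary RNFL (cpRNFL) profile therefore
has to be *resampled* from a segmented thickness map, and — because the
infant eye grows — at radii expressed in visual angle rather than
millimetres. This package implements that resampling geometry, the
quadrant-level measurement bookkeeping, the reliability statistics used to
validate such a protocol, feasibility accounting, and a synthetic phantom
that generates cohorts with known variance components so every estimator in
the package can be checked against ground truth.

## Coordinate and angle conventions

* **Scan frame.** x runs along the A-scan (fast) axis, y along the B-scan
  (slow) axis, origin at the top-left corner; the centre of 0-based pixel
  (row j, col i) is at ((i + 0.5)·dx, (j + 0.5)·dy) mm, with dx =
  width/n_ascans and dy = height/n_bscans. The default protocol (12 × 8 mm,
  600 × 80) gives the anisotropic spacings dx = 20 µm, dy = 100 µm.
* **TSNIT frame.** θ = 0° temporal, 90° superior, 180° nasal, 270° inferior
  for right-eye (OD) anatomy, superior pointing "up" (decreasing y).
  Left-eye (OS) scans are mirrored about the vertical axis *at sampling
  time*, so every reported angle is anatomical and downstream code never
  branches on laterality. No convention is universal here; TSNIT is the one
  used by circumpapillary analysis software generally and is fixed
  throughout.
* **Calibration.** 288 µm of retina per degree of visual angle (the
  hand-held adult-eye setting), so the 6° ring sits at 1.728 ≈ 1.73 mm.
  The value is a parameter (`angle_calibration()`), not a constant, since
  other devices print other factors.

## Resampling

Rings are sampled at `n_theta` evenly spaced anatomical angles (default
360, i.e. 1° steps) by bilinear interpolation *in physical coordinates*, so
the anisotropic pixel spacing is honoured. Bilinear was chosen as the
minimal-assumption standard; it is exact on affine fields — which yields
two strong tests: a ring mean over a full circle of an affine field equals
the field's value at the centre, and node positions reproduce node values
exactly. Nearest-neighbour or bicubic variants were considered and
rejected: the former is not exact on affine fields and the latter requires
boundary policies that are unverifiable against closed forms.

A sample is invalid when its position leaves the hull of pixel centres
(there is no extrapolation) or when any interpolation node with non-zero
weight is invalid — invalidity is deliberately *contagious* at mask edges
rather than silently interpolated across.

Annuli are sampled on an `n_r × n_theta` polar grid (default `n_r = 8`
equal-width shells at midpoint radii). Each sample carries weight
proportional to its radius — the polar area element — so the weighted mean
is the area average; with the field T = r the annulus mean converges to the
analytic centroid radius (2/3)·(r₂³−r₁³)/(r₂²−r₁²), which the tests verify
at 5°–6° (5.5151…). Whether uniform or area weighting was used by any given
clinical software is usually unstated; area weighting is the default and
uniform weighting is a switch (set every weight equal).

The `theta_offset_deg` argument corrects a known in-plane rotation of the
scan frame: positions are sampled at θ + offset while reported angles stay
at θ, so rotating the underlying field and the offset together leaves
quadrant means unchanged (tested to < 0.5 µm on noiseless phantoms). This
is also the hook for fovea-to-disc-axis referencing, which is otherwise out
of scope.

At default resolution the discretisation error on smooth phantom fields is
below 0.1 µm; ring samples agree with direct evaluation of the generating
field to < 0.5 µm on the default grid, dominated by bilinear curvature
error across the 100 µm B-scan spacing.

## Quadrants

Two sector schemes are built in. `equal90` (default): four 90° sectors
centred on 0/90/180/270. `gdx`: the GDx Nerve Fiber Analyzer proportions —
temporal 50°, superior 120°, nasal 70°, inferior 120°. The GDx boundary
angles are not printed in the protocol literature this package follows;
`equal90` is the default because it is fully self-evident and auditable,
and custom boundaries can be supplied. Every summary row records which
scheme produced it (via the config hash in written outputs).

## From scans to the measurement table

`summarize_scan()` reduces each (location × quadrant) cell to the
(area-)weighted mean over valid samples, with a `captured` flag: a quadrant
is captured when at least one sample is valid *and* the valid fraction
reaches `capture_threshold` (default 0.9). "Captured" is a qualitative
judgement in clinical practice and is never quantified in print; 0.9
tolerates edge clipping from a decentred window while rejecting
half-missing sectors. The threshold is config-exposed and reported.

Pair inclusion follows the clinical rule: a subject enters the reliability
analysis at a location when **at least three quadrants are captured in both
arms — the same three**. The `Average` measure is the unweighted mean of
the four quadrant means (not the mean over all ring samples — it matches
the row structure of clinical reliability tables; the sample-level mean is
a switch), and an Average pair exists only when all four quadrants are
common. Inclusion is recomputed per location, so a subject can be included
at 6° but excluded at 4°; per-scan-pair inclusion is available by
summarising only one location.

## Reliability statistics

* **ICC.** The headline form is ICC(A,1): two-way, absolute agreement,
  single measures, computed from the two-way ANOVA mean squares by direct
  summation, with F-based 95% limits (Satterthwaite degrees of freedom).
  Neither test–retest nor inter-assessor designs should forgive a
  systematic offset between arms, hence absolute agreement; the consistency
  form ICC(C,1) is selectable and reported alongside in verbose use.
  Single-measures is the headline because the clinical decision uses one
  scan, not the average of two. Zero total variance makes the ICC
  undefined; it is returned as a flagged degenerate case (`NA`), never as
  1.0.
* **CoV.** Within-subject SD per Bland, S_w = √(Σdᵢ²/2n) — the
  root-mean-square of the per-pair SDs — as a percentage of the grand mean.
  The common alternative (mean of per-pair CoVs) is a documented switch;
  the two differ when thickness and variability correlate across subjects.
* **Bias.** The arm effect of the balanced two-way additive fixed-effect
  model value = µ + arm + subject, fitted by least squares. With two arms
  and complete pairs this is *identical* to the paired t-test (the tests
  assert equality to 10⁻¹⁰), which is why a fuller mixed-model machinery is
  not carried: with one eye per subject the random-effects model collapses
  to this fixed-effects fit. Zero-variance differences are flagged
  degenerate (zero-width CI; p of 0 or 1).
* **Bland–Altman.** Bias, 1.96·SD limits of agreement, and the OLS trend of
  difference on mean with its p-value; under additive-only noise the trend
  p-values are null-uniform (verified by Monte-Carlo in the tests).
* No multiple-testing correction is applied across the 25 table cells
  (quadrants + Average × 5 locations); raw p-values are reported, as is
  conventional for descriptive reliability tables.

## The phantom

The generator exists so that the reliability machinery can be validated
against *known* population values; it is deliberately a statistical
phantom, not an optical one.

**Ground truth.** T(r, θ) = g · [base(θ) + peaks(θ)] · decay(r), zero
inside the optic disc (default radius 0.95°):

* base(θ) ramps between the temporal level at θ = 0° and the nasal level at
  180° with a cosine;
* peaks(θ) are raised-cosine bumps of half-width 60° centred at 90° and
  270° — the superior/inferior fiber bundles of the double-hump TSNIT
  profile. No published functional form exists for the angular profile;
  raised cosines are smooth, compactly supported and integrable in closed
  form.
* decay(r) = 1/(1 + d·(r − 4°)) with d = 0.05/degree, evaluated with r
  clamped at the disc edge — gentle thinning with eccentricity;
* g ∈ (0, 1] is a global glaucomatous thinning factor.

The four default amplitudes (base temporal 65.63, base nasal 70.52, peak
superior 74.65, peak inferior 72.96 µm) were obtained by solving the linear
4 × 4 system mapping them to the four equal90 quadrant means on the 6°
ring, so the control phantom reproduces typical control values at that
eccentricity — temporal 61, nasal 65, superior 106, inferior 105 µm —
within 2 µm, with the characteristic ordering inferior ≈ superior > nasal >
temporal.

**Noise model.** Additive, at three granularities matching the quadrant
-level analysis: a subject offset (SD 12 µm — between-subject spread of the
order seen in control cohorts), a scan offset per acquisition (SD 4 µm),
an assessor offset per segmentation (SD 2 µm), plus per-pixel noise of SD
`sigma_pixel/quality` (5 µm at quality 1). True magnitudes of these
components are not published for any hand-held cohort; the defaults were
chosen once to bracket the ICC ranges such studies print (test–retest
around 0.9, inter-assessor around 0.97) and are not tuned thereafter.
Quality indices are proprietary contrast scores; the only property used
here is monotone ranking, and 1/quality is the simplest monotone noise law.
`pixel_noise_ref_deg` optionally scales pixel noise as ref/r, emulating the
empirical pattern that measurements further from the disc are cleaner.
Offsets are spatially constant by design: the analysis consumes quadrant
means, and spatially varying segmentation error is not identifiable at that
granularity. Negative thickness is clamped to zero for physical
plausibility; pixels inside the disc are zero and masked.

**Designs.** `test_retest`: scans S1 (high quality) and S2 (low quality)
per subject with independent scan offsets; quadrant loss (probability 0.12
per scan, matching roughly 6 of 51 second scans losing one quadrant) can
affect only S2 — the examiner re-acquires until the first scan is complete.
`interassessor`: one underlying acquisition segmented twice; the two arms
share subject, scan *and pixel* noise and differ only by assessor offsets.

**Reproducibility.** Every random draw comes from a stream keyed by
`(seed, role, subject, scan, assessor)` through a 32-bit FNV-1a hash, so
cohorts are bit-reproducible and *extensible*: adding subjects never
reshuffles existing ones.

**What the phantom does not emulate** — and hence what passing tests do not
show about real data: speckle and shadowing, vessel artefacts, axial motion
and refixation warp, segmentation failure modes beyond additive offsets and
whole-quadrant loss, spatially correlated error, and axial-length-dependent
scaling. Tests passing on the phantom certify the estimators and the
geometry, not the scanner.

## Estimator calibration

Two simulation studies, run by the test suite and the acceptance script:

* **ICC recovery.** For population ICC = σ_subject²/(σ_subject² + σ_scan²)
  set to 0.6, 0.75 and 0.9, the full pipeline (render → ring sampling →
  quadrant summaries → pairing → ICC) is run on 500 independent 51-subject
  cohorts; the mean estimate must land within ±0.02 of the population value
  and the 95% CI must cover it between 92% and 98% of the time. These runs
  use a coarse 36 × 24 raster and 6°-ring sampling at 60 angles: the truth
  field is smooth, so the coarse grid shifts quadrant means identically for
  every subject and cancels in the ICC; this is a problem-size choice for
  the Monte-Carlo study, stated here once.
* **Eccentricity pattern.** With pixel noise ∝ 1/r (SD 50 µm referenced to
  4°) over a 51-subject cohort, the estimated ICC increases from the 4° to
  the 6° ring, reproducing the qualitative pattern that reliability
  improves with distance from the disc.

## Degenerate inputs and numerical notes

* ICC with zero total variance → flagged `NA`, never 1. ICC at the upper
  boundary (MSE = 0) → exactly 1 with a collapsed CI.
* Paired differences with zero variance → degenerate bias result (p = 0 or
  1, zero-width CI) rather than a NaN from a t-distribution.
* Bland–Altman trend on constant means → slope `NA` (no regressor
  variance).
* Zero feasibility denominators → `NaN` with a warning, not an error, so a
  partial table still prints.
* Report rounding is half-away-from-zero at one decimal (R's `round()`
  banker's rounding does not match printed clinical tables); full precision
  is kept internally and only the report layer rounds.
* t and F quantiles come from `stats::qt`/`stats::qf` in double precision;
  all CIs are two-sided 95%.

## Feasibility accounting

Attempt/exclusion counts must satisfy additivity (possible + Σ excluded =
attempted; violations are errors, not warnings). Published success rates
are printed as percentages; `reconstruct_counts()` inverts them to integer
eye counts (eyes are integers, and pooled totals are only consistent with
the per-group cells under integer pooling), reporting the rounding residual
as a diagnostic. Pooled rates sum reconstructed counts and denominators
across groups before dividing.

## Known limitations

* The ONH centre comes from metadata; automatic disc detection is out of
  scope (the acquisition protocol centres the window manually).
* One eye per subject is assumed; inter-eye correlation is not modelled.
* The visual-angle calibration is global, not per-subject axial-length
  corrected — the premise of working in visual angle is that this is
  largely unnecessary, and the calibration object is the extension point if
  it is not.
* Inter-device reliability is not implemented: it requires paired data from
  two instruments, for which no public reference exists.
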