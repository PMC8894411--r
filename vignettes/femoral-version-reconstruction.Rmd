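---
title: "Reconstructing femoral component version from biplanar angles: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing femoral component version from biplanar angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femver)
library(dplyr)
```

## The geometric model

The orientation of the neck of a femoral THA component is a single direction
in space — a unit vector $\mathbf{a} = (x, y, z)$ with $x$ medio-lateral
(the neck points medially, so $x > 0$), $y$ antero-posterior (anterior
positive) and $z$ vertical (superior positive). Radiographic views measure
its three orthogonal-plane projections:

* **Coronal inclination** $\mathrm{CI} = \operatorname{atan2}(z, x)$, the
  angle of the AP-view projection against the horizontal (low = varus,
  high = valgus), constrained to $(0^\circ, 90^\circ)$;
* **Sagittal inclination** $\mathrm{SI} = \operatorname{atan2}(y, z)$, the
  lateral-view projection against the vertical (positive =
  ante-inclination), in $(-90^\circ, 90^\circ)$;
* **Transverse version** $\mathrm{TV} = \operatorname{atan2}(y, x)$, the
  axial-view projection against the horizontal (positive = anteversion,
  negative = retroversion), in $(-90^\circ, 90^\circ)$.

With this convention $\tan\mathrm{CI} = z/x$, $\tan\mathrm{SI} = y/z$ and
$\tan\mathrm{TV} = y/x$, so the three angles are locked together by

$$\tan(\mathrm{TV}) = \tan(\mathrm{SI}) \cdot \tan(\mathrm{CI}),$$

and any two angles determine the third:

$$\mathrm{TV} = \arctan\!\big(\tan\mathrm{SI}\,\tan\mathrm{CI}\big), \quad
  \mathrm{CI} = \arctan\!\big(\tan\mathrm{TV}/\tan\mathrm{SI}\big), \quad
  \mathrm{SI} = \arctan\!\big(\tan\mathrm{TV}/\tan\mathrm{CI}\big).$$

These are `tv_from_ci_si()`, `ci_from_tv_si()` and `si_from_tv_ci()`. The
clinically interesting direction is the first: an AP and a lateral
radiograph give CI and SI, and the transverse version — normally requiring
CT — falls out in closed form. The relation is an identity of projection
geometry, not an approximation; in the noise-free limit the reconstruction
is exact (the test suite verifies agreement with brute-force vector
projection to $10^{-9}$ degrees on $10^4$ random axes).

```{r}
tv_from_ci_si(ci = 50.0, si = 11.3)
```

### Frames

Angles can be measured in the scanner frame (the identity triad) or
relative to the femur itself. `mechanical_frame()` builds the latter from
four landmarks: the vertical axis is the mechanical femoral axis (knee-joint
center to femoral-head center), the medio-lateral axis is the posterior
condylar direction (lateral to medial condyle) orthogonalized against it by
Gram–Schmidt, and the antero-posterior axis completes the right-handed
triad. `angles_from_axis(axis, frame)` re-expresses the axis before
projecting, so the same machinery produces scanner-frame and
mechanical-frame ("primed") angles.

### Numerical choices

Internally all angles are radians; every interface is degrees. Angles are
computed from vector components with `atan2`, which is well conditioned even
where tangents blow up; the tangent-product equations are exposed only
through the angle-valued API with open-domain guards. Inputs within
0.01° of a tangent pole or zero (CI at 0° or 90°, SI at 0° where it sits in
a denominator, any angle at ±90°) raise classed errors instead of returning
huge or NaN values — accuracy of the reconstruction genuinely degrades in
near-degenerate configurations, and silent garbage would be worse than a
refusal. Table-level conversion (`convert_table()`) flags such rows in a
`status` column rather than erroring, so one bad row cannot sink a batch.

Retroversion is represented as negative TV/SI throughout (the signed
convention). The default synthetic cohort uses an all-positive version
range, matching the reference cohort's printed minima; whether real
retroverted stems were folded to absolute values in that cohort is unknown,
and the signed representation keeps both options open.

## Non-orthogonal imaging

In practice the two views are rarely exactly 90° apart. The package models
this as the sagittal (lateral) view rotated by $\delta$ about the vertical
axis while the coronal view stays put — the rotation axis and sign are an
assumption, chosen so that positive $\delta$ *reduces* apparent anteversion,
the direction of the shift observed when views meet at 85°. The coronal
inclination is unaffected; the apparent sagittal inclination
$\mathrm{SI}'$ is the projection onto the rotated plane; and the version
reconstructed from the mismatched pair obeys the closed form

$$\tan(\mathrm{TV}') = \tan(\mathrm{TV})\cos\delta - \sin\delta.$$

```{r}
apparent_angles_nonorthogonal(axis_from_angles(50.0, 10.8),
                              mis = plane_misalignment(5))
```

A true anteversion of 10.8° appears as 5.87° on an 85° acquisition — a
bias of the same order as the quantity itself, which is why plane
orthogonality matters far more to this method than measurement noise does.

## The synthetic cohort

No raw per-hip data exist for the reference cohort, only distribution
summaries, so `sample_orientations()` emulates them: CI and TV are drawn
independently from truncated normals — CI with mean 50.0°, SD 9°, range
(26.1, 72.0); TV with mean 10.8°, SD 9°, range (0.4, 29.7) — and SI is
*derived* from the identity rather than sampled, so every simulated hip is a
geometrically exact triple. Sampling is inverse-CDF, hence exact and
bit-reproducible for a fixed seed. Independence of CI and TV is an
assumption (no correlations are reported); the truncation ranges are the
printed observed ranges.

Two features of this generator should temper interpretation. First,
truncating a Normal(10.8°, 9°) to (0.4, 29.7) shifts its mean to ≈ 12.5°
and shrinks its SD to ≈ 6.9° — the generator reproduces the printed
*parameters*, and no truncated normal can reproduce the printed mean, SD
and range simultaneously (an SD of 9° is impossible on a 29.3°-wide
support). Second, real measurement errors of two observers on the same
image are likely correlated; the noise model below is independent. Passing
tests therefore demonstrate the geometry and the statistical machinery, not
observer behaviour.

### Measurement noise and its calibration

`apply_noise()` adds i.i.d. Gaussian error with one common SD $\sigma$ to
every manually measured angle in both imaging series — per-plane error
levels are not separately estimable from the published summaries, so a
common $\sigma$ is the parsimonious choice. Noise is added *after* the
non-orthogonal projection: the observer measures the distorted image.
Noisy values are clipped into the open valid domains (events are logged).

$\sigma$ is not a free dial. `calibrate_noise()` fixes it by requiring the
simulation to reproduce the published validity figure — a median absolute
difference of 1.3° between manual TV and TV calculated from manual (CI, SI)
— via root-finding (Brent) on a forward simulation with pre-drawn,
$\sigma$-scaled errors, which makes the objective continuous and strictly
monotone. The calibrated value is verified to land within 0.02° of the
target (on a 200,000-hip calibration cohort by default) and comes out near
$\sigma \approx 1.17°$.

## The validation study

`run_validation_study()` reproduces the structure of the reference
validation on synthetic data. Per replicate: sample a cohort, add noise,
and compare

* **manual vs calculated** TV on the orthogonal series — the validity
  analysis; and
* **calculated vs calculated** TV between the orthogonal and 85° series —
  the out-of-plane error analysis,

each with the two-way mixed absolute-agreement ICC — ICC(A,1): the
single-rater, absolute-agreement intraclass correlation from the two-way
ANOVA mean squares, with the F-distribution 95% CI; the point estimator is
identical under the random and mixed models, only the interpretation of the
CI differs — plus Bland–Altman bias with 1.96·SD limits of agreement and
the median absolute difference with interquartile range
(linear-interpolation percentiles). Normality screening is deliberately not
a gate: the statistics are computed unconditionally, as in the reference
analysis, where distributions were checked descriptively.

```{r}
report <- run_validation_study(
  study_config(spec = cohort_spec(n = 20000, seed = 3), misalignment = 5, seed = 3)
)
report
```

At these study conditions the manual-vs-calculated comparison shows a
median absolute difference of 1.3° (the calibration target), ICC ≈ 0.96,
and 95% limits of agreement of about ±4°; the orthogonal-vs-85° comparison
shows a median absolute difference near 5° and a sharply lower ICC. The
simulated validity ICC sits a little below the published 0.98 for a
structural reason: the truncated cohort's between-subject SD (≈ 6.9°) is
smaller than the nominal 9°, and the ICC is between-subject variance
divided by itself plus error variance — less spread, same error, lower ICC.

Problem sizes were chosen so the whole pipeline stays interactive: 10,000
hips for noise-free geometric comparisons, 100,000 where percentile tails
are measured, 200,000 for calibration; the full study runs end to end in
seconds on one CPU.

## What is deliberately out of scope

No CT/DICOM reading, MIP rendering, registration or landmark detection:
inputs are angle or landmark tables (CSV). No acetabular-cup mathematics.
The human intra-/inter-observer reliability values and the real cohort's
agreement tables depend on the original patients and raters and are not
reproducible from summaries; in their place the suite checks the directions
that must hold — agreement degrades monotonically in both the noise level
and the plane misalignment — plus the exactness and oracle properties
above.
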