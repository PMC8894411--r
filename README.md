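# femver

Transverse version of a femoral total-hip-arthroplasty (THA) component,
reconstructed from its coronal and sagittal orientations.

## The problem

After THA, the rotational alignment ("anteversion") of the femoral stem
matters for stability, but the transverse-plane version (TV) of the neck is
normally measured on CT. The neck axis is a single direction in space, so its
three orthogonal-plane projection angles — coronal inclination (CI, on an AP
view, against the horizontal), sagittal inclination (SI, on a lateral view,
against the vertical) and transverse version (TV, on an axial view, against
the horizontal) — are not independent. With a right-handed frame (x
medio-lateral, y anterior, z superior) they satisfy

    tan(TV) = tan(SI) · tan(CI)

and any two determine the third:

    TV = arctan(tan(SI) · tan(CI))
    CI = arctan(tan(TV) / tan(SI))
    SI = arctan(tan(TV) / tan(CI))

so TV can be *calculated* from a pair of plain orthogonal radiographs instead
of measured on CT. femver implements these equations with full vector-geometry
backing (neck axes, scanner and mechanical-femoral frames built from
landmarks), a model of the bias introduced when the two views are not exactly
90° apart, a synthetic-cohort simulator with calibrated Gaussian measurement
noise, and the agreement statistics used to validate such a method: two-way
absolute-agreement ICC — ICC(A,1), with F-based 95% CI — Bland–Altman bias and
1.96·SD limits of agreement, and median absolute differences with IQR.

It is aimed at researchers in orthopedic biomechanics and medical-imaging
geometry who want to use, stress-test or extend biplanar angle reconstruction.

## Worked example

```r
library(femver)

# one hip measured on an AP and a lateral view
tv_from_ci_si(ci = 50.0, si = 11.3)
#> [1] 13.3947

# a whole table, with degenerate rows flagged instead of propagated
convert_table(tibble::tibble(hip_id = c("h1", "h2", "h3"),
                             ci_deg = c(50.0, 45, 90),
                             si_deg = c(11.3, 45, 10)))
#> # A tibble: 3 × 5
#>   hip_id ci_deg si_deg tv_calc_deg status
#>   <chr>   <dbl>  <dbl>       <dbl> <chr>
#> 1 h1         50   11.3        13.4 ok
#> 2 h2         45   45          45   ok
#> 3 h3         90   10          NA   degenerate
```

A hip with CI 50.0° and SI 11.3° carries a calculated transverse version of
13.4° of anteversion; at CI = 90° the tangent relation collapses and the row
is flagged rather than given a fabricated value.

The full synthetic validation study — sample a cohort of true orientations,
add measurement noise calibrated so the manual-vs-calculated median absolute
difference is 1.3°, image it both orthogonally and with the sagittal view at
85°, and compare the reconstructions:

```r
report <- run_validation_study(
  study_config(spec = cohort_spec(n = 20000, seed = 3), misalignment = 5, seed = 3)
)
report
#> Synthetic validation study: n = 20000 hips x 1 replicate(s), sigma = 1.18 deg, misalignment = 5.0 deg
#>
#>  replicate                      series  icc icc_ci_low icc_ci_high
#>          1        manual_vs_calculated 0.96       0.96        0.96
#>          1 orthogonal_vs_nonorthogonal 0.78      -0.05        0.94
#>  median_abs_diff mad_iqr_low mad_iqr_high bias loa_low loa_high
#>              1.3         0.6          2.3  0.0    -4.0      4.0
#>              4.8         3.5          6.1  4.8     0.6      9.1
```

Reading the first row: with realistic measurement noise the calculated TV
agrees with the manual TV to a median 1.3° (IQR 0.6–2.3), ICC 0.96, no bias,
and 95% limits of agreement of ±4° — the algorithm itself is exact, so all of
this error is injected noise. The second row is the cost of non-orthogonal
imaging: a 5° out-of-plane rotation biases the calculated version by ~4.8°
(median) and drops the ICC to 0.78, far more damage than observer noise does.

`autoplot(bland_altman(...))` draws the agreement plot; `tidy()`/`glance()`
methods return the statistics as tibbles. A thin CLI with `convert`,
`simulate`, `validate` and `icc` subcommands lives at `inst/cli/femver.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/femver.R", package="femver"))') validate --n 10000 --seed 1`).

## Scope

Inputs are angle tables and landmark coordinates (CSV) — no DICOM/CT reading,
MIP rendering or landmark detection, and no acetabular-cup mathematics. See
`vignettes/femoral-version-reconstruction.Rmd` for the model, assumptions,
calibration details and known limitations of the synthetic cohort.
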