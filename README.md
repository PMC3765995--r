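# densecmr

Strain, twist, torsion and synchrony analysis for cine DENSE cardiovascular
MRI in small animals, with the reproducibility statistics used to compare
repeated studies and observers, and an analytic phantom that makes every
stage of the pipeline testable against exact ground truth.

## The problem

Cine DENSE (Displacement ENcoding with Stimulated Echoes) MRI stores tissue
displacement in the image phase: a pixel whose tissue has moved by `u` mm
along the encoding axis carries phase

    phi = 2 * pi * k_e * u   (observed modulo 2*pi)

with encoding frequency `k_e` in cycles/mm (0.8 in a typical murine
protocol, so displacements beyond 0.625 mm wrap).  From one magnitude stack
and two orthogonally encoded phase stacks per slice, `densecmr` derives the
advanced measures of left-ventricular function used in mouse cardiology:

* **Strains** — Green-Lagrange tensors `E = (F'F - I)/2` from local
  least-squares fits of the deformation gradient, projected on the radial,
  circumferential and longitudinal directions (`E_rr`, `E_cc`, `E_ll`),
  aggregated over the 16-segment model and transmural thirds, with peak
  strains (%) and peak systolic/diastolic strain rates (%/ms);
* **Twist and torsion** — per-slice rotation about the LV centroid
  (counter-clockwise positive, viewed from the apex) and the apex-base
  twist difference normalized by the end-diastolic long-axis length
  (deg/cm);
* **Synchrony** — the CURE and RURE uniformity-ratio indices,
  `sum(S0) / sum(S0 + S1)` over zeroth/first spatial Fourier powers of the
  sector-mean strain (1 = synchronous, 0 = dyssynchronous);
* **Reproducibility** — the modified mean coefficient of variation
  `CoV = sum_i SD(x1_i, x2_i) / sum_i |(x1_i + x2_i)/2|` with the
  `CoV <= 20%` rule, and Bland-Altman limits of agreement
  (`mean +/- 2 SD` of the paired differences).

Because no public mouse DENSE data accompany the methodology, the package
includes an analytic contracting/twisting LV phantom (incompressible
annulus with closed-form strains) that renders realistic wrapped DENSE
series, and a virtual-cohort simulator reproducing a two-day, two-observer
reproducibility study design (nine animals: five normal, four with
depressed function; day-2 slice-position jitter; observer-2 contour
perturbation).

## Worked example

Render a noisy mid-ventricular slice from the default mouse model, run the
full single-slice analysis, and compare with the model's exact truth:

```r
library(densecmr)
model  <- deformation_model()                 # mouse LV, Ecc_endo ~ -16%
acq    <- acquisition_spec()                  # 32 mm FOV, 128x128, k_e = 0.8
series <- render_dense_series(model, acq, slice_descriptor("mid"),
                              rng_seed = 42)
series
#> DENSE series: mid slice (short_axis), 128 x 128 x 15 frames, 0.25 mm pixels, k_e = 0.80 cycles/mm

an <- analyze_dense_series(series, model_contours(model))
pk <- extract_peaks_rates(an$curves, an$es_frame, smooth_peaks = TRUE)
pk[pk$layer %in% c("endo", "global"), ]
#>  direction  layer peak_strain_pct peak_systolic_rate peak_diastolic_rate es_frame
#>         cc   endo          -11.93             -0.404               0.293        8
#>         cc global           -7.93             -0.259               0.191        8
#>         rr   endo           15.64              0.892              -0.391        8
#>         rr global            9.97              0.398              -0.227        8

an$twist[an$es_frame]
#> [1] 0.56  # degrees of mid-slice end-systolic twist

head(ground_truth_endpoints(model), 4)
#>        endpoint  value
#>    peak_cc_endo -12.34
#>     peak_cc_mid  -8.17
#>     peak_cc_epi  -5.71
#>  peak_cc_global  -8.15
```

With the default 0.1 rad phase noise the recovered global peaks sit within
a fraction of a percent strain of the analytic values, and the transmural
ordering (endocardial > mid-wall > epicardial `|E_cc|`) is preserved.

The statistical layer works on any paired endpoint table:

```r
day1 <- c(35, 31, 28, 33, 30, 27, 25, 36, 29)   # e.g. peak radial strain, 9 mice
day2 <- c(33, 30, 31, 35, 28, 27, 26, 33, 31)
modified_cov(day1, day2)
#> [1] 4.1        # percent: reproducible (<= 20)
bland_altman(day1, day2)
#> mean diff 0.00, limits of agreement [-4.24, 4.24]
```

A whole virtual study — simulation, analysis of every animal under every
condition, and the CoV/Bland-Altman report — is one call:

```r
study <- run_study(cohort_spec(seed = 1), out_dir = "study_out")
subset(study$report, scope == "all" & comparison == "inter_test",
       c(endpoint, n, cov, reproducible))
```

A thin command-line wrapper (`exec/densecmr`) exposes `simulate`,
`run-study` and `repro` subcommands over YAML configurations for shell use.

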