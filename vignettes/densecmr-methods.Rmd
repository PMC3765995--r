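---
title: "Methods: DENSE strain, torsion and synchrony analysis and its validation phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DENSE strain, torsion and synchrony analysis and its validation phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

Cine DENSE (Displacement ENcoding with Stimulated Echoes) MRI encodes tissue
displacement in the image phase: a pixel containing tissue that has moved by
`u` millimetres along the encoding axis carries a phase `2*pi*k_e*u`, with
`k_e` the encoding frequency in cycles/mm, observed modulo `2*pi`.  From one
magnitude stack plus two orthogonally encoded phase stacks per slice, the
package derives the advanced measures of left-ventricular (LV) function used
in small-animal cardiology:

* myocardial Green-Lagrange strains projected on the radial (`E_rr`),
  circumferential (`E_cc`) and longitudinal (`E_ll`) directions, aggregated
  over the 16-segment LV model and transmural thirds, with peak strains and
  peak systolic/diastolic strain rates;
* LV twist per short-axis slice and torsion (apex-base twist difference
  normalized by the end-diastolic long-axis epicardial length);
* the CURE and RURE uniformity-ratio synchrony indices; and
* the reproducibility statistics used to compare repeated studies and
  observers: the modified mean coefficient of variation (CoV) with its
  `<= 20%` reproducibility rule, and Bland-Altman limits of agreement
  (mean difference `+/- 2` SD).

Because no public mouse DENSE dataset accompanies the methodology, the
package also implements an analytic deformation phantom that renders
realistic wrapped DENSE series with known ground truth, and a virtual-cohort
simulator that reproduces the design of a two-day, two-observer
reproducibility study.  Every processing stage is validated against the
phantom's exact solution.

# The deformation phantom

The LV is modelled as an incompressible annulus (short-axis cross-section)
of a cylinder.  In reference polar coordinates `(R, Theta, Z)` a material
point moves to

    r(R, t)     = sqrt(R^2 - R_endo^2 + r_endo(t)^2)
    theta(t)    = Theta + twist(Z / L) * a(t)
    z(t)        = Z * (1 - lambda_ls * a(t))

with `r_endo(t) = R_endo (1 - s a(t))`.  Here `s` is the peak endocardial
circumferential shortening fraction, `lambda_ls` the longitudinal
shortening fraction, `twist(.)` the peak twist profile along the normalized
long axis (positive toward the apex, negative toward the base, by the
standard counter-clockwise-from-apex convention), and `a(t)` the temporal
activation: a squared-sine rise from 0 at end diastole to 1 at end systole
(40% of the cycle, the typical murine systolic fraction) and a squared-sine
return.  The radial map conserves cross-sectional area, which produces the
characteristic transmural gradient — endocardial `|E_cc|` exceeds
epicardial `|E_cc|` — without any further assumptions.

Exact Green-Lagrange strains follow in closed form: the in-plane deformation
gradient is diagonal in the polar basis with stretches
`lambda_r = R / r` and `lambda_c = r / R`, so
`E_rr = (lambda_r^2 - 1)/2`, `E_cc = (lambda_c^2 - 1)/2`, and
`E_ll = ((1 - lambda_ls a)^2 - 1)/2`.

## Default parameters

| parameter | default | rationale |
|---|---|---|
| endocardial / epicardial radius (ED) | 1.2 / 2.2 mm | typical adult C57BL/6 short-axis geometry |
| LV length (ED) | 8.5 mm | consistent with peak torsion near 7.9 deg/cm for a 6.7 deg apex-base twist difference |
| peak endocardial circumferential shortening | 0.18 | yields peak endocardial `E_cc` of about -16% |
| longitudinal shortening | 0.12 | yields peak `E_ll` of about -11% |
| twist profile | piecewise linear through +4.5 (apical), +0.5 (mid), -2.2 deg (basal) | typical murine slice twist magnitudes |
| cycle length / systolic fraction | 110 ms / 0.40 | 545 bpm heart rate |

The twist anchors are placed at the *material* positions the three standard
slices image at end systole (the ventricle shortens through the fixed
imaging planes), so a slice planned at 30/50/70% of the end-diastolic length
reads exactly the anchored value at end systole.

## Rendering

Slices are fixed laboratory planes (Eulerian slices, as in real imaging).
For each pixel inside the deformed myocardium the renderer inverts the
deformation analytically to find the in-plane Eulerian displacement `u` of
the tissue currently at that pixel, and writes
`phase = wrap(2*pi*k_e*u + eps)` with `eps ~ N(0, noise_sd)`.  Outside the
myocardium the phase is uniform on `(-pi, pi]` — no signal coherence — which
deliberately stresses the unwrapper's mask handling.  The magnitude image is
bright tissue (1.0) over dim background (0.08) plus Gaussian noise.
Acquisition defaults follow a typical murine spiral cine DENSE protocol:
32 mm field of view, 128 x 128 matrix (0.25 mm pixels), 15 frames at 7.1 ms,
`k_e = 0.8` cycles/mm, phase noise 0.1 rad.  Bloch-equation or k-space
simulation is out of scope by design: the analysis consumes phase images,
so phase images are synthesized directly from the deformation model.

Long-axis views (4-chamber, 2-chamber) are rendered as planes containing
the long axis of the same cylindrical model; they provide `E_ll` and the
end-diastolic epicardial length used to normalize torsion.  The model has
no apical cap, so long-axis myocardium appears as two straight wall bands —
adequate for longitudinal strain and length measurement, not for apical
anatomy.

## The virtual cohort

A cohort specification draws per-animal model parameters from group
distributions (defaults: five normal animals, four with depressed function —
lower contraction and twist), then simulates three conditions per animal:

* `obs1_day1` — the reference acquisition;
* `obs1_day2` — same heart, independent noise, and short-axis slice
  positions perturbed by `N(0, 0.3 mm)` (slice re-planning error);
* `obs2_day1` — the day-1 images re-analyzed with initial contours
  perturbed by a smooth low-order angular deformation of `N(0, 0.125 mm)`
  (half a pixel), the mechanism of inter-observer variance.

Everything is a pure function of the specification and its seed.  When both
inter-test degradations are zero, day 2 is bit-identical to day 1.

What the generator does *not* emulate: partial-volume and surface-coil
intensity effects, stimulated-echo signal decay over the cycle, respiratory
motion, papillary muscles, and through-plane displacement encoding.
Passing tests therefore demonstrate correctness of the *processing* under
controlled conditions, not robustness to every artefact of in-vivo data.

# Processing pipeline

**Segmentation.**  Per-frame masks come from an automatic magnitude
threshold (midpoint of the robust background and tissue levels), restricted
to a 2-pixel dilation of the previous frame's mask (motion guidance) and
reduced to the largest connected component.  The analyst's initial
end-diastolic contours define the material region of interest; "user
correction" is an input override, not an interactive tool.

**Phase unwrapping.**  Quality-guided region growing, seeded per connected
component at the pixel with the lowest local variance of wrapped phase
gradients; each pixel joins with the `2*pi` multiple closest to its solved
neighbour.  The global per-component multiple is fixed by minimizing
displacement magnitude at the first frame (motion is small immediately after
the R-wave) and by temporal continuity thereafter; a pixel-wise temporal
pass overrides residual spatial ambiguities, and isolated `2*pi` outliers
are repaired against the local neighbour median.  Displacements beyond a
physiologic cap (3 mm default) are flagged with a warning, never clipped.

**Tracking.**  The Eulerian field gives, at every masked pixel `x`, the
reference position `X = x - u(x, t)`.  Material trajectories invert this
map: the position of the point that started at `X0` solves
`x - u(x, t) = X0`, found by fixed-point iteration `x <- X0 + u(x, t)` with
bilinear sampling of the gridded field.  At mask edges the field is
extended into a small collar by local plane fits over the masked 5 x 5
window, which keeps the iteration exact for affine motion (a scattered-data
interpolation of the inverse map would solve the same equation; the
fixed-point form needs no triangulation and vectorizes over all points).
No temporal smoothing is applied to trajectories.

**Strain.**  Around each material point the local deformation map is fit
by least squares over the exact per-frame Eulerian pixel pairs
`(x, X = x - u(x, t))` within 0.75 mm radially and twice that
circumferentially, and `E = (F'F - I)/2` is taken from the linear part `F`.
For short-axis slices the fit is performed between the deformed and
reference *polar* frames (about the per-frame tracked centroid and the
end-diastolic centroid respectively) with a cubic radial / quadratic
circumferential basis, and in *inverse* form: the noisy reference
coordinates are regressed on the exact deformed pixel positions and the
fitted gradient is inverted, `F = G^-1`.  These choices are what make a
0.25 mm analysis of a 1 mm wall work.  Annular motion is nearly linear in
polar coordinates, whereas Cartesian polynomial bases alias the wall's
geometric curvature into strain precisely at the one-sided endocardial and
epicardial edges; wall thinning leaves no pixel centres over the innermost
fraction of the wall at end systole, which the cubic radial term
extrapolates correctly; regressing on the exact deformed positions avoids
the errors-in-variables attenuation a forward fit suffers when pixel noise
enters its predictors; and the wider circumferential window averages noise
without bias because the motion is circumferentially near-linear.  Under
noise three further elements activate (all inactive on noiseless data):
a pixel-wise temporal Savitzky-Golay filter of the displacement stacks
(the Eulerian field evolves smoothly over the cycle); a ridge prior on the
cubic radial coefficient at the physical scale of wall curvature,
strengthened where the window is radially one-sided; and a delta-method
second-order bias correction of `E` (which is quadratic in `F`, so
estimator variance would otherwise inflate the diagonal strains).  A plain
Cartesian fit over tracked trajectories (with optional quadratic terms)
remains available and is used for long-axis views, where the wall bands
are straight.  Points with rank-deficient neighbourhoods are flagged
invalid and excluded from all statistics.

**Peak extraction under noise.**  When the data are noisy, peak strains
are read from a temporal Savitzky-Golay (local quadratic) filtering of the
aggregated curves: strain curves are smooth and locally quadratic at their
extremum, so the filter passes true peaks unchanged while suppressing the
frame-to-frame noise that a raw extremum search would rectify into a
systematic overestimate.  Per-layer radial strain at this resolution and
noise level sits near the single-acquisition information floor, so the
validation suite asserts noisy recovery on the mean over five independent
acquisitions of the same phantom.

**Aggregation.**  Directional strains are averaged per (segment, layer)
cell and per frame; summary curves are means of per-segment means — not
pooled-pixel means, which differ when segments hold unequal point counts.
Segments follow the 16-segment model (6 basal, 6 mid, 4 apical sectors
about the landmark angle); layers are transmural thirds of the normalized
endocardium-to-epicardium depth at end diastole.  Longitudinal aggregation
excludes apical segments.  End systole is the frame of the extremal global
circumferential strain (per-study: the rounded mean over short-axis
slices); the `E_cc` extremum is the robust convention where no independent
end-systole marker exists.

**Rates.**  Strain, twist and torsion rates are centered finite differences
over the frame times with no smoothing: differentiating a noisy measurement
amplifies its noise, and the package reproduces that property rather than
hiding it — it is the mechanism behind peaks being more reproducible than
rates.  Peak systolic rates are the largest-magnitude rates up to end
systole, diastolic after it.  Reported rate units are %/ms and deg/ms
computed literally from curves in % and degrees against times in ms.

**Twist and torsion.**  Per-point signed angles between the end-diastolic
radial line (from the end-diastolic epicardial centroid) and the current
radial line (from the per-frame centroid of the propagated epicardial
contour), averaged with the circular mean over all valid myocardial points
of the slice; per-frame centroid tracking cancels bulk translation, and all
points contribute because the definition does not restrict to a layer.
Torsion is `(twist_apical - twist_basal) / L` with `L` the end-diastolic
epicardial length in cm, averaged over the two long-axis views when
present.

**Synchrony.**  Per frame and slice, sector means of the strain field
(24 sectors default, at least 4 points per sector at murine resolution) are
fit by least squares with zeroth and first circular harmonics only;
`S0 = a0^2`, `S1 = a1^2 + b1^2`.  The index is `sum(S0) / sum(S0 + S1)`
over the frame window with powers pooled across the three short-axis slices
before the ratio (a square-root variant and per-slice averaging are
available behind flags; pooling was chosen because summed powers weight
slices by signal rather than equally).  Windows: systolic = frames up to
and including end systole, diastolic = the rest, total = all frames.

**Reproducibility.**  The modified mean CoV is
`100 * sum_i SD(x1_i, x2_i) / sum_i |(x1_i + x2_i)/2|`, with the two-value
standard deviation `|x1 - x2| / sqrt(2)`.  The denominator takes the
absolute value of each subject's paired mean, so negative-valued endpoints
(circumferential strain) are handled; the statistic is scale-invariant but
*not* translation-invariant, which is exactly why endpoints whose values sit
near zero — mid-ventricular end-systolic twist in particular — produce
arbitrarily large CoVs.  `CoV <= 20%` (inclusive) is flagged reproducible.
Bland-Altman limits of agreement use `mean(d) +/- 2 sd(d)` (the 2-SD
convention, not 1.96).  Inter-test compares observer 1's day-1 and day-2
analyses; inter-observer compares observer 2's and observer 1's day-1
analyses.  Subjects with a missing value are dropped from that endpoint's
comparison with a logged count; comparisons left with fewer than two
subjects are reported as undefined rather than dropped.

# The slice-jitter experiment

The package's headline validation reproduces the central reproducibility
contrast: over a steep *linear* twist gradient whose zero crossing lies at
the material position the mid slice images at end systole
(-19.8 deg per unit normalized length, i.e. apical +4.5 deg and basal
-4.5 deg at the standard slice positions), a day-to-day slice-planning
error of 0.3 mm leaves each animal's mid-slice twist mean near zero while
its day-to-day difference is dominated by the jitter — the modified CoV
explodes (median above 100% across replicates).  Torsion divides the twist
*difference* by the length; with a linear gradient it is insensitive to
slice position, and its CoV stays in the low percent range.  The same
replicates show peak strains more reproducible than strain rates.  The
experiment runs 20 independent nine-animal cohorts on a 96 x 96 matrix
(the contrast under study is driven by slice positioning, not in-plane
resolution; a full-resolution replicate set would only lengthen the
computation), and is asserted on replicate medians because the CoV's
near-zero denominator makes its distribution heavy-tailed.

# Numerical choices and edge cases

* Wrapping convention: `(-pi, pi]`; displacements beyond `1/(2 k_e)`
  (0.625 mm at default `k_e`) alias and must be unwrapped.
* Fixed-point tracking: 25 iterations max, `1e-6` mm tolerance; converges
  whenever the displacement gradient is below one, which holds for
  physiologic cine motion.
* Strain fits require at least 3 non-collinear neighbours (linear), 6
  (quadratic) or a full-rank 7-column polar basis; failures flag the point
  invalid rather than guessing.
* Empty (segment, layer) cells are excluded from means and logged.
* All-zero strain in a synchrony window defines the index as 1 (perfectly
  uniform) with a notice; the index is clamped to `[0, 1]`.
* A degenerate end-systolic frame (first or last frame) is an error for
  windowing; the study-level end systole is clamped to the interior.
* CoV with a zero denominator is an error (undefined), mirroring the
  near-zero-twist pathology rather than returning infinity.
* Problem sizes used by the validation suite: full-resolution
  (128 x 128, 15 frames) single phantoms for recovery checks; 96 x 96 for
  the replicated cohort experiments; 96 x 96, 10 frames, two animals for
  end-to-end pipeline tests.

# Known limitations

* The phantom is a cylinder: no apical cap, no wall-thickness variation
  along the long axis, and uniform-in-depth twist.  Transmural twist
  gradients and shear strains are not modelled (and shear endpoints are not
  reported).
* 2D in-plane encoding only; through-plane motion changes which material
  shell a slice images (modelled) but through-plane displacement is not
  encoded (as in the 2D acquisitions the pipeline targets).
* The segmentation is magnitude-threshold-based and tuned to the phantom's
  bimodal intensity; real data with coil shading would need the contour
  override inputs.
* Printed rate units (%/ms, deg/ms) are computed literally; no rescaling is
  applied to match any particular published magnitude convention.
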