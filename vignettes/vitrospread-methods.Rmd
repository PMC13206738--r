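---
title: "Models and methods behind vitrospread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vitrospread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitrospread)
```

`vitrospread` has two halves: a measurement pipeline for photographs of
bisected eyes after intravitreal dye injection, and a synthetic-eye generator
that produces ground-truthed images of the same kind. This vignette explains
the models behind both, the parameters that matter, the numerical choices,
and what passing tests do and do not demonstrate about real data.

## The measurement model

Fluorescein signal is read from the green channel of the RGB photograph.
Preprocessing follows standard fluorescence practice: the background estimate
is the mean green intensity over a dye-free region (the median is available
via a flag, since "signal measured in a region" does not pin down a
statistic), subtracted pixel-wise with clamping at zero, and the result is
linearly rescaled so the image minimum maps to 0 and the maximum to 255.
Rescaled values are rounded half-away-from-zero — the rule is stated
explicitly because half-cases move threshold masks, and golden results must
be stable. A constant image (no dynamic range, hence no signal) maps to all
zeros rather than all 255. By default the min/max are taken over the whole
image; `range_mask` restricts them to the eye interior when bright artifacts
outside the eye would otherwise compress the range.

Segmentation applies a threshold `tau` to the eye interior with the inclusive
comparison `>= tau`, so a stated level such as 70 belongs to the mask it
defines. The fluorescent area is the single contiguous region of
above-threshold pixels: components are 8-connected (visually contiguous
diagonal signal should not fragment), and when several components exist the
largest is selected unless a seed point is given; ties fall back to the
centroid closest to a supplied entry point and then to the lowest row-major
index. Because "the contiguous region" is ambiguous when stray noise clears
the threshold, the fraction of lit pixels excluded by the selection is always
reported, making the choice auditable.

Three quantities summarize the region:

* **area percentage** against the eye area. The default denominator is the
  circle approximation `pi * (mean(d_NT, d_IS) / 2)^2` from the two manually
  measured orthogonal diameters, mirroring bench practice; the rasterized
  boundary-polygon area is available by flag.
* **Feret radius** — half the maximum pairwise distance between region pixel
  centers. It is computed on the convex hull, which attains the same maximum
  as the all-pairs scan (asserted against a brute-force oracle in the tests).
* **centroid radius** — the distance from the unweighted pixel centroid to
  the most distant region boundary pixel, where boundary pixels are region
  pixels with at least one 4-neighbor outside the region.

Coordinates are 0-based with the pixel-center convention; distances are
between pixel centers, scaled by mm/pixel. Radii are deliberately not capped
at the eye radius. Neither radius dominates the other in general, so the
tests assert only loose geometric bounds between them plus exact agreement on
discs. The hemifield comparison splits the region at the vertical line
through the eye-boundary centroid, pixels exactly on the line counting half
to each side; which image side is nasal comes from the annotation.

The repeatability audit re-runs the full segmentation-to-radius chain eight
times on the identical image. The implementation is deterministic, so the
spread must be exactly 0 mm, and the audit enforces the 0.001-mm
reproducibility bound as an internal invariant; a jitter flag perturbs the
threshold by ±1 per repeat to probe sensitivity instead.

## Group statistics

`t_test_groups()` defaults to the pooled-variance Student test (the named
method), with Welch behind a flag as the robust alternative. `anova_tukey()`
fits a one-way ANOVA and follows it with Tukey's HSD over all pairs via the
studentized-range distribution with pooled within-group variance; with two
groups this reduces exactly to the pooled t-test (`q = t * sqrt(2)`), a
reduction the tests check numerically. A variance ratio above 10 between
groups triggers a warning, not an error. Significance tiers are `*`, `**`,
`***` at 0.05, 0.01, 0.001. No multiplicity control is applied beyond Tukey's
procedure, and both SD and SEM are always reported because a bare "±" is
ambiguous. `cohort_report()` accepts only per-eye values, never summary
statistics, precisely because of that ambiguity.

## The synthetic-eye generator

The generator emulates the photographed cross-section, not the globe: all
measurements are made on 2-D images of bisected eyes, so the simulation is a
2-D disc on a Cartesian grid with a masked interior (radial symmetry is not
assumed). Physics is deliberately minimal — isotropic Fickian diffusion,

$$\partial C/\partial t = D\,\nabla^2 C,\qquad
D_{\mathrm{eff}} = \frac{k_B T}{6\pi\eta r_s}\,e^{-(r_s/\xi)^2},$$

the simplest model consistent with a size-dependent barrier: Stokes–Einstein
diffusivity damped by an Ogston-type hindrance factor for a mesh of size
`xi`. Key parameters, defaults and rationale:

| parameter | default | why |
|---|---|---|
| Stokes radii | 27 / 14.7 / 5.8 / 4.5 nm for 2 MDa … 40 kDa | published hydrodynamic radii for these dextran conjugates |
| 3 kDa radius | 1.3 nm, flagged extrapolated | no published value in the set used; must be below 4.5 nm and give near-complete 24-h spread |
| temperature | 277.15 K ex vivo, 310.15 K in vivo | cold incubation vs physiology |
| viscosity `eta` | 2.0 mPa·s | no measured vitreous value available; a single tunable effective value is exposed rather than hidden |
| mesh size `xi` | 550 nm | the literature estimate for bovine vitreous; pig/human meshes are plausibly smaller, so presets may shrink it |
| plasmin preset | `xi` × 3 | vitreolysis is modeled purely as mesh enlargement — a scenario knob, not a fitted enzyme model |
| bolus width `sigma0` | 1.0 mm | a 50-µL sphere has radius ≈ 2.29 mm; the Gaussian is set narrower so the rendered time-0 spot is compact |
| injection | entry 4 mm from the boundary (3.5 mm in vivo), bolus at 25% of the entry-to-center segment | the needle is "advanced toward the center"; the 25% depth is a free choice, configurable |
| eye diameter | uniform 19.935–25.626 mm ex vivo | the recorded diameter range; in-vivo (17–20 mm) and human (22–25 mm) ranges are not recorded and were chosen once as field-realistic |

The bolus is an isotropic Gaussian truncated to the domain and renormalized
to the configured mass. Occluders are closed polygons removed from the
domain: they model a bursa-like liquefied pocket that admits no dye, and the
generator asserts they exclude the injection point.

### Numerics

The solver is explicit FTCS in flux form: dye crosses a cell face only when
both cells are in the domain, so the eye wall and occluder edges are no-flux
boundaries and total mass is conserved to machine precision by construction
(the antisymmetric flux pairs cancel exactly). The time step honors the 2-D
stability bound with a 0.9 safety factor, `dt = 0.9 dx² / (4D)`, which also
keeps the update nonnegativity-preserving. Accuracy is O(dx²): at the default
resolution of 128 cells across the eye the free-space solution matches the
analytic Gaussian cell-wise within 2% over the region holding 99% of the
mass, and second moments recover `sigma²(t) = sigma0² + 2Dt` to better than
2% — both asserted in the tests at those grid sizes.

Rendering adds a background level, per-pixel Gaussian read noise (seeded;
byte-reproducible), an optional quadratic vignette, and quantizes to 8 bits
with the same half-away-from-zero rule as normalization. Exposure is
automatic by default — the gain is set so the peak green level sits 200 units
above background — because per-dye peak concentrations span an order of
magnitude and every image is min–max normalized downstream anyway; a fixed
gain can be supplied to emulate strictly identical camera settings.

### Diffusivity recovery

For a freely spreading Gaussian rendered and normalized this way, pixels at
or above threshold `tau` form a disc with
`r²(t) = 2 ln(255/tau) (sigma0² + 2Dt)`, so `fit_spread_rate()` regresses the
measured radius squared on time and reports
`D = slope / (4 ln(255/tau))`. On a six-point rendered series the estimate
lands within a few percent of the true value; the tests require 15%, with the
residual error dominated by pixelation and mild boundary reflection.

## Problem sizes and test design

The suite validates segmentation against an independent stack-based
flood-fill oracle on random 32×32 masks, Feret radii against the O(n²)
all-pairs scan, statistics against vectorized permutation oracles (10⁵
resamples), and the familywise error rate of the Tukey procedure under a
2,000-replicate null simulation (5 groups, n = 8), which must land in
[0.03, 0.07] at nominal 0.05. Cohort-level checks use the five-dye ex-vivo
preset at 24 h with n = 8 per group and fixed seeds: mean fluorescent area
must decrease strictly from 3 kDa to 2 MDa and the extreme contrast must
clear the `***` tier. These sizes were chosen to exercise every code path at
full fidelity while keeping the suite fast to run routinely.

## What passing tests do and do not show

The generator produces images whose difficulty is controlled: true boundary
polygons, pure Gaussian noise, no glare, no tissue autofluorescence, no lens
shadow, one face per eye, and diffusion as the only transport. Passing the
suite therefore demonstrates that the measurement chain is correct *given its
inputs* — that segmentation, radii, areas and statistics compute what their
definitions say, reproducibly. It does not validate the biology of real
eyes: hand-drawn boundaries, uneven illumination, convective transport in
vivo, dye binding or degradation, and bisection artifacts are all outside the
model. The simulator likewise does not resolve whether in-vivo enhancement of
small-dye spread reflects temperature, flow, or both — it exposes only
temperature and viscosity — and its plasmin scenario is a mesh-size knob with
no dose–response claim. Measured diffusion radii can exceed the eye radius
under one published convention; the package implements the two stated radius
definitions literally and makes no attempt to reproduce values that require a
different convention.
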