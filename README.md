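# vitrospread

Quantification of fluorescein–dextran distribution in photographs of bisected
eyes after intravitreal injection, paired with a physics-based synthetic-eye
generator so the entire measurement pipeline can be validated against known
ground truth.

The vitreous acts as a size-selective barrier: small tracers injected into the
eye spread almost everywhere within a day, while large ones stay near the
injection site. Quantifying that spread from photographs of bisected eyes
involves a chain of image-processing steps — background subtraction, linear
8-bit min–max normalization, threshold segmentation of the contiguous
fluorescent region, and two diffusion-radius definitions — followed by group
statistics. `vitrospread` implements that chain as tested, reusable R
functions for researchers working on intravitreal drug delivery and ocular
pharmacokinetics.

## What it computes

**Measurement side** (per photograph, on the green channel):

- background subtraction using a dye-free region, then linear rescaling so the
  image minimum maps to 0 and the maximum to 255;
- a threshold sweep (30, 50, 70, 90, 120, 150, 200 intensity units) and, at the
  working threshold of 70, selection of one contiguous (8-connected)
  fluorescent region;
- **area percentage**: region area relative to the eye area, with the eye area
  approximated as a circle from the averaged nasal–temporal and
  inferior–superior diameters, `A = π (d̄/2)²`;
- **Feret radius**: half the largest observable diameter of the region
  (maximum pairwise pixel distance / 2);
- **centroid radius**: distance from the region centroid to its most distant
  boundary pixel;
- nasal/temporal hemifield split of the signal, and an 8-repeat repeatability
  audit of the automated radius measurement;
- group statistics: pooled-variance Student's *t*-test (Welch by flag), one-way
  ANOVA with post hoc Tukey HSD, and `*`/`**`/`***` tiers at p < 0.05 / 0.01 /
  0.001.

**Simulation side** (ground-truthed synthetic eyes): a dye bolus placed where a
pars-plana needle would deposit it diffuses inside a disc-shaped eye
cross-section with effective diffusivity

```
D_eff = k_B T / (6 π η r_s) · exp(−(r_s/ξ)²)
```

— Stokes–Einstein diffusivity for a tracer of Stokes radius `r_s` in a medium
of viscosity `η`, damped by an Ogston-type hindrance factor for a polymer mesh
of size `ξ`. The solver is a mass-conserving explicit finite-difference scheme
with no-flux boundaries at the eye wall and at optional occluder compartments
(a bursa-like liquefied pocket that blocks dye entry). Fields are rendered as
noisy 8-bit RGB photographs, so the measurement side can be run unchanged on
synthetic data with known truth.

## Worked example

```r
library(vitrospread)
library(dplyr)

cohort <- generate_cohort("ex_vivo_5dye", n_eyes = 4, seed = 7, times_h = 24)
quant  <- quantify_cohort(cohort, threshold = 70)
quant |> select(eye_id, dye_label, area_percent, radius_centroid_mm) |> head(4)
#>   eye_id           dye_label area_percent radius_centroid_mm
#> 1 ex_vivo_5dye_001 3 kDa             24.8               7.32
#> 2 ex_vivo_5dye_002 3 kDa             34.5               7.60
#> 3 ex_vivo_5dye_003 3 kDa             35.9               7.58
#> 4 ex_vivo_5dye_004 3 kDa             27.2               7.38

cohort_report(quant)$summary
#>   dye_label time_h     n  mean    sd   sem
#> 1 2 MDa         24     4  3.21 0.311 0.155
#> 2 3 kDa         24     4 30.6  5.44  2.72
#> 3 40 kDa        24     4  8.50 0.878 0.439
#> 4 500 kDa       24     4  4.46 0.852 0.426
#> 5 70 kDa        24     4  7.81 1.33  0.666

at <- anova_tukey(quant, area_percent, dye_label)
glance(at)   # F(4, 15) = 76.3, p = 8.7e-10
tidy(at) |> filter(contrast == "3 kDa-2 MDa")
#>   contrast    diff statistic df p_adjusted tier
#> 1 3 kDa-2 MDa 27.4      15.1 15    1.6e-09 ***
```

Reading the output: at 24 h the smallest tracer (3 kDa) covers ~31% of the eye
cross-section while the largest (2 MDa) covers ~3%, the mean area falls
monotonically with molecular size, and the extreme contrast is significant at
the `***` tier — the size-dependent barrier effect the pipeline is built to
measure. Per-eye centroid radii (~7.4 mm for 3 kDa here) quantify the same
spread as a distance.

Four scenario presets ship in `inst/extdata/presets.yaml`: `ex_vivo_5dye`
(five dyes, 24/48 h, cold incubation), `in_vivo_2dye` (physiological
temperature, temporal injections), `plasmin` (enzymatically enlarged mesh) and
`human_bursa` (an impermeable bursa-like pocket). A thin command-line wrapper
(`inst/cli/vitrospread.R`) exposes `simulate`, `quantify`, `report` and
`audit` subcommands over the same functions.

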