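Package: vitrospread
Title: Quantification and Simulation of Intravitreal Dye Spread in Bisected-Eye Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the distribution of fluorescein-dextran tracers
    in photographs of bisected eyes after intravitreal injection: background
    subtraction and linear 8-bit min-max normalization, threshold-sweep
    segmentation of the contiguous fluorescent region, fluorescent-area
    percentage against a circle-approximated eye area, Feret-based and
    centroid-based diffusion radii, nasal/temporal hemifield comparison, and
    group statistics (Student's t-test, one-way ANOVA with post hoc Tukey HSD).
    A companion synthetic-eye generator simulates size-dependent hindered
    diffusion of a dye bolus (Stokes-Einstein diffusivity with an Ogston-type
    mesh hindrance factor) inside a disc-shaped cross-section and renders the
    concentration field as a noisy RGB fluorescence photograph, so that every
    stage of the pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
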