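#' Scenario presets for the cohort generator
#'
#' Reads the packaged YAML preset file (or a user-supplied one) describing the
#' four study designs emulated by the generator: the five-dye two-time-point
#' ex-vivo design, the two-dye in-vivo design, the plasmin-pretreated design
#' (modeled as an enlarged hindrance mesh) and the human design with a
#' bursa-like no-flux pocket.
#'
#' @param path Optional path to a presets YAML; default is the packaged file.
#' @return A named list: `defaults` plus one entry per preset.
#' @export
scenario_presets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "presets.yaml", package = "vitrospread")
  }
  yaml::read_yaml(path)
}

#' Generate a synthetic eye cohort with ground truth
#'
#' For each dye x time group in the preset, simulates `n_eyes` eyes:
#' a randomized eye diameter (uniform in the preset's range), a randomized or
#' fixed injection side, hindered diffusion of the bolus to the group's time
#' point, and a rendered noisy RGB photograph. Every image carries the true
#' disc geometry in its metadata, and the returned `truth` tibble records the
#' generating parameters per eye.
#'
#' @param preset Preset name (see [scenario_presets()]).
#' @param n_eyes Eyes per dye x time group.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(preset, n_eyes, seed)`.
#' @param times_h Optional override of the preset's time points (hours).
#' @param dyes Optional override of the preset's dye labels.
#' @param presets Parsed preset list, defaulting to the packaged one.
#' @param cells_across Grid cells across the eye diameter.
#' @return An `eye_cohort`: list with `images` (named list of [eye_image()]),
#'   `truth` (tibble: eye_id, preset, model, dye_label, stokes_radius_nm,
#'   d_eff_mm2_h, eye_diameter_mm, injection_side, time_h, seed,
#'   occluder_wkt) and `preset`.
#' @export
generate_cohort <- function(preset, n_eyes, seed = 1L, times_h = NULL,
                            dyes = NULL, presets = scenario_presets(),
                            cells_across = NULL) {
  if (n_eyes < 1L) stop("n_eyes must be >= 1", call. = FALSE)
  if (!preset %in% names(presets$presets)) {
    stop("unknown preset '", preset, "'. Known: ",
         paste(names(presets$presets), collapse = ", "), call. = FALSE)
  }
  def <- presets$defaults
  ps <- presets$presets[[preset]]
  times_h <- times_h %||% unlist(ps$times_h)
  dye_labels <- dyes %||% unlist(ps$dyes)
  cells_across <- cells_across %||% def$cells_across
  mesh_nm <- (ps$mesh_size_nm %||% def$mesh_size_nm) *
    (ps$mesh_multiplier %||% 1)
  cat_ <- dye_catalog()
  groups <- tidyr::expand_grid(dye_label = dye_labels, time_h = times_h)

  withr::with_seed(as.integer(seed), {
    rows <- list()
    images <- list()
    idx <- 0L
    for (g in seq_len(nrow(groups))) {
      dy <- dye_spec(groups$dye_label[g])
      t_h <- groups$time_h[g]
      for (e in seq_len(n_eyes)) {
        idx <- idx + 1L
        diam <- stats::runif(1, ps$eye_diameter_range_mm[[1]],
                             ps$eye_diameter_range_mm[[2]])
        side <- if (isTRUE(ps$randomize_side)) {
          sample(c("nasal", "temporal"), 1L)
        } else {
          ps$side %||% "temporal"
        }
        render_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        occluders <- list()
        occ_wkt <- ""
        if (!is.null(ps$bursa)) {
          ctr <- unlist(ps$bursa$center_frac) * diam / 2
          poly <- occluder_disc(ctr, ps$bursa$radius_mm,
                                ps$bursa$n_vertices %||% 24L)
          occluders <- list(poly)
          occ_wkt <- polygon_wkt(poly)
        }
        cfg <- sim_config(
          eye_diameter_mm = diam,
          grid_spacing_mm = diam / cells_across,
          injection_offset_mm = ps$injection_offset_mm,
          injection_side = side,
          needle_depth_frac = ps$needle_depth_frac %||% def$needle_depth_frac,
          bolus_sigma_mm = ps$bolus_sigma_mm %||% def$bolus_sigma_mm,
          bolus_mass = ps$bolus_mass %||% def$bolus_mass,
          temperature = ps$temperature_k,
          viscosity = ps$viscosity_pa_s %||% def$viscosity_pa_s,
          mesh_size_nm = mesh_nm,
          duration_h = t_h, output_times_h = t_h,
          occluders = occluders, seed = render_seed
        )
        d_eff <- stokes_einstein_diffusivity(
          dy$stokes_radius_nm, cfg$temperature, cfg$viscosity, cfg$mesh_size_nm
        )
        fld <- simulate_diffusion(initialize_bolus(cfg), d_eff, t_h)[[1]]
        eye_id <- sprintf("%s_%03d", preset, idx)
        n_px <- nrow(fld$grid)
        md <- list(
          eye_id = eye_id, model = ps$model, dye_label = dy$label,
          time_h = t_h, side = side, eye_diameter_mm = diam,
          center_px = c((n_px - 1) / 2, (n_px - 1) / 2),
          radius_px = (diam / 2) / fld$grid_spacing_mm,
          occluder_wkt = occ_wkt
        )
        img <- render_image(fld, render_config(
          background_level = ps$background_level %||% def$background_level,
          noise_sigma = ps$noise_sigma %||% def$noise_sigma,
          auto_target = ps$auto_target %||% def$auto_target,
          seed = render_seed
        ), metadata = md)
        images[[eye_id]] <- img
        rows[[idx]] <- tibble::tibble(
          eye_id = eye_id, preset = preset, model = ps$model,
          dye_label = dy$label, stokes_radius_nm = dy$stokes_radius_nm,
          d_eff_mm2_h = d_eff, eye_diameter_mm = diam, injection_side = side,
          time_h = t_h, seed = as.integer(seed), occluder_wkt = occ_wkt
        )
      }
    }
    structure(list(images = images, truth = dplyr::bind_rows(rows),
                   preset = preset),
              class = "eye_cohort")
  })
}

polygon_wkt <- function(poly) {
  poly <- close_polygon(as.matrix(poly))
  paste0("POLYGON((",
         paste(sprintf("%.4f %.4f", poly[, 1], poly[, 2]), collapse = ", "),
         "))")
}

#' @export
print.eye_cohort <- function(x, ...) {
  cat(sprintf("<eye_cohort> preset '%s': %d eyes, %d dye x time groups\n",
              x$preset, nrow(x$truth),
              nrow(dplyr::distinct(x$truth, .data$dye_label, .data$time_h))))
  invisible(x)
}

#' Quantify every eye of a synthetic cohort
#'
#' Runs the measurement pipeline per image — green channel, background
#' subtraction over the outside-the-eye region, min-max normalization,
#' threshold segmentation and all per-eye metrics — and returns one tidy row
#' per eye, ready for [cohort_report()].
#'
#' @param cohort An `eye_cohort` from [generate_cohort()].
#' @param threshold Segmentation threshold (default 70).
#' @param denominator Passed to [area_percent()].
#' @return A tibble: one [measure_eye()] row per eye joined with the cohort's
#'   ground-truth columns.
#' @export
quantify_cohort <- function(cohort, threshold = 70,
                            denominator = c("circle", "mask")) {
  stopifnot(inherits(cohort, "eye_cohort"))
  denominator <- match.arg(denominator)
  res <- purrr::map(cohort$images, function(img) {
    norm <- preprocess_image(img, background_region = outside_eye_region(img))
    bnd <- true_boundary(img)
    measure_eye(norm, bnd, metadata = img$metadata, threshold = threshold,
                denominator = denominator)
  })
  meas <- dplyr::bind_rows(res)
  dplyr::left_join(
    meas,
    dplyr::select(cohort$truth, "eye_id", "stokes_radius_nm", "d_eff_mm2_h",
                  "eye_diameter_mm", "occluder_wkt"),
    by = "eye_id"
  )
}

#' Estimate diffusivity from the growth of the measured radius
#'
#' For a freely spreading Gaussian bolus the pixels above a normalized
#' threshold \eqn{\tau} form a disc of squared radius
#' \eqn{r^2(t) = 2\,\ln(255/\tau)\,(\sigma_0^2 + 2Dt)}, so the slope of a
#' straight-line fit of the measured radius squared against time recovers the
#' diffusivity as \eqn{\hat D = \mathrm{slope} / (4 \ln(255/\tau))}.
#'
#' @param data A data frame with one measured radius per time point.
#' @param time Column with time in hours (tidy-eval).
#' @param radius Column with the radius in mm (tidy-eval).
#' @param threshold Normalized threshold used for segmentation.
#' @return A one-row tibble: `d_mm2_h` (the estimate), `slope`, `intercept`,
#'   `sigma0_mm` (implied initial width), `r_squared`, `n`.
#' @export
fit_spread_rate <- function(data, time = time_h, radius = radius_centroid_mm,
                            threshold = 70) {
  t_h <- dplyr::pull(data, {{ time }})
  r_mm <- dplyr::pull(data, {{ radius }})
  ok <- is.finite(t_h) & is.finite(r_mm)
  if (sum(ok) < 3L) stop("need at least 3 time points to fit", call. = FALSE)
  fit <- stats::lm(I(r_mm[ok]^2) ~ t_h[ok])
  sl <- unname(stats::coef(fit)[2])
  ic <- unname(stats::coef(fit)[1])
  lfac <- 2 * log(255 / threshold)
  tibble::tibble(
    d_mm2_h = sl / (2 * lfac),
    slope = sl, intercept = ic,
    sigma0_mm = if (ic > 0) sqrt(ic / lfac) else NA_real_,
    r_squared = summary(fit)$r.squared,
    n = sum(ok)
  )
}
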