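#' Simulation configuration for the synthetic eye
#'
#' Bundles the geometry and physics of one simulated eye cross-section: a disc
#' of diameter `eye_diameter_mm` on a Cartesian grid, an injected Gaussian
#' bolus placed where a pars-plana needle would deposit it, medium conditions
#' (temperature, effective viscosity, mesh size) and optional no-flux occluder
#' compartments (a bursa-like liquefied pocket that blocks dye entry).
#'
#' The injection geometry mirrors the bench procedure: the needle enters
#' `injection_offset_mm` from the boundary (the limbus analog) on the
#' configured side and is advanced toward the center; the bolus center sits on
#' that entry-to-center segment at fraction `needle_depth_frac` of the way to
#' the center. By image convention the nasal side is the left half
#' (negative x) and the temporal side the right half.
#'
#' @param eye_diameter_mm Eye (disc) diameter in mm.
#' @param grid_spacing_mm Cell size in mm; must give at least 50 cells across
#'   the eye. Default resolves 128 cells across.
#' @param injection_offset_mm Distance of the needle entry point from the
#'   boundary, mm.
#' @param injection_side `"nasal"` or `"temporal"`.
#' @param needle_depth_frac Fraction of the entry-to-center segment at which
#'   the bolus is centered.
#' @param bolus_sigma_mm Initial Gaussian width of the bolus, mm.
#' @param bolus_mass Total injected mass (arbitrary units).
#' @param temperature Kelvin. 277.15 matches cold ex-vivo incubation;
#'   310.15 is physiological.
#' @param viscosity Effective medium viscosity, Pa s.
#' @param mesh_size_nm Hindrance mesh size, nm.
#' @param duration_h Total simulated time, hours.
#' @param output_times_h Times (hours) at which fields are returned.
#' @param occluders List of closed polygons (two-column matrices of x, y in mm,
#'   origin at the disc center, y downward) treated as impermeable, dye-free
#'   compartments.
#' @param seed Integer seed used by downstream stochastic steps.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(eye_diameter_mm = 22.8,
                       grid_spacing_mm = eye_diameter_mm / 128,
                       injection_offset_mm = 4,
                       injection_side = c("temporal", "nasal"),
                       needle_depth_frac = 0.25,
                       bolus_sigma_mm = 1.0,
                       bolus_mass = 1.0,
                       temperature = 277.15,
                       viscosity = 2e-3,
                       mesh_size_nm = 550,
                       duration_h = 24,
                       output_times_h = duration_h,
                       occluders = list(),
                       seed = 1L) {
  injection_side <- match.arg(injection_side)
  cfg <- list(
    eye_diameter_mm = eye_diameter_mm, grid_spacing_mm = grid_spacing_mm,
    injection_offset_mm = injection_offset_mm, injection_side = injection_side,
    needle_depth_frac = needle_depth_frac, bolus_sigma_mm = bolus_sigma_mm,
    bolus_mass = bolus_mass, temperature = temperature, viscosity = viscosity,
    mesh_size_nm = mesh_size_nm, duration_h = duration_h,
    output_times_h = sort(output_times_h), occluders = occluders,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(grid_spacing_mm > 0 && grid_spacing_mm <= eye_diameter_mm / 50)) {
      stop("grid_spacing_mm must be in (0, eye_diameter_mm/50]: ",
           "need at least 50 cells across the eye", call. = FALSE)
    }
    if (!(injection_offset_mm > 0 && injection_offset_mm < eye_diameter_mm / 2)) {
      stop("injection_offset_mm must lie in (0, eye radius)", call. = FALSE)
    }
    if (temperature <= 0 || viscosity <= 0 || mesh_size_nm <= 0 ||
        bolus_sigma_mm <= 0 || bolus_mass <= 0) {
      stop("temperature, viscosity, mesh_size_nm, bolus_sigma_mm and ",
           "bolus_mass must all be > 0", call. = FALSE)
    }
    if (needle_depth_frac < 0 || needle_depth_frac >= 1) {
      stop("needle_depth_frac must be in [0, 1)", call. = FALSE)
    }
    if (any(output_times_h < 0)) stop("output times must be >= 0", call. = FALSE)
  })
  r <- cfg$eye_diameter_mm / 2
  inj <- injection_point(cfg)
  for (poly in cfg$occluders) {
    poly <- as.matrix(poly)
    if (ncol(poly) != 2) stop("occluder polygons need two columns (x, y)", call. = FALSE)
    if (any(sqrt(rowSums(poly^2)) >= r)) {
      stop("occluder polygons must lie entirely inside the eye disc", call. = FALSE)
    }
    if (mgcv::in.out(close_polygon(poly), matrix(inj, ncol = 2))) {
      stop("occluder polygons must exclude the injection point", call. = FALSE)
    }
  }
  cfg
}

# bolus center (x, y) in mm, origin at disc center; nasal = -x, temporal = +x
injection_point <- function(cfg) {
  r <- cfg$eye_diameter_mm / 2
  sgn <- if (cfg$injection_side == "temporal") 1 else -1
  entry_x <- sgn * (r - cfg$injection_offset_mm)
  c(entry_x * (1 - cfg$needle_depth_frac), 0)
}

close_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Regular-polygon occluder helper
#'
#' Convenience constructor for a disc-like occluder polygon, e.g. a bursa-like
#' liquefied compartment.
#'
#' @param center_mm Length-2 center (x, y) in mm, origin at the disc center.
#' @param radius_mm Polygon circumradius in mm.
#' @param n_vertices Number of vertices.
#' @return A two-column matrix of vertices.
#' @export
occluder_disc <- function(center_mm, radius_mm, n_vertices = 24L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = center_mm[1] + radius_mm * cos(th),
        y = center_mm[2] + radius_mm * sin(th))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n",
      sprintf("  eye %.2f mm across, grid %.3f mm (%d cells across)\n",
              x$eye_diameter_mm, x$grid_spacing_mm,
              round(x$eye_diameter_mm / x$grid_spacing_mm)),
      sprintf("  injection: %s side, %.1f mm from limbus, depth frac %.2f\n",
              x$injection_side, x$injection_offset_mm, x$needle_depth_frac),
      sprintf("  medium: T = %.2f K, eta = %.3g Pa s, mesh = %.0f nm\n",
              x$temperature, x$viscosity, x$mesh_size_nm),
      sprintf("  %d occluder(s); output at %s h\n", length(x$occluders),
              paste(x$output_times_h, collapse = ", ")), sep = "")
  invisible(x)
}
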