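#' Built-in FITC-dextran dye catalog
#'
#' Hydrodynamic (Stokes) radii for the FITC-dextran tracers used throughout
#' the package. Molecular weight tracks hydrodynamic size, so the catalog is
#' strictly increasing in `stokes_radius_nm`. The 3 kDa radius is not part of
#' the published radii for these conjugates; it is an extrapolated default
#' (flagged in the `extrapolated` column) and can be overridden wherever a
#' `stokes_radius_nm` argument is accepted.
#'
#' @return A tibble with columns `label`, `molecular_weight_da`,
#'   `stokes_radius_nm` and `extrapolated`.
#' @examples
#' dye_catalog()
#' @export
dye_catalog <- function() {
  tibble::tibble(
    label = c("3 kDa", "40 kDa", "70 kDa", "500 kDa", "2 MDa"),
    molecular_weight_da = c(3e3, 40e3, 70e3, 500e3, 2e6),
    stokes_radius_nm = c(1.3, 4.5, 5.8, 14.7, 27),
    extrapolated = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Look up a dye by label
#'
#' @param label Dye label, e.g. `"40 kDa"`.
#' @return One catalog row as a tibble.
#' @export
dye_spec <- function(label) {
  cat_ <- dye_catalog()
  hit <- cat_[cat_$label == label, ]
  if (nrow(hit) != 1L) {
    stop("Unknown dye label '", label, "'. Known: ",
         paste(cat_$label, collapse = ", "), call. = FALSE)
  }
  hit
}

# Boltzmann constant, J/K (exact, SI 2019)
.kB <- 1.380649e-23

#' Hindered Stokes-Einstein diffusivity
#'
#' Effective diffusivity of a tracer of Stokes radius \eqn{r_s} in a mesh-like
#' medium, \deqn{D_{eff} = \frac{k_B T}{6\pi\eta r_s}\,
#' \exp\!\left[-(r_s/\xi)^2\right],} i.e. the Stokes-Einstein free diffusivity
#' damped by an Ogston-type hindrance factor for a polymer network of
#' characteristic mesh size \eqn{\xi}. With `mesh_size_nm = Inf` the hindrance
#' is disabled and the bare Stokes-Einstein value is returned.
#'
#' @param stokes_radius_nm Stokes radius in nanometers (vectorized).
#' @param temperature Absolute temperature in kelvin.
#' @param viscosity Effective medium viscosity in pascal-seconds
#'   (water at 4 C is about 1.57e-3; the default 2e-3 stands for a vitreous-like
#'   effective value).
#' @param mesh_size_nm Hindrance length \eqn{\xi} in nanometers; `Inf` disables
#'   hindrance.
#' @return Effective diffusivity in mm^2/hour.
#' @examples
#' stokes_einstein_diffusivity(4.5, temperature = 277.15, viscosity = 1e-3,
#'                             mesh_size_nm = Inf)
#' @export
stokes_einstein_diffusivity <- function(stokes_radius_nm,
                                        temperature = 277.15,
                                        viscosity = 2e-3,
                                        mesh_size_nm = 550) {
  if (any(!is.finite(stokes_radius_nm)) || any(stokes_radius_nm <= 0)) {
    stop("stokes_radius_nm must be finite and > 0", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  if (viscosity <= 0) stop("viscosity must be > 0 Pa s", call. = FALSE)
  if (any(mesh_size_nm <= 0)) stop("mesh_size_nm must be > 0", call. = FALSE)
  r_m <- stokes_radius_nm * 1e-9
  d_m2_s <- .kB * temperature / (6 * pi * viscosity * r_m)
  hindrance <- exp(-(stokes_radius_nm / mesh_size_nm)^2)
  # m^2/s -> mm^2/h: 1e6 mm^2 per m^2, 3600 s per h
  d_m2_s * hindrance * 1e6 * 3600
}

#' Effective diffusivities for a table of dyes
#'
#' Data-frame-first convenience wrapper: adds a `d_eff_mm2_h` column to a dye
#' table (such as [dye_catalog()]) under given medium conditions.
#'
#' @param dyes A data frame with a `stokes_radius_nm` column.
#' @inheritParams stokes_einstein_diffusivity
#' @return The input tibble with `d_eff_mm2_h` appended.
#' @export
dye_diffusivities <- function(dyes, temperature = 277.15, viscosity = 2e-3,
                              mesh_size_nm = 550) {
  stopifnot(is.data.frame(dyes), "stokes_radius_nm" %in% names(dyes))
  dplyr::mutate(
    tibble::as_tibble(dyes),
    d_eff_mm2_h = stokes_einstein_diffusivity(
      .data$stokes_radius_nm, temperature, viscosity, mesh_size_nm
    )
  )
}
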