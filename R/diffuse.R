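#' Simulate hindered diffusion of the bolus
#'
#' Integrates \eqn{\partial C/\partial t = D \nabla^2 C} on the masked grid
#' with an explicit forward-time centered-space (FTCS) scheme written in flux
#' form: dye moves only across faces whose two cells are both inside the
#' domain, so the eye wall and occluder edges are no-flux (reflecting)
#' boundaries and total mass is conserved to machine precision. The internal
#' time step honors the 2-D stability bound, `dt = safety * dx^2 / (4 D)`.
#'
#' @param field Starting [conc_field()].
#' @param diffusivity Effective diffusivity, mm^2/h (see
#'   [stokes_einstein_diffusivity()]).
#' @param output_times_h Increasing times (hours, `>= field$time_h`) at which
#'   snapshots are returned.
#' @param safety Stability safety factor in (0, 1].
#' @return A list of `conc_field` objects, one per output time.
#' @export
simulate_diffusion <- function(field, diffusivity, output_times_h,
                               safety = 0.9) {
  stopifnot(inherits(field, "conc_field"))
  if (diffusivity < 0) stop("diffusivity must be >= 0", call. = FALSE)
  if (safety <= 0 || safety > 1) stop("safety must be in (0, 1]", call. = FALSE)
  output_times_h <- sort(output_times_h)
  if (any(output_times_h < field$time_h)) {
    stop("output times must not precede the field's current time", call. = FALSE)
  }
  C <- field$grid
  m <- field$domain_mask
  dx <- field$grid_spacing_mm
  t_now <- field$time_h
  out <- vector("list", length(output_times_h))
  for (k in seq_along(output_times_h)) {
    t_target <- output_times_h[k]
    if (diffusivity > 0 && t_target > t_now) {
      C <- ftcs_advance(C, m, diffusivity, dx, t_target - t_now, safety)
    }
    t_now <- t_target
    out[[k]] <- conc_field(C, m, time_h = t_now, grid_spacing_mm = dx)
  }
  out
}

# Advance C by `span` hours with n equal FTCS steps under the stability bound.
ftcs_advance <- function(C, mask, D, dx, span, safety = 0.9) {
  dt_max <- safety * dx^2 / (4 * D)
  n_steps <- max(1L, ceiling(span / dt_max))
  lam <- D * (span / n_steps) / dx^2
  nr <- nrow(C)
  nc <- ncol(C)
  md <- mask * 1
  wv <- md[-nr, ] * md[-1, ]   # vertical faces (between row i and i+1)
  wh <- md[, -nc] * md[, -1]   # horizontal faces
  for (s in seq_len(n_steps)) {
    fv <- (C[-nr, ] - C[-1, ]) * wv   # downward flux across vertical faces
    fh <- (C[, -nc] - C[, -1]) * wh
    net <- matrix(0, nr, nc)
    net[-1, ] <- fv
    net[-nr, ] <- net[-nr, ] - fv
    net[, -1] <- net[, -1] + fh
    net[, -nc] <- net[, -nc] - fh
    C <- C + lam * net
  }
  C
}

#' Simulate one synthetic eye end to end
#'
#' Convenience wrapper: builds the bolus from `config`, computes the dye's
#' effective diffusivity under the configured medium and integrates to the
#' configured output times.
#'
#' @param config A [sim_config()].
#' @param stokes_radius_nm Tracer Stokes radius, nm.
#' @return A list of `conc_field` snapshots at `config$output_times_h`.
#' @export
simulate_eye <- function(config, stokes_radius_nm) {
  d_eff <- stokes_einstein_diffusivity(
    stokes_radius_nm, config$temperature, config$viscosity, config$mesh_size_nm
  )
  simulate_diffusion(initialize_bolus(config), d_eff, config$output_times_h)
}
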