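#' Concentration fields on a masked grid
#'
#' A `conc_field` holds a 2-D grid of dye mass per cell, a boolean domain mask
#' (inside the eye disc, outside any occluder), the simulation time in hours
#' and the grid spacing in mm. Matrix rows are image rows (y, downward) and
#' columns are x (rightward); cell centers carry mm coordinates with the
#' origin at the disc center.
#'
#' @param grid Numeric matrix, mass per cell; zero outside `domain_mask`.
#' @param domain_mask Logical matrix, same shape.
#' @param time_h Simulation time, hours.
#' @param grid_spacing_mm Cell size, mm.
#' @return An object of class `conc_field`.
#' @export
conc_field <- function(grid, domain_mask, time_h, grid_spacing_mm) {
  stopifnot(is.matrix(grid), is.matrix(domain_mask),
            all(dim(grid) == dim(domain_mask)))
  if (any(grid < 0)) stop("concentration must be >= 0 everywhere", call. = FALSE)
  if (any(grid[!domain_mask] != 0)) {
    stop("concentration must be exactly 0 outside the domain mask", call. = FALSE)
  }
  structure(
    list(grid = grid, domain_mask = domain_mask, time_h = time_h,
         grid_spacing_mm = grid_spacing_mm),
    class = "conc_field"
  )
}

# mm coordinates of cell centers for an n_row x n_col grid centered on origin
grid_coords <- function(n_row, n_col, dx) {
  list(
    x = (seq_len(n_col) - (n_col + 1) / 2) * dx,
    y = (seq_len(n_row) - (n_row + 1) / 2) * dx
  )
}

# Domain mask for a config: disc minus occluders, on a grid with margin cells
# so rendered images are at least 64 px across.
domain_geometry <- function(cfg, margin_cells = 6L) {
  dx <- cfg$grid_spacing_mm
  n <- ceiling(cfg$eye_diameter_mm / dx) + 2L * margin_cells
  n <- max(n, 64L)
  co <- grid_coords(n, n, dx)
  xg <- matrix(co$x, n, n, byrow = TRUE)
  yg <- matrix(co$y, n, n)
  mask <- (xg^2 + yg^2) <= (cfg$eye_diameter_mm / 2)^2
  for (poly in cfg$occluders) {
    pts <- cbind(as.vector(xg), as.vector(yg))
    inside <- mgcv::in.out(close_polygon(as.matrix(poly)), pts)
    mask <- mask & !matrix(inside, n, n)
  }
  list(n = n, dx = dx, x = co$x, y = co$y, xg = xg, yg = yg, mask = mask)
}

#' Initialize the injected bolus
#'
#' Places an isotropic Gaussian of width `bolus_sigma_mm` at the needle-tip
#' position implied by the injection geometry, truncates it to the domain
#' (eye disc minus occluders) and renormalizes so the total mass equals
#' `bolus_mass`.
#'
#' @param config A [sim_config()].
#' @return A [conc_field()] at time 0 whose grid sums to `config$bolus_mass`.
#' @export
initialize_bolus <- function(config) {
  geo <- domain_geometry(config)
  ctr <- injection_point(config)
  if (!any(geo$mask)) stop("empty domain", call. = FALSE)
  # the bolus center must be a live domain cell
  i <- which.min(abs(geo$y - ctr[2]))
  j <- which.min(abs(geo$x - ctr[1]))
  if (!geo$mask[i, j]) {
    stop("bolus center falls outside the domain (occluded or out of disc)",
         call. = FALSE)
  }
  s2 <- config$bolus_sigma_mm^2
  g <- exp(-((geo$xg - ctr[1])^2 + (geo$yg - ctr[2])^2) / (2 * s2))
  g[!geo$mask] <- 0
  g <- g * (config$bolus_mass / sum(g))
  conc_field(g, geo$mask, time_h = 0, grid_spacing_mm = geo$dx)
}

#' Total mass and spatial moments of a field
#'
#' @param field A [conc_field()].
#' @return A one-row tibble with `mass`, centroid (`mx_mm`, `my_mm`) and the
#'   per-axis-averaged second central moment `sigma2_mm2`
#'   (\eqn{(Var[x]+Var[y])/2}), the quantity that grows as
#'   \eqn{\sigma^2(t) = \sigma_0^2 + 2Dt} for free diffusion.
#' @export
field_moments <- function(field) {
  stopifnot(inherits(field, "conc_field"))
  n <- dim(field$grid)
  co <- grid_coords(n[1], n[2], field$grid_spacing_mm)
  w <- field$grid
  m <- sum(w)
  wx <- colSums(w)  # weight per x (column)
  wy <- rowSums(w)
  mx <- sum(wx * co$x) / m
  my <- sum(wy * co$y) / m
  v <- (sum(wx * (co$x - mx)^2) + sum(wy * (co$y - my)^2)) / m / 2
  tibble::tibble(mass = m, mx_mm = mx, my_mm = my, sigma2_mm2 = v,
                 time_h = field$time_h)
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("<conc_field> %d x %d cells, %.3f mm/cell, t = %.2f h, mass = %.6g\n",
              nrow(x$grid), ncol(x$grid), x$grid_spacing_mm, x$time_h,
              sum(x$grid)))
  invisible(x)
}
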