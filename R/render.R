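#' Camera model for rendering synthetic fluorescence photographs
#'
#' @param gain Green intensity units per unit concentration; `NA` requests
#'   auto-exposure (gain chosen so the peak green level sits at
#'   `auto_target` above background, emulating per-shot exposure control).
#' @param background_level Additive background, 0-255 scale.
#' @param noise_sigma Gaussian read-noise standard deviation, intensity units.
#' @param vignette_strength 0-1; darkening toward the image corners.
#' @param auto_target Peak (green - background) level targeted by
#'   auto-exposure.
#' @param seed Integer seed making the noise reproducible.
#' @return An object of class `render_config`.
#' @export
render_config <- function(gain = NA_real_, background_level = 12,
                          noise_sigma = 2, vignette_strength = 0,
                          auto_target = 200, seed = 1L) {
  if (!is.na(gain) && gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (background_level < 0 || background_level >= 255) {
    stop("background_level must be in [0, 255)", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (vignette_strength < 0 || vignette_strength > 1) {
    stop("vignette_strength must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(gain = gain, background_level = background_level,
         noise_sigma = noise_sigma, vignette_strength = vignette_strength,
         auto_target = auto_target, seed = as.integer(seed)),
    class = "render_config"
  )
}

# round half away from zero (used everywhere an 8-bit value is quantized,
# because half-cases move threshold masks)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip8 <- function(x) pmin(pmax(round_half_away(x), 0), 255)

#' Render a concentration field as an RGB eye photograph
#'
#' Forward camera model: the green channel is
#' `clip(background + gain * C + vignette + noise, 0, 255)`; red and blue carry
#' `background/2 + noise` only. The vignette term is
#' `-strength * 255 * (r / r_corner)^2` with `r` the distance from the image
#' center. Noise is i.i.d. Gaussian, seeded and independent per channel.
#'
#' @param field A [conc_field()].
#' @param render A [render_config()].
#' @param metadata Named list stored on the image (dye label, time, side, ...).
#' @return An `eye_image`: integer array `[rows, cols, 3]` in 0-255 plus
#'   `pixel_scale_mm` (= the field's grid spacing) and metadata.
#' @export
render_image <- function(field, render = render_config(), metadata = list()) {
  stopifnot(inherits(field, "conc_field"), inherits(render, "render_config"))
  C <- field$grid
  nr <- nrow(C)
  nc <- ncol(C)
  gain <- render$gain
  if (is.na(gain)) {
    peak <- max(C)
    gain <- if (peak > 0) render$auto_target / peak else 1
  }
  vig <- 0
  if (render$vignette_strength > 0) {
    co <- grid_coords(nr, nc, 1)
    r2 <- outer(co$y^2, co$x^2, `+`)
    vig <- -render$vignette_strength * 255 * r2 / max(r2)
  }
  noise <- withr::with_seed(render$seed, {
    array(stats::rnorm(nr * nc * 3L, 0, render$noise_sigma), c(nr, nc, 3L))
  })
  if (render$noise_sigma == 0) noise <- array(0, c(nr, nc, 3L))
  img <- array(0L, c(nr, nc, 3L))
  img[, , 2] <- clip8(render$background_level + gain * C + vig + noise[, , 2])
  img[, , 1] <- clip8(render$background_level / 2 + noise[, , 1])
  img[, , 3] <- clip8(render$background_level / 2 + noise[, , 3])
  storage.mode(img) <- "integer"
  eye_image(img, pixel_scale_mm = field$grid_spacing_mm, metadata = metadata)
}

#' RGB eye photograph container
#'
#' @param pixels Integer array `[rows, cols, 3]`, values 0-255.
#' @param pixel_scale_mm Physical size of one pixel, mm.
#' @param metadata Named list (eye_id, dye label, time point, injection side,
#'   model tag, ...).
#' @return An object of class `eye_image`.
#' @export
eye_image <- function(pixels, pixel_scale_mm, metadata = list()) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(dim(pixels)[1:2] < 64L)) {
    stop("eye images must be at least 64 x 64 pixels", call. = FALSE)
  }
  if (pixel_scale_mm <= 0) stop("pixel_scale_mm must be > 0", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in 0-255", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_scale_mm = pixel_scale_mm,
                 metadata = metadata),
            class = "eye_image")
}

#' @export
print.eye_image <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<eye_image> %d x %d px, %.4f mm/px%s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$pixel_scale_mm,
              if (!is.null(md$eye_id)) paste0(", id ", md$eye_id) else ""))
  invisible(x)
}
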