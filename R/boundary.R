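#' Eye boundary from a drawn polygon
#'
#' Wraps the manually drawn (or, for synthetic eyes, ground-truth) eye outline:
#' the polygon, its rasterized interior mask, the two orthogonal diameters
#' (nasal-temporal = horizontal extent, inferior-superior = vertical extent,
#' unless supplied from caliper measurements) and the circle-approximated eye
#' area \eqn{\pi (\bar d / 2)^2} with \eqn{\bar d} the mean of the two
#' diameters.
#'
#' Pixel coordinates are 0-based, pixel-center convention: x grows rightward
#' (columns), y downward (rows).
#'
#' @param polygon Two-column matrix or data frame of vertices (x, y) in pixel
#'   coordinates; must be a simple closed polygon.
#' @param image_dim Length-2 integer `(rows, cols)` of the image the boundary
#'   belongs to.
#' @param pixel_scale_mm Physical pixel size, mm.
#' @param diameter_nt_mm,diameter_is_mm Optional caliper diameters, mm;
#'   computed from the polygon extents when missing.
#' @return An object of class `eye_boundary` with fields `polygon`, `mask`,
#'   `diameter_nt_mm`, `diameter_is_mm`, `mean_diameter_mm`, `circle_area_mm2`,
#'   `pixel_scale_mm`.
#' @export
eye_boundary <- function(polygon, image_dim, pixel_scale_mm,
                         diameter_nt_mm = NULL, diameter_is_mm = NULL) {
  poly <- as.matrix(polygon)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  if (is_self_intersecting(poly)) {
    stop("eye boundary polygon must be simple (non-self-intersecting)",
         call. = FALSE)
  }
  nr <- image_dim[1]
  nc <- image_dim[2]
  pts <- cbind(rep(seq_len(nc) - 1, each = nr), rep(seq_len(nr) - 1, nc))
  inside <- mgcv::in.out(close_polygon(poly), pts)
  mask <- matrix(inside, nr, nc)
  if (is.null(diameter_nt_mm)) {
    diameter_nt_mm <- diff(range(poly[, 1])) * pixel_scale_mm
  }
  if (is.null(diameter_is_mm)) {
    diameter_is_mm <- diff(range(poly[, 2])) * pixel_scale_mm
  }
  mean_d <- (diameter_nt_mm + diameter_is_mm) / 2
  structure(
    list(polygon = poly, mask = mask,
         diameter_nt_mm = diameter_nt_mm, diameter_is_mm = diameter_is_mm,
         mean_diameter_mm = mean_d, circle_area_mm2 = pi * (mean_d / 2)^2,
         pixel_scale_mm = pixel_scale_mm),
    class = "eye_boundary"
  )
}

# segment-intersection test over non-adjacent edges; O(n^2), n is small for
# hand-drawn outlines
is_self_intersecting <- function(poly) {
  n <- nrow(poly)
  p <- rbind(poly, poly[1, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- cross(b1, b2, a1); d2 <- cross(b1, b2, a2)
    d3 <- cross(a1, a2, b1); d4 <- cross(a1, a2, b2)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent around the loop
      if (seg_int(p[i, ], p[i + 1, ], p[j, ], p[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Ground-truth boundary for a synthetic eye image
#'
#' Synthetic images carry the true disc geometry in their metadata; this
#' builds the corresponding [eye_boundary()] as a regular polygon, standing in
#' for the outline an analyst would draw by hand.
#'
#' @param image An [eye_image()] produced by [generate_cohort()].
#' @param n_vertices Number of polygon vertices.
#' @return An `eye_boundary`.
#' @export
true_boundary <- function(image, n_vertices = 72L) {
  md <- image$metadata
  if (is.null(md$center_px) || is.null(md$radius_px)) {
    stop("image metadata lacks the true disc geometry (center_px/radius_px)",
         call. = FALSE)
  }
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  poly <- cbind(md$center_px[1] + md$radius_px * cos(th),
                md$center_px[2] + md$radius_px * sin(th))
  eye_boundary(poly, dim(image$pixels)[1:2], image$pixel_scale_mm,
               diameter_nt_mm = md$eye_diameter_mm,
               diameter_is_mm = md$eye_diameter_mm)
}

#' Signal-free background region for a synthetic eye image
#'
#' All pixels at least `margin_px` outside the true disc — the analog of the
#' dye-free regions used to estimate background in real photographs.
#'
#' @param image An [eye_image()] with true disc metadata.
#' @param margin_px Clearance outside the disc, pixels.
#' @return Logical matrix.
#' @export
outside_eye_region <- function(image, margin_px = 2) {
  md <- image$metadata
  nr <- dim(image$pixels)[1]
  nc <- dim(image$pixels)[2]
  x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr) - 1, nr, nc)
  (x - md$center_px[1])^2 + (y - md$center_px[2])^2 >
    (md$radius_px + margin_px)^2
}

#' @export
print.eye_boundary <- function(x, ...) {
  cat(sprintf(
    "<eye_boundary> %d vertices, diameters %.2f x %.2f mm, circle area %.1f mm^2\n",
    nrow(x$polygon), x$diameter_nt_mm, x$diameter_is_mm, x$circle_area_mm2))
  invisible(x)
}
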