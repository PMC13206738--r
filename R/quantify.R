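#' Threshold sweep over a normalized image
#'
#' Applies each threshold to the eye interior (pixels with intensity
#' `>= tau`, before any connected-component selection) and reports the raw
#' lit-pixel counts, mirroring the systematic evaluation of candidate
#' thresholds before one is fixed for analysis.
#'
#' @param image A `normalized_image` (see [normalize_image()]).
#' @param boundary An [eye_boundary()].
#' @param thresholds Intensity thresholds in 0-255. The default is the
#'   seven-level sweep 30, 50, 70, 90, 120, 150, 200.
#' @return A tibble with one row per threshold: `threshold`, `n_pixels`, and a
#'   `mask` list-column of logical matrices.
#' @export
sweep_thresholds <- function(image, boundary,
                             thresholds = c(30, 50, 70, 90, 120, 150, 200)) {
  stopifnot(inherits(image, "normalized_image"), inherits(boundary, "eye_boundary"))
  if (any(thresholds < 0 | thresholds > 255)) {
    stop("thresholds must lie in [0, 255]", call. = FALSE)
  }
  masks <- purrr::map(thresholds, function(tau) {
    image$pixels >= tau & boundary$mask
  })
  tibble::tibble(
    threshold = thresholds,
    n_pixels = purrr::map_int(masks, sum),
    mask = masks
  )
}

#' Select the contiguous fluorescent region
#'
#' Reduces a thresholded mask to one 8-connected component — the contiguous
#' region carrying the visible fluorescence. With a `seed_point` the component
#' containing it is taken (when lit); otherwise the largest component wins,
#' ties broken by centroid distance to `entry_point` (when given) and then by
#' the lowest row-major pixel index. The fraction of lit pixels left outside
#' the selected component is always reported so the selection is auditable.
#'
#' @param mask Logical matrix of above-threshold pixels inside the boundary.
#' @param boundary Optional [eye_boundary()]; when given, `seed_point` must
#'   fall inside it.
#' @param seed_point Optional `(x, y)` 0-based pixel.
#' @param entry_point Optional `(x, y)` used only to break size ties.
#' @param threshold Threshold recorded on the region (bookkeeping only).
#' @return A `fluor_region`: `mask`, `threshold`, `pixel_count`, `centroid`
#'   (unweighted mean pixel coordinate), `boundary_pixels` (two-column matrix;
#'   region pixels with a 4-neighbor outside the region),
#'   `excluded_signal_fraction` (percent).
#' @export
extract_region <- function(mask, boundary = NULL, seed_point = NULL,
                           entry_point = NULL, threshold = NA_real_) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is.null(seed_point) && !is.null(boundary)) {
    if (!boundary$mask[seed_point[2] + 1L, seed_point[1] + 1L]) {
      stop("seed_point lies outside the eye boundary", call. = FALSE)
    }
  }
  lit <- which(mask)
  if (length(lit) == 0L) {
    return(structure(
      list(mask = mask, threshold = threshold, pixel_count = 0L,
           centroid = c(NA_real_, NA_real_),
           boundary_pixels = matrix(numeric(0), 0, 2),
           excluded_signal_fraction = 0),
      class = "fluor_region"))
  }
  labels <- label_components8(mask, lit)
  chosen <- NA_integer_
  if (!is.null(seed_point)) {
    nr <- nrow(mask)
    # linear index for (x, y): column x (0-based) * nrow + row y (0-based) + 1
    seed_lin <- seed_point[1] * nr + seed_point[2] + 1L
    pos <- match(seed_lin, lit)
    if (!is.na(pos)) chosen <- labels[pos]
  }
  if (is.na(chosen)) {
    sizes <- tabulate(labels)
    top <- which(sizes == max(sizes))
    if (length(top) > 1L && !is.null(entry_point)) {
      nr <- nrow(mask)
      d2 <- vapply(top, function(k) {
        px <- lit[labels == k]
        cx <- mean((px - 1L) %/% nr)
        cy <- mean((px - 1L) %% nr)
        (cx - entry_point[1])^2 + (cy - entry_point[2])^2
      }, numeric(1))
      top <- top[d2 == min(d2)]
    }
    if (length(top) > 1L) {
      first_idx <- vapply(top, function(k) min(lit[labels == k]), numeric(1))
      top <- top[which.min(first_idx)]
    }
    chosen <- top[1]
  }
  keep <- lit[labels == chosen]
  sel <- matrix(FALSE, nrow(mask), ncol(mask))
  sel[keep] <- TRUE
  build_region(sel, n_lit_total = length(lit), threshold = threshold)
}

# 8-connected labeling of the lit pixels of `mask` via a pixel graph;
# `lit` is which(mask). Returns an integer component label per lit pixel.
label_components8 <- function(mask, lit = which(mask)) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  n <- length(lit)
  id <- matrix(0L, nr, nc)
  id[lit] <- seq_len(n)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))  # (drow, dcol)
  k <- 0L
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r_a <- max(1L, 1L - dr):min(nr, nr - dr)
    c_a <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- id[r_a, c_a, drop = FALSE]
    b <- id[r_a + dr, c_a + dc, drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) {
      k <- k + 1L
      edges[[k]] <- rbind(a[both], b[both])
    }
  }
  if (k == 0L) return(seq_len(n))  # no adjacency: every lit pixel its own blob
  g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                          n = n, directed = FALSE)
  igraph::components(g)$membership
}

# Assemble a fluor_region from a single-component mask.
build_region <- function(sel, n_lit_total, threshold = NA_real_) {
  nr <- nrow(sel)
  keep <- which(sel)
  x <- (keep - 1L) %/% nr   # 0-based column
  y <- (keep - 1L) %% nr    # 0-based row
  # boundary pixels: any 4-neighbor outside the region (or off the image)
  pad <- rbind(FALSE, cbind(FALSE, sel, FALSE), FALSE)
  ri <- y + 2L
  ci <- x + 2L
  interior <- pad[cbind(ri - 1L, ci)] & pad[cbind(ri + 1L, ci)] &
    pad[cbind(ri, ci - 1L)] & pad[cbind(ri, ci + 1L)]
  bp <- cbind(x = x[!interior], y = y[!interior])
  excl <- if (n_lit_total > 0) 100 * (n_lit_total - length(keep)) / n_lit_total else 0
  structure(
    list(mask = sel, threshold = threshold, pixel_count = length(keep),
         centroid = c(mean(x), mean(y)), boundary_pixels = bp,
         excluded_signal_fraction = excl),
    class = "fluor_region")
}

#' @export
print.fluor_region <- function(x, ...) {
  cat(sprintf(
    "<fluor_region> %d px at threshold %s, centroid (%.1f, %.1f), %.2f%% signal excluded\n",
    x$pixel_count, format(x$threshold), x$centroid[1], x$centroid[2],
    x$excluded_signal_fraction))
  invisible(x)
}

#' Fluorescent-area percentage
#'
#' Region area as a percentage of the eye area. The default denominator is the
#' circle approximation from the averaged orthogonal diameters; the rasterized
#' polygon-mask area is available as an alternative.
#'
#' @param region A [extract_region()] result.
#' @param boundary An [eye_boundary()].
#' @param pixel_scale_mm Pixel size, mm.
#' @param denominator `"circle"` (default) or `"mask"`.
#' @return Percentage (0-100, can exceed 100 only if the drawn circle
#'   underestimates the true area).
#' @export
area_percent <- function(region, boundary, pixel_scale_mm,
                         denominator = c("circle", "mask")) {
  denominator <- match.arg(denominator)
  area_mm2 <- region$pixel_count * pixel_scale_mm^2
  denom <- if (denominator == "circle") boundary$circle_area_mm2 else
    sum(boundary$mask) * pixel_scale_mm^2
  if (denom <= 0) stop("eye area denominator is zero", call. = FALSE)
  100 * area_mm2 / denom
}

#' Feret-based diffusion radius
#'
#' Half the largest observable diameter of the fluorescent region: the maximum
#' pairwise distance between region pixel centers (computed on the convex hull
#' for efficiency, which attains the same maximum), divided by two and scaled
#' to mm.
#'
#' @inheritParams area_percent
#' @return Radius in mm.
#' @export
radius_feret <- function(region, pixel_scale_mm) {
  if (region$pixel_count == 0L) {
    stop("diffusion radius is undefined for an empty region", call. = FALSE)
  }
  nr <- nrow(region$mask)
  keep <- which(region$mask)
  pts <- cbind((keep - 1L) %/% nr, (keep - 1L) %% nr)
  if (nrow(pts) == 1L) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], `-`)^2 + outer(hp[, 2], hp[, 2], `-`)^2
  sqrt(max(d2)) * pixel_scale_mm / 2
}

#' Centroid-based diffusion radius
#'
#' Distance from the region centroid to the most distant region boundary
#' pixel, in mm — the automated counterpart to the Feret-based radius.
#'
#' @inheritParams area_percent
#' @return Radius in mm.
#' @export
radius_centroid <- function(region, pixel_scale_mm) {
  if (region$pixel_count == 0L) {
    stop("diffusion radius is undefined for an empty region", call. = FALSE)
  }
  bp <- region$boundary_pixels
  if (nrow(bp) == 0L) return(0)
  d2 <- (bp[, 1] - region$centroid[1])^2 + (bp[, 2] - region$centroid[2])^2
  sqrt(max(d2)) * pixel_scale_mm
}

#' Nasal/temporal hemifield split of the fluorescent signal
#'
#' Splits the region at the vertical line through the eye-boundary centroid;
#' pixels exactly on the line count half to each side. By image convention the
#' nasal half is the left side unless `nasal_side = "right"`.
#'
#' @inheritParams area_percent
#' @param nasal_side `"left"` or `"right"`: which image side is nasal.
#' @return A named numeric vector `c(nasal = ..., temporal = ...)` of
#'   percentages summing to 100.
#' @export
hemifield_fractions <- function(region, boundary, nasal_side = c("left", "right")) {
  nasal_side <- match.arg(nasal_side)
  if (region$pixel_count == 0L) {
    stop("hemifield fractions are undefined for an empty region", call. = FALSE)
  }
  nr <- nrow(boundary$mask)
  bm <- which(boundary$mask)
  cx <- mean((bm - 1L) %/% nr)
  keep <- which(region$mask)
  x <- (keep - 1L) %/% nr
  left <- sum(x < cx) + 0.5 * sum(x == cx)
  right <- region$pixel_count - left
  frac <- 100 * c(left, right) / region$pixel_count
  if (nasal_side == "left") {
    c(nasal = frac[1], temporal = frac[2])
  } else {
    c(nasal = frac[2], temporal = frac[1])
  }
}

#' Repeatability audit of the automated radius measurement
#'
#' Re-runs the full segmentation-to-radius chain (threshold, component
#' selection, centroid radius) `n_repeats` times on the identical image and
#' reports the spread. The pipeline is deterministic, so the spread is
#' expected to be exactly 0 mm and is asserted to stay under the 0.001 mm
#' reproducibility bound; an optional jitter mode perturbs the threshold by
#' +/-1 per repeat to probe sensitivity instead.
#'
#' @param image A `normalized_image`.
#' @param boundary An [eye_boundary()].
#' @param n_repeats Number of repeated analyses (>= 2).
#' @param threshold Segmentation threshold.
#' @param jitter If `TRUE`, each repeat uses `threshold + U{-1,0,1}`.
#' @param seed Seed for the jitter draws.
#' @return A list with `radii` (tibble: `repeat_id`, `threshold`,
#'   `radius_centroid_mm`), `spread_mm` (max - min), `sd_mm`, and `pass`
#'   (`spread_mm < 0.001`, only asserted when `jitter = FALSE`).
#' @export
repeatability_audit <- function(image, boundary, n_repeats = 8L,
                                threshold = 70, jitter = FALSE, seed = 1L) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2", call. = FALSE)
  taus <- if (jitter) {
    withr::with_seed(seed, threshold + sample(c(-1, 0, 1), n_repeats, TRUE))
  } else {
    rep(threshold, n_repeats)
  }
  radii <- vapply(taus, function(tau) {
    m <- image$pixels >= tau & boundary$mask
    reg <- extract_region(m, boundary, threshold = tau)
    radius_centroid(reg, boundary$pixel_scale_mm)
  }, numeric(1))
  spread <- max(radii) - min(radii)
  if (!jitter && spread >= 0.001) {
    stop(sprintf(
      "repeatability audit failed: spread %.6f mm exceeds 0.001 mm", spread),
      call. = FALSE)
  }
  list(
    radii = tibble::tibble(repeat_id = seq_len(n_repeats), threshold = taus,
                           radius_centroid_mm = radii),
    spread_mm = spread, sd_mm = stats::sd(radii),
    pass = spread < 0.001
  )
}

#' Measure one eye at the selected threshold
#'
#' Composes segmentation, area percentage, both diffusion radii and the
#' hemifield split into one per-eye record at a single threshold (70 by
#' default, the level fixed for all analyses after the sweep).
#'
#' @param image A `normalized_image`.
#' @param boundary An [eye_boundary()].
#' @param metadata Named list (eye_id, model, dye_label, time_h, side).
#' @param threshold Selected threshold.
#' @param denominator Passed to [area_percent()].
#' @param nasal_side Passed to [hemifield_fractions()].
#' @param seed_point Optional `(x, y)` passed to [extract_region()].
#' @return A one-row tibble: `eye_id`, `model`, `dye_label`, `time_h`, `side`,
#'   `threshold`, `area_percent`, `radius_feret_mm`, `radius_centroid_mm`,
#'   `nasal_pct`, `temporal_pct`, `excluded_pct`. Radii and hemifields are
#'   `NA` when no pixel clears the threshold.
#' @export
measure_eye <- function(image, boundary, metadata = list(), threshold = 70,
                        denominator = c("circle", "mask"),
                        nasal_side = c("left", "right"), seed_point = NULL) {
  denominator <- match.arg(denominator)
  nasal_side <- match.arg(nasal_side)
  m <- image$pixels >= threshold & boundary$mask
  reg <- extract_region(m, boundary, seed_point = seed_point,
                        threshold = threshold)
  empty <- reg$pixel_count == 0L
  hemi <- if (empty) c(nasal = NA_real_, temporal = NA_real_) else
    hemifield_fractions(reg, boundary, nasal_side)
  tibble::tibble(
    eye_id = metadata$eye_id %||% NA_character_,
    model = metadata$model %||% NA_character_,
    dye_label = metadata$dye_label %||% NA_character_,
    time_h = metadata$time_h %||% NA_real_,
    side = metadata$side %||% NA_character_,
    threshold = threshold,
    area_percent = area_percent(reg, boundary, boundary$pixel_scale_mm,
                                denominator),
    radius_feret_mm = if (empty) NA_real_ else
      radius_feret(reg, boundary$pixel_scale_mm),
    radius_centroid_mm = if (empty) NA_real_ else
      radius_centroid(reg, boundary$pixel_scale_mm),
    nasal_pct = hemi[["nasal"]],
    temporal_pct = hemi[["temporal"]],
    excluded_pct = reg$excluded_signal_fraction
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
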