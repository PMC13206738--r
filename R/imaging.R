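#' Extract the green channel
#'
#' Fluorescein signal is quantified on the green channel of the RGB
#' photograph; the channel is returned unchanged as a numeric matrix.
#'
#' @param image An [eye_image()].
#' @return Numeric matrix with the image's row/column shape.
#' @export
extract_green_channel <- function(image) {
  stopifnot(inherits(image, "eye_image"))
  ch <- image$pixels[, , 2]
  storage.mode(ch) <- "double"
  ch
}

#' Subtract background measured in a signal-free region
#'
#' The background estimate is the mean (optionally median) green intensity
#' over a dye-free region; it is subtracted from every pixel and negative
#' values are clamped to zero. The output stays real-valued: quantization back
#' to 8 bits happens in [normalize_image()].
#'
#' @param channel Numeric matrix (green channel).
#' @param region Logical matrix of the same shape marking the signal-free
#'   region; must contain at least 25 pixels.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return A list with `channel` (the subtracted matrix) and
#'   `background_estimate`.
#' @export
subtract_background <- function(channel, region, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(channel), is.logical(region),
            all(dim(channel) == dim(region)))
  n_bg <- sum(region)
  if (n_bg == 0) stop("background region is empty", call. = FALSE)
  if (n_bg < 25) stop("background region must contain at least 25 pixels",
                      call. = FALSE)
  est <- if (statistic == "mean") mean(channel[region]) else
    stats::median(channel[region])
  list(channel = pmax(channel - est, 0), background_estimate = est)
}

#' Min-max normalize a channel to the 8-bit range
#'
#' Linear rescaling mapping the image minimum to 0 and maximum to 255, with
#' half-values rounded away from zero. A constant channel (no dynamic range,
#' i.e. no signal after background subtraction) maps to all zeros. Optionally
#' the min/max can be computed over the eye interior only while still
#' rescaling every pixel.
#'
#' @param channel Numeric matrix.
#' @param range_mask Optional logical matrix restricting where the min and max
#'   are taken (e.g. an eye-boundary interior); rescaled values outside that
#'   range are clipped to 0-255.
#' @param source Optional identifier recorded on the result.
#' @param background_estimate Optional number recorded on the result.
#' @return A `normalized_image`: list with integer `pixels` (0-255), `source`
#'   and `background_estimate`.
#' @export
normalize_image <- function(channel, range_mask = NULL, source = NULL,
                            background_estimate = NA_real_) {
  stopifnot(is.matrix(channel), length(channel) > 0)
  ref <- if (is.null(range_mask)) channel else {
    stopifnot(all(dim(range_mask) == dim(channel)))
    channel[range_mask]
  }
  lo <- min(ref)
  hi <- max(ref)
  px <- if (hi > lo) {
    pmin(pmax(round_half_away((channel - lo) * 255 / (hi - lo)), 0), 255)
  } else {
    matrix(0, nrow(channel), ncol(channel))
  }
  storage.mode(px) <- "integer"
  structure(list(pixels = px, source = source,
                 background_estimate = background_estimate),
            class = "normalized_image")
}

#' @export
print.normalized_image <- function(x, ...) {
  cat(sprintf("<normalized_image> %d x %d px, range %d-%d%s\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (!is.null(x$source)) paste0(", source ", x$source) else ""))
  invisible(x)
}

#' Background subtraction + normalization in one step
#'
#' Standard preprocessing applied to each photograph: take the green channel,
#' subtract the background measured in the given signal-free region, then
#' min-max rescale to 0-255.
#'
#' @param image An [eye_image()].
#' @param background_region Logical matrix marking a dye-free region; if
#'   `NULL` no subtraction is performed.
#' @inheritParams normalize_image
#' @inheritParams subtract_background
#' @return A `normalized_image`.
#' @export
preprocess_image <- function(image, background_region = NULL,
                             range_mask = NULL,
                             statistic = c("mean", "median")) {
  ch <- extract_green_channel(image)
  est <- NA_real_
  if (!is.null(background_region)) {
    sb <- subtract_background(ch, background_region, match.arg(statistic))
    ch <- sb$channel
    est <- sb$background_estimate
  }
  normalize_image(ch, range_mask = range_mask,
                  source = image$metadata$eye_id, background_estimate = est)
}

#' Read an RGB eye photograph from disk
#'
#' Reads an 8-bit RGB PNG (or TIFF when the `tiff` package is available).
#' 16-bit input is linearly rescaled to 8 bits with a warning.
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#' @param pixel_scale_mm Physical pixel size, mm.
#' @param metadata Named list attached to the image.
#' @return An [eye_image()].
#' @export
read_eye_image <- function(path, pixel_scale_mm, metadata = list()) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3]
  px <- round_half_away(arr * 255)
  if (max(px) > 255) {  # 16-bit source read as >1 scale
    warning("16-bit image linearly rescaled to 8 bits", call. = FALSE)
    px <- round_half_away(px * 255 / max(px))
  }
  storage.mode(px) <- "integer"
  eye_image(px, pixel_scale_mm, metadata)
}

#' Write an eye photograph or normalized image as PNG
#'
#' @param image An [eye_image()] or `normalized_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (inherits(image, "eye_image")) {
    png::writePNG(image$pixels / 255, path)
  } else if (inherits(image, "normalized_image")) {
    png::writePNG(image$pixels / 255, path)
  } else {
    stop("unsupported image object", call. = FALSE)
  }
  invisible(path)
}
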