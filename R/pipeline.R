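#' Write a synthetic cohort to disk
#'
#' Materializes a [generate_cohort()] result as the same file layout the
#' analysis side consumes for real data: one 8-bit RGB PNG per eye, one JSON
#' annotation per eye (boundary polygon, background-region polygon, pixel
#' scale, nasal-side label, diameters), a `truth.csv` with one ground-truth
#' row per eye, a `config.json` sidecar and a `manifest.json` with file
#' checksums for reproducibility audits.
#'
#' @param cohort An `eye_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eye_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$images)) {
    img <- cohort$images[[id]]
    write_image_png(img, file.path(dir, paste0(id, ".png")))
    write_annotation(img, file.path(dir, paste0(id, ".json")))
  }
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(
    list(preset = cohort$preset, n_eyes = nrow(cohort$truth),
         seed = cohort$truth$seed[1]),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE
  )
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("vitrospread")),
    files = as.list(tools::md5sum(file.path(dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# JSON annotation for one synthetic image: the true disc outline plays the
# role of the hand-drawn boundary; coordinates are 0-based pixel indices,
# origin top-left, x rightward, y downward.
write_annotation <- function(image, path, n_vertices = 72L) {
  md <- image$metadata
  bnd <- true_boundary(image, n_vertices)
  corner <- 16L
  ann <- list(
    eye_id = md$eye_id,
    pixel_scale_mm = image$pixel_scale_mm,
    boundary = unname(apply(bnd$polygon, 1, as.list)),
    background = list(list(0L, 0L), list(corner, 0L), list(corner, corner),
                      list(0L, corner)),
    nasal_side = "left",
    diameter_nt_mm = bnd$diameter_nt_mm,
    diameter_is_mm = bnd$diameter_is_mm,
    metadata = md[c("model", "dye_label", "time_h", "side")]
  )
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a per-image JSON annotation
#'
#' @param path Annotation file written by [write_annotation()] or drawn by an
#'   analyst with the same schema.
#' @return A list with `boundary` and `background` polygons (two-column
#'   matrices), `pixel_scale_mm`, diameters, `nasal_side` and metadata.
#' @export
read_annotation <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_poly <- function(p) {
    if (is.matrix(p)) return(p)
    matrix(unlist(p), ncol = 2, byrow = TRUE)
  }
  ann$boundary <- as_poly(ann$boundary)
  if (!is.null(ann$background)) ann$background <- as_poly(ann$background)
  ann
}

polygon_region_mask <- function(poly, image_dim) {
  nr <- image_dim[1]
  nc <- image_dim[2]
  pts <- cbind(rep(seq_len(nc) - 1, each = nr), rep(seq_len(nr) - 1, nc))
  matrix(mgcv::in.out(close_polygon(as.matrix(poly)), pts), nr, nc)
}

#' Quantify a directory of images with annotations
#'
#' Disk-based counterpart to [quantify_cohort()]: every `<id>.png` with a
#' matching `<id>.json` annotation is preprocessed (green channel, background
#' subtraction over the annotated region, normalization) and measured at the
#' selected threshold. Images lacking an annotation are skipped with a
#' warning and listed in the `skipped` attribute.
#'
#' @param dir Directory holding PNG images and JSON annotations.
#' @param threshold Segmentation threshold.
#' @param denominator Passed to [area_percent()].
#' @param csv Optional path; when given the table is also written as CSV.
#' @return A tibble of [measure_eye()] rows (attribute `skipped` lists image
#'   files without annotations).
#' @export
quantify_dir <- function(dir, threshold = 70,
                         denominator = c("circle", "mask"), csv = NULL) {
  denominator <- match.arg(denominator)
  pngs <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  rows <- list()
  skipped <- character()
  for (p in pngs) {
    ann_path <- sub("\\.png$", ".json", p)
    if (!file.exists(ann_path)) {
      warning("no annotation for ", basename(p), "; skipped", call. = FALSE)
      skipped <- c(skipped, basename(p))
      next
    }
    ann <- read_annotation(ann_path)
    img <- read_eye_image(p, ann$pixel_scale_mm,
                          metadata = c(list(eye_id = ann$eye_id), ann$metadata))
    bg <- polygon_region_mask(ann$background, dim(img$pixels)[1:2])
    norm <- preprocess_image(img, background_region = bg)
    bnd <- eye_boundary(ann$boundary, dim(img$pixels)[1:2], ann$pixel_scale_mm,
                        diameter_nt_mm = ann$diameter_nt_mm,
                        diameter_is_mm = ann$diameter_is_mm)
    rows[[ann$eye_id]] <- measure_eye(
      norm, bnd,
      metadata = c(list(eye_id = ann$eye_id), ann$metadata),
      threshold = threshold, denominator = denominator,
      nasal_side = ann$nasal_side %||% "left"
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  if (!is.null(csv)) readr::write_csv(out, csv)
  out
}

#' Write a cohort report to CSV + JSON
#'
#' @param report A [cohort_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$summary, file.path(dir, "group_summary.csv"))
  if (nrow(report$dye_contrasts)) {
    readr::write_csv(report$dye_contrasts, file.path(dir, "dye_contrasts.csv"))
  }
  if (nrow(report$time_contrasts)) {
    readr::write_csv(report$time_contrasts, file.path(dir, "time_contrasts.csv"))
  }
  jsonlite::write_json(
    list(summary = report$summary, anova = report$anova,
         dye_contrasts = report$dye_contrasts,
         time_contrasts = report$time_contrasts),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
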