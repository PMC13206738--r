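# boundary spanning (almost) the whole test grid
full_boundary <- function(n = 32, pixel_scale_mm = 0.1) {
  poly <- cbind(c(-0.5, n - 0.5, n - 0.5, -0.5),
                c(-0.5, -0.5, n - 0.5, n - 0.5))
  eye_boundary(poly, c(n, n), pixel_scale_mm)
}

norm_from_matrix <- function(px) {
  storage.mode(px) <- "integer"
  structure(list(pixels = px, source = "test", background_estimate = NA_real_),
            class = "normalized_image")
}

test_that("the default sweep yields seven masks with oracle-checked counts", {
  set.seed(77)
  px <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  img <- norm_from_matrix(px)
  b <- full_boundary(32)
  sw <- sweep_thresholds(img, b)
  expect_identical(nrow(sw), 7L)
  expect_identical(sw$threshold, c(30, 50, 70, 90, 120, 150, 200))
  # per-pixel counting oracle and monotone non-increase in tau
  for (k in seq_len(nrow(sw))) {
    cnt <- 0L
    for (i in 1:32) for (j in 1:32) {
      if (b$mask[i, j] && px[i, j] >= sw$threshold[k]) cnt <- cnt + 1L
    }
    expect_identical(sw$n_pixels[k], cnt)
  }
  expect_true(all(diff(sw$n_pixels) <= 0))
  # tau = 0 lights the full boundary interior
  sw0 <- sweep_thresholds(img, b, 0)
  expect_identical(sw0$n_pixels, sum(b$mask))
  expect_error(sweep_thresholds(img, b, 300), "0, 255")
})

test_that("component selection matches the flood-fill oracle on random masks", {
  set.seed(12)
  for (k in 1:60) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    lab <- flood_fill_label8(m)
    if (!any(m)) next
    reg <- extract_region(m)
    sizes <- tabulate(lab[m])
    expect_identical(reg$pixel_count, max(sizes))
    # the selected mask is exactly one oracle component
    sel_labels <- unique(lab[reg$mask])
    expect_length(sel_labels, 1L)
    expect_identical(sum(lab == sel_labels), reg$pixel_count)
    expect_equal(reg$excluded_signal_fraction,
                 100 * (sum(m) - reg$pixel_count) / sum(m))
  }
})

test_that("two-blob selection follows the largest-then-seed policy", {
  m <- matrix(FALSE, 64, 64)
  m[5:24, 5:29] <- TRUE   # 20 x 25 = 500 px
  m[45:52, 45:49] <- TRUE # 8 x 5 = 40 px
  reg <- extract_region(m)
  expect_identical(reg$pixel_count, 500L)
  expect_equal(reg$excluded_signal_fraction, 100 * 40 / 540, tolerance = 1e-12)
  # seeded selection overrides size: seed in the 40-px blob (x=46, y=46)
  b <- full_boundary(64)
  reg2 <- extract_region(m, b, seed_point = c(46, 46))
  expect_identical(reg2$pixel_count, 40L)
  expect_error(extract_region(m, full_boundary(64), seed_point = c(63, 63)),
               NA)  # inside boundary: fine even if unlit (falls back to largest)
  expect_identical(extract_region(m, b, seed_point = c(63, 63))$pixel_count,
                   500L)
  # single blob -> that blob, nothing excluded
  m2 <- matrix(FALSE, 32, 32)
  m2[10:15, 10:15] <- TRUE
  reg3 <- extract_region(m2)
  expect_identical(reg3$pixel_count, 36L)
  expect_identical(reg3$excluded_signal_fraction, 0)
  # empty mask -> empty region
  expect_identical(extract_region(matrix(FALSE, 8, 8))$pixel_count, 0L)
})

test_that("centroid is the unweighted mean of region pixel coordinates", {
  m <- matrix(FALSE, 32, 32)
  m[11:14, 21:26] <- TRUE  # rows 11:14 (y 10:13), cols 21:26 (x 20:25)
  reg <- extract_region(m)
  expect_equal(reg$centroid, c(mean(20:25), mean(10:13)))
})

test_that("area percentage follows the circle-approximation definition", {
  b <- full_boundary(32, pixel_scale_mm = 0.5)
  m <- matrix(FALSE, 32, 32)
  m[1:10, 1:10] <- TRUE
  reg <- extract_region(m)
  expect_equal(area_percent(reg, b, 0.5),
               100 * (100 * 0.25) / b$circle_area_mm2)
  # mask denominator: fraction of the boundary interior
  expect_equal(area_percent(reg, b, 0.5, denominator = "mask"),
               100 * 100 / sum(b$mask))
  # empty region -> 0 %
  expect_equal(area_percent(extract_region(matrix(FALSE, 32, 32)), b, 0.5), 0)
})

test_that("a pixelated disc recovers the closed-form area ratio within 1%", {
  # disc radius 5 mm in an eye of mean diameter 20 mm at 0.05 mm/px -> 25%
  n <- 440
  px_scale <- 0.05
  th <- seq(0, 2 * pi, length.out = 145)[-145]
  c0 <- (n - 1) / 2
  r_eye_px <- 10 / px_scale
  poly <- cbind(c0 + r_eye_px * cos(th), c0 + r_eye_px * sin(th))
  b <- eye_boundary(poly, c(n, n), px_scale,
                    diameter_nt_mm = 20, diameter_is_mm = 20)
  m <- disc_mask(n, 5 / px_scale)
  reg <- extract_region(m)
  expect_equal(area_percent(reg, b, px_scale), 25, tolerance = 0.01)
})

test_that("Feret radius equals the all-pairs oracle on fixed and random blobs", {
  # axis-aligned 6 x 8 rectangle: half-diagonal sqrt(5^2 + 7^2)/2 px
  m <- matrix(FALSE, 32, 32)
  m[10:15, 12:19] <- TRUE
  reg <- extract_region(m)
  expect_equal(radius_feret(reg, 1), sqrt(74) / 2, tolerance = 1e-12)
  expect_equal(radius_feret(reg, 0.2), 0.2 * sqrt(74) / 2, tolerance = 1e-12)
  # single pixel -> 0
  m1 <- matrix(FALSE, 8, 8); m1[3, 3] <- TRUE
  expect_identical(radius_feret(extract_region(m1), 0.1), 0)
  # random blobs vs O(n^2) oracle
  set.seed(21)
  for (k in 1:25) {
    mb <- random_blob_mask(32)
    regb <- extract_region(mb)
    expect_equal(radius_feret(regb, 1), feret_all_pairs(regb$mask) / 2,
                 tolerance = 1e-12)
  }
  expect_error(radius_feret(extract_region(matrix(FALSE, 8, 8)), 1),
               "undefined")
})

test_that("both radius metrics agree on a disc to within half a pixel", {
  m <- disc_mask(101, 40)
  reg <- extract_region(m)
  rf <- radius_feret(reg, 1)
  rc <- radius_centroid(reg, 1)
  expect_equal(rf, 40, tolerance = 0.5 / 40)
  expect_equal(rc, 40, tolerance = 0.5 / 40)
  expect_lt(abs(rf - rc), 0.5)
})

test_that("centroid radius matches the exhaustive boundary scan on a crescent", {
  n <- 64
  m <- disc_mask(n, 25) & !disc_mask_off(n, 20, dx = 10)
  reg <- extract_region(m)
  # exhaustive oracle: every region pixel with a 4-neighbor outside
  nr <- n
  keep <- which(reg$mask)
  x <- (keep - 1L) %/% nr
  y <- (keep - 1L) %% nr
  cx <- mean(x); cy <- mean(y)
  best <- 0
  for (i in seq_along(keep)) {
    nb_out <- FALSE
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      xx <- x[i] + d[1]; yy <- y[i] + d[2]
      if (xx < 0 || yy < 0 || xx >= n || yy >= n || !m[yy + 1, xx + 1]) nb_out <- TRUE
    }
    if (nb_out) best <- max(best, sqrt((x[i] - cx)^2 + (y[i] - cy)^2))
  }
  expect_equal(radius_centroid(reg, 1), best, tolerance = 1e-12)
  # loose geometric bounds relating the two radii
  rf <- radius_feret(reg, 1)
  expect_lte(radius_centroid(reg, 1), 2 * rf + 1e-9)
  expect_lte(rf, radius_centroid(reg, 1) + rf + 1e-9)
})

test_that("radii scale linearly with pixel size; area percent does not", {
  set.seed(33)
  m <- random_blob_mask(32)
  reg <- extract_region(m)
  b <- full_boundary(32, 0.1)
  b2 <- full_boundary(32, 0.3)
  expect_equal(radius_feret(reg, 0.3), 3 * radius_feret(reg, 0.1))
  expect_equal(radius_centroid(reg, 0.3), 3 * radius_centroid(reg, 0.1))
  expect_equal(area_percent(reg, b, 0.1), area_percent(reg, b2, 0.3))
})

test_that("hemifield fractions split signal at the boundary centroid", {
  b <- full_boundary(32)  # centroid x = 15.5
  m <- matrix(FALSE, 32, 32)
  m[5:20, 1:10] <- TRUE   # x 0..9, all left of 15.5
  reg <- extract_region(m)
  expect_equal(hemifield_fractions(reg, b), c(nasal = 100, temporal = 0))
  expect_equal(hemifield_fractions(reg, b, nasal_side = "right"),
               c(nasal = 0, temporal = 100))
  # mirror-symmetric region -> 50/50
  m2 <- matrix(FALSE, 32, 32)
  m2[10:20, 10:22] <- TRUE  # x 9..21 symmetric about 15
  m2s <- m2 | m2[, 32:1]
  reg2 <- extract_region(m2s)
  hf <- hemifield_fractions(reg2, b)
  expect_equal(unname(hf[1] + hf[2]), 100)
  expect_equal(unname(hf[1]), 50, tolerance = 0.06)
  # arbitrary mask vs per-pixel counting oracle
  set.seed(44)
  m3 <- random_blob_mask(32)
  reg3 <- extract_region(m3)
  keep <- which(reg3$mask)
  x <- (keep - 1L) %/% 32L
  left <- sum(x < 15.5)
  expect_equal(unname(hemifield_fractions(reg3, b)[1]),
               100 * left / length(keep))
  expect_error(hemifield_fractions(extract_region(matrix(FALSE, 32, 32)), b),
               "undefined")
})

test_that("repeated automated analysis of a fixed image has zero spread", {
  fx <- fixture_eye(seed = 88)
  aud <- repeatability_audit(fx$norm, fx$boundary, n_repeats = 8)
  expect_identical(aud$spread_mm, 0)
  expect_identical(aud$sd_mm, 0)
  expect_true(aud$pass)
  aud2 <- repeatability_audit(fx$norm, fx$boundary, n_repeats = 2)
  expect_identical(aud2$sd_mm, 0)
})

test_that("threshold jitter reproduces a brute-force rerun of the chain", {
  fx <- fixture_eye(seed = 88)
  aud <- repeatability_audit(fx$norm, fx$boundary, n_repeats = 6,
                             jitter = TRUE, seed = 3)
  manual <- vapply(aud$radii$threshold, function(tau) {
    m <- fx$norm$pixels >= tau & fx$boundary$mask
    radius_centroid(extract_region(m), fx$boundary$pixel_scale_mm)
  }, numeric(1))
  expect_equal(aud$radii$radius_centroid_mm, manual)
  expect_equal(aud$spread_mm, max(manual) - min(manual))
})

test_that("measure_eye composes the metrics and flags empty fluorescence", {
  fx <- fixture_eye(seed = 88)
  row <- measure_eye(fx$norm, fx$boundary, metadata = fx$image$metadata)
  expect_identical(row$threshold, 70)
  expect_gt(row$area_percent, 0)
  expect_equal(row$nasal_pct + row$temporal_pct, 100)
  expect_gt(row$radius_feret_mm, 0)
  # blank image: zero area, radii undefined
  fxb <- fx$boundary
  blank <- norm_from_matrix(matrix(0L, nrow(fxb$mask), ncol(fxb$mask)))
  row2 <- measure_eye(blank, fxb)
  expect_equal(row2$area_percent, 0)
  expect_true(is.na(row2$radius_feret_mm))
  expect_true(is.na(row2$radius_centroid_mm))
})

test_that("area percent is non-increasing in the threshold for real renders", {
  fx <- fixture_eye(seed = 90)
  sw <- sweep_thresholds(fx$norm, fx$boundary)
  areas <- vapply(seq_len(nrow(sw)), function(k) {
    reg <- extract_region(sw$mask[[k]], threshold = sw$threshold[k])
    area_percent(reg, fx$boundary, fx$boundary$pixel_scale_mm)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})
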