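# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: flood fill is an explicit stack walk, Feret is the
# O(n^2) all-pairs scan, counting is per-pixel loops.

# 8-connected components by explicit stack-based flood fill.
# Returns an integer label matrix (0 = background).
flood_fill_label8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        lab[i, j] <- cur
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (di in -1:1) for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            ii <- p[1] + di
            jj <- p[2] + dj
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                mask[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- cur
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# all-pairs maximum pairwise distance between pixel centers of a mask
feret_all_pairs <- function(mask) {
  nr <- nrow(mask)
  keep <- which(mask)
  if (length(keep) < 2) return(0)
  x <- (keep - 1L) %/% nr
  y <- (keep - 1L) %% nr
  best <- 0
  for (a in seq_along(keep)) {
    d2 <- (x - x[a])^2 + (y - y[a])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# random blob: union of a few random discs on an n x n grid
random_blob_mask <- function(n = 32, n_discs = 3) {
  m <- matrix(FALSE, n, n)
  xg <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  yg <- matrix(seq_len(n) - 1, n, n)
  for (k in seq_len(n_discs)) {
    cx <- runif(1, 4, n - 5)
    cy <- runif(1, 4, n - 5)
    r <- runif(1, 2, n / 4)
    m <- m | ((xg - cx)^2 + (yg - cy)^2 <= r^2)
  }
  m
}

# disc mask shifted horizontally by dx pixels
disc_mask_off <- function(n, radius_px, dx = 0) {
  xg <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  yg <- matrix(seq_len(n) - 1, n, n)
  c0 <- (n - 1) / 2
  (xg - c0 - dx)^2 + (yg - c0)^2 <= radius_px^2
}

# disc mask centered mid-grid
disc_mask <- function(n, radius_px) {
  xg <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  yg <- matrix(seq_len(n) - 1, n, n)
  c0 <- (n - 1) / 2
  (xg - c0)^2 + (yg - c0)^2 <= radius_px^2
}

# a small synthetic image + boundary fixture used by several files:
# one simulated eye rendered with a fixed seed
fixture_eye <- function(seed = 101L, noise_sigma = 2, time_h = 12,
                        stokes_radius_nm = 4.5) {
  cfg <- sim_config(eye_diameter_mm = 22, grid_spacing_mm = 22 / 110,
                    duration_h = time_h, output_times_h = time_h,
                    seed = seed)
  fld <- simulate_eye(cfg, stokes_radius_nm)[[1]]
  n <- nrow(fld$grid)
  md <- list(eye_id = sprintf("fix_%d", seed), model = "synthetic",
             dye_label = "40 kDa", time_h = time_h, side = "temporal",
             eye_diameter_mm = 22, center_px = c((n - 1) / 2, (n - 1) / 2),
             radius_px = 11 / fld$grid_spacing_mm)
  img <- render_image(fld, render_config(seed = seed, noise_sigma = noise_sigma),
                      metadata = md)
  list(config = cfg, field = fld, image = img,
       norm = preprocess_image(img, background_region = outside_eye_region(img)),
       boundary = true_boundary(img))
}
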