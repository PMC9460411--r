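# Shared fixtures, built in code at test time.

# Well-spread random point set (K x d) on the 0-255 scale.
random_points <- function(K, d, seed, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(K * d, lo, hi), K, d)
}

# Flat synthetic chart frame: each of the 24 patches painted with `colors`
# on a mid-grey canvas; returns the image and its annotation.
flat_chart_image <- function(colors = as.matrix(reference_chart()[, c("R", "G", "B")]),
                             patch = 24L, gap = 4L, margin = 6L) {
  h <- margin * 2L + 4L * patch + 3L * gap
  w <- margin * 2L + 6L * patch + 5L * gap
  img <- array(128, c(h, w, 3))
  rects <- matrix(NA_real_, 24, 4)
  for (i in 1:4) for (j in 1:6) {
    r0 <- margin + 1L + (i - 1L) * (patch + gap)
    c0 <- margin + 1L + (j - 1L) * (patch + gap)
    k <- (i - 1) * 6 + j
    rects[k, ] <- c(r0, c0, r0 + patch - 1L, c0 + patch - 1L)
    for (ch in 1:3) img[r0:(r0 + patch - 1), c0:(c0 + patch - 1), ch] <- colors[k, ch]
  }
  list(image = as_rgb_image(img), annotation = patch_annotation(rects))
}

# Smooth synthetic test image (no chart/landmarks) for warp round trips.
smooth_test_image <- function(h = 120, w = 150, seed = 1) {
  set.seed(seed)
  r <- outer(seq_len(h), seq_len(w), function(i, j) 120 + 60 * sin(i / 17) * cos(j / 23))
  g <- outer(seq_len(h), seq_len(w), function(i, j) 130 + 50 * cos(i / 11 + j / 31))
  b <- outer(seq_len(h), seq_len(w), function(i, j) 90 + 40 * sin((i + j) / 19))
  as_rgb_image(pmin(pmax(array(c(r, g, b), c(h, w, 3)), 0), 255))
}

# Detect the centre of a bright circular landmark target near `approx`
# (row, col) by intensity-weighted centroid of near-white pixels.
detect_disc <- function(image, approx, radius = 8) {
  rr <- max(1, round(approx[1]) - radius):min(dim(image)[1], round(approx[1]) + radius)
  cc <- max(1, round(approx[2]) - radius):min(dim(image)[2], round(approx[2]) + radius)
  lum <- (unclass(image)[rr, cc, 1] + unclass(image)[rr, cc, 2] +
            unclass(image)[rr, cc, 3]) / 3
  wts <- pmax(lum - 160, 0)^2
  c(sum(row(wts) * wts) / sum(wts) + rr[1] - 1,
    sum(col(wts) * wts) / sum(wts) + cc[1] - 1)
}

# Mean absolute pixel error between two images.
image_mae <- function(a, b) mean(abs(unclass(a)[, , 1:3] - unclass(b)[, , 1:3]))

# One full-stack ground-truth recovery run: render a 15-frame survey at the
# given severity, calibrate every frame against its own chart, and return
# the mean absolute error vs the base scene for both conditions.
recovery_run <- function(master_seed, severity = 0.5, n_images = 15) {
  base <- make_base_scene(orthocal:::substream_seed(master_seed, "scene"), 256, 320)
  truth <- render_survey(base, n_images, severity, jitter_px = 0.5,
                         master_seed = master_seed)
  cal <- lapply(truth$frames, function(img)
    apply_color_calibration(fit_color_calibration(measure_patches(img, truth$chart)), img))
  c(uncal = mean(vapply(truth$frames, image_mae, numeric(1), b = base$image)),
    cal = mean(vapply(cal, image_mae, numeric(1), b = base$image)))
}

# Run the default synthetic comparison pipeline in memory (15 + 15 frames,
# severity 0.5, n points sampled in the central ROI); returns the
# homogeneity comparison result.
default_pipeline_comparison <- function(master_seed = 1, n_images = 15,
                                        severity = 0.5, n_points = 300) {
  base <- make_base_scene(orthocal:::substream_seed(master_seed, "scene"), 256, 320)
  truth <- render_survey(base, n_images, severity, jitter_px = 0.5,
                         master_seed = master_seed)
  cal <- lapply(truth$frames, function(img)
    apply_color_calibration(fit_color_calibration(measure_patches(img, truth$chart)), img))
  cons <- procrustes_consensus(truth$landmarks)
  supc <- mapply(function(i, l) unwarp_to_consensus(i, l, cons),
                 cal, truth$landmarks, SIMPLIFY = FALSE)
  supr <- mapply(function(i, l) unwarp_to_consensus(i, l, cons),
                 truth$frames, truth$landmarks, SIMPLIFY = FALSE)
  compare_conditions(supc, supr, roi = c(64, 80, 192, 240), n = n_points,
                     seed = orthocal:::substream_seed(master_seed, "sampling"))
}
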