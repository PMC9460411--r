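base_shape <- function() {
  as.matrix(expand.grid(row = c(40, 120, 200), col = c(50, 150, 250)))
}

test_that("consensus of identical or translated configurations is the centered shape", {
  sh <- base_shape()
  centered <- sweep(sh, 2, colMeans(sh))
  same <- procrustes_consensus(list(sh, sh, sh))
  expect_lt(max(abs(same$points - centered)), 1e-8)

  translated <- lapply(1:5, function(i) sweep(sh, 2, c(3 * i, -2 * i), "+"))
  cons <- procrustes_consensus(translated)
  expect_lt(max(abs(cons$points - centered)), 1e-8)
  expect_lt(max(abs(colMeans(cons$points))), 1e-10)   # centroid exactly zero
})

test_that("consensus of jittered copies concentrates at the base shape", {
  sh <- base_shape()
  centered <- sweep(sh, 2, colMeans(sh))
  sigma <- 2
  # CLT: each consensus coordinate estimates the base with SE sigma/sqrt(30);
  # the per-seed RMS deviation over the 18 coordinates stays within 3 SE
  bound <- 3 * sigma / sqrt(30)
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    configs <- lapply(1:30, function(i) sh + matrix(rnorm(18, 0, sigma), ncol = 2))
    cons <- procrustes_consensus(configs)
    worst <- max(worst, sqrt(mean((cons$points - centered)^2)))
  }
  expect_lt(worst, bound)
})

test_that("consensus is order-invariant and equivariant under common rigid motion", {
  set.seed(4)
  sh <- base_shape()
  configs <- lapply(1:8, function(i) sh + matrix(rnorm(18, 0, 3), ncol = 2))
  cons <- procrustes_consensus(configs)
  cons_rev <- procrustes_consensus(rev(configs))
  expect_lt(max(abs(cons$points - cons_rev$points)), 1e-6)

  # one common rotation + translation applied to every configuration:
  # the consensus is the same shape (zero full-Procrustes distance)
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- lapply(configs, function(x) sweep(x %*% R, 2, c(20, -35), "+"))
  cons_m <- procrustes_consensus(moved)
  realigned <- orthocal:::rotate_onto(cons_m$points, cons$points)
  expect_lt(max(abs(realigned - cons$points)), 1e-6)
})

test_that("pairwise rotation alignment agrees with an independent Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(12)
  a <- matrix(rnorm(18, sd = 10), ncol = 2)
  th <- 0.4
  b <- a %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) +
    matrix(rnorm(18, sd = 1), ncol = 2)
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  ours <- orthocal:::rotate_onto(b, a)
  ref <- vegan::procrustes(a, b, scale = FALSE, symmetric = FALSE)
  expect_lt(max(abs(ours - ref$Yrot)), 1e-8)
})

test_that("degenerate or mismatched landmark sets are rejected", {
  sh <- base_shape()
  line <- cbind(1:9, 2 * (1:9))
  expect_error(procrustes_consensus(list(sh, line)), "collinear")
  expect_error(procrustes_consensus(list(sh, sh[1:6, ])), "expected")
  expect_error(procrustes_consensus(list(sh)), "at least 2")
})

test_that("unwarping to identical landmarks is a no-op and shifts are exact", {
  img <- smooth_test_image(120, 150, seed = 2)
  lmk <- as.matrix(expand.grid(row = c(20, 60, 100), col = c(25, 75, 125)))
  out <- unwarp_to_consensus(img, lmk, lmk)
  expect_lte(max(abs(unclass(out)[, , ] - unclass(img)[, , ])), 1)

  # landmarks = consensus + (5, 0): output row r shows source row r + 5
  out_sh <- unwarp_to_consensus(img, lmk + cbind(rep(5, 9), 0), lmk)
  expect_lt(max(abs(unclass(out_sh)[10:100, , ] - unclass(img)[15:105, , ])), 1e-9)
  expect_equal(dim(out_sh), dim(img))
  valid <- attr(out_sh, "valid")
  expect_false(any(valid[117:120, ]))   # rows mapped outside the source
})

test_that("a forward warp followed by its inverse unwarp recovers the image", {
  img <- smooth_test_image(120, 150, seed = 9)
  lmk0 <- as.matrix(expand.grid(row = c(20, 60, 100), col = c(25, 75, 125)))
  set.seed(33)
  lmk1 <- lmk0 + matrix(rnorm(18, 0, 3), ncol = 2)
  warped <- unwarp_to_consensus(img, lmk0, lmk1)    # landmarks now at lmk1
  back <- unwarp_to_consensus(warped, lmk1, lmk0)
  interior <- list(20:100, 20:130)
  diff <- abs(unclass(back)[interior[[1]], interior[[2]], ] -
                unclass(img)[interior[[1]], interior[[2]], ])
  expect_lt(mean(diff), 2)
})

test_that("unwarped stacks pin the landmark targets onto the consensus", {
  base <- make_base_scene(3, 256, 320)
  truth <- render_survey(base, n_images = 8, severity = 0, jitter_px = 0.8,
                         master_seed = 5, landmark_noise_px = 0)
  cons <- procrustes_consensus(truth$landmarks)
  target <- orthocal:::consensus_pixels(cons)
  detected <- array(NA_real_, c(8, 9, 2))
  for (i in 1:8) {
    un <- unwarp_to_consensus(truth$frames[[i]], truth$landmarks[[i]], cons)
    for (k in 1:9) detected[i, k, ] <- detect_disc(un, target[k, ])
  }
  sds <- apply(detected, c(2, 3), sd)
  expect_lt(max(sds), 0.5)                       # per-coordinate SD across images
  mean_pos <- apply(detected, c(2, 3), mean)
  expect_lt(max(abs(mean_pos - target)), 0.5)    # and they sit on the consensus
})

test_that("landmark files round-trip through the text format", {
  sets <- list(img1 = base_shape() + 0.25, img2 = base_shape() - 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(sets, path)
  back <- read_landmarks(path)
  expect_equal(names(back), names(sets))
  expect_equal(back$img1, sets$img1, tolerance = 1e-6, ignore_attr = TRUE)
})
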