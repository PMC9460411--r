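test_that("point sampling is deterministic, distinct, in bounds, and exhaustive when asked", {
  pts <- sample_points(c(1, 1, 1000, 1000), 300, 4, seed = 7)
  expect_equal(nrow(pts), 300)
  expect_equal(nrow(unique(pts)), 300)
  expect_true(all(pts[, 1] >= 5 & pts[, 1] <= 996 & pts[, 2] >= 5 & pts[, 2] <= 996))
  expect_identical(pts, sample_points(c(1, 1, 1000, 1000), 300, 4, seed = 7))

  # exhaustive: n equals the number of available cells
  all_pts <- sample_points(c(10, 10, 15, 13), 6 * 4, 0, seed = 1)
  expect_equal(nrow(unique(all_pts)), 24)
  expect_setequal(paste(all_pts[, 1], all_pts[, 2]),
                  paste(rep(10:15, 4), rep(10:13, each = 6)))
  expect_error(sample_points(c(1, 1, 20, 20), 400, 4, seed = 1), "too small")
})

test_that("window means follow the documented 8x8 anchoring", {
  img <- array(100, c(40, 40, 3))
  expect_true(all(window_means(as_rgb_image(img), rbind(c(20, 20))) == 100))

  # block holding 0..63 in one channel: mean 31.5 at the anchored window
  img2 <- array(0, c(40, 40, 3))
  img2[17:24, 17:24, 1] <- matrix(0:63, 8, 8)
  wm <- window_means(as_rgb_image(pmax(img2, 0)), rbind(c(21, 21)))
  expect_equal(unname(wm[1, 1]), 31.5)

  # linearity: on a vertical gradient, shifting the point one row shifts the
  # mean by exactly the gradient step
  grad <- array(rep(seq_len(40) * 2, 40 * 3), c(40, 40, 3))
  w1 <- window_means(as_rgb_image(grad / 2), rbind(c(20, 20)))
  w2 <- window_means(as_rgb_image(grad / 2), rbind(c(21, 20)))
  expect_equal(w2[1, ] - w1[1, ], c(R = 1, G = 1, B = 1))

  expect_error(window_means(as_rgb_image(img), rbind(c(2, 20))), "outside")
})

test_that("rms_sd matches its closed form and a brute-force oracle", {
  # two images with (10,10,10) and (20,20,20): per-channel SD 10/sqrt(2)
  stack <- array(NA_real_, c(2, 1, 3))
  stack[1, 1, ] <- 10; stack[2, 1, ] <- 20
  expect_equal(rms_sd(stack), 10 / sqrt(2), tolerance = 1e-10)
  expect_equal(round(rms_sd(stack), 4), 7.0711)

  set.seed(5)
  big <- array(rnorm(12 * 50 * 3, 100, 8), c(12, 50, 3))
  brute <- vapply(1:50, function(p) {
    sqrt(mean(vapply(1:3, function(ch) sd(big[, p, ch])^2, numeric(1))))
  }, numeric(1))
  expect_lt(max(abs(rms_sd(big) - brute)), 1e-10)

  expect_true(all(rms_sd(array(7, c(5, 4, 3))) == 0))   # identical images
  expect_error(rms_sd(big[1, , , drop = FALSE]), "at least 2")
})

test_that("rms_sd is invariant to image permutation and constant offsets", {
  set.seed(6)
  stack <- array(rnorm(10 * 30 * 3, 120, 10), c(10, 30, 3))
  expect_equal(rms_sd(stack[sample(10), , ]), rms_sd(stack))
  expect_equal(rms_sd(stack + 25), rms_sd(stack), tolerance = 1e-10)
  perm <- sample(30)
  expect_equal(rms_sd(stack[, perm, ]), rms_sd(stack)[perm])
})

test_that("the signed-rank test matches exhaustive enumeration and a reference implementation", {
  # literal enumeration over all 2^n sign vectors, midranks included
  enum_p <- function(d) {
    d <- d[d != 0]
    rk <- rank(abs(d))
    tot <- sum(rk)
    obs <- min(sum(rk[d > 0]), tot - sum(rk[d > 0]))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    w <- as.vector(signs %*% rk)
    mean(pmin(w, tot - w) <= obs + 1e-9)
  }
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(10, 0.3); y <- rnorm(10)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_two_sided, enum_p(x - y), tolerance = 1e-12)
    # untied data: agrees with the exact reference distribution
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(res$p_two_sided, ref, tolerance = 1e-12)
  }
  # ties: enumeration still the oracle
  x <- c(5, 5, 3, 2, 2, 1, 0, 4, 4, 6); y <- c(3, 3, 3, 4, 4, 2, 1, 1, 1, 2)
  expect_equal(wilcoxon_signed_rank(x, y)$p_two_sided, enum_p(x - y),
               tolerance = 1e-12)
})

test_that("exact and approximate p agree within 0.005 for n between 20 and 30", {
  set.seed(9)
  worst <- 0
  for (i in 1:100) {
    n <- sample(20:30, 1)
    x <- rnorm(n, mean = runif(1, 0, 0.8)); y <- rnorm(n)
    pe <- wilcoxon_signed_rank(x, y, method = "exact")$p_two_sided
    pa <- wilcoxon_signed_rank(x, y, method = "approx")$p_two_sided
    worst <- max(worst, abs(pe - pa))
  }
  expect_lt(worst, 0.005)
})

test_that("degenerate and edge-case inputs are handled per contract", {
  res <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(res$degenerate)
  expect_equal(res$p_two_sided, 1)
  expect_error(wilcoxon_signed_rank(1:4, 1:5), "lengths differ")
  one <- wilcoxon_signed_rank(2, 1)
  expect_gt(one$p_two_sided, 0)
  expect_lte(one$p_two_sided, 1)
})

test_that("condition comparison is paired, and an outlier image raises rms_sd everywhere", {
  img <- smooth_test_image(64, 80, seed = 3)
  shifted <- function(k) as_rgb_image(pmin(unclass(img)[, , ] + k, 255))
  stack_a <- lapply(c(0, 1, 2, 3), shifted)
  res_same <- compare_conditions(stack_a, stack_a, n = 40, seed = 2)
  expect_true(res_same$test$degenerate)
  expect_equal(res_same$test$p_two_sided, 1)

  stack_b <- stack_a
  stack_b[[2]] <- shifted(31)   # one globally brightened image
  res <- compare_conditions(stack_a, stack_b, n = 40, seed = 2)
  expect_true(all(res$rms_sd[, 2] >= res$rms_sd[, 1]))
  expect_equal(res$summary$condition, c("calibrated", "non-calibrated"))
  expect_equal(dim(res$rms_sd), c(40L, 2L))
})

test_that("windows overlapping invalid regions are rejected and resampled", {
  img <- smooth_test_image(64, 80, seed = 4)
  mask <- matrix(TRUE, 64, 80)
  mask[1:40, 1:40] <- FALSE     # large invalid block
  imgm <- img
  attr(imgm, "valid") <- mask
  res <- compare_conditions(list(imgm, img), list(img, img), n = 30, seed = 6)
  expect_gt(res$n_rejected, 0)
  lo <- 4; hi <- 3
  for (i in seq_len(30)) {
    win <- mask[(res$points[i, 1] - lo):(res$points[i, 1] + hi),
                (res$points[i, 2] - lo):(res$points[i, 2] + hi)]
    expect_true(all(win))
  }
})

test_that("homogeneity results round-trip to CSV and JSON", {
  img <- smooth_test_image(64, 80, seed = 3)
  stack <- lapply(c(0, 2, 4), function(k) as_rgb_image(pmin(unclass(img)[, , ] + k, 255)))
  res <- compare_conditions(stack, stack, n = 25, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_homogeneity_results(res, csv, js)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(nrow(back), 25)
  expect_equal(back[["calibrated"]], unname(res$rms_sd[, 1]))
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(doc$wilcoxon$p_two_sided, res$test$p_two_sided)
  expect_equal(doc$seed, 3)
})
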