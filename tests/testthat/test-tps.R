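test_that("identity and pure-shift fits are recognised as affine maps", {
  for (d in 2:3) {
    src <- random_points(12, d, seed = 100 + d)
    fit_id <- tps(src, src)
    expect_lt(max(abs(fit_id$weights)), 1e-8)
    expect_lt(max(abs(fit_id$affine - rbind(0, diag(d)))), 1e-8)

    shift <- seq_len(d) * 5
    fit_sh <- tps(src, sweep(src, 2, shift, "+"))
    expect_lt(max(abs(fit_sh$weights)), 1e-8)
    expect_equal(fit_sh$affine[1, ], shift, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("general affine targets produce zero radial weights", {
  for (d in 2:3) {
    src <- random_points(15, d, seed = 7 * d)
    A <- matrix(rnorm(d * d, sd = 0.4), d, d) + diag(d)
    b <- rnorm(d, sd = 20)
    fit <- tps(src, sweep(src %*% t(A), 2, b, "+"))
    expect_lt(max(abs(fit$weights)), 1e-6)
  }
})

test_that("lambda = 0 interpolates exactly and satisfies the side conditions", {
  # 3D colour-style fit through per-channel monotone cubic curves
  src <- random_points(24, 3, seed = 42)
  curve <- function(x, a) 255 * (a * (x / 255)^3 + (1 - a) * (x / 255))
  dst <- cbind(curve(src[, 1], 0.35), curve(src[, 2], 0.5), curve(src[, 3], 0.2))
  fit <- tps(src, dst)
  expect_lt(max(abs(predict(fit, src) - dst)), 1e-6)
  expect_lt(max(abs(orthocal:::tps_side_conditions(fit))), 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-6)

  # 2D geometric fit
  src2 <- random_points(9, 2, seed = 3, lo = 10, hi = 240)
  dst2 <- src2 + 4 * sin(src2 / 40)
  fit2 <- tps(src2, dst2)
  expect_lt(max(abs(predict(fit2, src2) - dst2)), 1e-6)
  expect_lt(max(abs(orthocal:::tps_side_conditions(fit2))), 1e-8)
})

test_that("evaluation matches a brute-force kernel-sum oracle", {
  brute <- function(fit, pts) {
    K <- nrow(fit$control_points)
    out <- matrix(0, nrow(pts), fit$dim_out)
    for (i in seq_len(nrow(pts))) {
      x <- pts[i, ]
      acc <- fit$affine[1, ] + drop(x %*% fit$affine[-1, , drop = FALSE])
      for (k in seq_len(K)) {
        r <- sqrt(sum((x - fit$control_points[k, ])^2))
        u <- if (fit$dim_in == 2) { if (r == 0) 0 else r^2 * log(r) } else -r
        acc <- acc + u * fit$weights[k, ]
      }
      out[i, ] <- acc
    }
    out
  }
  for (d in 2:3) {
    src <- random_points(25, d, seed = 11 * d)
    dst <- src + random_points(25, d, seed = 13 * d, lo = -20, hi = 20)
    fit <- tps(src, dst)
    pts <- random_points(1000, d, seed = 17 * d)
    expect_lt(max(abs(predict(fit, pts) - brute(fit, pts))), 1e-10)
  }
})

test_that("increasing lambda shrinks the radial weights monotonically", {
  src <- random_points(20, 3, seed = 5)
  dst <- src + random_points(20, 3, seed = 6, lo = -30, hi = 30)
  norms <- vapply(c(0, 0.1, 1, 10, 100, 1000),
                  function(l) sqrt(sum(tps(src, dst, lambda = l)$weights^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("parameter bookkeeping follows the 2(K + 3) rule and its general form", {
  fit24 <- tps(random_points(24, 2, seed = 1), random_points(24, 2, seed = 2))
  expect_equal(unname(tps_parameter_count(fit24)), c(6L, 48L, 54L))

  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))   # minimal 2D configuration
  fit3 <- tps(tri, tri + 1)
  expect_equal(unname(tps_parameter_count(fit3)), c(6L, 6L, 12L))

  fit3d <- tps(random_points(24, 3, seed = 8), random_points(24, 3, seed = 9))
  expect_equal(unname(tps_parameter_count(fit3d)), c(12L, 72L, 84L))
})

test_that("degenerate configurations and contract violations raise errors", {
  line <- cbind(1:10, 2 * (1:10) + 3)               # collinear in 2D
  expect_error(tps(line, line + 1), "collinear")
  plane <- cbind(random_points(10, 2, seed = 4), 0)  # coplanar in 3D
  plane[, 3] <- plane[, 1] + plane[, 2]
  expect_error(tps(plane, plane), "coplanar")
  expect_error(tps(random_points(8, 2, seed = 1), random_points(7, 2, seed = 2)),
               "source has 8 points but target has 7")
  expect_error(tps(random_points(3, 2, seed = 1)[1:3, ], random_points(3, 2, seed = 2),
                   lambda = -1), "lambda")
  fit <- tps(random_points(6, 2, seed = 1), random_points(6, 2, seed = 2))
  expect_error(predict(fit, random_points(5, 3, seed = 3)), "input dimensions")
})

test_that("JSON serialization round-trips a fitted model", {
  src <- random_points(24, 3, seed = 21)
  dst <- src * 0.9 + 5
  fit <- tps(src, dst, lambda = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_tps_json(fit, path)
  back <- read_tps_json(path)
  expect_equal(back$dim_in, fit$dim_in)
  expect_equal(back$lambda, fit$lambda)
  pts <- random_points(50, 3, seed = 22)
  expect_lt(max(abs(predict(back, pts) - predict(fit, pts))), 1e-10)
})
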