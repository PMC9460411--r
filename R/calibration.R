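#' Fit the 3D thin-plate-spline colour calibration
#'
#' Fits a thin-plate spline in RGB colour space mapping the 24 measured
#' chart-patch colours of an acquired frame onto the known reference
#' coordinates of the chart. With \code{lambda = 0} (the default) every
#' patch correspondence is interpolated exactly, so the map removes the
#' frame's global colour distortion (cast, gamma, gain/offset) wherever it
#' varies smoothly in colour space.
#'
#' @param measured 24 x 3 matrix of measured patch RGB values (0-255).
#' @param reference 24 x 3 matrix of reference RGB values; defaults to the
#'   bundled [reference_chart()].
#' @param lambda nonnegative smoothing parameter passed to [tps()].
#' @return a \code{"tps"} model with \code{dim_in = dim_out = 3}.
#' @export
fit_color_calibration <- function(measured,
                                  reference = as.matrix(reference_chart()[, c("R", "G", "B")]),
                                  lambda = 0) {
  measured <- as.matrix(measured)
  reference <- as.matrix(reference)
  if (nrow(measured) != 24 || nrow(reference) != 24 ||
      ncol(measured) != 3 || ncol(reference) != 3)
    stopf("measured and reference must both be 24 x 3")
  tps(measured, reference, lambda = lambda)
}

#' Apply a colour calibration to a whole image
#'
#' Maps every pixel through a fitted 3D colour thin-plate spline and clips
#' the result to [0, 255]. Optionally the mapping is evaluated on a
#' \code{lut_resolution}^3 lattice spanning the RGB cube and applied by
#' trilinear interpolation, which trades a bounded approximation error
#' (at most one grey level for \code{lut_resolution >= 33}) for speed on
#' large rasters.
#'
#' @param model a \code{"tps"} colour model (\code{dim_in = dim_out = 3}).
#' @param image an RGB image array (0-255).
#' @param lut_resolution optional integer >= 2; NULL (default) evaluates the
#'   spline directly at every pixel.
#' @return the calibrated image (same dimensions, same metadata attributes).
#' @export
apply_color_calibration <- function(model, image, lut_resolution = NULL) {
  stopifnot(inherits(model, "tps"))
  if (model$dim_in != 3 || model$dim_out != 3)
    stopf("colour calibration needs a 3D -> 3D model, got %dD -> %dD",
          model$dim_in, model$dim_out)
  d <- dim(image)
  px <- matrix(unclass(image), d[1] * d[2], 3)
  mapped <- if (is.null(lut_resolution)) {
    predict(model, px)
  } else {
    apply_color_lut(build_color_lut(model, lut_resolution), px)
  }
  out <- array(clip255(mapped), d)
  for (a in c("id", "source")) attr(out, a) <- attr(image, a, exact = TRUE)
  attr(out, "condition") <- "calibrated"
  class(out) <- c("rgb_image", class(out))
  out
}

# Evaluate the colour model on an n^3 lattice over [0, 255]^3.
build_color_lut <- function(model, n) {
  n <- as.integer(n)
  if (n < 2) stopf("lut_resolution must be >= 2")
  g <- seq(0, 255, length.out = n)
  lattice <- as.matrix(expand.grid(R = g, G = g, B = g))
  list(n = n, grid = g, values = predict(model, lattice))
}

# Trilinear interpolation of a colour LUT at pixel colours (m x 3, 0-255).
apply_color_lut <- function(lut, px) {
  n <- lut$n
  step <- 255 / (n - 1)
  u <- clip255(px) / step            # lattice coordinates, 0 .. n-1
  i0 <- pmin(floor(u), n - 2)        # lower cell corner, 0-based
  f <- u - i0
  out <- matrix(0, nrow(px), 3)
  # lattice linear index (1-based) of corner (iR, iG, iB), 0-based each
  lin <- function(iR, iG, iB) 1 + iR + n * (iG + n * iB)
  for (dR in 0:1) for (dG in 0:1) for (dB in 0:1) {
    wt <- (if (dR) f[, 1] else 1 - f[, 1]) *
          (if (dG) f[, 2] else 1 - f[, 2]) *
          (if (dB) f[, 3] else 1 - f[, 3])
    idx <- lin(i0[, 1] + dR, i0[, 2] + dG, i0[, 3] + dB)
    out <- out + wt * lut$values[idx, , drop = FALSE]
  }
  out
}

#' Percent colour-reconstruction error
#'
#' Mean Euclidean RGB distance between calibrated colours and their ground
#' truth, normalised by the RGB cube diagonal (255 sqrt(3)) and expressed
#' as a percentage — a bounded, channel-symmetric error measure for
#' held-out colours not used in the chart fit.
#'
#' @param model a fitted 3D colour \code{"tps"} model.
#' @param measured_heldout N x 3 matrix of measured (distorted) colours.
#' @param truth N x 3 matrix of corresponding true colours.
#' @return mean percent error (scalar).
#' @export
calibration_error_percent <- function(model, measured_heldout, truth) {
  measured_heldout <- as.matrix(measured_heldout)
  truth <- as.matrix(truth)
  if (nrow(measured_heldout) != nrow(truth))
    stopf("held-out and truth row counts differ (%d vs %d)",
          nrow(measured_heldout), nrow(truth))
  if (nrow(truth) < 1) stopf("need at least one held-out colour")
  pred <- clip255(predict(model, measured_heldout))
  err <- sqrt(rowSums((pred - truth)^2))
  mean(err) / (255 * sqrt(3)) * 100
}

#' Synthetic calibration-accuracy study
#'
#' Measures the colour-reconstruction accuracy of the chart-fitted 3D
#' thin-plate-spline calibration on held-out scene colours. For each
#' (seed, severity) pair: a synthetic base scene is rendered, one
#' illuminant distortion is drawn and applied, the 24 chart patches are
#' measured from the distorted frame and the calibration fitted, and the
#' percent reconstruction error ([calibration_error_percent()]) is
#' evaluated on \code{n_heldout} random scene pixels outside the chart
#' region (distorted values in, true base-scene values as truth).
#'
#' @param seeds integer vector of master seeds (one run per seed and
#'   severity).
#' @param severities numeric vector of severities in [0, 1].
#' @param n_heldout held-out scene colours per run (default 50).
#' @param height,width scene dimensions.
#' @return data.frame with columns \code{seed}, \code{severity},
#'   \code{error_percent}.
#' @export
calibration_error_study <- function(seeds = 1:20,
                                    severities = c(0.25, 0.5, 1.0),
                                    n_heldout = 50,
                                    height = 256, width = 320) {
  grid <- expand.grid(seed = seeds, severity = severities)
  err <- mapply(function(seed, severity) {
    base <- make_base_scene(substream_seed(seed, "scene"), height, width)
    params <- draw_illuminant_params(severity,
                                     substream_seed(seed, "illuminant"))
    frame <- apply_illuminant(base$image, params)
    model <- fit_color_calibration(measure_patches(frame, base$chart))
    # held-out pixels: random positions clear of the chart corner
    chart_max <- c(max(base$chart$rects[, 3]), max(base$chart$rects[, 4]))
    pts <- sample_points(c(1, 1, height, width), 8 * n_heldout, 8,
                         substream_seed(seed, "heldout"))
    pts <- pts[!(pts[, 1] <= chart_max[1] + 4 & pts[, 2] <= chart_max[2] + 4), ,
               drop = FALSE]
    pts <- pts[seq_len(n_heldout), , drop = FALSE]
    at <- function(img) vapply(1:3, function(ch) unclass(img)[cbind(pts, ch)],
                               numeric(n_heldout))
    calibration_error_percent(model, at(frame), at(base$image))
  }, grid$seed, grid$severity)
  data.frame(seed = grid$seed, severity = grid$severity, error_percent = err)
}
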