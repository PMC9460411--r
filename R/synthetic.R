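#' Generate a synthetic base scene
#'
#' Builds an orthophoto-like ground-truth scene: a smooth band-limited
#' random texture in a green-dominated palette (a set-aside grass field),
#' nine high-contrast circular landmark targets on a 3 x 3 grid (the
#' ground-control-point markers used for superimposition), and a 24-patch
#' reference chart rendered from [reference_chart()] in the top-left
#' corner. Deterministic given \code{seed}.
#'
#' @param seed integer seed.
#' @param height,width scene dimensions in pixels (both >= 256).
#' @return list of class \code{"base_scene"}: \code{image} (an
#'   \code{"rgb_image"}), \code{landmarks} (9 x 2), \code{chart} (a
#'   \code{"patch_annotation"}), \code{seed}.
#' @export
make_base_scene <- function(seed, height = 256, width = 320) {
  if (height < 256 || width < 256)
    stopf("scene must be at least 256 x 256 to host chart and margins, got %d x %d",
          height, width)
  # smooth texture: coarse random lattice upsampled bilinearly, per channel
  palette_mean <- c(R = 95, G = 135, B = 75)
  palette_sd <- c(R = 18, G = 22, B = 14)
  cell <- 24
  gh <- ceiling(height / cell) + 1L
  gw <- ceiling(width / cell) + 1L
  img <- with_seed(seed, {
    arr <- array(0, c(height, width, 3))
    grid <- pixel_grid(height, width)
    gcoords <- cbind((grid[, 1] - 1) / cell + 1, (grid[, 2] - 1) / cell + 1)
    for (ch in 1:3) {
      coarse <- array(stats::rnorm(gh * gw, palette_mean[ch], palette_sd[ch]),
                      c(gh, gw, 1))
      arr[, , ch] <- matrix(bilinear_sample(coarse, gcoords, fill = palette_mean[ch])$values[, 1],
                            height, width)
    }
    clip255(arr)
  })

  # nine GCP-style targets: white disc with black ring, centres on a 3x3 grid
  lmk <- as.matrix(expand.grid(
    row = round(height * c(0.25, 0.5, 0.75)),
    col = round(width * c(0.25, 0.5, 0.75))
  ))
  lmk <- lmk[order(lmk[, 1], lmk[, 2]), ]
  for (i in seq_len(nrow(lmk))) {
    rr <- (lmk[i, 1] - 6):(lmk[i, 1] + 6)
    cc <- (lmk[i, 2] - 6):(lmk[i, 2] + 6)
    d <- sqrt(outer((rr - lmk[i, 1])^2, (cc - lmk[i, 2])^2, "+"))
    for (ch in 1:3) {
      block <- img[rr, cc, ch]
      block[d <= 6] <- 0
      block[d <= 3.5] <- 255
      img[rr, cc, ch] <- block
    }
  }

  chart <- corner_chart_annotation()
  ref <- as.matrix(reference_chart()[, c("R", "G", "B")])
  img <- stamp_chart(img, chart, ref)

  structure(list(image = as_rgb_image(img, id = "base"),
                 landmarks = lmk, chart = chart, seed = as.integer(seed)),
            class = "base_scene")
}

# Fixed chart layout in the top-left corner: 4 x 6 patches of 10 px with
# 2 px gaps, 4 px outer margin.
corner_chart_annotation <- function(patch = 10L, gap = 2L, margin = 4L) {
  rects <- matrix(NA_real_, 24, 4)
  for (i in 1:4) for (j in 1:6) {
    r0 <- margin + 1L + (i - 1L) * (patch + gap)
    c0 <- margin + 1L + (j - 1L) * (patch + gap)
    rects[(i - 1) * 6 + j, ] <- c(r0, c0, r0 + patch - 1L, c0 + patch - 1L)
  }
  patch_annotation(rects, shrink_fraction = 0.2)
}

# Paint flat chart patches (24 x 3 colours) into an image array.
stamp_chart <- function(img, annotation, colors) {
  for (i in seq_len(24)) {
    rect <- annotation$rects[i, ]
    for (ch in 1:3) img[rect[1]:rect[3], rect[2]:rect[4], ch] <- colors[i, ch]
  }
  img
}

#' Draw per-image illuminant distortion parameters
#'
#' Draws the parameters of one frame's smooth radiometric distortion:
#' a diagonally dominant 3 x 3 colour-cast matrix, per-channel gamma,
#' global gain and offset, a radial vignette, and sensor noise. All
#' magnitudes scale linearly with \code{severity}; severity 0 is exactly
#' the identity transform with zero noise.
#'
#' @param severity distortion severity in [0, 1].
#' @param seed integer seed for the draw.
#' @return list of class \code{"illuminant_params"} with elements
#'   \code{cast} (3 x 3), \code{gamma} (3), \code{gain}, \code{offset}
#'   (grey levels), \code{vignette_strength}, \code{noise_sd} (grey
#'   levels), \code{seed}.
#' @export
draw_illuminant_params <- function(severity, seed) {
  if (severity < 0 || severity > 1) stopf("severity must be in [0, 1]")
  with_seed(seed, {
    off <- stats::runif(6, 0, 0.08) * severity
    cast <- diag(1 + stats::runif(3, -0.05, 0.05) * severity)
    cast[row(cast) != col(cast)] <- off
    params <- list(
      cast = cast,
      gamma = 1 + stats::runif(3, -0.2, 0.2) * severity,
      gain = 1 + stats::runif(1, -0.15, 0.15) * severity,
      offset = stats::runif(1, -12, 12) * severity,
      vignette_strength = stats::runif(1, 0, 0.15) * severity,
      noise_sd = 2 * severity,
      seed = as.integer(seed)
    )
    structure(params, class = "illuminant_params")
  })
}

#' Identity illuminant parameters
#'
#' @return an \code{"illuminant_params"} object that leaves images
#'   unchanged.
#' @export
identity_illuminant <- function() {
  structure(list(cast = diag(3), gamma = c(1, 1, 1), gain = 1, offset = 0,
                 vignette_strength = 0, noise_sd = 0, seed = 0L),
            class = "illuminant_params")
}

# The pixelwise illuminant transfer applied to colours (m x 3, 0-255) at
# squared normalized radius rho2 (vignette position); noise excluded.
illuminant_transfer <- function(params, rgb, rho2 = 0) {
  # exact identity short-circuit: severity-0 parameters change nothing
  if (identical(params$cast, diag(3)) && all(params$gamma == 1) &&
      params$gain == 1 && params$offset == 0 && params$vignette_strength == 0)
    return(as.matrix(rgb))
  x <- as.matrix(rgb) / 255
  x <- x %*% t(params$cast)
  x <- pmax(x, 0)
  for (ch in 1:3) x[, ch] <- x[, ch]^params$gamma[ch]
  x <- x * params$gain + params$offset / 255
  x <- x * (1 - params$vignette_strength * rho2)
  clip255(x * 255)
}

#' Apply an illuminant distortion to an image
#'
#' Per pixel: normalise to [0, 1], mix channels with the cast matrix,
#' apply per-channel gamma, gain and offset, multiply by the radial
#' vignette \eqn{1 - v \rho^2} (\eqn{\rho} the radius normalised to 1 at
#' the image corner), rescale to 0-255, add Gaussian sensor noise, clip.
#' Identity parameters return the input unchanged.
#'
#' @param image an RGB image array (0-255).
#' @param params an \code{"illuminant_params"} object.
#' @return the distorted \code{"rgb_image"}.
#' @export
apply_illuminant <- function(image, params) {
  stopifnot(inherits(params, "illuminant_params"))
  d <- dim(image)
  h <- d[1]; w <- d[2]
  px <- matrix(unclass(image), h * w, 3)
  grid <- pixel_grid(h, w)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  rho2 <- ((grid[, 1] - ctr[1])^2 + (grid[, 2] - ctr[2])^2) /
    ((h - ctr[1])^2 + (w - ctr[2])^2)
  out <- illuminant_transfer(params, px, rho2)
  if (params$noise_sd > 0) {
    noise <- with_seed(substream_seed(params$seed, "noise"),
                       stats::rnorm(length(out), 0, params$noise_sd))
    out <- out + noise
  }
  res <- array(clip255(out), d)
  for (a in c("id", "condition", "source"))
    attr(res, a) <- attr(image, a, exact = TRUE)
  class(res) <- c("rgb_image", class(res))
  res
}

# Similarity transform of (row, col) points: rotate by `angle` (radians)
# about `center`, scale, then translate by (dr, dc).
similarity_points <- function(points, angle, scale, shift, center) {
  p <- sweep(as.matrix(points), 2, center)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * (p %*% t(R)), 2, center + shift, "+")
}

# Backward-map similarity warp of an image (bilinear). Identity parameters
# short-circuit to the untouched input.
warp_similarity <- function(image, angle, scale, shift, fill = c(0, 0, 0)) {
  d <- dim(image)
  if (angle == 0 && scale == 1 && all(shift == 0)) {
    attr(image, "valid") <- matrix(TRUE, d[1], d[2])
    return(image)
  }
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  grid <- pixel_grid(d[1], d[2])
  # invert y = scale*R(angle)*(x - ctr) + ctr + shift for the source point x
  src <- similarity_points(grid, -angle, 1 / scale,
                           shift = -shift, center = ctr + shift)
  smp <- bilinear_sample(unclass(image), src, fill = fill)
  out <- array(clip255(smp$values), d)  # guard against bilinear round-off
  attr(out, "valid") <- matrix(smp$valid, d[1], d[2])
  class(out) <- c("rgb_image", class(out))
  out
}

#' Render a synthetic UAV survey with ground truth
#'
#' Renders \code{n_images} frames of one base scene, each with its own
#' smooth illuminant distortion and a small geometric perturbation
#' (similarity transform of the scene plus landmark measurement jitter),
#' and with the reference chart re-stamped at a fixed location so each
#' frame carries its own in-frame calibration chart (acquired colours then
#' follow the frame's illuminant). The calibrated condition is produced
#' downstream by chart fitting; the generator emits distorted frames plus
#' the complete ground truth needed to reproduce them.
#'
#' All randomness flows from \code{master_seed} through named substreams
#' (illuminant, geometry, landmark jitter, sensor noise).
#'
#' @param base a \code{"base_scene"} from [make_base_scene()].
#' @param n_images number of frames (>= 2).
#' @param severity illuminant severity in [0, 1]; default 0.5.
#' @param jitter_px geometric perturbation scale: landmark jitter SD in
#'   pixels, and the scale of the per-frame similarity transform; 0
#'   disables geometry changes. Default 0.5.
#' @param master_seed integer master seed.
#' @param landmark_noise_px SD (pixels) of the noise added to the recorded
#'   landmark coordinates (landmark "clicking" error); defaults to
#'   \code{jitter_px}. Set to 0 to record the true positions.
#' @return list of class \code{"scene_truth"}: \code{frames} (list of
#'   distorted \code{"rgb_image"}s), \code{base} (the base scene),
#'   \code{illuminants} (per frame), \code{geometry} (per frame:
#'   angle/scale/shift), \code{true_landmarks} and \code{landmarks}
#'   (recorded = true + jitter; per frame 9 x 2), \code{chart},
#'   \code{severity}, \code{jitter_px}, \code{master_seed}.
#' @export
render_survey <- function(base, n_images = 15, severity = 0.5,
                          jitter_px = 0.5, master_seed = 1,
                          landmark_noise_px = jitter_px) {
  stopifnot(inherits(base, "base_scene"))
  if (n_images < 2) stopf("need at least 2 frames")
  ref <- as.matrix(reference_chart()[, c("R", "G", "B")])
  frames <- vector("list", n_images)
  illums <- vector("list", n_images)
  geoms <- vector("list", n_images)
  true_lmk <- vector("list", n_images)
  rec_lmk <- vector("list", n_images)
  d <- dim(base$image)
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  for (i in seq_len(n_images)) {
    geom <- with_seed(substream_seed(master_seed, "geometry", i), list(
      angle = stats::rnorm(1, 0, 0.0035) * jitter_px,
      scale = exp(stats::rnorm(1, 0, 0.003) * jitter_px),
      shift = stats::rnorm(2, 0, 2) * jitter_px
    ))
    illum <- draw_illuminant_params(severity,
                                    substream_seed(master_seed, "illuminant", i))
    frames[[i]] <- render_frame(base, geom, illum, ref,
                                id = sprintf("frame%02d", i))
    geoms[[i]] <- geom
    illums[[i]] <- illum
    true_lmk[[i]] <- similarity_points(base$landmarks, geom$angle, geom$scale,
                                       geom$shift, ctr)
    jit <- with_seed(substream_seed(master_seed, "landmark_jitter", i),
                     matrix(stats::rnorm(length(base$landmarks), 0,
                                         landmark_noise_px), ncol = 2))
    rec_lmk[[i]] <- true_lmk[[i]] + jit
  }
  names(frames) <- names(illums) <- names(geoms) <- sprintf("frame%02d", seq_len(n_images))
  names(true_lmk) <- names(rec_lmk) <- names(frames)
  structure(list(frames = frames, base = base, illuminants = illums,
                 geometry = geoms, true_landmarks = true_lmk,
                 landmarks = rec_lmk, chart = base$chart,
                 severity = severity, jitter_px = jitter_px,
                 landmark_noise_px = landmark_noise_px,
                 master_seed = as.integer(master_seed)),
            class = "scene_truth")
}

# Render one frame: similarity-warp the scene, re-stamp the chart at its
# fixed annotation, then apply the illuminant (chart included, so measured
# chart colours follow the frame's distortion).
render_frame <- function(base, geom, illum, ref, id) {
  img <- warp_similarity(base$image, geom$angle, geom$scale, geom$shift)
  valid <- attr(img, "valid", exact = TRUE)
  img <- stamp_chart(unclass(img), base$chart, ref)
  valid[1:(max(base$chart$rects[, 3]) + 2), 1:(max(base$chart$rects[, 4]) + 2)] <- TRUE
  img <- as_rgb_image(img, id = id, condition = "non-calibrated")
  out <- apply_illuminant(img, illum)
  attr(out, "valid") <- valid
  out
}

#' Re-render a survey from its stored ground truth
#'
#' Reproduces the frame stack bit-exactly from a \code{"scene_truth"}
#' object (determinism contract of the generator).
#'
#' @param truth a \code{"scene_truth"}.
#' @return list of frames identical to \code{truth$frames}.
#' @export
re_render <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  ref <- as.matrix(reference_chart()[, c("R", "G", "B")])
  lapply(seq_along(truth$frames), function(i)
    render_frame(truth$base, truth$geometry[[i]], truth$illuminants[[i]],
                 ref, id = sprintf("frame%02d", i)))
}
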