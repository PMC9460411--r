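#' Flight geometry parameters
#'
#' Parameter bundle for the closed-form photogrammetric flight-geometry
#' calculators. Defaults describe the survey configuration of a small
#' consumer quadcopter: 22 m above ground level, 4.5 mm focal length,
#' 6.17 mm x 4.56 mm sensor (width x height), 3968 x 2976 px stills,
#' 2 m/s ground speed, one still every 3.34 s. The sensor height (4.56 mm)
#' is the along-track dimension.
#'
#' @param altitude_m flight height above ground (m).
#' @param focal_mm lens focal length (mm).
#' @param sensor_w_mm,sensor_h_mm sensor width and height (mm).
#' @param image_w_px,image_h_px still-image pixel dimensions.
#' @param speed_m_s ground speed (m/s).
#' @param shot_interval_s time between consecutive stills (s).
#' @return list of class \code{"flight_params"}.
#' @export
flight_params <- function(altitude_m = 22, focal_mm = 4.5,
                          sensor_w_mm = 6.17, sensor_h_mm = 4.56,
                          image_w_px = 3968, image_h_px = 2976,
                          speed_m_s = 2, shot_interval_s = 3.34) {
  p <- list(altitude_m = altitude_m, focal_mm = focal_mm,
            sensor_w_mm = sensor_w_mm, sensor_h_mm = sensor_h_mm,
            image_w_px = image_w_px, image_h_px = image_h_px,
            speed_m_s = speed_m_s, shot_interval_s = shot_interval_s)
  if (any(unlist(p) <= 0)) stopf("all flight parameters must be positive")
  structure(p, class = "flight_params")
}

#' Forward overlap between consecutive stills
#'
#' The along-track ground footprint of one still is
#' \eqn{altitude \cdot sensor_h / focal}; consecutive shot centres are
#' \eqn{speed \cdot interval} apart. Forward overlap is the shared
#' fraction, \eqn{100 (1 - speed \cdot interval \cdot focal /
#' (altitude \cdot sensor_h))}, clamped to [0, 100].
#'
#' @param p a \code{"flight_params"} object.
#' @return overlap percentage.
#' @export
forward_overlap <- function(p) {
  stopifnot(inherits(p, "flight_params"))
  footprint <- p$altitude_m * p$sensor_h_mm / p$focal_mm
  if (footprint <= 0) stopf("nonpositive along-track footprint")
  spacing <- p$speed_m_s * p$shot_interval_s
  min(max(100 * (1 - spacing / footprint), 0), 100)
}

#' Ground sample distance
#'
#' Ground size of one image pixel across track:
#' \eqn{100 \cdot altitude \cdot sensor_w / (focal \cdot image_w)} in
#' cm/pixel.
#'
#' @param p a \code{"flight_params"} object.
#' @return GSD in cm per pixel.
#' @export
ground_sample_distance <- function(p) {
  stopifnot(inherits(p, "flight_params"))
  100 * p$altitude_m * p$sensor_w_mm / (p$focal_mm * p$image_w_px)
}

#' Side overlap between adjacent flight lanes
#'
#' \eqn{100 (1 - spacing \cdot focal / (altitude \cdot sensor_w))},
#' clamped to [0, 100]; the cross-track footprint is
#' \eqn{altitude \cdot sensor_w / focal}.
#'
#' @param p a \code{"flight_params"} object.
#' @param lane_spacing_m distance between adjacent flight lanes (m).
#' @return sidelap percentage.
#' @export
side_overlap <- function(p, lane_spacing_m) {
  stopifnot(inherits(p, "flight_params"))
  if (lane_spacing_m < 0) stopf("lane spacing must be nonnegative")
  footprint <- p$altitude_m * p$sensor_w_mm / p$focal_mm
  min(max(100 * (1 - lane_spacing_m / footprint), 0), 100)
}

#' @export
print.flight_params <- function(x, ...) {
  cat(sprintf("Flight: %.1f m AGL, %.2f mm focal, sensor %.2f x %.2f mm, %d x %d px\n",
              x$altitude_m, x$focal_mm, x$sensor_w_mm, x$sensor_h_mm,
              x$image_w_px, x$image_h_px))
  cat(sprintf("Speed %.2f m/s, shot interval %.2f s\n",
              x$speed_m_s, x$shot_interval_s))
  cat(sprintf("Forward overlap: %.1f%%   GSD: %.3f cm/px\n",
              forward_overlap(x), ground_sample_distance(x)))
  invisible(x)
}
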