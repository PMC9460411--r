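#' The 24-patch ColorChecker reference chart
#'
#' Returns the bundled reference table for the classic 24-patch
#' ColorChecker chart: patch names and nominal sRGB coordinates (0-255),
#' in the fixed 4 x 6 row-major order, dark skin first, black last. The
#' last row is the six-step neutral (grey) series. These are the chart
#' manufacturer's published sRGB values for the post-November-2014 target,
#' shipped as a versioned constant so calibration needs no external data.
#'
#' @return data.frame with columns \code{name}, \code{R}, \code{G}, \code{B}
#'   (24 rows).
#' @seealso [measure_patches()], [fit_color_calibration()]
#' @export
reference_chart <- function() {
  data.frame(
    name = c("dark skin", "light skin", "blue sky", "foliage", "blue flower",
             "bluish green", "orange", "purplish blue", "moderate red",
             "purple", "yellow green", "orange yellow", "blue", "green",
             "red", "yellow", "magenta", "cyan", "white 9.5", "neutral 8",
             "neutral 6.5", "neutral 5", "neutral 3.5", "black 2"),
    R = c(115, 194,  98,  87, 133, 103, 214,  80, 193,  94, 157, 224,
           56,  70, 175, 231, 187,   8, 243, 200, 160, 122,  85,  52),
    G = c( 82, 150, 122, 108, 128, 189, 126,  91,  90,  60, 188, 163,
           61, 148,  54, 199,  86, 133, 243, 200, 160, 122,  85,  52),
    B = c( 68, 130, 157,  67, 177, 170,  44, 166,  99, 108,  64,  46,
          150,  73,  60,  31, 149, 161, 242, 200, 160, 121,  85,  52),
    stringsAsFactors = FALSE
  )
}

#' Export the reference chart as CSV
#'
#' @param path output path.
#' @export
write_chart_csv <- function(path) {
  utils::write.csv(reference_chart(), path, row.names = FALSE)
  invisible(path)
}

#' Build a patch annotation
#'
#' Describes where the 24 chart patches lie in a calibration frame as
#' axis-aligned rectangles \code{c(r0, c0, r1, c1)} (1-based, inclusive).
#' Before measuring, each rectangle is shrunk towards its centre by
#' \code{shrink_fraction} per side, which discards patch-edge pixels
#' (borders, bleed, slight misregistration).
#'
#' @param rects 24 x 4 matrix (or list of length-4 vectors) of rectangles in
#'   chart order.
#' @param shrink_fraction fraction in [0, 1) trimmed from each side;
#'   default 0.2.
#' @return list of class \code{"patch_annotation"}.
#' @export
patch_annotation <- function(rects, shrink_fraction = 0.2) {
  if (is.list(rects)) rects <- do.call(rbind, rects)
  rects <- as.matrix(rects)
  if (nrow(rects) != 24 || ncol(rects) != 4)
    stopf("annotation needs 24 rectangles of (r0, c0, r1, c1), got %d x %d",
          nrow(rects), ncol(rects))
  if (any(rects[, 1] > rects[, 3]) || any(rects[, 2] > rects[, 4]))
    stopf("malformed rectangle: r0 > r1 or c0 > c1")
  if (shrink_fraction < 0 || shrink_fraction >= 0.5)
    stopf("shrink_fraction must be in [0, 0.5)")
  structure(list(rects = rects, shrink_fraction = shrink_fraction),
            class = "patch_annotation")
}

#' Read / write a patch annotation as JSON
#'
#' The JSON document holds the 24 named rectangles (1-based inclusive
#' pixel coordinates) and the shrink fraction.
#'
#' @param annotation a \code{"patch_annotation"}.
#' @param path file path.
#' @export
write_annotation_json <- function(annotation, path) {
  stopifnot(inherits(annotation, "patch_annotation"))
  doc <- list(
    coordinate_convention = "1-based (row, col), inclusive rectangles",
    shrink_fraction = annotation$shrink_fraction,
    patches = lapply(seq_len(24), function(i) list(
      name = reference_chart()$name[i],
      rect = annotation$rects[i, ]
    ))
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  patch_annotation(do.call(rbind, doc$patches$rect),
                   shrink_fraction = doc$shrink_fraction)
}

# Shrink a rectangle towards its centre by `frac` of its extent per side,
# keeping at least a 2 x 2 pixel core.
shrink_rect <- function(rect, frac) {
  dr <- floor((rect[3] - rect[1] + 1) * frac)
  dc <- floor((rect[4] - rect[2] + 1) * frac)
  out <- c(rect[1] + dr, rect[2] + dc, rect[3] - dr, rect[4] - dc)
  if (out[1] > out[3] || out[2] > out[4]) NULL else out
}

#' Measure chart patch colours from a calibration frame
#'
#' For every annotated patch, takes the trimmed mean (central 80 per cent,
#' per channel) of the pixels inside the shrunken rectangle. The trimmed
#' mean makes the measurement robust to residual edge bleed and specular
#' outliers while remaining exact on flat patches.
#'
#' @param image an RGB image array (0-255).
#' @param annotation a \code{"patch_annotation"} locating the 24 patches.
#' @return 24 x 3 matrix of measured RGB values in [0, 255].
#' @export
measure_patches <- function(image, annotation) {
  stopifnot(inherits(annotation, "patch_annotation"))
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(NA_real_, 24, 3, dimnames = list(reference_chart()$name,
                                                 c("R", "G", "B")))
  for (i in seq_len(24)) {
    rect <- annotation$rects[i, ]
    if (rect[1] < 1 || rect[2] < 1 || rect[3] > h || rect[4] > w)
      stopf("patch %d region [%d,%d]-[%d,%d] outside %d x %d image",
            i, rect[1], rect[2], rect[3], rect[4], h, w)
    rect <- shrink_rect(rect, annotation$shrink_fraction)
    if (is.null(rect) || (rect[3] - rect[1] + 1) * (rect[4] - rect[2] + 1) < 4)
      stopf("patch %d region has fewer than 4 pixels after shrinking", i)
    block <- unclass(image)[rect[1]:rect[3], rect[2]:rect[4], , drop = FALSE]
    out[i, ] <- apply(block, 3, mean, trim = 0.1)
  }
  out
}
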