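#' RGB image containers and I/O
#'
#' Images are plain numeric H x W x 3 arrays with values on the 0-255 scale
#' (reals internally; quantized to 8 bits only when written to disk).
#' Coordinates are (row, col), 1-based, with pixel centres at integer
#' positions. `as_rgb_image()` validates and normalises an array; metadata
#' (image id, condition label, source path) travels in attributes.
#'
#' @param pixels numeric H x W x 3 array, values in [0, 255].
#' @param id optional image identifier.
#' @param condition optional condition label ("calibrated"/"non-calibrated").
#' @param source optional source path.
#' @return the validated array with class \code{"rgb_image"}.
#' @export
as_rgb_image <- function(pixels, id = NULL, condition = NULL, source = NULL) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stopf("an RGB image must be an H x W x 3 array")
  if (dim(pixels)[1] < 16 || dim(pixels)[2] < 16)
    stopf("image too small: need H, W >= 16, got %d x %d",
          dim(pixels)[1], dim(pixels)[2])
  if (!all(is.finite(pixels)))
    stopf("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stopf("image values must lie in [0, 255]")
  storage.mode(pixels) <- "double"
  if (!is.null(id)) attr(pixels, "id") <- id
  if (!is.null(condition)) attr(pixels, "condition") <- condition
  if (!is.null(source)) attr(pixels, "source") <- source
  class(pixels) <- c("rgb_image", class(pixels))
  pixels
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path image file; format chosen by extension (.png, .tif/.tiff).
#' @return an \code{"rgb_image"} array on the 0-255 scale.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (use png or tiff)", ext))
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  as_rgb_image(raw * 255, source = path)
}

#' Write an RGB image as 8-bit PNG or TIFF (LZW)
#'
#' Values are clipped to [0, 255] and quantized with round-half-to-even
#' (base R `round`), so repeated write/read cycles are stable.
#'
#' @param image an RGB image array.
#' @param path output path; .png writes PNG, .tif/.tiff writes LZW TIFF.
#' @export
write_rgb_image <- function(image, path) {
  x <- round(clip255(unclass(image))) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L, compression = "LZW"),
    stopf("unsupported image format '%s' (use png or tiff)", ext))
  invisible(path)
}

# Bilinear sampling of `image` (H x W x C) at real-valued (row, col)
# coordinates. Points outside [1, H] x [1, W] get `fill`; `valid` in the
# result marks in-bounds samples.
bilinear_sample <- function(image, coords, fill = c(0, 0, 0)) {
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  r <- coords[, 1]; cc <- coords[, 2]
  # sub-ulp tolerance so border pixels mapped onto themselves stay in bounds
  tol <- 1e-6
  valid <- r >= 1 - tol & r <= h + tol & cc >= 1 - tol & cc <= w + tol
  r <- pmin(pmax(r, 1), h); cc <- pmin(pmax(cc, 1), w)
  r0 <- pmin(pmax(floor(r), 1), h - 1); c0 <- pmin(pmax(floor(cc), 1), w - 1)
  fr <- r - r0; fc <- cc - c0
  out <- matrix(rep(fill, each = nrow(coords)), nrow(coords), nc)
  idx <- function(ri, ci, ch) ri + (ci - 1) * h + (ch - 1) * h * w
  v <- which(valid)
  if (length(v)) {
    for (ch in seq_len(nc)) {
      p00 <- image[idx(r0[v], c0[v], ch)]
      p01 <- image[idx(r0[v], c0[v] + 1, ch)]
      p10 <- image[idx(r0[v] + 1, c0[v], ch)]
      p11 <- image[idx(r0[v] + 1, c0[v] + 1, ch)]
      out[v, ch] <- p00 * (1 - fr[v]) * (1 - fc[v]) + p01 * (1 - fr[v]) * fc[v] +
        p10 * fr[v] * (1 - fc[v]) + p11 * fr[v] * fc[v]
    }
  }
  list(values = out, valid = valid)
}

# All (row, col) pixel-centre coordinates of an H x W raster, in R's
# column-major linear order (index = r + (c - 1) * h).
pixel_grid <- function(h, w) {
  cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h))
}
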