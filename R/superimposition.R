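#' Generalized Procrustes consensus of landmark configurations
#'
#' Computes the consensus (average) shape of corresponding 2D landmark
#' configurations by iterative generalized Procrustes analysis: each
#' configuration is translated to a common centroid and scaled to unit
#' centroid size, then the configurations are alternately rotated onto the
#' current mean and re-averaged until the mean moves less than \code{tol}
#' (or 100 iterations). Rotations are proper (no reflection). With
#' \code{scaling = FALSE}, centroid sizes are left untouched (partial
#' Procrustes).
#'
#' The returned consensus has its centroid exactly at the origin; for use as
#' a pixel-space unwarp target it is rescaled to the mean centroid size of
#' the inputs, and the mean input centroid is stored as the pixel-space
#' anchor.
#'
#' @param configs list of k x 2 landmark matrices ((row, col), same k >= 3
#'   and same landmark order across the stack), or a list of objects with a
#'   \code{points} element.
#' @param scaling include scale in the superimposition (default TRUE).
#' @param tol convergence tolerance on the mean-shape displacement.
#' @return list of class \code{"procrustes_consensus"}: \code{points}
#'   (k x 2 consensus, centroid at origin, mean input centroid size),
#'   \code{anchor} (mean input centroid, length 2), \code{scale} (mean input
#'   centroid size), \code{aligned} (list of aligned configurations, same
#'   scale/origin as \code{points}), \code{iterations}.
#' @export
procrustes_consensus <- function(configs, scaling = TRUE, tol = 1e-8) {
  configs <- lapply(configs, function(x) {
    if (is.list(x) && !is.null(x$points)) x <- x$points
    as.matrix(x)
  })
  if (length(configs) < 2) stopf("need at least 2 configurations")
  k <- nrow(configs[[1]])
  if (k < 3) stopf("need at least 3 landmarks, got %d", k)
  for (i in seq_along(configs)) {
    if (!identical(dim(configs[[i]]), dim(configs[[1]])))
      stopf("configuration %d has %d x %d landmarks, expected %d x 2",
            i, nrow(configs[[i]]), ncol(configs[[i]]), k)
    sv <- svd(scale(configs[[i]], center = TRUE, scale = FALSE))$d
    if (sv[2] <= max(sv[1], 1) * 1e-10)
      stopf("configuration %d is degenerate (landmarks collinear)", i)
  }

  centroids <- t(vapply(configs, colMeans, numeric(2)))
  centered <- lapply(configs, function(x) sweep(x, 2, colMeans(x)))
  sizes <- vapply(centered, function(x) sqrt(sum(x^2)), numeric(1))
  shapes <- if (scaling) Map(`/`, centered, sizes) else centered

  # order-symmetric initialization: plain average of the pre-scaled shapes,
  # so the consensus orientation does not depend on which config comes first
  mean_shape <- Reduce(`+`, shapes) / length(shapes)
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    aligned <- lapply(shapes, rotate_onto, target = mean_shape)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    # fix rotational gauge: align the running mean to the previous one
    new_mean <- rotate_onto(new_mean, mean_shape)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || iterations >= 100L) break
  }
  aligned <- lapply(shapes, rotate_onto, target = mean_shape)

  size <- mean(sizes)
  anchor <- colMeans(centroids)
  structure(list(
    points = mean_shape * size,
    anchor = anchor,
    scale = size,
    aligned = lapply(aligned, `*`, size),
    scaling = scaling,
    iterations = iterations
  ), class = "procrustes_consensus")
}

# Optimal proper rotation of `x` onto `target` (both centered k x 2).
rotate_onto <- function(x, target) {
  s <- svd(crossprod(target, x))
  R <- s$v %*% t(s$u)
  if (det(R) < 0) {       # force a proper rotation
    s$v[, 2] <- -s$v[, 2]
    R <- s$v %*% t(s$u)
  }
  x %*% R
}

#' @export
print.procrustes_consensus <- function(x, ...) {
  cat(sprintf("Procrustes consensus: %d landmarks, %d configurations, %s\n",
              nrow(x$points), length(x$aligned),
              if (x$scaling) "with scaling" else "without scaling"))
  cat(sprintf("Converged in %d iterations; centroid size %.2f px, anchor (%.1f, %.1f)\n",
              x$iterations, x$scale, x$anchor[1], x$anchor[2]))
  invisible(x)
}

# Consensus landmark positions in pixel coordinates.
consensus_pixels <- function(consensus) {
  sweep(consensus$points, 2, consensus$anchor, "+")
}

#' Unwarp an image to the consensus shape
#'
#' Warps an image so that its landmarks land on the consensus configuration,
#' using backward mapping: a 2D thin-plate spline is fitted from the
#' consensus landmarks (in pixel space) to the image's landmarks, evaluated
#' at every output pixel centre, and the source image is sampled bilinearly
#' at the mapped positions. Output pixels whose source location falls
#' outside the image get \code{fill}; a logical validity mask is attached as
#' attribute \code{"valid"} so downstream sampling can avoid fill regions.
#' The output canvas keeps the input dimensions.
#'
#' @param image an RGB image array (0-255).
#' @param landmarks k x 2 matrix of the image's landmark positions
#'   ((row, col), 1-based).
#' @param consensus a \code{"procrustes_consensus"} object (or a k x 2
#'   matrix of target pixel positions).
#' @param fill RGB triple used outside the source footprint; default black.
#' @return the unwarped \code{"rgb_image"} with attribute \code{"valid"}
#'   (H x W logical matrix).
#' @export
unwarp_to_consensus <- function(image, landmarks, consensus, fill = c(0, 0, 0)) {
  landmarks <- as.matrix(landmarks)
  target <- if (inherits(consensus, "procrustes_consensus"))
    consensus_pixels(consensus) else as.matrix(consensus)
  if (!identical(dim(landmarks), dim(target)))
    stopf("landmarks (%d x %d) and consensus (%d x %d) differ",
          nrow(landmarks), ncol(landmarks), nrow(target), ncol(target))
  h <- dim(image)[1]; w <- dim(image)[2]
  warp <- tps(target, landmarks, lambda = 0)
  grid <- pixel_grid(h, w)
  src <- predict(warp, grid)
  smp <- bilinear_sample(unclass(image), src, fill = fill)
  out <- array(smp$values, c(h, w, 3))
  for (a in c("id", "condition", "source"))
    attr(out, a) <- attr(image, a, exact = TRUE)
  valid <- smp$valid
  in_mask <- attr(image, "valid", exact = TRUE)
  if (!is.null(in_mask)) {
    # carry the source's own validity through the warp: a resampled pixel is
    # valid only if its source neighbourhood was fully valid
    m <- bilinear_sample(array(as.numeric(in_mask), c(h, w, 1)), src, fill = 0)
    valid <- valid & (m$values[, 1] >= 1 - 1e-9)
  }
  attr(out, "valid") <- matrix(valid, h, w)
  class(out) <- c("rgb_image", class(out))
  out
}

#' Read / write landmark files
#'
#' Plain-text format, one block per image: a line \code{ID <image id>}
#' followed by k lines \code{row,col} (1-based pixel coordinates, pixel
#' centres at integers). Blank lines between blocks; \code{#} lines are
#' comments.
#'
#' @param sets named list of k x 2 landmark matrices (names are image ids).
#' @param path file path.
#' @export
write_landmarks <- function(sets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# landmark file: blocks of 'ID <image>' then k lines 'row,col'", con)
  writeLines("# coordinates are 1-based pixel centres", con)
  for (id in names(sets)) {
    writeLines(paste("ID", id), con)
    m <- sets[[id]]
    writeLines(sprintf("%.6g,%.6g", m[, 1], m[, 2]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @return \code{read_landmarks}: named list of k x 2 matrices.
#' @export
read_landmarks <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  id <- NULL
  rows <- list()
  flush_block <- function() {
    if (!is.null(id)) {
      m <- do.call(rbind, rows)
      colnames(m) <- c("row", "col")
      out[[id]] <<- m
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "ID ")) {
      flush_block()
      id <- sub("^ID +", "", ln)
      rows <- list()
    } else {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(ln, ",")[[1]])
    }
  }
  flush_block()
  out
}
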