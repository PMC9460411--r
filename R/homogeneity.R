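#' Sample random evaluation points in a region of interest
#'
#' Draws \code{n} distinct pixel positions uniformly without replacement
#' from a rectangular ROI shrunk by \code{margin} on every side (the margin
#' keeps subsequent sampling windows inside the image). Deterministic given
#' \code{seed}; the caller's RNG state is untouched.
#'
#' @param roi rectangle \code{c(r0, c0, r1, c1)}, 1-based inclusive.
#' @param n number of points.
#' @param margin border (pixels) excluded on each side of the ROI; must be
#'   at least half the sampling window.
#' @param seed integer seed (mandatory, recorded downstream).
#' @return n x 2 integer matrix of (row, col) positions.
#' @export
sample_points <- function(roi, n, margin, seed) {
  roi <- as.numeric(roi)
  r0 <- roi[1] + margin; c0 <- roi[2] + margin
  r1 <- roi[3] - margin; c1 <- roi[4] - margin
  nr <- r1 - r0 + 1; nc <- c1 - c0 + 1
  if (nr < 1 || nc < 1 || nr * nc < n)
    stopf("ROI too small: %g x %g cells available after margin %d, need %d",
          max(nr, 0), max(nc, 0), margin, n)
  cells <- with_seed(seed, sample.int(nr * nc, n))
  cbind(row = r0 + (cells - 1) %% nr,
        col = c0 + (cells - 1) %/% nr)
}

#' Mean colour of square windows around sample points
#'
#' For each point, the arithmetic mean of each channel over the
#' \code{window} x \code{window} pixel block anchored so that a point
#' \code{(r, c)} with the default \code{window = 8} spans rows
#' \code{(r-4):(r+3)} and columns \code{(c-4):(c+3)}.
#'
#' @param image an RGB image array (0-255).
#' @param points n x 2 matrix of (row, col) positions.
#' @param window window side length in pixels (default 8).
#' @return n x 3 matrix of per-channel window means.
#' @export
window_means <- function(image, points, window = 8) {
  points <- as.matrix(points)
  h <- dim(image)[1]; w <- dim(image)[2]
  lo <- floor(window / 2)
  hi <- window - lo - 1
  if (any(points[, 1] - lo < 1) || any(points[, 1] + hi > h) ||
      any(points[, 2] - lo < 1) || any(points[, 2] + hi > w))
    stopf("a %d x %d window falls outside the %d x %d image", window, window, h, w)
  img <- unclass(image)
  out <- matrix(NA_real_, nrow(points), 3)
  for (i in seq_len(nrow(points))) {
    r <- points[i, 1]; cc <- points[i, 2]
    block <- img[(r - lo):(r + hi), (cc - lo):(cc + hi), , drop = FALSE]
    out[i, ] <- colMeans(matrix(block, window * window, 3))
  }
  colnames(out) <- c("R", "G", "B")
  out
}

#' Per-point RMS of across-image channel standard deviations
#'
#' The colour-homogeneity statistic: at each sampled point, the sample
#' standard deviation (n-1 denominator) of the window means across the
#' images of a condition is taken per channel, and the root mean square of
#' the three channel SDs summarises them into one value (grey levels).
#' Zero exactly when all images agree at that window.
#'
#' @param stack_means numeric images x n x 3 array of window means (one
#'   slice per image of the condition).
#' @return numeric vector of n RMS-SD values.
#' @export
rms_sd <- function(stack_means) {
  d <- dim(stack_means)
  if (is.null(d) || length(d) != 3)
    stopf("stack_means must be an images x n x 3 array")
  if (d[1] < 2) stopf("need at least 2 images, got %d", d[1])
  sds <- apply(stack_means, c(2, 3), stats::sd)
  sqrt(rowMeans(sds^2))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired Wilcoxon signed-rank test. Zero differences are
#' dropped; tied absolute differences receive midranks; the reported
#' statistic is the smaller of the positive and negative rank sums. The
#' null distribution is computed exactly — by convolution over the (mid)rank
#' values, equivalent to enumerating all \code{2^n} sign assignments — when
#' \code{n_effective <= 12} (or \code{method = "exact"}), and otherwise by
#' a normal approximation with tie correction, continuity correction and an
#' Edgeworth fourth-moment refinement (which keeps the approximate p within
#' 0.005 of the exact one for n as low as 20).
#' If every difference is zero the test is degenerate: p = 1
#' and the \code{degenerate} flag is set (no error).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param method \code{"auto"} (default), \code{"exact"} or
#'   \code{"approx"}.
#' @return list of class \code{"wilcoxon_signed_rank"}: \code{statistic}
#'   (smaller signed-rank sum W), \code{n_effective}, \code{p_two_sided},
#'   \code{method} used, \code{degenerate}.
#' @export
wilcoxon_signed_rank <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(x) != length(y))
    stopf("x and y lengths differ (%d vs %d)", length(x), length(y))
  if (length(x) < 1) stopf("need at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(statistic = 0, n_effective = 0L, p_two_sided = 1,
                          method = "degenerate", degenerate = TRUE),
                     class = "wilcoxon_signed_rank"))
  }
  rk <- rank(abs(d))                       # midranks for ties
  w_pos <- sum(rk[d > 0])
  total <- n * (n + 1) / 2
  w <- min(w_pos, total - w_pos)
  use_exact <- method == "exact" || (method == "auto" && n <= 12)
  if (use_exact) {
    p <- signed_rank_exact_p(rk, w)
    used <- "exact"
  } else {
    mu <- total / 2
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w + 0.5 - mu) / sqrt(sigma2)            # lower tail, continuity-corrected
    lower <- stats::pnorm(z)
    # Edgeworth fourth-cumulant refinement: the signed-rank sum is a sum of
    # independent bounded terms with kurtosis correction kappa4 = -sum(r^4)/8.
    # The term is an asymptotic correction for the body of the distribution;
    # deep in the tail it would swamp the leading term, so it is only applied
    # while it stays small relative to the Gaussian tail itself.
    k4 <- -sum(rk^4) / 8
    edge <- stats::dnorm(z) * (k4 / (24 * sigma2^2)) * (z^3 - 3 * z)
    if (abs(edge) < 0.5 * lower) lower <- lower - edge
    p <- min(1, max(2 * lower, .Machine$double.xmin))
    used <- "normal_approximation"
  }
  structure(list(statistic = w, n_effective = as.integer(n),
                 p_two_sided = p, method = used, degenerate = FALSE),
            class = "wilcoxon_signed_rank")
}

# Exact two-sided p for the signed-rank statistic with (mid)ranks `rk`:
# P(min(W+, total - W+) <= w) under random signs. The null distribution of
# W+ is built by convolution over the doubled ranks (integers even with
# midranks), which enumerates all 2^n sign assignments implicitly.
signed_rank_exact_p <- function(rk, w) {
  r2 <- as.integer(round(2 * rk))
  tot2 <- sum(r2)
  dist <- numeric(tot2 + 1)        # dist[s + 1] = #assignments with 2*W+ = s
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(tot2 + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  s <- 0:tot2
  wmin <- pmin(s, tot2 - s) / 2
  sum(dist[wmin <= w + 1e-9])
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test (two-sided)\n")
  if (x$degenerate) {
    cat("All paired differences are zero: degenerate data, p = 1\n")
  } else {
    cat(sprintf("W = %g (smaller rank sum), n effective = %d, method = %s\n",
                x$statistic, x$n_effective, x$method))
    cat(sprintf("p = %.4g\n", x$p_two_sided))
  }
  invisible(x)
}

#' Compare colour homogeneity between two superimposed stacks
#'
#' Runs the paired homogeneity analysis: samples \code{n} random window
#' positions once, extracts per-image window means in both conditions at
#' the same points, reduces each condition to per-point RMS-SD values, and
#' compares the paired values with a two-sided Wilcoxon signed-rank test.
#' Windows that touch invalid (fill) pixels of any image — as flagged by
#' the \code{"valid"} masks produced by [unwarp_to_consensus()] — are
#' rejected and redrawn; the rejection count is recorded.
#'
#' @param stack_a,stack_b lists of RGB images, both superimposed to the same
#'   consensus (condition A is conventionally "calibrated", B
#'   "non-calibrated").
#' @param roi rectangle \code{c(r0, c0, r1, c1)}, 1-based inclusive; default
#'   the full image.
#' @param n number of sampled points (default 300).
#' @param seed integer seed for the point sampling.
#' @param window window side (default 8).
#' @param labels length-2 character vector naming the conditions.
#' @return list of class \code{"homogeneity_comparison"}: \code{points},
#'   \code{window_means} (per condition, images x n x 3), \code{rms_sd}
#'   (n x 2 matrix), \code{summary} (mean, SD, median per condition),
#'   \code{test} (a \code{"wilcoxon_signed_rank"}), \code{n_rejected},
#'   \code{seed}.
#' @export
compare_conditions <- function(stack_a, stack_b, roi = NULL, n = 300,
                               seed = 1, window = 8,
                               labels = c("calibrated", "non-calibrated")) {
  if (length(stack_a) < 2 || length(stack_b) < 2)
    stopf("each condition needs at least 2 images")
  d <- dim(stack_a[[1]])
  for (img in c(stack_a, stack_b))
    if (!identical(dim(img)[1:2], d[1:2]))
      stopf("all images must share dimensions %d x %d", d[1], d[2])
  if (is.null(roi)) roi <- c(1, 1, d[1], d[2])
  margin <- ceiling(window / 2)

  # combined validity: a window is usable only if fully valid in every image
  masks <- lapply(c(stack_a, stack_b), function(img) {
    m <- attr(img, "valid", exact = TRUE)
    if (is.null(m)) matrix(TRUE, d[1], d[2]) else m
  })
  combined <- Reduce(`&`, masks)

  lo <- floor(window / 2); hi <- window - lo - 1
  window_ok <- function(pts) {
    vapply(seq_len(nrow(pts)), function(i) {
      all(combined[(pts[i, 1] - lo):(pts[i, 1] + hi),
                   (pts[i, 2] - lo):(pts[i, 2] + hi)])
    }, logical(1))
  }
  key <- function(m) paste(m[, 1], m[, 2])
  pts <- sample_points(roi, n, margin, seed)
  ok <- window_ok(pts)
  n_rejected <- sum(!ok)
  kept <- pts[ok, , drop = FALSE]
  attempt <- 0L
  while (nrow(kept) < n) {
    attempt <- attempt + 1L
    if (attempt > 100L)
      stopf("could not place %d valid windows in the ROI (too much fill)", n)
    fresh <- sample_points(roi, n, margin, substream_seed(seed, "resample", attempt))
    fresh <- fresh[!(key(fresh) %in% key(kept)), , drop = FALSE]
    fok <- window_ok(fresh)
    n_rejected <- n_rejected + sum(!fok)
    kept <- rbind(kept, fresh[fok, , drop = FALSE])
  }
  pts <- kept[seq_len(n), , drop = FALSE]

  means_for <- function(stack) {
    out <- array(NA_real_, c(length(stack), n, 3))
    for (i in seq_along(stack)) out[i, , ] <- window_means(stack[[i]], pts, window)
    out
  }
  wm_a <- means_for(stack_a)
  wm_b <- means_for(stack_b)
  rms <- cbind(rms_sd(wm_a), rms_sd(wm_b))
  colnames(rms) <- labels
  summ <- data.frame(
    condition = labels,
    mean = colMeans(rms),
    sd = apply(rms, 2, stats::sd),
    median = apply(rms, 2, stats::median),
    row.names = NULL
  )
  test <- wilcoxon_signed_rank(rms[, 1], rms[, 2])
  structure(list(points = pts,
                 window_means = stats::setNames(list(wm_a, wm_b), labels),
                 rms_sd = rms, summary = summ, test = test,
                 n_rejected = n_rejected, seed = seed, window = window),
            class = "homogeneity_comparison")
}

#' @export
print.homogeneity_comparison <- function(x, ...) {
  cat(sprintf("Colour-homogeneity comparison: %d points, %d x %d windows (seed %d)\n",
              nrow(x$points), x$window, x$window, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s RMS-SD mean %.2f  sd %.2f  median %.2f\n",
                s$condition[i], s$mean[i], s$sd[i], s$median[i]))
  if (x$n_rejected > 0)
    cat(sprintf("  (%d windows rejected for touching fill regions)\n", x$n_rejected))
  print(x$test)
  invisible(x)
}

#' @export
summary.homogeneity_comparison <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' @export
plot.homogeneity_comparison <- function(x, ...) {
  graphics::boxplot(x$rms_sd, ylab = "RMS of channel SDs (grey levels)",
                    main = "Per-point colour homogeneity", ...)
  invisible(x)
}

#' Write homogeneity results to disk
#'
#' Writes the per-point RMS-SD values per condition as CSV and a JSON
#' summary (per-condition mean/SD/median, W, p, n effective, seed).
#'
#' @param result a \code{"homogeneity_comparison"}.
#' @param csv_path,json_path output paths.
#' @export
write_homogeneity_results <- function(result, csv_path, json_path) {
  df <- data.frame(row = result$points[, 1], col = result$points[, 2],
                   result$rms_sd, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  doc <- list(
    summary = result$summary,
    wilcoxon = list(W = result$test$statistic,
                    p_two_sided = result$test$p_two_sided,
                    n_effective = result$test$n_effective,
                    method = result$test$method,
                    degenerate = result$test$degenerate),
    n_points = nrow(result$points),
    n_rejected = result$n_rejected,
    window = result$window,
    seed = result$seed
  )
  jsonlite::write_json(doc, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(result)
}
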