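#' Fit a thin-plate-spline interpolant
#'
#' Fits a thin-plate spline (TPS) mapping a set of source points onto a set of
#' target points. Two input dimensionalities are supported: \code{D = 2} for
#' image-geometry warps (landmark superimposition) and \code{D = 3} for maps of
#' RGB colour space (radiometric calibration against a reference chart). The
#' fitted map is the sum of an affine part and a radial-basis part,
#' \deqn{f(x) = c + A x + \sum_{i=1}^{K} w_i \, U(\|x - s_i\|),}
#' with kernel \eqn{U(r) = r^2 \log r} in 2D (the biharmonic fundamental
#' solution in the plane, \eqn{U(0) = 0}) and \eqn{U(r) = -r} in 3D. The
#' weights satisfy the orthogonality side conditions
#' \eqn{\sum_i w_i = 0} and \eqn{\sum_i w_i s_i = 0} per output dimension, so
#' the radial part carries no affine component.
#'
#' Coefficients are obtained from the standard bordered linear system
#' \deqn{\begin{bmatrix} K + \lambda I & P \\ P^\top & 0 \end{bmatrix}
#'       \begin{bmatrix} W \\ A \end{bmatrix} =
#'       \begin{bmatrix} T \\ 0 \end{bmatrix}}
#' where \eqn{K_{ij} = U(\|s_i - s_j\|)} and \eqn{P = [1, S]}. With
#' \code{lambda = 0} the spline interpolates every correspondence exactly;
#' \code{lambda > 0} trades interpolation for smoothness by penalising the
#' bending energy (\code{lambda} is added to the kernel diagonal, in squared
#' units of the input coordinates).
#'
#' @param source numeric K x D matrix of source points (D = 2 or 3). For
#'   image geometry the convention is (row, col), 1-based, pixel centres at
#'   integer coordinates; for colour maps the columns are (R, G, B) on the
#'   0-255 scale.
#' @param target numeric K x M matrix of target points, same K.
#' @param lambda nonnegative smoothing parameter; default 0 (exact
#'   interpolation).
#' @return An object of class \code{"tps"} with components
#'   \code{control_points} (K x D), \code{weights} (K x M),
#'   \code{affine} ((D+1) x M; first row the constant term), \code{dim_in},
#'   \code{dim_out}, \code{lambda}, and \code{fitted} (the map evaluated at
#'   the control points).
#' @seealso [predict.tps()], [tps_parameter_count()], [write_tps_json()]
#' @examples
#' src <- cbind(c(0, 0, 10, 10, 5), c(0, 10, 0, 10, 5))
#' dst <- src + 2
#' fit <- tps(src, dst)
#' max(abs(predict(fit, src) - dst))  # exact interpolation
#' @export
tps <- function(source, target, lambda = 0) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  storage.mode(source) <- "double"
  storage.mode(target) <- "double"
  K <- nrow(source)
  D <- ncol(source)
  if (!D %in% c(2L, 3L))
    stopf("tps supports 2 or 3 input dimensions, got %d", D)
  if (nrow(target) != K)
    stopf("source has %d points but target has %d", K, nrow(target))
  if (!all(is.finite(source)) || !all(is.finite(target)))
    stopf("source and target must be finite")
  if (K < D + 1)
    stopf("need at least %d points for a %dD thin-plate spline, got %d",
          D + 1, D, K)
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0)
    stopf("lambda must be a single nonnegative number")

  # Degeneracy: the affine side block P = [1, S] must have full column rank,
  # i.e. the source points must not be collinear (2D) / coplanar (3D).
  ctr <- scale(source, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[D] <= max(sv[1], 1) * 1e-10)
    stopf(paste0("degenerate source configuration: points are ",
                 if (D == 2) "collinear" else "coplanar",
                 " (rank %d < %d after centering)"), sum(sv > sv[1] * 1e-10), D)

  Kmat <- tps_kernel(cross_dist(source, source), D)
  P <- cbind(1, source)
  n <- K + D + 1L
  A <- matrix(0, n, n)
  A[1:K, 1:K] <- Kmat + diag(lambda, K)
  A[1:K, (K + 1):n] <- P
  A[(K + 1):n, 1:K] <- t(P)
  rhs <- rbind(target, matrix(0, D + 1L, ncol(target)))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stopf("singular thin-plate-spline system (degenerate source configuration): %s",
          conditionMessage(e)))
  # one step of iterative refinement keeps the side conditions near machine
  # precision even on 0-255-scale coordinates
  sol <- sol + solve(A, rhs - A %*% sol)

  weights <- sol[1:K, , drop = FALSE]
  affine <- sol[(K + 1):n, , drop = FALSE]
  obj <- structure(list(
    dim_in = D, dim_out = ncol(target),
    control_points = source, weights = weights, affine = affine,
    lambda = lambda, target = target
  ), class = "tps")
  obj$fitted <- predict(obj, source)
  obj
}

# Radial kernel: r^2 log r in 2D (0 at r = 0), -r in 3D.
tps_kernel <- function(r, dim_in) {
  if (dim_in == 2L) {
    out <- r * r * log(r)
    out[r == 0] <- 0
    out
  } else {
    -r
  }
}

#' Evaluate a fitted thin-plate spline at new points
#'
#' @param object a fitted \code{"tps"} model.
#' @param newdata numeric N x D matrix of evaluation points (D must equal
#'   \code{object$dim_in}). A single point may be given as a vector.
#' @param ... unused.
#' @return numeric N x M matrix of mapped points.
#' @export
predict.tps <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$dim_in)
    stopf("model expects %d input dimensions, newdata has %d",
          object$dim_in, ncol(newdata))
  U <- tps_kernel(cross_dist(newdata, object$control_points), object$dim_in)
  cbind(1, newdata) %*% object$affine + U %*% object$weights
}

#' @export
print.tps <- function(x, ...) {
  cat(sprintf("Thin-plate spline: %dD -> %dD, K = %d control points, lambda = %g\n",
              x$dim_in, x$dim_out, nrow(x$control_points), x$lambda))
  pc <- tps_parameter_count(x)
  cat(sprintf("Parameters: %d affine + %d weights = %d total\n",
              pc["affine_count"], pc["weight_count"], pc["total"]))
  invisible(x)
}

#' @export
summary.tps <- function(object, ...) {
  res <- residuals(object)
  cat(sprintf("Thin-plate spline fit (%dD -> %dD)\n",
              object$dim_in, object$dim_out))
  cat(sprintf("Control points: %d   lambda: %g\n",
              nrow(object$control_points), object$lambda))
  cat(sprintf("Max |residual| at control points: %.3g\n", max(abs(res))))
  cat(sprintf("Max |weight|: %.3g   max |side-condition violation|: %.3g\n",
              max(abs(object$weights)), max(abs(tps_side_conditions(object)))))
  invisible(object)
}

#' @export
coef.tps <- function(object, ...) {
  list(affine = object$affine, weights = object$weights)
}

#' @export
residuals.tps <- function(object, ...) {
  object$target - object$fitted
}

# Side-condition residuals: colSums(W) and t(S) %*% W, stacked; all should be
# numerically zero for a valid fit.
tps_side_conditions <- function(model) {
  rbind(colSums(model$weights), crossprod(model$control_points, model$weights))
}

#' Parameter bookkeeping of a fitted thin-plate spline
#'
#' A D-to-M thin-plate spline on K correspondences has \eqn{M (D + 1)} affine
#' parameters and \eqn{M K} radial-basis weights. In the classic 2D-to-2D case
#' this is the familiar count of six global affine parameters plus 2K
#' coefficients, \eqn{2(K + 3)} in total.
#'
#' @param model a fitted \code{"tps"} object.
#' @return named integer vector with elements \code{affine_count},
#'   \code{weight_count} and \code{total}.
#' @export
tps_parameter_count <- function(model) {
  stopifnot(inherits(model, "tps"))
  K <- nrow(model$control_points)
  a <- model$dim_out * (model$dim_in + 1L)
  w <- model$dim_out * K
  c(affine_count = a, weight_count = w, total = a + w)
}

#' Serialize a thin-plate-spline model to JSON
#'
#' Writes dimensions, control points, weights, affine coefficients and lambda
#' so a fitted map can be reused across runs.
#'
#' @param model a fitted \code{"tps"} object.
#' @param path file path to write.
#' @export
write_tps_json <- function(model, path) {
  stopifnot(inherits(model, "tps"))
  doc <- list(
    dim_in = model$dim_in, dim_out = model$dim_out,
    lambda = model$lambda,
    control_points = model$control_points,
    weights = model$weights,
    affine = model$affine,
    target = model$target
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a thin-plate-spline model from JSON
#'
#' @param path file written by [write_tps_json()].
#' @return a \code{"tps"} object.
#' @export
read_tps_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- structure(list(
    dim_in = as.integer(doc$dim_in), dim_out = as.integer(doc$dim_out),
    control_points = as.matrix(doc$control_points),
    weights = as.matrix(doc$weights),
    affine = as.matrix(doc$affine),
    lambda = doc$lambda,
    target = as.matrix(doc$target)
  ), class = "tps")
  obj$fitted <- predict(obj, obj$control_points)
  obj
}
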