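#' Rigid transform in 3-D
#'
#' A proper rigid-body transform `p -> R p + t` used to express pose changes
#' of the knee between scanning sessions and to map landmark sets between
#' coordinate frames. The rotation must be proper orthonormal
#' (`det(R) = +1`, columns orthonormal to 1e-9).
#'
#' @param rotation 3x3 proper orthonormal rotation matrix.
#' @param translation length-3 numeric translation in mm.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(t, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || anyNA(rotation))
    stop("rotation must be a numeric 3x3 matrix")
  if (length(translation) != 3L || anyNA(translation))
    stop("translation must be a length-3 numeric vector")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9)
    stop(sprintf("rotation is not orthonormal (max deviation %.3g)", err))
  if (det(rotation) < 0)
    stop("rotation must be proper (det = +1), reflections are not allowed")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points Length-3 vector or n x 3 matrix of points (mm).
#' @return Transformed points, same shape as the input. Pairwise distances
#'   are preserved.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), nrow = 1L) else as.matrix(points)
  if (ncol(p) != 3L) stop("points must have 3 coordinates")
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`,
#' i.e. `compose_transforms(second, first)(p) == second(first(p))`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  stopifnot(inherits(second, "rigid_transform"), inherits(first, "rigid_transform"))
  rigid_transform(second$rotation %*% first$rotation,
                  drop(second$rotation %*% first$translation) + second$translation)
}

#' In-plane (axial) pose
#'
#' Convenience constructor for a rigid transform confined to the axial
#' plane: a rotation about the superior axis plus an in-plane translation.
#' Session-to-session posture differences in the phantom are modelled this
#' way so that the axial geometry (and hence the analytic ground truth)
#' is preserved.
#'
#' @param theta_deg Rotation about the superior (z) axis, degrees.
#' @param tx,ty In-plane translation components, mm.
#' @return A [rigid_transform()].
#' @export
planar_pose <- function(theta_deg = 0, tx = 0, ty = 0) {
  th <- theta_deg * pi / 180
  r <- matrix(c(cos(th), sin(th), 0,
                -sin(th), cos(th), 0,
                0, 0, 1), 3L, 3L)
  rigid_transform(r, c(tx, ty, 0))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", format(x$translation), "\n")
  invisible(x)
}

is_identity_transform <- function(t, tol = 1e-12) {
  max(abs(t$rotation - diag(3))) < tol && max(abs(t$translation)) < tol
}

#' Read or write a rigid transform as JSON
#'
#' Transforms (for example a supine-to-upright registration computed in
#' external software) are exchanged as JSON with a 3x3 `rotation` and a
#' length-3 `translation`.
#'
#' @param transform A [rigid_transform()].
#' @param path File path.
#' @return `read_transform` returns a [rigid_transform()];
#'   `write_transform` returns `path` invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  jsonlite::write_json(list(rotation = transform$rotation,
                            translation = transform$translation),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation, x$translation)
}
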