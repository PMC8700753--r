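#' Rigid transform in mm world space
#'
#' A proper rigid transform (rotation plus translation) mapping points
#' between world frames, e.g. from the MRI frame to the CT frame. The
#' rotation must be orthonormal with determinant +1; reflections are
#' rejected because a mirrored solution would silently flip anatomy.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `cf_transform`.
#' @examples
#' t1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(1, 2, 3))
#' p <- matrix(rnorm(30), ncol = 3)
#' max(abs(apply_transform(invert_transform(t1), apply_transform(t1, p)) - p))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (reflection); not a proper rotation")
  structure(list(rotation = rotation, translation = translation),
            class = "cf_transform")
}

#' @export
print.cf_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<cf_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis numeric length-3 axis (need not be unit length).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Angle of a rotation matrix in degrees
#' @param R 3x3 rotation matrix.
#' @return Rotation angle in degrees, in [0, 180].
#' @export
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a `cf_transform`.
#' @param points n x 3 matrix of mm coordinates (or a length-3 vector).
#' @return Transformed points with the same shape.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "cf_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first and
#' then `a` (i.e. `a(b(x))`).
#' @param a,b `cf_transform` objects.
#' @return A `cf_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `cf_transform`.
#' @return The inverse `cf_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' The schema is `{rotation: 9 floats row-major, translation: 3 floats,
#' units: "mm"}`.
#' @param transform a `cf_transform`.
#' @param path file path.
#' @return `read_transform` returns a `cf_transform`; `write_transform`
#'   returns the path invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "cf_transform"))
  obj <- list(rotation = as.numeric(t(transform$rotation)),
              translation = transform$translation,
              units = "mm")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}
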