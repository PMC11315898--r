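#' Rigid-body transform
#'
#' A proper rigid transform in three dimensions: a rotation (3x3 orthonormal
#' matrix with determinant +1) followed by a translation in Angstrom.
#' Transforms act on column vectors: `x' = R x + t`, in a right-handed frame.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation vector (Angstrom).
#' @param tol orthonormality tolerance.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-6) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform: rotation must be 3x3 and translation length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol || abs(det(rotation) - 1) > tol)
    stop(sprintf(
      "rigid_transform: rotation is not a proper orthonormal matrix (orthogonality error %.2e, det %.8f)",
      err, det(rotation)))
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation angle:",
      sprintf("%.2f deg", rotation_angle(x$R)),
      "\n  translation:", sprintf("%.3f", x$t), "\n")
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform equivalent to applying `b` first
#' and then `a`: `x -> a$R (b$R x + b$t) + a$t`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#'
#' @param a a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_invert <- function(a) {
  stopifnot(is_rigid_transform(a))
  rigid_transform(t(a$R), as.numeric(-t(a$R) %*% a$t))
}

#' Apply a rigid transform to coordinates
#'
#' @param a a `rigid_transform`.
#' @param xyz n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates, same shape as input.
#' @export
rt_apply <- function(a, xyz) {
  stopifnot(is_rigid_transform(a))
  if (is.null(dim(xyz))) return(as.numeric(a$R %*% xyz) + a$t)
  sweep(xyz %*% t(a$R), 2L, a$t, "+")
}

#' Rotation angle of a rotation matrix
#'
#' Geodesic distance of `R` from the identity, in degrees.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Geodesic distance between two rotations, degrees
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Angle of `t(R1) %*% R2` in degrees.
#' @export
rotation_distance <- function(R1, R2) rotation_angle(crossprod(R1, R2))

# axis (unit vector) / angle (degrees) -> rotation matrix (Rodrigues)
rotation_about_axis <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# unit quaternion (w,x,y,z) -> rotation matrix
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Random rigid transform (seeded)
#'
#' Uniform random rotation (quaternion method) plus a uniform random
#' translation in a cube, for property tests and fixture perturbation.
#'
#' @param max_translation half-width of the translation cube (Angstrom).
#' @param max_rotation optional cap on the rotation angle in degrees; `NULL`
#'   draws from the uniform (Haar) distribution over all rotations.
#' @return A `rigid_transform`. Uses the current RNG stream.
#' @export
random_transform <- function(max_translation = 50, max_rotation = NULL) {
  if (is.null(max_rotation)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    R <- quat_to_matrix(q)
  } else {
    ax <- stats::rnorm(3)
    ang <- stats::runif(1, 0, max_rotation)
    R <- rotation_about_axis(ax, ang)
  }
  rigid_transform(R, stats::runif(3, -max_translation, max_translation))
}

# short deterministic text key for a transform (tie-breaking)
transform_key <- function(a) {
  paste(sprintf("%.6f", c(a$R, a$t)), collapse = ",")
}
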