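# Low-level rotation utilities shared by all modules.
# Convention: rotation matrices act on column vectors, map body -> world.
# Angles are degrees at every exported API; radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about a coordinate axis
#'
#' @param angle_deg rotation angle in degrees (right-handed about the axis).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis (Rodrigues)
#'
#' @param axis 3-vector (need not be unit).
#' @param angle_deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) {
    if (abs(angle_deg) < 1e-12) return(diag(3))
    stop("rotation_about_axis: zero axis with non-zero angle")
  }
  a <- axis / n
  t <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

#' Axis-angle (log map) of a rotation
#'
#' Returns the rotation vector \code{axis * angle} in degrees; the zero vector
#' for the identity.
#' @param R 3x3 rotation matrix.
#' @return length-3 numeric, degrees.
#' @export
rotation_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (theta > pi - 1e-6) {
    # near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    a <- sqrt(pmax(diag(B), 0))
    i <- which.max(a)
    a <- B[, i] / a[i]
    a <- a / sqrt(sum(a^2))
    return(rad2deg(theta) * a)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(theta))
  rad2deg(theta) * w
}

#' Exponential map: rotation vector (degrees) to matrix
#' @param w length-3 rotation vector, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_exp <- function(w) {
  ang <- sqrt(sum(w^2))
  if (ang < 1e-15) return(diag(3))
  rotation_about_axis(w / ang, ang)
}

#' Angle between two 3D vectors, degrees
#' @keywords internal
vec_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  rad2deg(acos(max(-1, min(1, ca))))
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-15) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Project a near-rotation matrix onto SO(3)
#' @keywords internal
project_so3 <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Time-stamped series of rotations
#'
#' Container for per-frame orthonormal rotations of the head or one eye.
#'
#' @param timestamps strictly increasing times, seconds.
#' @param rotations 3x3xN array (or list of 3x3 matrices), each orthonormal
#'   with determinant +1.
#' @param frame_label one of \code{"head"}, \code{"left_eye"}, \code{"right_eye"}.
#' @return object of class \code{rotation_series}.
#' @export
rotation_series <- function(timestamps, rotations, frame_label = "head") {
  if (is.list(rotations)) {
    rotations <- array(unlist(rotations), dim = c(3, 3, length(rotations)))
  }
  stopifnot(length(dim(rotations)) == 3, all(dim(rotations)[1:2] == c(3, 3)))
  n <- dim(rotations)[3]
  if (length(timestamps) != n) stop("timestamps and rotations disagree in length")
  if (n > 1 && any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  if (!frame_label %in% c("head", "left_eye", "right_eye")) {
    stop("frame_label must be head, left_eye or right_eye")
  }
  for (i in seq_len(n)) {
    if (!is_rotation(rotations[, , i], tol = 1e-8)) {
      stop(sprintf("rotation %d is not orthonormal with det +1", i))
    }
  }
  structure(list(timestamps = as.numeric(timestamps), rotations = rotations,
                 frame_label = frame_label),
            class = "rotation_series")
}

#' @export
length.rotation_series <- function(x) dim(x$rotations)[3]

#' @export
print.rotation_series <- function(x, ...) {
  cat(sprintf("<rotation_series '%s': %d frames, t = [%.3f, %.3f] s>\n",
              x$frame_label, length(x), min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Chordal L2 mean of a set of rotations
#'
#' The rotation minimizing the summed squared Frobenius distance to the set:
#' the SO(3) projection of the elementwise mean matrix.
#'
#' @param rotations 3x3xN array or rotation_series.
#' @return 3x3 rotation matrix.
#' @export
chordal_mean <- function(rotations) {
  if (inherits(rotations, "rotation_series")) rotations <- rotations$rotations
  M <- apply(rotations, c(1, 2), mean)
  project_so3(M)
}
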