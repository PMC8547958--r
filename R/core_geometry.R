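# Head-frame construction, eye-rotation composition, geodesic interpolation,
# rigid registration, horizon alignment and differential rotations.

#' Anatomical landmark set for head-frame construction
#'
#' @param left_canthus,right_canthus,left_nostril,right_nostril 3D positions (m)
#'   of the medial canthi and the nostrils.
#' @param led_positions optional list of 3D LED positions (m).
#' @return object of class \code{anatomical_landmarks}.
#' @export
anatomical_landmarks <- function(left_canthus, right_canthus,
                                 left_nostril, right_nostril,
                                 led_positions = list()) {
  pts <- list(left_canthus = left_canthus, right_canthus = right_canthus,
              left_nostril = left_nostril, right_nostril = right_nostril)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (length(p) != 3 || !all(is.finite(p))) stop(sprintf("%s must be a finite 3-vector", nm))
  }
  if (sqrt(sum((left_canthus - right_canthus)^2)) < 1e-12) stop("canthi coincide")
  if (sqrt(sum((left_nostril - right_nostril)^2)) < 1e-12) stop("nostrils coincide")
  structure(c(pts, list(led_positions = led_positions)), class = "anatomical_landmarks")
}

#' Build the head-fixed forward-left-up coordinate frame
#'
#' The nose point is the mean of the nostrils and the eye midpoint the mean of
#' the canthi. A pre-forward vector runs from the eye midpoint to the nose; the
#' left vector is orthogonal to pre-forward and to the inter-canthus axis.
#' The returned forward vector is the pre-forward vector elevated by
#' \code{tilt_deg} about the left axis, which places the frame on the
#' bregma-lambda sagittal plane convention for the mouse skull.
#'
#' @param landmarks \code{anatomical_landmarks}.
#' @param tilt_deg upward tilt of the eyes-nose plane, degrees (default 40).
#' @return object of class \code{head_frame} with fields \code{origin} (eye
#'   midpoint), \code{forward}, \code{left}, \code{up}, and \code{rotation}
#'   (columns forward/left/up: head -> world).
#' @export
build_head_frame <- function(landmarks, tilt_deg = 40) {
  stopifnot(inherits(landmarks, "anatomical_landmarks"))
  nose <- (landmarks$left_nostril + landmarks$right_nostril) / 2
  eye_mid <- (landmarks$left_canthus + landmarks$right_canthus) / 2
  pre_forward <- nose - eye_mid
  if (sqrt(sum(pre_forward^2)) < 1e-12) stop("invalid geometry: nose coincides with eye midpoint")
  pre_forward <- unit3(pre_forward)
  e_lr <- landmarks$right_canthus - landmarks$left_canthus
  pre_up <- cross3(e_lr, pre_forward)
  if (sqrt(sum(pre_up^2)) < 1e-9) stop("invalid geometry: canthi collinear with nose direction")
  pre_up <- unit3(pre_up)
  left <- unit3(cross3(pre_up, pre_forward))
  # elevate forward about the left axis; sign chosen so forward gains altitude
  fwd <- as.numeric(rotation_about_axis(left, -tilt_deg) %*% pre_forward)
  if (tilt_deg > 0 && sum(fwd * pre_up) < 0) {
    fwd <- as.numeric(rotation_about_axis(left, tilt_deg) %*% pre_forward)
  }
  up <- unit3(cross3(fwd, left))
  R <- cbind(fwd, left, up)
  structure(list(origin = eye_mid, forward = fwd, left = left, up = up,
                 rotation = R),
            class = "head_frame")
}

#' Compose an eye rotation from vertical, horizontal and torsional angles
#'
#' The total eye rotation is the matrix product R_phi R_theta R_psi with
#' phi the vertical, theta the horizontal and psi the torsional angle, and
#' the reference gaze direction (0, 0, -1).
#'
#' @param phi_vertical,theta_horizontal,psi_torsion angles in degrees.
#' @return list with \code{rotation} (3x3) and \code{gaze} (unit 3-vector).
#' @export
compose_eye_rotation <- function(phi_vertical, theta_horizontal, psi_torsion) {
  stopifnot(is.finite(phi_vertical), is.finite(theta_horizontal), is.finite(psi_torsion))
  p <- deg2rad(phi_vertical); t <- deg2rad(theta_horizontal); s <- deg2rad(psi_torsion)
  Rphi <- matrix(c(1, 0, 0,
                   0, cos(p), sin(p),
                   0, -sin(p), cos(p)), 3, 3)
  Rtheta <- matrix(c(cos(t), 0, sin(t),
                     0, 1, 0,
                     -sin(t), 0, cos(t)), 3, 3)
  Rpsi <- matrix(c(cos(s), sin(s), 0,
                   -sin(s), cos(s), 0,
                   0, 0, 1), 3, 3)
  R <- Rphi %*% Rtheta %*% Rpsi
  list(rotation = R, gaze = as.numeric(R %*% c(0, 0, -1)))
}

#' Decompose an eye rotation into (phi, theta, psi) angles
#'
#' Inverse of \code{\link{compose_eye_rotation}}; unique for theta in
#' (-90, 90) degrees.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector \code{c(phi, theta, psi)} in degrees.
#' @export
decompose_eye_rotation <- function(R) {
  # R = Rphi %*% Rtheta %*% Rpsi with the matrices of compose_eye_rotation:
  # R[1,3] = -sin(theta); column/row structure gives the rest.
  theta <- asin(max(-1, min(1, -R[1, 3])))
  ct <- cos(theta)
  if (abs(ct) < 1e-9) stop("gimbal-degenerate eye rotation (|theta| = 90 deg)")
  phi <- atan2(-R[2, 3] / ct, R[3, 3] / ct)
  psi <- atan2(-R[1, 2] / ct, R[1, 1] / ct)
  c(phi = rad2deg(phi), theta = rad2deg(theta), psi = rad2deg(psi))
}

#' Geodesic interpolation between two rotations
#'
#' Places the interpolated gaze vector on the great circle through the two
#' gaze directions, at a fraction \code{s} of the angle between them, while a
#' vector perpendicular to the reference gaze rotates uniformly (uniform
#' twist). Implemented as a swing-twist factorization: a uniform great-circle
#' swing of the gaze composed with a uniform torsion about the gaze axis.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @param s interpolation fraction in [0, 1].
#' @return 3x3 rotation matrix.
#' @export
interpolate_rotation <- function(R1, R2, s) {
  stopifnot(s >= 0, s <= 1)
  u <- c(0, 0, -1)
  v1 <- as.numeric(R1 %*% u)
  v2 <- as.numeric(R2 %*% u)
  ang <- vec_angle(v1, v2)
  if (ang > 180 - 1e-7) stop("ambiguous geodesic: gaze vectors are antipodal")
  if (ang < 1e-12) {
    Q_s <- diag(3); Q <- diag(3)
  } else {
    axis <- unit3(cross3(v1, v2))
    Q_s <- rotation_about_axis(axis, s * ang)
    Q <- rotation_about_axis(axis, ang)
  }
  Tw <- t(Q %*% R1) %*% R2          # residual twist, fixes u (rotation about z)
  tw_ang <- rad2deg(atan2(Tw[2, 1], Tw[1, 1]))
  Q_s %*% R1 %*% rot_z(s * tw_ang)
}

#' Resample a rotation series onto new timestamps
#'
#' Per-interval geodesic (swing-twist) interpolation; query times outside the
#' series range are clamped to the end rotations.
#'
#' @param series \code{rotation_series}.
#' @param times numeric vector of query times, seconds.
#' @return \code{rotation_series} at \code{times}.
#' @export
resample_rotation_series <- function(series, times) {
  stopifnot(inherits(series, "rotation_series"))
  ts <- series$timestamps
  out <- array(0, dim = c(3, 3, length(times)))
  for (k in seq_along(times)) {
    t <- times[k]
    if (t <= ts[1]) { out[, , k] <- series$rotations[, , 1]; next }
    if (t >= ts[length(ts)]) { out[, , k] <- series$rotations[, , length(ts)]; next }
    i <- findInterval(t, ts)
    s <- (t - ts[i]) / (ts[i + 1] - ts[i])
    out[, , k] <- interpolate_rotation(series$rotations[, , i],
                                       series$rotations[, , i + 1], s)
  }
  rotation_series(times, out, series$frame_label)
}

#' Least-squares rigid registration of two point sets
#'
#' Kabsch/Procrustes solution for the rotation and translation minimizing the
#' summed squared distance between \code{R src + t} and \code{dst}, as used to
#' register fiducial markers between the tracking and scanned coordinate
#' systems.
#'
#' @param src,dst N x 3 matrices of corresponding points (m), N >= 3,
#'   non-collinear.
#' @return list with \code{rotation}, \code{translation}, \code{residuals}
#'   (N x 3 signed, m), \code{rms} and \code{mean_abs_axis} (per-axis mean
#'   absolute residual).
#' @export
register_point_sets <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 3, ncol(dst) == 3, nrow(src) == nrow(dst))
  if (nrow(src) < 3) stop("degenerate registration: need at least 3 points")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  if (svd(A)$d[2] < 1e-12 * max(svd(A)$d[1], 1e-30)) {
    stop("degenerate registration: source points are collinear")
  }
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cd - as.numeric(R %*% cs)
  fitted <- t(R %*% t(src)) + matrix(tr, nrow(src), 3, byrow = TRUE)
  res <- dst - fitted
  list(rotation = R, translation = tr, residuals = res,
       rms = sqrt(mean(rowSums(res^2))),
       mean_abs_axis = colMeans(abs(res)))
}

# --- head Euler convention -------------------------------------------------
# Head rotation H maps head coords (x = forward, y = left, z = up) to world.
# Intrinsic yaw (about up) - pitch (about left) - roll (about forward):
#   H = Rz(yaw) Ry(-pitch) Rx(roll)
# Positive pitch = nose up; positive roll = roll right (left ear up).

#' Head Euler angles (yaw-pitch-roll)
#'
#' @param H 3x3 head rotation (head -> world, columns forward/left/up).
#' @return named vector \code{c(yaw, pitch, roll)} in degrees.
#' @export
head_euler <- function(H) {
  pitch <- asin(max(-1, min(1, H[3, 1])))
  cp <- cos(pitch)
  if (abs(cp) < 1e-9) stop("gimbal-degenerate head pose (|pitch| = 90 deg)")
  yaw <- atan2(H[2, 1], H[1, 1])
  roll <- atan2(H[3, 2], H[3, 3])
  c(yaw = rad2deg(yaw), pitch = rad2deg(pitch), roll = rad2deg(roll))
}

#' @rdname head_euler
#' @param yaw,pitch,roll angles in degrees.
#' @export
head_from_euler <- function(yaw, pitch, roll) {
  rot_z(yaw) %*% rot_y(-pitch) %*% rot_x(roll)
}

#' Horizon-align a head rotation series
#'
#' Normalizes the series so the average pitch and average roll are zero while
#' yaw is unchanged: each frame is decomposed into yaw-pitch-roll, the series
#' means of pitch and roll are subtracted, and the frames are recomposed.
#'
#' @param head \code{rotation_series} with \code{frame_label = "head"}.
#' @return horizon-aligned \code{rotation_series}.
#' @export
horizon_align <- function(head) {
  stopifnot(inherits(head, "rotation_series"))
  n <- length(head)
  ang <- t(vapply(seq_len(n), function(i) head_euler(head$rotations[, , i]),
                  numeric(3)))
  pm <- mean(ang[, "pitch"]); rm <- mean(ang[, "roll"])
  out <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) {
    out[, , i] <- head_from_euler(ang[i, "yaw"], ang[i, "pitch"] - pm,
                                  ang[i, "roll"] - rm)
  }
  rotation_series(head$timestamps, out, head$frame_label)
}

#' Differential rotations relative to the series chordal mean
#'
#' Returns per-frame rotations \code{R_i \%*\% solve(mean)} where the mean is
#' the chordal L2 mean of the series, so the outputs describe the deviation of
#' each frame from the average pose.
#'
#' @param series \code{rotation_series}.
#' @return list with \code{deltas} (3x3xN array) and \code{mean} (3x3).
#' @export
differential_rotations <- function(series) {
  stopifnot(inherits(series, "rotation_series"))
  M <- chordal_mean(series)
  n <- length(series)
  out <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) out[, , i] <- series$rotations[, , i] %*% t(M)
  list(deltas = out, mean = M)
}
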