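# Optic flow on the corneal view: central-difference flow from rendered
# frames, the analytic flow of the idealized spherical surround, flow-pole
# directions with Gaussian density, and solid-angle-weighted regional
# statistics.
#
# Flow is evaluated per pixel in the local orthonormal tangent basis
# (v_theta, v_phi) of the spherical chart about the optical axis; only these
# two components enter the reported speed (the third, radial component is
# excluded).

# Tangent basis vectors (eye frame) for every pixel of the grid.
grid_tangent_basis <- function(grid) {
  gg <- grid_geometry(grid)
  g <- deg2rad(gg$radial_deg); tau <- gg$tau
  v_theta <- cbind(c(cos(g) * cos(tau)), c(cos(g) * sin(tau)), c(sin(g)))
  v_phi <- cbind(c(-sin(tau)), c(cos(tau)), 0)
  list(v_theta = v_theta, v_phi = v_phi, inside = gg$inside)
}

#' Optic flow from three consecutive corneal-view frames
#'
#' For each pixel, the difference of the world-frame 3D intersection points
#' one frame before and after the frame of interest, divided by 2 dt and by
#' the eye-to-surface distance, gives a 3D angular-velocity vector; its
#' orthogonal projection onto the local tangent plane spanned by v_theta and
#' v_phi is the 2D flow, reported in deg/s. Pixels lacking a surface hit in
#' any of the three frames are masked.
#'
#' @param prev,cur,nxt \code{eye_view_frame}s on the same grid.
#' @param dt inter-frame interval, seconds.
#' @return object of class \code{flow_field}: matrices \code{v_theta},
#'   \code{v_phi} and \code{speed} (deg/s), plus the grid.
#' @export
flow_from_frames <- function(prev, cur, nxt, dt) {
  stopifnot(dt > 0,
            prev$grid$resolution == cur$grid$resolution,
            nxt$grid$resolution == cur$grid$resolution)
  n <- cur$grid$resolution
  basis <- grid_tangent_basis(cur$grid)
  R <- cur$eye_rotation
  f3 <- lapply(1:3, function(k) {
    (c(nxt$xyz[, , k]) - c(prev$xyz[, , k])) / (2 * dt) / c(cur$depth)
  })
  bt <- basis$v_theta %*% t(R)  # tangent basis rotated to world, N x 3
  bp <- basis$v_phi %*% t(R)
  vt <- f3[[1]] * bt[, 1] + f3[[2]] * bt[, 2] + f3[[3]] * bt[, 3]
  vp <- f3[[1]] * bp[, 1] + f3[[2]] * bp[, 2] + f3[[3]] * bp[, 3]
  vt <- rad2deg(vt); vp <- rad2deg(vp)
  mask <- is.na(c(prev$depth)) | is.na(c(cur$depth)) | is.na(c(nxt$depth)) |
    !c(basis$inside)
  vt[mask] <- NA_real_; vp[mask] <- NA_real_
  structure(list(v_theta = matrix(vt, n, n), v_phi = matrix(vp, n, n),
                 speed = matrix(sqrt(vt^2 + vp^2), n, n), grid = cur$grid),
            class = "flow_field")
}

#' Analytic optic flow for translation inside a fixed sphere
#'
#' The idealized surround is a sphere of radius \code{r} centered on the head;
#' the eye translates at speed \code{v} along \code{heading} (eye-frame unit
#' vector) without rotating. The flow magnitude is (v/r) sin(theta) at angle
#' theta from the heading, zero at the heading and anti-heading poles.
#'
#' @param v translation speed, m/s.
#' @param r sphere radius, m.
#' @param grid \code{spherical_grid}.
#' @param heading unit 3-vector in the eye frame (default the optical axis).
#' @return \code{flow_field} (deg/s).
#' @export
idealized_translation_flow <- function(v, r, grid, heading = c(0, 0, -1)) {
  stopifnot(r > 0, v >= 0)
  heading <- unit3(heading)
  gg <- grid_geometry(grid)
  basis <- grid_tangent_basis(grid)
  d <- gg$dirs
  # surface point moves at -v*heading in eye coordinates; normalized by r
  vd <- d %*% heading
  f3 <- -(matrix(heading, nrow(d), 3, byrow = TRUE) -
            d * as.numeric(vd)) * (v / r)
  vt <- rad2deg(rowSums(f3 * basis$v_theta))
  vp <- rad2deg(rowSums(f3 * basis$v_phi))
  vt[!c(basis$inside)] <- NA_real_
  vp[!c(basis$inside)] <- NA_real_
  n <- grid$resolution
  structure(list(v_theta = matrix(vt, n, n), v_phi = matrix(vp, n, n),
                 speed = matrix(sqrt(vt^2 + vp^2), n, n), grid = grid),
            class = "flow_field")
}

#' Optic-flow pole directions and their Gaussian density
#'
#' The pole of frame i is the central-difference translation direction of the
#' eye trajectory over \code{h} frames, expressed in that frame's eye
#' coordinates and normalized. Densities use a two-dimensional Gaussian
#' smoother over chordal distances with standard deviation \code{sigma}
#' (default 2 pi / 180), divided by the number of contributing frames.
#'
#' @param eye_positions N x 3 matrix of eye positions (m, world).
#' @param eye_rotations 3x3xN array of eye-to-world rotations.
#' @param timestamps length-N times, seconds (uniform sampling assumed for the
#'   difference quotient).
#' @param h difference window, frames (default 4).
#' @param sigma Gaussian standard deviation, radians.
#' @return object of class \code{flow_pole_density}: data frame with frame
#'   index, pole components x/y/z (eye frame) and density \code{s}.
#' @export
flow_pole_directions <- function(eye_positions, eye_rotations, timestamps,
                                 h = 4, sigma = 2 * pi / 180) {
  eye_positions <- as.matrix(eye_positions)
  n <- nrow(eye_positions)
  stopifnot(n >= h + 1, dim(eye_rotations)[3] == n,
            length(timestamps) == n, sigma > 0, h %% 2 == 0)
  half <- h / 2
  idx <- seq(1 + ceiling(half), n - ceiling(half))
  poles <- matrix(NA_real_, n, 3)
  for (i in idx) {
    dp <- (eye_positions[i + half, ] - eye_positions[i - half, ]) /
      (timestamps[i + half] - timestamps[i - half])
    sp <- sqrt(sum(dp^2))
    if (sp < 1e-12) next  # zero-velocity frame: pole undefined
    poles[i, ] <- as.numeric(t(eye_rotations[, , i]) %*% (dp / sp))
  }
  keep <- which(is.finite(poles[, 1]))
  if (length(keep) == 0) stop("no frames with defined flow pole")
  x <- poles[keep, , drop = FALSE]
  nF <- length(keep)
  d2 <- as.matrix(stats::dist(x))^2
  K <- exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  s <- rowSums(K) / nF
  structure(list(poles = data.frame(frame = keep, x = x[, 1], y = x[, 2],
                                    z = x[, 3], s = s),
                 sigma = sigma, h = h, n_frames = nF),
            class = "flow_pole_density")
}

# Membership mask of a corneal-coordinate window on the grid.
region_mask <- function(grid, region) {
  gg <- grid_geometry(grid)
  rot_deg <- rad2deg(gg$tau)
  dr <- abs(gg$radial_deg - region$center[1])
  drot <- abs(((rot_deg - region$center[2] + 180) %% 360) - 180)
  m <- dr <= region$width / 2 & drot <= region$height / 2 & gg$inside
  matrix(m, grid$resolution, grid$resolution)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Solid-angle-weighted flow statistics per corneal region
#'
#' @param field \code{flow_field}.
#' @param regions named list of windows, each
#'   \code{list(center = c(radial_deg, rotation_deg), width, height)} in
#'   degrees on the (radial, rotation) chart.
#' @return data frame with per-region weighted mean, median and IQR of the 2D
#'   flow speed; NA rows for empty or fully masked regions.
#' @export
regional_flow_stats <- function(field, regions) {
  w_all <- grid_solid_angle(field$grid)
  out <- lapply(names(regions), function(nm) {
    m <- region_mask(field$grid, regions[[nm]])
    x <- field$speed[m]; w <- w_all[m]
    ok <- is.finite(x) & is.finite(w)
    if (!any(ok)) {
      return(data.frame(region = nm, mean = NA_real_, median = NA_real_,
                        iqr = NA_real_, n_pixels = 0L))
    }
    x <- x[ok]; w <- w[ok]
    q <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
    data.frame(region = nm, mean = sum(w * x) / sum(w), median = q[2],
               iqr = q[3] - q[1], n_pixels = sum(ok))
  })
  do.call(rbind, out)
}
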