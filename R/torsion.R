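# Ocular torsion from a tracked corneal spot: forward pixel model, per-frame
# torsion estimation, calibration of the spot's anatomical parameters (r, alpha)
# and session-wise torsion normalization.

#' Pupil camera model
#'
#' @param eye_center_px length-2 pixel coordinates (aEC, bEC) of the eyeball
#'   center in the eye-camera image.
#' @param scale projection scale f/z0 in pixels per model unit (the pupil
#'   rotation radius is the model unit); must be > 0.
#' @return object of class \code{pupil_camera_model}.
#' @export
pupil_camera_model <- function(eye_center_px, scale) {
  stopifnot(length(eye_center_px) == 2, all(is.finite(eye_center_px)), scale > 0)
  structure(list(eye_center_px = as.numeric(eye_center_px), scale = scale),
            class = "pupil_camera_model")
}

#' Anatomical parameters of the corneal torsion-tracking spot
#'
#' @param r radial distance of the spot from the eyeball center in units of the
#'   pupil rotation radius; must exceed 1 (the spot sits on the eyeball
#'   surface outside the pupil rotation sphere).
#' @param alpha fixed angle between the spot and the gaze vector, degrees,
#'   in (0, 180).
#' @return object of class \code{spot_params}.
#' @export
spot_params <- function(r, alpha) {
  stopifnot(is.finite(r), r > 1, is.finite(alpha), alpha > 0, alpha < 180)
  structure(list(r = r, alpha = alpha), class = "spot_params")
}

#' Tracked corneal-spot trajectory
#'
#' @param timestamps increasing times, seconds.
#' @param spot_px N x 2 matrix of spot pixel coordinates; rows may be NA for
#'   frames in which the spot was not tracked.
#' @param phi,theta per-frame vertical and horizontal eye angles, degrees
#'   (from pupil tracking).
#' @return object of class \code{spot_track}.
#' @export
spot_track <- function(timestamps, spot_px, phi, theta) {
  spot_px <- as.matrix(spot_px)
  n <- length(timestamps)
  stopifnot(nrow(spot_px) == n, ncol(spot_px) == 2,
            length(phi) == n, length(theta) == n)
  if (n > 1 && any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  ok <- stats::complete.cases(spot_px)
  if (any(!is.finite(spot_px[ok, ]))) stop("non-finite spot pixels in tracked frames")
  structure(list(timestamps = as.numeric(timestamps), spot_px = spot_px,
                 phi = as.numeric(phi), theta = as.numeric(theta)),
            class = "spot_track")
}

# Coefficients of the predicted spot pixel as a function of torsion psi:
#   x(psi) = aEC + scale * (a1 cos psi + c1)
#   y(psi) = bEC + scale * (a2 cos psi + b2 sin psi + c2)
# derived from v_mark = R_eye (r sin a, 0, -r cos a)^T. Vectorized over frames.
spot_pixel_coeffs <- function(phi, theta, params, cam) {
  p <- deg2rad(phi); t <- deg2rad(theta)
  sa <- sin(deg2rad(params$alpha)); ca <- cos(deg2rad(params$alpha))
  r <- params$r
  list(a1 = r * cos(t) * sa,
       c1 = r * sin(t) * ca,
       a2 = -r * sa * sin(p) * sin(t),
       b2 = r * sa * cos(p),
       c2 = r * sin(p) * cos(t) * ca,
       ax = cam$eye_center_px[1], ay = cam$eye_center_px[2], f = cam$scale)
}

#' Predicted pixel location of the torsion-tracking spot
#'
#' Forward model: the spot sits at \code{(r sin alpha, 0, -r cos alpha)} in the
#' reference eye frame, is rotated by the eye rotation, and its first two
#' components are projected to pixels by the camera model.
#'
#' @param phi,theta,psi eye angles, degrees (vectors of equal length allowed).
#' @param params \code{spot_params}.
#' @param cam \code{pupil_camera_model}.
#' @return N x 2 matrix of pixel coordinates.
#' @export
project_spot <- function(phi, theta, psi, params, cam) {
  co <- spot_pixel_coeffs(phi, theta, params, cam)
  cp <- cos(deg2rad(psi)); sp <- sin(deg2rad(psi))
  cbind(x = co$ax + co$f * (co$a1 * cp + co$c1),
        y = co$ay + co$f * (co$a2 * cp + co$b2 * sp + co$c2))
}

# Vectorized per-frame torsion search: coarse grid then golden-section
# refinement, all frames in lockstep. Returns psi (deg) and residual (px).
torsion_search <- function(spot_px, phi, theta, params, cam,
                           bounds = c(-90, 90)) {
  co <- spot_pixel_coeffs(phi, theta, params, cam)
  obj <- function(psi_deg) {
    # psi_deg: vector (per frame) or scalar
    cp <- cos(deg2rad(psi_deg)); sp <- sin(deg2rad(psi_deg))
    dx <- co$ax + co$f * (co$a1 * cp + co$c1) - spot_px[, 1]
    dy <- co$ay + co$f * (co$a2 * cp + co$b2 * sp + co$c2) - spot_px[, 2]
    dx * dx + dy * dy
  }
  grid <- seq(bounds[1] + 0.5, bounds[2] - 0.5, by = 1)
  vals <- matrix(vapply(grid, function(g) obj(g), numeric(nrow(spot_px))),
                 nrow = nrow(spot_px))
  best <- max.col(-vals, ties.method = "first")
  lo <- pmax(grid[best] - 1, bounds[1])
  hi <- pmin(grid[best] + 1, bounds[2])
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  for (it in 1:40) {
    take2 <- f1 > f2
    lo <- ifelse(take2, x1, lo)
    hi <- ifelse(take2, hi, x2)
    x1n <- hi - gr * (hi - lo); x2n <- lo + gr * (hi - lo)
    x1 <- x1n; x2 <- x2n
    f1 <- obj(x1); f2 <- obj(x2)
  }
  psi <- (x1 + x2) / 2
  list(psi = psi, residual = sqrt(obj(psi)))
}

#' Estimate torsion for a single frame
#'
#' Finds the torsion angle psi minimizing the squared pixel distance between
#' the predicted and the marked spot location, over a bounded physiological
#' interval.
#'
#' @param spot_px length-2 pixel coordinates of the marked spot (NA allowed).
#' @param phi,theta eye angles for the frame, degrees.
#' @param params \code{spot_params}; \code{cam} \code{pupil_camera_model}.
#' @param cam \code{pupil_camera_model}.
#' @param bounds search interval for psi, degrees.
#' @param residual_threshold_px residual above which the fit is flagged.
#' @return list with \code{psi} (deg, NA if the spot is missing),
#'   \code{residual} (px) and \code{flagged}.
#' @export
estimate_torsion_frame <- function(spot_px, phi, theta, params, cam,
                                   bounds = c(-90, 90),
                                   residual_threshold_px = 5) {
  if (any(!is.finite(spot_px))) {
    return(list(psi = NA_real_, residual = NA_real_, flagged = FALSE))
  }
  res <- torsion_search(matrix(spot_px, 1, 2), phi, theta, params, cam, bounds)
  list(psi = res$psi, residual = res$residual,
       flagged = res$residual > residual_threshold_px)
}

#' Initialize the spot parameters (r, alpha) from a track
#'
#' For a candidate r, each frame's marked pixel is back-projected to a 3D spot
#' location on the sphere of radius r (with the in-plane component clamped so
#' the square root stays real), yielding a per-frame angle alpha_init between
#' the gaze vector and the reconstructed spot. The correct r makes these
#' per-frame angles agree, so r is initialized by minimizing the across-frame
#' variance of alpha_init; alpha is initialized as their mean at that r.
#'
#' @param track \code{spot_track}; \code{cam} \code{pupil_camera_model}.
#' @param cam \code{pupil_camera_model}.
#' @param r_range search interval for r.
#' @return list with \code{r_init}, \code{alpha_init} (deg) and
#'   \code{alpha_var} at the optimum.
#' @export
initialize_spot_params <- function(track, cam, r_range = c(1.001, 3)) {
  ok <- stats::complete.cases(track$spot_px)
  if (sum(ok) < 2) stop("unidentifiable r: need at least 2 tracked frames")
  px <- track$spot_px[ok, , drop = FALSE]
  phi <- track$phi[ok]; theta <- track$theta[ok]
  if (max(abs(phi - phi[1])) < 1e-9 && max(abs(theta - theta[1])) < 1e-9) {
    stop("unidentifiable r: all frames share an identical eye pose")
  }
  p <- deg2rad(phi); t <- deg2rad(theta)
  vg <- cbind(sin(t), sin(p) * cos(t), -cos(p) * cos(t))  # gaze per frame
  da <- (px[, 1] - cam$eye_center_px[1]) / cam$scale
  db <- (px[, 2] - cam$eye_center_px[2]) / cam$scale
  rho <- sqrt(da^2 + db^2)
  alpha_init_fun <- function(r) {
    m <- pmin(1, r / pmax(rho, 1e-12))
    z <- -sqrt(pmax(r^2 - m^2 * rho^2, 0))
    v <- cbind(m * da, m * db, z)
    ca <- rowSums(vg * v) / r
    rad2deg(acos(pmax(-1, pmin(1, ca))))
  }
  opt <- stats::optimize(function(r) stats::var(alpha_init_fun(r)),
                         interval = r_range, tol = 1e-8)
  a <- alpha_init_fun(opt$minimum)
  list(r_init = opt$minimum, alpha_init = mean(a), alpha_var = opt$objective)
}

#' Calibrate the spot parameters by joint optimization
#'
#' Jointly optimizes (r, alpha) with a derivative-free simplex so that the sum
#' over frames of squared pixel errors is minimized, the per-frame torsion
#' being re-estimated inside the objective for every candidate (r, alpha).
#'
#' @param track \code{spot_track}; \code{cam} \code{pupil_camera_model}.
#' @param cam \code{pupil_camera_model}.
#' @param init optional list with \code{r_init}, \code{alpha_init}; computed by
#'   \code{\link{initialize_spot_params}} when missing.
#' @param max_iter maximum simplex iterations.
#' @return list with \code{params} (\code{spot_params}), \code{psi} (per-frame
#'   torsion, deg, NA on untracked frames), \code{residuals} (px), \code{sse},
#'   \code{iterations} and \code{converged}.
#' @export
calibrate_spot_params <- function(track, cam, init = NULL, max_iter = 400) {
  ok <- stats::complete.cases(track$spot_px)
  if (sum(ok) < 2) stop("unidentifiable calibration: need at least 2 tracked frames")
  if (is.null(init)) init <- initialize_spot_params(track, cam)
  px <- track$spot_px[ok, , drop = FALSE]
  phi <- track$phi[ok]; theta <- track$theta[ok]
  sse_fun <- function(par) {
    r <- par[1]; alpha <- par[2]
    if (r <= 1.0005 || alpha <= 0.5 || alpha >= 179.5) return(1e12)
    pr <- spot_params(r, alpha)
    sum(torsion_search(px, phi, theta, pr, cam)$residual^2)
  }
  opt <- stats::optim(c(init$r_init, init$alpha_init), sse_fun,
                      method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-10))
  params <- spot_params(opt$par[1], opt$par[2])
  fit <- torsion_search(px, phi, theta, params, cam)
  psi <- rep(NA_real_, length(track$timestamps))
  res <- rep(NA_real_, length(track$timestamps))
  psi[ok] <- fit$psi; res[ok] <- fit$residual
  out <- list(params = params, psi = psi, residuals = res, sse = opt$value,
              iterations = opt$counts[["function"]],
              converged = opt$convergence == 0)
  if (!out$converged) {
    warning("calibration did not converge within max_iter; returning best-so-far")
  }
  out
}

#' Normalize a torsion series to a head-posture reference
#'
#' Subtracts the mean torsion over the reference frames, defined as the
#' fraction of frames closest (in Chebyshev distance) to both the median head
#' pitch and the median head roll; at least one frame is always selected.
#'
#' @param psi torsion series, degrees (NA allowed).
#' @param pitch,roll head pitch and roll series, degrees, time-aligned to psi.
#' @param fraction fraction of frames used as reference (default 1e-4,
#'   i.e. 0.01 percent).
#' @return normalized torsion series, degrees.
#' @export
normalize_torsion <- function(psi, pitch, roll, fraction = 1e-4) {
  n <- length(psi)
  stopifnot(length(pitch) == n, length(roll) == n)
  k <- max(1L, as.integer(ceiling(fraction * n)))
  d <- pmax(abs(pitch - stats::median(pitch, na.rm = TRUE)),
            abs(roll - stats::median(roll, na.rm = TRUE)))
  d[is.na(psi)] <- Inf   # reference frames must carry a torsion value
  sel <- order(d)[seq_len(k)]
  psi - mean(psi[sel], na.rm = TRUE)
}
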