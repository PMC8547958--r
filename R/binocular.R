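# Binocular analyses in the idealized zero-baseline spherical environment:
# inter-ocular projection and alignment, overlap probability maps, digital
# freezing of eye-rotation components, and head-to-eye compensation gains.

#' Per-frame eye and head pose set
#'
#' Holds the eye-to-global transforms l', r' and the head-to-global transform
#' h for a series of frames; the eye-in-head rotations l = h^-1 l' and
#' r = h^-1 r' are derived.
#'
#' @param timestamps shared times, seconds.
#' @param left,right,head \code{rotation_series} (rotation parts of l', r', h).
#' @return object of class \code{eye_pose_frames} with derived
#'   \code{left_in_head}, \code{right_in_head} series.
#' @export
eye_pose_frames <- function(timestamps, left, right, head) {
  n <- length(timestamps)
  stopifnot(length(left) == n, length(right) == n, length(head) == n)
  lih <- rih <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) {
    hi <- t(head$rotations[, , i])
    lih[, , i] <- hi %*% left$rotations[, , i]
    rih[, , i] <- hi %*% right$rotations[, , i]
  }
  structure(list(timestamps = timestamps, left = left, right = right,
                 head = head,
                 left_in_head = rotation_series(timestamps, lih, "left_eye"),
                 right_in_head = rotation_series(timestamps, rih, "right_eye")),
            class = "eye_pose_frames")
}

#' Project a direction from one eye into the other
#'
#' In the idealized environment (unit sphere, zero inter-eye baseline) a
#' direction u seen by the source eye corresponds to the point u on the
#' sphere; its direction in the target eye is p_i = L_i^-1 R_i u per frame.
#'
#' @param u unit direction in the source eye's coordinates.
#' @param source,target \code{rotation_series} of eye-to-global rotations for
#'   the source and target eye (time-aligned).
#' @return N x 3 matrix of per-frame unit directions p_i in the target eye.
#' @export
project_across_eyes <- function(u, source, target) {
  u <- unit3(u)
  n <- length(source)
  stopifnot(length(target) == n)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    out[i, ] <- as.numeric(t(target$rotations[, , i]) %*%
                             source$rotations[, , i] %*% u)
  }
  out
}

#' Mean inter-ocular misalignment of a projected direction series
#'
#' Chordal deviation of each projected direction from the normalized mean
#' direction, converted to an angle via 2 arcsin(|p_i - mean| / 2), averaged
#' over frames.
#'
#' @param p N x 3 matrix of unit directions.
#' @return list with \code{mean_deg} and the per-frame \code{deviation_deg}
#'   series.
#' @export
alignment_statistic <- function(p) {
  p <- matrix(p, ncol = 3)
  m <- colMeans(p)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-12) stop("undefined mean direction: antipodally balanced set")
  m <- m / nm
  chord <- sqrt(rowSums(sweep(p, 2, m)^2))
  dev <- rad2deg(2 * asin(pmin(1, chord / 2)))
  list(mean_deg = mean(dev), deviation_deg = dev)
}

#' Binocular overlap probability map
#'
#' In the zero-baseline idealized sphere, a direction belongs to the
#' overlapping field of a frame when it lies within 90 degrees of both eyes'
#' optical axes. The probability map averages this indicator over frames, on
#' the corneal grid of the reference eye.
#'
#' @param left,right \code{rotation_series} of eye-to-global rotations.
#' @param grid \code{spherical_grid}; the map is rendered in the coordinates
#'   of \code{reference}.
#' @param reference \code{"left"} or \code{"right"}.
#' @return matrix of per-pixel overlap probabilities in [0, 1] (NA outside
#'   the field).
#' @export
overlap_probability_map <- function(left, right, grid, reference = "left") {
  n <- length(left)
  stopifnot(length(right) == n)
  gg <- grid_geometry(grid)
  ref <- if (reference == "left") left else right
  oth <- if (reference == "left") right else left
  acc <- numeric(nrow(gg$dirs))
  u <- c(0, 0, -1)
  for (i in seq_len(n)) {
    dirs_g <- gg$dirs %*% t(ref$rotations[, , i])      # directions in global
    ax_ref <- as.numeric(ref$rotations[, , i] %*% u)
    ax_oth <- as.numeric(oth$rotations[, , i] %*% u)
    acc <- acc + as.numeric((dirs_g %*% ax_ref > 0) & (dirs_g %*% ax_oth > 0))
  }
  p <- acc / n
  p[!c(gg$inside)] <- NA_real_
  matrix(p, grid$resolution, grid$resolution)
}

#' Digitally freeze eye-rotation components
#'
#' Decomposes each frame of an eye-in-head rotation series into vertical,
#' horizontal and torsional angles (relative to the mean eye pose), replaces
#' the selected components by their series means, and recomposes the series.
#'
#' @param series \code{rotation_series} of eye rotations.
#' @param axes subset of \code{c("torsion", "vertical", "horizontal")} or
#'   \code{"all"}.
#' @param reference optional 3x3 reference (anatomical) orientation; defaults
#'   to the chordal mean of the series, so angles are deviations from the
#'   average pose.
#' @return \code{rotation_series} with the selected components frozen.
#' @export
freeze_eye_rotations <- function(series, axes = "all", reference = NULL) {
  stopifnot(inherits(series, "rotation_series"))
  if (identical(axes, "all")) axes <- c("torsion", "vertical", "horizontal")
  stopifnot(all(axes %in% c("torsion", "vertical", "horizontal")))
  n <- length(series)
  if (is.null(reference)) reference <- chordal_mean(series)
  ang <- t(vapply(seq_len(n), function(i) {
    decompose_eye_rotation(t(reference) %*% series$rotations[, , i])
  }, numeric(3)))
  if ("vertical" %in% axes) ang[, "phi"] <- mean(ang[, "phi"])
  if ("horizontal" %in% axes) ang[, "theta"] <- mean(ang[, "theta"])
  if ("torsion" %in% axes) ang[, "psi"] <- mean(ang[, "psi"])
  out <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) {
    out[, , i] <- reference %*%
      compose_eye_rotation(ang[i, "phi"], ang[i, "theta"], ang[i, "psi"])$rotation
  }
  rotation_series(series$timestamps, out, series$frame_label)
}

# Signed rotation angle of a differential rotation about a fixed axis:
# projection of the axis-angle vector onto the axis (degrees).
angle_about_axis <- function(deltas, axis) {
  axis <- unit3(axis)
  vapply(seq_len(dim(deltas)[3]), function(i) {
    sum(rotation_log(deltas[, , i]) * axis)
  }, numeric(1))
}

#' Head-to-eye compensation gain about a common axis
#'
#' Extracts per-frame head and eye rotation angles about a common head axis
#' (X = pitch axis = the head's left axis, Y = roll axis = the head's forward
#' axis) from differential rotations relative to each series' mean pose, and
#' fits the gain as the least-squares slope of eye angle against head angle.
#' A compensatory eye movement gives a negative slope.
#'
#' @param head horizon-aligned head \code{rotation_series}.
#' @param eye eye-in-head \code{rotation_series}, time-aligned with the head
#'   series (resample first if the rates differ).
#' @param axis \code{"X"} (pitch) or \code{"Y"} (roll).
#' @param bin_width_deg width of the head-angle bins of the summary curve.
#' @return list with \code{slope}, \code{slope_se}, \code{n}, and
#'   \code{curve} (data frame: bin center, mean and SD of the eye angle).
#' @export
compensation_gain <- function(head, eye, axis = c("X", "Y"),
                              bin_width_deg = 2) {
  axis <- match.arg(axis)
  n <- length(head)
  if (length(eye) != n) stop("head and eye series must be time-aligned")
  if (n < 10) stop("insufficient data: need at least 10 paired frames")
  # head axes in head coordinates: x = forward, y = left, z = up; the pitch
  # (X) angle is positive nose-up, i.e. rotation about the negative left axis,
  # the roll (Y) angle positive roll-right, about the forward axis.
  ax <- if (axis == "X") c(0, -1, 0) else c(1, 0, 0)
  hd <- differential_rotations(head)$deltas
  ed <- differential_rotations(eye)$deltas
  # express the common axis in global coordinates per frame via the mean head
  # pose: differential rotations act in global/head-mean coordinates.
  hm <- chordal_mean(head)
  ax_g <- as.numeric(hm %*% ax)
  h_ang <- angle_about_axis(hd, ax_g)
  e_ang <- angle_about_axis(ed, ax)
  fit <- stats::lm(e_ang ~ h_ang)
  co <- summary(fit)$coefficients
  br <- seq(floor(min(h_ang)), ceiling(max(h_ang)), by = bin_width_deg)
  if (length(br) < 2) br <- range(h_ang) + c(-1, 1)
  bin <- cut(h_ang, br, include.lowest = TRUE)
  curve <- data.frame(
    center = (utils::head(br, -1) + utils::tail(br, -1)) / 2,
    mean = as.numeric(tapply(e_ang, bin, mean)),
    sd = as.numeric(tapply(e_ang, bin, stats::sd)),
    n = as.integer(table(bin)))
  list(slope = unname(co["h_ang", "Estimate"]),
       slope_se = unname(co["h_ang", "Std. Error"]),
       n = n, curve = curve)
}
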