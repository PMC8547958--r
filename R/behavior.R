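# Pursuit behavior: Gaussian smoothing, target bearing, rule-based
# detect/track/capture epoch classification with escapes, trajectory
# straightness metrics, prey-image density maps with highest-density-region
# contours, and per-trial summarization.

#' Gaussian sliding-window smoothing
#'
#' Gaussian-weighted sliding average over a fixed time window (default 50 ms);
#' the kernel is truncated at the window edges and renormalized, including at
#' the series ends. The kernel standard deviation is a quarter of the window.
#'
#' @param x numeric series, uniformly sampled.
#' @param dt sampling interval, seconds.
#' @param window window length, seconds (default 0.05).
#' @return smoothed series, same length.
#' @export
smooth_series <- function(x, dt, window = 0.05) {
  half <- floor((window / dt) / 2)
  if (half < 1) {
    warning("smoothing window shorter than 2 samples; series returned unchanged")
    return(x)
  }
  off <- (-half):half
  w <- exp(-off^2 / (2 * (half / 2)^2))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    out[i] <- sum(w[ok] * x[j[ok]]) / sum(w[ok])
  }
  out
}

#' Target bearing in the horizontal plane
#'
#' Signed angle between the head's forward direction and the direction to the
#' cricket, both projected to the horizontal plane. Positive bearings are to
#' the animal's left; range (-180, 180].
#'
#' @param head \code{head_frame} (or list with \code{origin}, \code{forward},
#'   \code{left}).
#' @param cricket 3-vector (m).
#' @param up world up axis (default +z).
#' @return bearing, degrees.
#' @export
target_bearing <- function(head, cricket, up = c(0, 0, 1)) {
  v <- cricket - head$origin
  vh <- v - sum(v * up) * up
  if (sqrt(sum(vh^2)) < 1e-12) stop("undefined bearing: target directly above the head")
  fh <- head$forward - sum(head$forward * up) * up
  fh <- unit3(fh); vh <- unit3(vh)
  s <- sum(cross3(fh, vh) * up)
  rad2deg(atan2(s, sum(fh * vh)))
}

#' Pursuit trajectory container
#'
#' @param timestamps seconds (nominally 200 Hz).
#' @param mouse,cricket N x 3 matrices of tracked positions (m).
#' @param bearing_deg optional per-frame target bearing (deg); computed by the
#'   caller from head frames (see \code{\link{target_bearing}}).
#' @return object of class \code{pursuit_trajectory}.
#' @export
pursuit_trajectory <- function(timestamps, mouse, cricket, bearing_deg = NULL) {
  mouse <- as.matrix(mouse); cricket <- as.matrix(cricket)
  n <- length(timestamps)
  stopifnot(nrow(mouse) == n, nrow(cricket) == n,
            ncol(mouse) == 3, ncol(cricket) == 3)
  if (n > 1 && any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(timestamps = timestamps, mouse = mouse, cricket = cricket,
                 bearing_deg = bearing_deg),
            class = "pursuit_trajectory")
}

#' Classify pursuit epochs from a trajectory
#'
#' Applies the classification rules on series smoothed with a 50 ms Gaussian window:
#' the detect end point is the last frame before (1) head velocity toward the
#' cricket is at least 20 cm/s, (2) the bearing stays below 90 degrees, and
#' (3) the inter-animal distance decreases continuously (negative smoothed
#' derivative through to the approach end); the detect start is 500 ms
#' earlier. Tracking runs from the frame after detect end to the first
#' contact (6 cm); a rebound of at least 5 cm after a contact is a cricket
#' escape, after which tracking resumes to the next contact. The capture
#' start is the beginning of the first approach after which every escape
#' stays within 5 cm of the contact zone (11 cm); the capture end is the
#' manually identified end point. Tracking periods starting at 20 cm or less
#' are flagged excluded; a mask marks frames within 3 cm of the cricket.
#'
#' @param traj \code{pursuit_trajectory} with \code{bearing_deg} set.
#' @param manual_capture_end timestamp of the manually identified capture end
#'   (the final 6 cm crossing before consumption), or NULL.
#' @param contact_dist_m,escape_rebound_m,detect_lookback_s,speed_thresh_ms
#'   rule constants (defaults 0.06 m, 0.05 m, 0.5 s, 0.20 m/s).
#' @return object of class \code{epoch_segmentation}: data frame of epochs
#'   (\code{kind}, \code{t_start}, \code{t_end}, \code{excluded}), data frame
#'   of \code{escapes}, and the whisker-zone mask (\code{close_mask},
#'   distance <= 3 cm).
#' @export
classify_epochs <- function(traj, manual_capture_end = NULL,
                            contact_dist_m = 0.06, escape_rebound_m = 0.05,
                            detect_lookback_s = 0.5, speed_thresh_ms = 0.20) {
  ts <- traj$timestamps
  n <- length(ts)
  dt <- stats::median(diff(ts))
  dist <- sqrt(rowSums((traj$mouse - traj$cricket)^2))
  vel <- rbind((traj$mouse[2, ] - traj$mouse[1, ]) / dt,
               (traj$mouse[3:n, ] - traj$mouse[1:(n - 2), ]) / (2 * dt),
               (traj$mouse[n, ] - traj$mouse[n - 1, ]) / dt)
  to_cricket <- (traj$cricket - traj$mouse) /
    pmax(dist, 1e-12)
  v_toward <- rowSums(vel * to_cricket)
  if (is.null(traj$bearing_deg)) stop("trajectory lacks bearing_deg")
  v_s <- smooth_series(v_toward, dt)
  b_s <- smooth_series(abs(traj$bearing_deg), dt)
  d_s <- smooth_series(dist, dt)
  dd <- c(diff(d_s), 0) / dt

  # contacts: first crossings into the 6 cm zone; rebounds >= 5 cm afterwards
  # are escapes
  contacts <- integer(0); escapes <- list()
  i <- 1
  while (i <= n) {
    hit <- which(d_s[i:n] <= contact_dist_m)
    if (length(hit) == 0) break
    ci <- i + hit[1] - 1
    contacts <- c(contacts, ci)
    # follow the rebound after this contact
    j <- ci
    min_d <- d_s[ci]
    esc_at <- NA_integer_
    while (j <= n) {
      min_d <- min(min_d, d_s[j])
      if (d_s[j] - min_d >= escape_rebound_m) { esc_at <- j; break }
      j <- j + 1
    }
    if (is.na(esc_at)) break
    # rebound peak: frame of maximum distance before the next approach dips
    k <- esc_at
    while (k < n && d_s[k + 1] >= d_s[k]) k <- k + 1
    escapes[[length(escapes) + 1]] <-
      data.frame(contact_frame = ci, escape_frame = esc_at,
                 peak_frame = k, peak_dist_m = d_s[k])
    i <- which(d_s[k:n] <= contact_dist_m)
    if (length(i) == 0) break
    i <- k + i[1] - 1
    # continue scanning from just after re-entry
    contacts <- c(contacts, i)
    i <- i + 1
  }
  contacts <- unique(contacts)
  escapes <- if (length(escapes)) do.call(rbind, escapes) else
    data.frame(contact_frame = integer(0), escape_frame = integer(0),
               peak_frame = integer(0), peak_dist_m = numeric(0))

  # detect end: last frame before all three criteria hold, the distance
  # criterion meaning a negative derivative from the candidate through the
  # first contact
  first_contact <- if (length(contacts)) contacts[1] else n
  crit <- v_s >= speed_thresh_ms & b_s < 90
  cand <- NA_integer_
  for (f in seq_len(max(1, first_contact - 1))) {
    if (!crit[f]) next
    if (all(dd[f:max(f, first_contact - 1)] < 0)) { cand <- f; break }
  }
  epochs <- list()
  if (!is.na(cand)) {
    t_end_detect <- ts[cand] - dt         # last frame before the criteria hold
    t_start_detect <- t_end_detect - detect_lookback_s
    epochs[[1]] <- data.frame(kind = "detect", t_start = t_start_detect,
                              t_end = t_end_detect, excluded = FALSE)
    # track: from the frame after detect end; if the bearing was above 90
    # before the turn, from the first frame below 90
    tr_start <- cand
    if (any(b_s[1:cand] > 90)) {
      over <- which(b_s[1:cand] >= 90)
      tr_start <- max(over) + 1   # first frame of the final below-90 run
    }
    if (length(contacts)) {
      tr_end <- contacts[1]
      excl <- d_s[tr_start] <= 0.20
      epochs[[2]] <- data.frame(kind = "track", t_start = ts[tr_start],
                                t_end = ts[tr_end], excluded = excl)
    }
  }
  # capture: start of the first approach after which all escapes stay within
  # 5 cm of the contact zone (peak < 11 cm)
  if (!is.null(manual_capture_end) && length(contacts)) {
    ok_from <- 1
    if (nrow(escapes)) {
      big <- escapes$peak_dist_m >= contact_dist_m + escape_rebound_m
      if (any(big)) ok_from <- max(escapes$peak_frame[big]) + 1
    }
    # approach onset: first frame at/after ok_from from which the distance
    # decreases into the final contact
    dec <- dd < 0
    fin <- which(ts >= manual_capture_end)[1]
    if (is.na(fin)) fin <- n
    on <- ok_from
    while (on < fin && !dec[on]) on <- on + 1
    epochs[[length(epochs) + 1]] <-
      data.frame(kind = "capture", t_start = ts[on],
                 t_end = manual_capture_end, excluded = FALSE)
  } else if (is.null(manual_capture_end)) {
    warning("no manual capture end supplied; capture epoch omitted")
  }
  structure(list(epochs = if (length(epochs)) do.call(rbind, epochs) else
                   data.frame(kind = character(0), t_start = numeric(0),
                              t_end = numeric(0), excluded = logical(0)),
                 escapes = data.frame(
                   t_contact = ts[escapes$contact_frame],
                   t_escape = ts[escapes$escape_frame],
                   peak_dist_m = escapes$peak_dist_m),
                 close_mask = dist <= 0.03,
                 smoothed = data.frame(t = ts, v_toward = v_s,
                                       bearing = b_s, dist = d_s)),
            class = "epoch_segmentation")
}

#' Straightness metrics of a pursuit path
#'
#' The path is rotated so the chord from start to end lies on the abscissa;
#' reported are the absolute lateral deviation at 20 cm (chord distance) from
#' the end, the maximum absolute lateral deviation, and the unsigned area
#' between the path and the chord.
#'
#' @param path N x 2 matrix (m), ordered start to end.
#' @return list with \code{dev_at_20cm_cm} (NA when the chord is shorter than
#'   20 cm), \code{max_dev_cm} and \code{area_cm2}.
#' @export
straightness_metrics <- function(path) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2)
  chord <- path[nrow(path), ] - path[1, ]
  L <- sqrt(sum(chord^2))
  if (L < 1e-12) stop("zero-length path chord")
  e1 <- chord / L
  e2 <- c(-e1[2], e1[1])
  rel <- sweep(path, 2, path[1, ])
  x <- rel %*% e1
  y <- rel %*% e2
  dev20 <- NA_real_
  if (L >= 0.20) {
    xq <- L - 0.20
    dev20 <- abs(stats::approx(x, y, xout = xq, ties = "ordered")$y) * 100
  }
  area <- sum(diff(as.numeric(x)) *
                (abs(utils::head(y, -1)) + abs(utils::tail(y, -1))) / 2) * 1e4
  list(dev_at_20cm_cm = dev20, max_dev_cm = max(abs(y)) * 100,
       area_cm2 = area)
}

#' Prey-image probability density map on the corneal grid
#'
#' Histograms corneal positions of the prey onto the grid with solid-angle
#' correction, normalizes to total mass 1, and (when several sequences are
#' given) averages per-sequence maps with equal weight regardless of their
#' frame counts.
#'
#' @param positions N x 2 matrix of corneal coordinates (radial, rotation;
#'   degrees), or a list of such matrices (one per sequence).
#' @param grid \code{spherical_grid}.
#' @param smooth_px optional isotropic Gaussian smoothing, pixels.
#' @return object of class \code{density_map}: \code{mass} (probability per
#'   pixel, sums to 1), \code{density} (mass per unit solid angle) and the
#'   grid.
#' @export
prey_density_map <- function(positions, grid, smooth_px = 0) {
  if (!is.list(positions)) positions <- list(positions)
  if (any(vapply(positions, nrow, 1L) == 0) || length(positions) == 0) {
    stop("empty corneal position input")
  }
  n <- grid$resolution
  one <- function(pos) {
    gam <- deg2rad(pos[, 1])
    d <- cbind(sin(gam) * cos(deg2rad(pos[, 2])),
               sin(gam) * sin(deg2rad(pos[, 2])), -cos(gam))
    px <- direction_to_pixel(grid, d)
    ij <- cbind(pmin(pmax(round(px[, 1]), 1), n), pmin(pmax(round(px[, 2]), 1), n))
    m <- matrix(0, n, n)
    for (k in seq_len(nrow(ij))) {
      if (any(is.na(ij[k, ]))) next
      m[ij[k, 1], ij[k, 2]] <- m[ij[k, 1], ij[k, 2]] + 1
    }
    if (smooth_px > 0) m <- gaussian_blur(m, smooth_px)
    m / sum(m)
  }
  maps <- lapply(positions, one)
  mass <- Reduce(`+`, maps) / length(maps)
  w <- grid_solid_angle(grid)
  dens <- mass / w
  dens[is.na(w)] <- NA_real_
  structure(list(mass = mass, density = dens, grid = grid),
            class = "density_map")
}

# Separable Gaussian blur with edge renormalization (mass preserving).
gaussian_blur <- function(m, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- i + (-half):half
      ok <- j >= 1 & j <= n
      out[i] <- sum(k[ok] * v[j[ok]]) / sum(k[ok])
    }
    out
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Highest-density-region contours of a corneal density map
#'
#' A level-p region is the smallest set of pixels (ranked by density per
#' solid angle) containing p percent of the total mass. Contour polygons are
#' extracted at the corresponding density threshold; each region's center of
#' mass is reported in corneal coordinates. Regions may be disconnected; all
#' polygon components are returned.
#'
#' @param map \code{density_map}.
#' @param levels percentages in (0, 100).
#' @return list per level: \code{level}, \code{mass} (achieved mass),
#'   \code{threshold}, \code{region} (logical pixel mask), \code{contours}
#'   (list of polygon data frames in pixel coordinates), \code{center}
#'   (radial, rotation, degrees).
#' @export
hdr_contours <- function(map, levels = c(50, 75, 90, 95)) {
  stopifnot(all(levels > 0), all(levels < 100))
  dens <- map$density
  mass <- map$mass
  ok <- which(is.finite(dens))
  o <- ok[order(dens[ok], decreasing = TRUE)]
  cmass <- cumsum(mass[o])
  gg <- grid_geometry(map$grid)
  lapply(levels, function(lv) {
    k <- which(cmass >= lv / 100)[1]
    if (is.na(k)) k <- length(o)
    # take whichever cut is nearer the target mass (within half a bin)
    if (k > 1 && abs(cmass[k - 1] - lv / 100) < abs(cmass[k] - lv / 100)) {
      k <- k - 1
    }
    region <- matrix(FALSE, nrow(dens), ncol(dens))
    region[o[seq_len(k)]] <- TRUE
    thr <- dens[o[k]]
    dd <- dens
    dd[!is.finite(dd)] <- 0
    cl <- grDevices::contourLines(x = seq_len(nrow(dd)), y = seq_len(ncol(dd)),
                                  z = dd, levels = thr)
    w <- mass[region]
    dirs <- gg$dirs[which(region), , drop = FALSE]
    ctr <- colSums(dirs * w) / sum(w)
    list(level = lv, mass = sum(mass[region]), threshold = thr,
         region = region,
         contours = lapply(cl, function(p) data.frame(x = p$x, y = p$y)),
         center = direction_to_corneal(ctr))
  })
}

#' Per-trial median summary
#'
#' Collapses each trial's temporal trace to its median, the per-trial summary
#' used before across-trial statistics (medians resist within-trial outliers
#' and autocorrelation).
#'
#' @param x numeric values.
#' @param trial trial labels, same length.
#' @return named numeric vector, one median per trial (NA for empty trials).
#' @export
per_trial_median <- function(x, trial) {
  stopifnot(length(x) == length(trial))
  out <- tapply(x, trial, function(v) stats::median(v, na.rm = TRUE))
  out[vapply(split(x, trial), function(v) all(is.na(v)) || length(v) == 0,
             logical(1))] <- NA_real_
  out
}
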