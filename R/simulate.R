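# Seeded synthetic-data generators: arena/room meshes, scripted prey
# pursuits with ground-truth epoch boundaries, head/eye rotation series with
# programmable VOR gains, and corneal-spot observations. Every generator is a
# pure function of its configuration (same seed, same bytes); generators draw
# from named substreams so adding one does not shift the others.

#' Simulation configuration
#'
#' @param seed master RNG seed; all generators derive their substreams from
#'   it.
#' @param head_rate_hz,eye_rate_hz tracking rates (defaults 200 and 60 Hz).
#' @param duration_s length of rotation series.
#' @param arena_dims_m arena width x depth x height (default 1 x 1 x 0.26 m).
#' @param gain_pitch,gain_roll programmed VOR gains (eye rotation about the
#'   head pitch/roll axis per unit head rotation; compensation is negative).
#' @param head_sd_deg named SDs of the band-limited head angles
#'   (yaw/pitch/roll).
#' @param angle_noise_deg angular measurement noise added to eye rotations.
#' @param pixel_noise_px corneal-spot pixel noise.
#' @param position_noise_m tracking noise on mouse/cricket positions.
#' @param spot_dropout fraction of spot frames dropped.
#' @param eye_azimuth_deg optical-axis azimuth of each eye from the head
#'   forward direction (left eye positive-left).
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1, head_rate_hz = 200, eye_rate_hz = 60,
                              duration_s = 10,
                              arena_dims_m = c(1, 1, 0.26),
                              gain_pitch = -0.45, gain_roll = -0.51,
                              head_sd_deg = c(yaw = 8, pitch = 8, roll = 6),
                              angle_noise_deg = 0, pixel_noise_px = 0,
                              position_noise_m = 0, spot_dropout = 0,
                              eye_azimuth_deg = 60) {
  stopifnot(head_rate_hz > 0, eye_rate_hz > 0, duration_s > 0,
            all(arena_dims_m > 0), is.finite(gain_pitch), is.finite(gain_roll))
  structure(as.list(environment()), class = "simulation_config")
}

# Named substreams off the master seed (kept below 2^31).
substream_seed <- function(config, name) {
  off <- c(mesh = 101L, pursuit = 211L, vor = 307L, spots = 401L,
           angles = 503L)
  (config$seed * 1009L + off[[name]]) %% .Machine$integer.max
}

# Closed axis-aligned box as 12 triangles; face labels by side.
box_mesh <- function(mins, maxs, id_prefix, inward = TRUE, open_top = FALSE) {
  v <- as.matrix(expand.grid(x = c(mins[1], maxs[1]), y = c(mins[2], maxs[2]),
                             z = c(mins[3], maxs[3])))
  # vertex index = 1 + (x_hi) + 2*(y_hi) + 4*(z_hi)
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  faces <- rbind(quad(1, 2, 4, 3), quad(5, 7, 8, 6),   # floor, ceiling
                 quad(1, 5, 6, 2), quad(3, 4, 8, 7),   # y walls
                 quad(1, 3, 7, 5), quad(2, 6, 8, 4))   # x walls
  ids <- c(rep("floor", 2), rep("ceiling", 2), rep("wall", 8))
  if (open_top) {
    keep <- ids != "ceiling"
    faces <- faces[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  scene_mesh(v, faces, paste0(id_prefix, "_", ids))
}

#' Synthetic arena and room mesh
#'
#' A watertight box arena inside a room shell, with per-face object IDs
#' (\code{arena_floor}, \code{arena_wall}, \code{arena_ceiling},
#' \code{room_*}). Stands in for the laser-scanned environment.
#'
#' @param config \code{simulation_config}.
#' @param open_ceiling drop the arena ceiling so the room is visible from
#'   inside.
#' @param room_dims_m room shell dimensions.
#' @return \code{scene_mesh}.
#' @export
make_room_mesh <- function(config = simulation_config(),
                           open_ceiling = FALSE, room_dims_m = c(5, 5, 3)) {
  a <- config$arena_dims_m
  arena <- box_mesh(c(-a[1] / 2, -a[2] / 2, 0), c(a[1] / 2, a[2] / 2, a[3]),
                    "arena", open_top = open_ceiling)
  room <- box_mesh(c(-room_dims_m[1] / 2, -room_dims_m[2] / 2, -0.001),
                   room_dims_m / 2 * c(1, 1, 2), "room")
  merge_meshes(arena, room)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron, used as the idealized spherical surround in optic
#' flow tests.
#'
#' @param radius m.
#' @param subdiv subdivision level (faces = 20 * 4^subdiv).
#' @param center 3-vector.
#' @param object_id face label.
#' @return \code{scene_mesh}.
#' @export
make_icosphere_mesh <- function(radius = 0.5, subdiv = 3, center = c(0, 0, 0),
                                object_id = "sphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_key <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_key[[key]]
      if (!is.null(m)) return(m)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      edge_key[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  scene_mesh(v, f, rep(object_id, nrow(f)))
}

#' Scripted prey pursuit with ground-truth epochs
#'
#' Generates a pursuit whose signals are piecewise linear around every rule
#' boundary, so the classifier's smoothed criteria cross where the script
#' says they do: idle, a turn sweeping the bearing below 90 degrees, a speed
#' ramp through 20 cm/s, a straight approach to the 6 cm contact, optionally
#' one cricket escape (rebound above 5 cm) and a final approach to capture.
#' Script parameters are drawn from the seeded substream within ranges that
#' respect the rule margins.
#'
#' @param config \code{simulation_config}.
#' @param with_escape include one escape (rebound to ~14 cm, beyond the
#'   11 cm capture zone).
#' @param initial_distance_m mouse-cricket distance at script start; values
#'   at or below 0.20 m produce a track epoch flagged excluded.
#' @return list with \code{trajectory} (\code{pursuit_trajectory}),
#'   \code{manual_capture_end}, and \code{truth}: epoch boundary times and
#'   escape count as scripted.
#' @export
simulate_pursuit <- function(config = simulation_config(), with_escape = FALSE,
                             initial_distance_m = NULL) {
  set.seed(substream_seed(config, "pursuit"))
  dt <- 1 / config$head_rate_hz
  d0 <- if (is.null(initial_distance_m)) stats::runif(1, 0.32, 0.45) else
    initial_distance_m
  b0 <- stats::runif(1, 105, 150)        # initial bearing, above 90
  v_pk <- stats::runif(1, 0.24, 0.30)    # approach speed, above 20 cm/s
  t_idle <- stats::runif(1, 0.8, 1.2)
  t_turn <- 0.2
  t_ramp <- 0.3

  # timeline: idle | turn | quadratic speed ramp | linear approach | parabolic
  # dip to 5 cm, with boundary crossings kept on smooth or mid-linear stretches
  # so the classifier's 50 ms smoothing does not move them.
  t_acc <- t_idle + t_turn
  t_cross <- t_acc + t_ramp * (0.20 / v_pk)     # speed crosses 20 cm/s
  d_ramp_end <- d0 - v_pk * t_ramp / 2
  t_lin_end <- t_acc + t_ramp + (d_ramp_end - 0.08) / v_pk
  T_dip <- 0.06 / v_pk                          # 3 cm parabolic dip half-time
  a_dip <- v_pk / (2 * T_dip)
  t_min1 <- t_lin_end + T_dip
  t_c1 <- t_min1 - sqrt(0.01 / a_dip)           # 6 cm contact crossing
  dip <- function(t, t_min) 0.05 + a_dip * (t - t_min)^2
  if (with_escape) {
    t_rise_end <- t_min1 + 0.07 / v_pk          # linear rise 5 -> 12 cm
    T_cap <- 2 * 0.02 / v_pk                    # parabolic cap 12 -> 14 cm
    a_cap <- v_pk / (2 * T_cap)
    t_peak <- t_rise_end + T_cap
    t_fall_end <- t_peak + T_cap + 0.04 / v_pk  # linear fall 12 -> 8 cm
    t_min2 <- t_fall_end + T_dip
    t_c2 <- t_min2 - sqrt(0.01 / a_dip)         # final 6 cm crossing
    t_escape <- t_min1 + 0.05 / v_pk            # rebound reaches +5 cm
    t_total <- t_min2 + 0.25
  } else {
    t_total <- t_min1 + T_dip + 0.25
    t_c2 <- t_c1
  }
  dist_fun <- function(t) {
    if (t < t_acc) return(d0)
    if (t < t_acc + t_ramp) return(d0 - v_pk * (t - t_acc)^2 / (2 * t_ramp))
    if (t < t_lin_end) return(d_ramp_end - v_pk * (t - t_acc - t_ramp))
    if (!with_escape) {
      if (t < t_min1 + T_dip) return(dip(t, t_min1))
      return(0.08)                              # 3 cm rebound: not an escape
    }
    if (t < t_min1) return(dip(t, t_min1))
    if (t < t_rise_end) return(0.05 + v_pk * (t - t_min1))
    if (t < t_peak + T_cap) return(0.14 - a_cap * (t - t_peak)^2)
    if (t < t_fall_end) return(0.12 - v_pk * (t - t_peak - T_cap))
    if (t < t_min2 + T_dip) return(dip(t, t_min2))
    return(0.05)
  }
  ts <- seq(0, t_total, by = dt)
  n <- length(ts)
  dist <- vapply(ts, dist_fun, numeric(1))
  bear <- ifelse(ts < t_idle, b0,
                 ifelse(ts < t_acc, b0 + (10 - b0) * (ts - t_idle) / t_turn, 10))

  # embed in the arena: cricket fixed, mouse on a straight line toward it
  cricket <- matrix(rep(c(0.15, 0.15, 0.01), each = n), n, 3)
  appr <- unit3(c(-1, -0.4, 0))
  mouse <- cricket + outer(dist, -appr)
  if (config$position_noise_m > 0) {
    mouse <- mouse + matrix(stats::rnorm(3 * n, 0, config$position_noise_m),
                            n, 3)
  }
  traj <- pursuit_trajectory(ts, mouse, cricket, bearing_deg = bear)
  t_bear_cross <- t_idle + t_turn * (b0 - 90) / (b0 - 10)
  grid_ceil <- function(t) ceiling(t / dt - 1e-9) * dt
  truth <- list(
    detect_t_end = grid_ceil(t_cross) - dt,
    detect_t_start = grid_ceil(t_cross) - dt - 0.5,
    track_t_start = grid_ceil(t_bear_cross),
    track_t_end = grid_ceil(t_c1),
    n_escapes = as.integer(with_escape),
    t_escape = if (with_escape) grid_ceil(t_escape) else NA_real_,
    capture_t_start = if (with_escape) round(t_peak / dt) * dt + dt else
      NA_real_,
    capture_t_end = grid_ceil(t_c2),
    excluded_track = d0 <= 0.20)
  list(trajectory = traj, manual_capture_end = truth$capture_t_end,
       truth = truth)
}

# Band-limited zero-mean angle signal: a fixed number of random sinusoids,
# scaled to the target SD; evaluable at arbitrary times.
sinusoid_signal <- function(sd_deg, n_comp = 8, f_range = c(0.2, 1.5)) {
  f <- stats::runif(n_comp, f_range[1], f_range[2])
  ph <- stats::runif(n_comp, 0, 2 * pi)
  a <- stats::runif(n_comp, 0.5, 1)
  a <- a / sqrt(sum(a^2) / 2) * sd_deg
  function(t) {
    out <- numeric(length(t))
    for (k in seq_len(n_comp)) out <- out + a[k] * sin(2 * pi * f[k] * t + ph[k])
    out
  }
}

# Anatomical reference orientation of an eye in the head frame: optical axis
# at the given azimuth from forward (positive = leftward) and elevation above
# the horizontal plane.
# The twist about the gaze sets how the eye camera's vertical/horizontal axes
# sit on the globe; -90 deg makes head roll load mostly on vertical eye
# rotation and head pitch on torsion, the coupling seen in lateral-eyed
# rodents.
eye_reference_orientation <- function(azimuth_deg, elevation_deg = 22,
                                      twist_deg = -90) {
  rot_z(azimuth_deg) %*% rotation_about_axis(c(0, -1, 0), elevation_deg) %*%
    rot_y(-90) %*% rot_z(twist_deg)
}

#' Synthetic head and eye rotation series with programmed VOR structure
#'
#' Head yaw/pitch/roll are independent band-limited signals; each eye
#' counter-rotates about the head pitch and roll axes with the programmed
#' gains (plus optional angular noise), on 60 Hz timestamps offset from the
#' 200 Hz head timestamps so downstream analyses must interpolate.
#'
#' @param config \code{simulation_config}.
#' @return list with \code{head} (\code{rotation_series}, head -> world),
#'   \code{left}, \code{right} (eye-in-head \code{rotation_series}),
#'   \code{left_ref}, \code{right_ref} (anatomical reference orientations),
#'   and the head angle signals evaluated on the head timestamps.
#' @export
simulate_vor_head_eye <- function(config = simulation_config()) {
  set.seed(substream_seed(config, "vor"))
  yaw <- sinusoid_signal(config$head_sd_deg[["yaw"]])
  pitch <- sinusoid_signal(config$head_sd_deg[["pitch"]])
  roll <- sinusoid_signal(config$head_sd_deg[["roll"]])
  th <- seq(0, config$duration_s, by = 1 / config$head_rate_hz)
  te <- seq(0.0023, config$duration_s, by = 1 / config$eye_rate_hz)
  nh <- length(th); ne <- length(te)
  H <- array(0, dim = c(3, 3, nh))
  for (i in seq_len(nh)) {
    H[, , i] <- head_from_euler(yaw(th[i]), pitch(th[i]), roll(th[i]))
  }
  eye_series <- function(tt, label) {
    n <- length(tt)
    E <- array(0, dim = c(3, 3, n))
    p <- pitch(tt); r <- roll(tt)
    if (config$angle_noise_deg > 0) {
      p <- p + stats::rnorm(n, 0, config$angle_noise_deg)
      r <- r + stats::rnorm(n, 0, config$angle_noise_deg)
    }
    ref <- eye_reference_orientation(
      if (label == "left_eye") config$eye_azimuth_deg else -config$eye_azimuth_deg)
    for (i in seq_len(n)) {
      comp <- rotation_about_axis(c(0, -1, 0), config$gain_pitch * p[i]) %*%
        rotation_about_axis(c(1, 0, 0), config$gain_roll * r[i])
      E[, , i] <- comp %*% ref
    }
    rotation_series(tt, E, label)
  }
  list(head = rotation_series(th, H, "head"),
       left = eye_series(te, "left_eye"),
       right = eye_series(te, "right_eye"),
       left_ref = eye_reference_orientation(config$eye_azimuth_deg),
       right_ref = eye_reference_orientation(-config$eye_azimuth_deg),
       head_angles = data.frame(t = th, yaw = yaw(th), pitch = pitch(th),
                                roll = roll(th)))
}

#' Synthetic smooth eye-angle series
#'
#' Band-limited vertical/horizontal/torsional angle traces for exercising the
#' corneal-spot pipeline.
#'
#' @param config \code{simulation_config}.
#' @param n_frames frames at the eye rate.
#' @param sd_deg named SDs for \code{phi}, \code{theta}, \code{psi}.
#' @return data frame with \code{t}, \code{phi}, \code{theta}, \code{psi}
#'   (degrees).
#' @export
simulate_eye_angles <- function(config = simulation_config(), n_frames = 200,
                                sd_deg = c(phi = 10, theta = 12, psi = 6)) {
  set.seed(substream_seed(config, "angles"))
  tt <- (seq_len(n_frames) - 1) / config$eye_rate_hz
  data.frame(t = tt,
             phi = sinusoid_signal(sd_deg[["phi"]])(tt),
             theta = sinusoid_signal(sd_deg[["theta"]])(tt),
             psi = sinusoid_signal(sd_deg[["psi"]])(tt))
}

#' Synthetic corneal-spot observations
#'
#' Forward-projects the spot for each frame of an eye-angle series, adds
#' Gaussian pixel noise, and drops frames at the configured rate.
#'
#' @param config \code{simulation_config}.
#' @param angles data frame from \code{\link{simulate_eye_angles}} (columns
#'   \code{t}, \code{phi}, \code{theta}, \code{psi}).
#' @param params \code{spot_params}; \code{cam} \code{pupil_camera_model}.
#' @param cam \code{pupil_camera_model}.
#' @return \code{spot_track}.
#' @export
simulate_spot_observations <- function(config, angles, params, cam) {
  set.seed(substream_seed(config, "spots"))
  px <- project_spot(angles$phi, angles$theta, angles$psi, params, cam)
  n <- nrow(px)
  if (config$pixel_noise_px > 0) {
    px <- px + matrix(stats::rnorm(2 * n, 0, config$pixel_noise_px), n, 2)
  }
  if (config$spot_dropout > 0) {
    drop <- stats::runif(n) < config$spot_dropout
    px[drop, ] <- NA_real_
  }
  spot_track(angles$t, px, angles$phi, angles$theta)
}
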