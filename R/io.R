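# File interfaces: CSV for landmark sets, rotation series, spot tracks and
# pursuit trajectories; OBJ meshes with a JSON object-ID sidecar; YAML eye
# parameters; JSON reports.

#' Read anatomical landmarks from CSV
#'
#' Expects columns \code{name,x,y,z} (m) with names \code{left_canthus},
#' \code{right_canthus}, \code{left_nostril}, \code{right_nostril}; any
#' \code{led_*} rows become LED positions.
#'
#' @param path CSV file.
#' @return \code{anatomical_landmarks}.
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x", "y", "z") %in% names(d)))
  get <- function(nm) {
    r <- d[d$name == nm, , drop = FALSE]
    if (nrow(r) != 1) stop(sprintf("landmark '%s' missing or duplicated", nm))
    as.numeric(r[1, c("x", "y", "z")])
  }
  leds <- d[grepl("^led", d$name), , drop = FALSE]
  anatomical_landmarks(get("left_canthus"), get("right_canthus"),
                       get("left_nostril"), get("right_nostril"),
                       led_positions = lapply(seq_len(nrow(leds)), function(i) {
                         as.numeric(leds[i, c("x", "y", "z")])
                       }))
}

#' Read and write rotation series CSV
#'
#' Two layouts are accepted: \code{timestamp, r11..r33} (row-major rotation
#' entries) or \code{timestamp, phi_deg, theta_deg, psi_deg} (eye angles,
#' composed via \code{\link{compose_eye_rotation}}).
#'
#' @param path CSV file.
#' @param frame_label series label.
#' @return \code{rotation_series}.
#' @export
read_rotation_series_csv <- function(path, frame_label = "head") {
  d <- utils::read.csv(path)
  rc <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  n <- nrow(d)
  R <- array(0, dim = c(3, 3, n))
  if (all(rc %in% names(d))) {
    for (i in seq_len(n)) {
      R[, , i] <- matrix(as.numeric(d[i, rc]), 3, 3, byrow = TRUE)
    }
  } else if (all(c("phi_deg", "theta_deg", "psi_deg") %in% names(d))) {
    for (i in seq_len(n)) {
      R[, , i] <- compose_eye_rotation(d$phi_deg[i], d$theta_deg[i],
                                       d$psi_deg[i])$rotation
    }
  } else {
    stop("need either r11..r33 or phi_deg/theta_deg/psi_deg columns")
  }
  rotation_series(d$timestamp, R, frame_label)
}

#' @rdname read_rotation_series_csv
#' @param series \code{rotation_series} to write.
#' @export
write_rotation_series_csv <- function(series, path) {
  n <- length(series)
  m <- t(vapply(seq_len(n), function(i) as.numeric(t(series$rotations[, , i])),
                numeric(9)))
  colnames(m) <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  utils::write.csv(cbind(timestamp = series$timestamps, as.data.frame(m)),
                   path, row.names = FALSE)
}

#' Read and write spot-track CSV
#'
#' Columns \code{timestamp, spot_x_px, spot_y_px, phi_deg, theta_deg}; empty
#' pixel fields mark untracked frames.
#'
#' @param path CSV file.
#' @return \code{spot_track}.
#' @export
read_spot_track_csv <- function(path) {
  d <- utils::read.csv(path)
  spot_track(d$timestamp, cbind(d$spot_x_px, d$spot_y_px), d$phi_deg,
             d$theta_deg)
}

#' @rdname read_spot_track_csv
#' @param track \code{spot_track} to write.
#' @export
write_spot_track_csv <- function(track, path) {
  utils::write.csv(data.frame(timestamp = track$timestamps,
                              spot_x_px = track$spot_px[, 1],
                              spot_y_px = track$spot_px[, 2],
                              phi_deg = track$phi, theta_deg = track$theta),
                   path, row.names = FALSE)
}

#' Read and write pursuit-trajectory CSV
#'
#' Columns \code{t, mouse_x, mouse_y, mouse_z, cricket_x, cricket_y,
#' cricket_z} and optionally \code{bearing_deg}.
#'
#' @param path CSV file.
#' @return \code{pursuit_trajectory}.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  pursuit_trajectory(d$t, as.matrix(d[, c("mouse_x", "mouse_y", "mouse_z")]),
                     as.matrix(d[, c("cricket_x", "cricket_y", "cricket_z")]),
                     bearing_deg = d$bearing_deg)
}

#' @rdname read_trajectory_csv
#' @param traj \code{pursuit_trajectory} to write.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(t = traj$timestamps,
                              mouse_x = traj$mouse[, 1], mouse_y = traj$mouse[, 2],
                              mouse_z = traj$mouse[, 3],
                              cricket_x = traj$cricket[, 1],
                              cricket_y = traj$cricket[, 2],
                              cricket_z = traj$cricket[, 3],
                              bearing_deg = traj$bearing_deg),
                   path, row.names = FALSE)
}

#' Read a Wavefront OBJ mesh
#'
#' Supports \code{v} and (triangular) \code{f} records; faces are labeled by
#' the most recent \code{o}/\code{g}/\code{usemtl} statement, or by a JSON
#' sidecar mapping face ranges to object IDs.
#'
#' @param path OBJ file.
#' @param id_sidecar optional JSON file: list of \code{{"id": name,
#'   "from": i, "to": j}} 1-based face ranges overriding the group labels.
#' @return \code{scene_mesh}.
#' @export
read_obj_mesh <- function(path, id_sidecar = NULL) {
  ln <- readLines(path, warn = FALSE)
  vs <- list(); fs <- list(); ids <- character(0)
  cur <- "default"
  for (l in ln) {
    if (startsWith(l, "v ")) {
      vs[[length(vs) + 1]] <- as.numeric(strsplit(trimws(sub("^v", "", l)),
                                                  "\\s+")[[1]])[1:3]
    } else if (startsWith(l, "f ")) {
      tok <- strsplit(trimws(sub("^f", "", l)), "\\s+")[[1]]
      vi <- as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1))
      if (length(vi) != 3) stop("read_obj_mesh supports triangular faces only")
      fs[[length(fs) + 1]] <- vi
      ids <- c(ids, cur)
    } else if (grepl("^(o|g|usemtl) ", l)) {
      cur <- strsplit(trimws(l), "\\s+")[[1]][2]
    }
  }
  if (!is.null(id_sidecar)) {
    sc <- jsonlite::fromJSON(id_sidecar, simplifyVector = FALSE)
    for (e in sc) ids[seq(e$from, e$to)] <- e$id
  }
  scene_mesh(do.call(rbind, vs), do.call(rbind, fs), ids)
}

#' @rdname read_obj_mesh
#' @param mesh \code{scene_mesh} to write (groups from object IDs).
#' @export
write_obj_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  ids <- as.character(mesh$object_ids)
  last <- ""
  for (k in seq_len(nrow(mesh$faces))) {
    if (ids[k] != last) {
      writeLines(paste("g", ids[k]), con)
      last <- ids[k]
    }
    writeLines(sprintf("f %d %d %d", mesh$faces[k, 1], mesh$faces[k, 2],
                       mesh$faces[k, 3]), con)
  }
  invisible(path)
}

#' Read schematic-eye parameters from YAML
#'
#' Top-level keys \code{radii}, \code{thicknesses}, \code{indices},
#' \code{pupil_radius} mirroring the \code{\link{schematic_eye}} arguments;
#' missing keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return \code{schematic_eye}.
#' @export
read_eye_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$radii)) args$radii <- unlist(y$radii)
  if (!is.null(y$thicknesses)) args$thicknesses <- unlist(y$thicknesses)
  if (!is.null(y$indices)) args$indices <- unlist(y$indices)
  if (!is.null(y$pupil_radius)) args$pupil_radius <- y$pupil_radius
  do.call(schematic_eye, args)
}

#' Write an epoch segmentation to JSON
#'
#' @param seg \code{epoch_segmentation}.
#' @param path output file.
#' @export
write_segmentation_json <- function(seg, path) {
  jsonlite::write_json(list(epochs = seg$epochs, escapes = seg$escapes),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
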