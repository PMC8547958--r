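# Corneal-view rendering: spherical (azimuthal-equidistant) pixel grid over a
# 180-degree field, per-pixel ray casting of the environment mesh and the
# cricket disk, and point projection into corneal coordinates.
#
# Eye-frame convention: the optical axis is the reference gaze (0, 0, -1);
# the corneal coordinates of a direction are its radial angle off the optical
# axis and its rotational angle about it.

#' Triangle scene mesh with per-face object IDs
#'
#' @param vertices N x 3 matrix (m).
#' @param faces K x 3 integer matrix of 1-based vertex indices.
#' @param object_ids length-K integer or factor/character labels per face.
#' @return object of class \code{scene_mesh}; \code{object_ids} is stored as a
#'   factor whose levels name the objects.
#' @export
scene_mesh <- function(vertices, faces, object_ids) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            length(object_ids) == nrow(faces))
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (max(faces) > nrow(vertices) || min(faces) < 1) stop("face index out of range")
  # reject degenerate (zero-area) faces
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (any(rowSums(cr^2) < 1e-24)) stop("mesh contains zero-area faces")
  structure(list(vertices = vertices, faces = faces,
                 object_ids = as.factor(object_ids)),
            class = "scene_mesh")
}

#' Merge two scene meshes
#' @param a,b \code{scene_mesh} objects.
#' @return combined \code{scene_mesh}.
#' @export
merge_meshes <- function(a, b) {
  scene_mesh(rbind(a$vertices, b$vertices),
             rbind(a$faces, b$faces + nrow(a$vertices)),
             c(as.character(a$object_ids), as.character(b$object_ids)))
}

#' Cricket model: a vertical-axis disk
#'
#' Crickets are modeled as closed disks (default 2 cm diameter, 1 cm thick)
#' centered on the tracked position with the axis parallel to gravity.
#'
#' @param center 3-vector (m).
#' @param diameter,thickness disk dimensions (m).
#' @param n_seg rim segments of the tessellation.
#' @param object_id face label.
#' @return \code{scene_mesh} of the closed disk.
#' @export
cricket_disk_mesh <- function(center, diameter = 0.02, thickness = 0.01,
                              n_seg = 64, object_id = "cricket") {
  r <- diameter / 2
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ring_lo <- cbind(r * cos(th), r * sin(th), -thickness / 2)
  ring_hi <- cbind(r * cos(th), r * sin(th), +thickness / 2)
  verts <- rbind(ring_lo, ring_hi, c(0, 0, -thickness / 2), c(0, 0, thickness / 2))
  verts <- sweep(verts, 2, center, "+")
  c_lo <- 2 * n_seg + 1; c_hi <- 2 * n_seg + 2
  nxt <- c(2:n_seg, 1)
  faces <- rbind(
    cbind(seq_len(n_seg), nxt, c_lo),                        # bottom cap
    cbind(n_seg + nxt, n_seg + seq_len(n_seg), c_hi),        # top cap
    cbind(seq_len(n_seg), n_seg + seq_len(n_seg), nxt),      # side
    cbind(nxt, n_seg + seq_len(n_seg), n_seg + nxt))
  scene_mesh(verts, faces, rep(object_id, nrow(faces)))
}

#' Spherical corneal-view pixel grid
#'
#' Azimuthal-equidistant projection about the optical axis: the center pixel
#' maps to the optical axis and radial pixel distance is proportional to the
#' angle off the axis, up to half the opening angle at the disk edge.
#'
#' @param resolution pixels per side (default 1024).
#' @param opening_angle full field of view, degrees (default 180).
#' @return object of class \code{spherical_grid}.
#' @export
spherical_grid <- function(resolution = 1024, opening_angle = 180) {
  stopifnot(resolution >= 3, opening_angle > 0, opening_angle <= 360)
  structure(list(resolution = as.integer(resolution),
                 opening_angle = opening_angle),
            class = "spherical_grid")
}

#' Pixel to view direction and back
#'
#' @param grid \code{spherical_grid}.
#' @param pixel N x 2 matrix (or length-2 vector) of pixel coordinates
#'   (1-based, x = column, y = row).
#' @return \code{pixel_to_direction}: N x 3 matrix of unit directions in the
#'   eye frame (NA rows outside the opening angle); \code{direction_to_pixel}:
#'   N x 2 matrix of pixel coordinates (NA rows beyond the field).
#' @export
pixel_to_direction <- function(grid, pixel) {
  px <- matrix(pixel, ncol = 2)
  ctr <- (grid$resolution + 1) / 2
  rad_px <- grid$resolution / 2
  dx <- px[, 1] - ctr; dy <- px[, 2] - ctr
  rho <- sqrt(dx^2 + dy^2)
  gam <- deg2rad((rho / rad_px) * (grid$opening_angle / 2))
  tau <- atan2(dy, dx)
  out <- cbind(sin(gam) * cos(tau), sin(gam) * sin(tau), -cos(gam))
  out[gam > deg2rad(grid$opening_angle / 2) + 1e-12, ] <- NA_real_
  out
}

#' @rdname pixel_to_direction
#' @param direction N x 3 matrix (or 3-vector) of directions in the eye frame.
#' @export
direction_to_pixel <- function(grid, direction) {
  d <- matrix(direction, ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  ctr <- (grid$resolution + 1) / 2
  rad_px <- grid$resolution / 2
  gam <- rad2deg(acos(pmax(-1, pmin(1, -d[, 3]))))
  rho <- gam / (grid$opening_angle / 2) * rad_px
  tau <- atan2(d[, 2], d[, 1])
  out <- cbind(ctr + rho * cos(tau), ctr + rho * sin(tau))
  out[gam > grid$opening_angle / 2 + 1e-12, ] <- NA_real_
  out
}

# All pixel-center directions of the grid plus the in-field mask and per-pixel
# radial/rotation angles (degrees). Cached layout: row-major over (y, x) is
# avoided; matrices are indexed [x, y] consistent with R matrix [row, col] =
# [x index, y index].
grid_geometry <- function(grid) {
  n <- grid$resolution
  ctr <- (n + 1) / 2
  rad_px <- n / 2
  xs <- (1:n) - ctr
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  rho <- sqrt(X^2 + Y^2)
  gam_deg <- (rho / rad_px) * (grid$opening_angle / 2)
  tau <- atan2(Y, X)
  inside <- gam_deg <= grid$opening_angle / 2 + 1e-12
  gam <- deg2rad(gam_deg)
  dirs <- cbind(c(sin(gam) * cos(tau)), c(sin(gam) * sin(tau)), c(-cos(gam)))
  list(dirs = dirs, inside = inside, radial_deg = gam_deg, tau = tau)
}

#' Per-pixel solid-angle weights of a spherical grid
#'
#' The azimuthal-equidistant chart is not equal-area; statistics over the map
#' must weight each pixel by its subtended solid angle, proportional to
#' sin(gamma)/gamma with gamma the angle off the optical axis.
#'
#' @param grid \code{spherical_grid}.
#' @return matrix of relative solid-angle weights (NA outside the field).
#' @export
grid_solid_angle <- function(grid) {
  gg <- grid_geometry(grid)
  g <- deg2rad(gg$radial_deg)
  w <- ifelse(g < 1e-9, 1, sin(g) / pmax(g, 1e-12))
  w[!gg$inside] <- NA_real_
  matrix(w, grid$resolution, grid$resolution)
}

#' Render the corneal view of a scene
#'
#' Casts one ray per grid pixel from the eye position and records the nearest
#' mesh intersection: object ID, depth (m) and the 3D intersection point.
#' Intersection points are stored in the static world frame together with the
#' eye pose, so consecutive frames share a common coordinate system.
#'
#' @param mesh \code{scene_mesh} of the environment.
#' @param cricket optional \code{scene_mesh} (e.g.
#'   \code{\link{cricket_disk_mesh}}) merged into the scene.
#' @param eye_position 3-vector, eye location (m, world).
#' @param eye_rotation 3x3 matrix mapping eye coordinates to world (the
#'   optical axis (0,0,-1) maps to the gaze direction).
#' @param grid \code{spherical_grid}.
#' @return object of class \code{eye_view_frame}: matrices \code{object_id}
#'   (factor levels in \code{$levels}), \code{depth}, arrays \code{xyz}
#'   (res x res x 3, world frame), plus the pose and grid.
#' @export
render_eye_view <- function(mesh, cricket = NULL, eye_position, eye_rotation,
                            grid) {
  stopifnot(inherits(mesh, "scene_mesh"), inherits(grid, "spherical_grid"))
  if (!is_rotation(eye_rotation, tol = 1e-6)) stop("eye_rotation is not a rotation")
  scene <- if (is.null(cricket)) mesh else merge_meshes(mesh, cricket)
  gg <- grid_geometry(grid)
  dirs_world <- gg$dirs %*% t(eye_rotation)
  dirs_world[!gg$inside, ] <- NA_real_
  hit <- ray_cast_cpp(as.numeric(eye_position), dirs_world,
                      scene$vertices, scene$faces - 1L)
  n <- grid$resolution
  depth <- matrix(hit$t, n, n)
  fid <- hit$face
  obj <- matrix(NA_integer_, n, n)
  obj[!is.na(fid)] <- as.integer(scene$object_ids[fid[!is.na(fid)]])
  xyz <- array(NA_real_, dim = c(n, n, 3))
  ok <- !is.na(hit$t)
  for (k in 1:3) {
    v <- rep(NA_real_, n * n)
    v[ok] <- eye_position[k] + hit$t[ok] * dirs_world[ok, k]
    xyz[, , k] <- matrix(v, n, n)
  }
  structure(list(object_id = obj, levels = levels(scene$object_ids),
                 depth = depth, xyz = xyz,
                 eye_position = as.numeric(eye_position),
                 eye_rotation = eye_rotation, grid = grid),
            class = "eye_view_frame")
}

#' @export
print.eye_view_frame <- function(x, ...) {
  cat(sprintf("<eye_view_frame %dx%d, %d/%d pixels hit, objects: %s>\n",
              x$grid$resolution, x$grid$resolution,
              sum(!is.na(x$depth)), x$grid$resolution^2,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Project a world point to corneal coordinates
#'
#' @param point 3-vector (m, world).
#' @param eye_position,eye_rotation eye pose as in
#'   \code{\link{render_eye_view}}.
#' @return named vector \code{c(radial, rotation)} in degrees, or NA values
#'   (with attribute \code{status = "out-of-field"}) beyond 90 degrees off
#'   axis.
#' @export
project_point_to_cornea <- function(point, eye_position, eye_rotation) {
  v <- point - eye_position
  if (sqrt(sum(v^2)) < 1e-12) stop("undefined direction: point at the eye center")
  d_eye <- as.numeric(t(eye_rotation) %*% v)
  cc <- direction_to_corneal(d_eye)
  if (cc[["radial"]] > 90 + 1e-9) {
    out <- c(radial = NA_real_, rotation = NA_real_)
    attr(out, "status") <- "out-of-field"
    return(out)
  }
  cc
}
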