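# Schematic mouse eye with a gradient-index (GRIN) lens: geometry from
# measured biometry, ray tracing, three-stage lens optimization,
# retina-to-cornea Monte-Carlo projection and parameter-sensitivity analysis.
#
# Internal coordinates: optical axis = +z, anterior cornea vertex at z = 0,
# light from the world enters traveling +z; lengths in micrometers. Surface
# axial positions follow from cumulative thicknesses. Radii are stored as the
# tabulated signed values; the geometry uses their magnitudes with the physical
# orientation of each surface (cornea and anterior lens convex toward the
# world, posterior lens and retina concave toward the world).

#' Schematic mouse eye
#'
#' Builds the model eye from surface radii of curvature, component thicknesses
#' and refractive indices. Defaults are measured mouse biometry values;
#' the pupil radius default (594 um) is the mean of the constricted and
#' dilated mouse pupil.
#'
#' @param radii named vector of radii of curvature (um): \code{anterior_cornea},
#'   \code{posterior_cornea}, \code{anterior_lens}, \code{posterior_lens},
#'   \code{retina}. Signed values are stored as given; magnitudes define the
#'   geometry.
#' @param thicknesses named vector (um): \code{cornea}, \code{anterior_chamber},
#'   \code{lens}, \code{vitreous}.
#' @param indices named vector: \code{cornea}, \code{anterior_chamber},
#'   \code{vitreous}.
#' @param pupil_radius pupil aperture radius, um.
#' @param lattice_dim,lattice_side GRIN lattice nodes per axis and cube side
#'   length (um).
#' @return object of class \code{schematic_eye}. The lens is unset until
#'   \code{\link{optimize_lens}} is run.
#' @export
schematic_eye <- function(radii = c(anterior_cornea = -1408,
                                    posterior_cornea = -1372,
                                    anterior_lens = 1150,
                                    posterior_lens = 1134,
                                    retina = 1598),
                          thicknesses = c(cornea = 92,
                                          anterior_chamber = 278,
                                          lens = 2004,
                                          vitreous = 609),
                          indices = c(cornea = 1.402,
                                      anterior_chamber = 1.334,
                                      vitreous = 1.333),
                          pupil_radius = 594,
                          lattice_dim = 40, lattice_side = 2400) {
  stopifnot(all(thicknesses > 0), all(indices > 1), pupil_radius > 0,
            all(abs(radii) > 0))
  eye <- structure(list(radii = radii, thicknesses = thicknesses,
                        indices = indices, pupil_radius = pupil_radius,
                        lattice_dim = lattice_dim, lattice_side = lattice_side,
                        lens = NULL),
                   class = "schematic_eye")
  eye
}

# Axial vertex positions (um) from cumulative thicknesses.
eye_vertices <- function(eye) {
  th <- eye$thicknesses
  z_ac <- 0
  z_pc <- z_ac + th[["cornea"]]
  z_al <- z_pc + th[["anterior_chamber"]]
  z_pl <- z_al + th[["lens"]]
  z_ret <- z_pl + th[["vitreous"]]
  c(anterior_cornea = z_ac, posterior_cornea = z_pc, anterior_lens = z_al,
    posterior_lens = z_pl, retina = z_ret)
}

# Geometry vector consumed by the C++ tracer (slot order fixed there).
eye_geom_vector <- function(eye) {
  v <- eye_vertices(eye)
  R <- abs(eye$radii)
  c(cz_ac = v[["anterior_cornea"]] + R[["anterior_cornea"]],
    R_ac = R[["anterior_cornea"]],
    cz_pc = v[["posterior_cornea"]] + R[["posterior_cornea"]],
    R_pc = R[["posterior_cornea"]],
    cz_al = v[["anterior_lens"]] + R[["anterior_lens"]],
    R_al = R[["anterior_lens"]],
    cz_pl = v[["posterior_lens"]] - R[["posterior_lens"]],
    R_pl = R[["posterior_lens"]],
    cz_ret = v[["retina"]] - R[["retina"]],
    R_ret = R[["retina"]],
    pupil_z = v[["anterior_lens"]],
    pupil_r = eye$pupil_radius,
    n_cor = eye$indices[["cornea"]],
    n_aq = eye$indices[["anterior_chamber"]],
    n_vit = eye$indices[["vitreous"]],
    aperture = 1400)
}

# Lattice node coordinates, centered on the lens body.
eye_lattice_spec <- function(eye) {
  v <- eye_vertices(eye)
  zc <- (v[["anterior_lens"]] + v[["posterior_lens"]]) / 2
  n <- eye$lattice_dim
  h <- eye$lattice_side / (n - 1)
  origin <- c(-eye$lattice_side / 2, -eye$lattice_side / 2,
              zc - eye$lattice_side / 2)
  list(origin = origin, h = h, dim = c(n, n, n),
       x = origin[1] + h * (0:(n - 1)),
       y = origin[2] + h * (0:(n - 1)),
       z = origin[3] + h * (0:(n - 1)))
}

# Logical 3D array: lattice nodes inside the lens body (intersection of the
# two lens surface spheres).
eye_lens_mask <- function(eye, lat = eye_lattice_spec(eye)) {
  g <- eye_geom_vector(eye)
  n <- lat$dim
  gx <- lat$x; gy <- lat$y; gz <- lat$z
  X <- array(rep(gx, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(gy, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(gz, each = n[1] * n[2]), dim = n)
  da <- X^2 + Y^2 + (Z - g[["cz_al"]])^2
  dp <- X^2 + Y^2 + (Z - g[["cz_pl"]])^2
  da <= g[["R_al"]]^2 & dp <= g[["R_pl"]]^2
}

#' Poisson profile for the gradient lens model
#'
#' Solves the Poisson equation (unit source, Dirichlet zero boundary) on the
#' lattice nodes inside the lens body with a 7-point finite-difference
#' Laplacian and a direct sparse solve. The gradient-model refractive index is
#' \code{n_b + c * u} with boundary index \code{n_b = 1.333} and gradient
#' strength \code{c}.
#'
#' @param eye \code{schematic_eye}.
#' @return list with \code{u} (3D array, um^2, zero outside the lens),
#'   \code{mask} (logical 3D array) and the lattice spec.
#' @export
grin_poisson_profile <- function(eye) {
  lat <- eye_lattice_spec(eye)
  mask <- eye_lens_mask(eye, lat)
  n <- lat$dim
  id <- array(0L, dim = n)
  ins <- which(mask)
  id[ins] <- seq_along(ins)
  ni <- length(ins)
  if (ni == 0) stop("lens body contains no lattice nodes")
  # assemble the 7-point Laplacian over interior nodes
  ai <- integer(0); aj <- integer(0)
  idx3 <- arrayInd(ins, n)
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx3
      nb[, d] <- nb[, d] + s
      ok <- nb[, d] >= 1 & nb[, d] <= n[d]
      lin <- rep(0L, ni)
      lin[ok] <- id[nb[ok, , drop = FALSE]]
      has <- lin > 0
      ai <- c(ai, which(has)); aj <- c(aj, lin[has])
    }
  }
  h2 <- lat$h^2
  A <- Matrix::sparseMatrix(i = c(seq_len(ni), ai), j = c(seq_len(ni), aj),
                            x = c(rep(6 / h2, ni), rep(-1 / h2, length(ai))),
                            dims = c(ni, ni))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  u_in <- as.numeric(Matrix::solve(ch, rep(1, ni)))
  u <- array(0, dim = n)
  u[ins] <- u_in
  list(u = u, mask = mask, lattice = lat)
}

# Assemble the blended lattice values: alpha * n_c + (1 - alpha) * (n_b + c u).
# Outside the lens the values reduce to the (constant) boundary value of the
# blend, so the interpolated log-gradient vanishes there and the surface jump
# is handled by Snell refraction alone.
blend_lattice <- function(n_c, c_grad, alpha, u, n_b = 1.333) {
  alpha * n_c + (1 - alpha) * (n_b + c_grad * u)
}

# Low-level dispatch to the C++ tracer.
trace_eye_rays <- function(eye, origins, dirs, lens, step = 5,
                           backward = FALSE) {
  g <- eye_geom_vector(eye)
  if (lens$type == "const") {
    out <- trace_rays_cpp(origins, dirs, g, 0L, lens$n, numeric(1),
                          numeric(3), 1, c(2L, 2L, 2L), step, backward)
  } else {
    lat <- lens$lattice
    out <- trace_rays_cpp(origins, dirs, g, 1L, 0, as.numeric(lens$values),
                          lat$origin, lat$h, as.integer(lat$dim), step,
                          backward)
  }
  out
}

#' Refract a ray at a spherical surface
#'
#' Analytic Snell refraction in the plane of incidence. The surface is a
#' sphere; the nearest intersection along the ray is used.
#'
#' @param position,direction ray origin and unit direction.
#' @param surface list with \code{center} (3-vector) and \code{radius}.
#' @param n1,n2 refractive indices before and after the surface.
#' @return list with \code{status} (\code{"refracted"}, \code{"absorbed"} for
#'   total internal reflection, or \code{"miss"}), and for refracted rays
#'   \code{position} (intersection) and \code{direction}.
#' @export
refract_at_surface <- function(position, direction, surface, n1, n2) {
  d <- unit3(direction)
  oc <- position - surface$center
  b <- sum(d * oc); cc <- sum(oc * oc) - surface$radius^2
  disc <- b^2 - cc
  if (disc < 0) return(list(status = "miss"))
  ts <- c(-b - sqrt(disc), -b + sqrt(disc))
  ts <- ts[ts > 1e-9]
  if (length(ts) == 0) return(list(status = "miss"))
  p <- position + ts[1] * d
  nrm <- unit3(p - surface$center)
  ci <- -sum(d * nrm)
  if (ci < 0) { nrm <- -nrm; ci <- -ci }
  eta <- n1 / n2
  st2 <- eta^2 * (1 - ci^2)
  if (st2 > 1) return(list(status = "absorbed", position = p))
  ct <- sqrt(1 - st2)
  list(status = "refracted", position = p,
       direction = unit3(eta * d + (eta * ci - ct) * nrm))
}

#' Propagate a ray through the GRIN lens lattice
#'
#' Explicit step-wise update: the position advances along the unit direction,
#' the direction is incremented by the trilinearly interpolated gradient of
#' log(n) and renormalized each step, until the ray leaves the lens body.
#'
#' @param eye \code{schematic_eye} with an optimized (or manually set) lens of
#'   type \code{"grin"}.
#' @param position starting point inside the lens (um).
#' @param direction initial unit direction.
#' @param step step length, um (> 0).
#' @param max_steps safety cap.
#' @return list with \code{path} (N x 3 matrix ending on the lens boundary),
#'   \code{direction} (exit direction before surface refraction) and
#'   \code{exit} (\code{"posterior"}, \code{"anterior"} or \code{"lost"}).
#' @export
propagate_grin <- function(eye, position, direction, step = 5,
                           max_steps = 6000) {
  if (step <= 0) stop("step must be positive")
  lens <- eye$lens
  if (is.null(lens) || lens$type != "grin") {
    stop("eye has no GRIN lens; run optimize_lens() or set one manually")
  }
  lat <- lens$lattice
  out <- grin_path_cpp(as.numeric(position), as.numeric(direction),
                       eye_geom_vector(eye), as.numeric(lens$values),
                       lat$origin, lat$h, as.integer(lat$dim), step,
                       as.integer(max_steps))
  list(path = out$path, direction = as.numeric(out$dir),
       exit = c("anterior", "lost", "posterior")[out$exit_code + 2])
}

#' Least-squares focal point of a ray bundle
#'
#' The point minimizing the summed squared distance to the ray lines
#' (closed form).
#'
#' @param points N x 3 matrix of ray origins.
#' @param dirs N x 3 matrix of ray directions.
#' @return list with \code{point}, \code{rms} (root-mean-square distance to
#'   the rays).
#' @export
focal_point <- function(points, dirs) {
  points <- as.matrix(points); dirs <- as.matrix(dirs)
  stopifnot(nrow(points) >= 2, all(dim(points) == dim(dirs)))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (i in seq_len(nrow(points))) {
    M <- diag(3) - tcrossprod(dirs[i, ])
    A <- A + M
    b <- b + as.numeric(M %*% points[i, ])
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9 * max(ev)) stop("no focus: rays are parallel")
  p <- as.numeric(solve(A, b))
  d2 <- vapply(seq_len(nrow(points)), function(i) {
    w <- p - points[i, ]
    sum(w^2) - sum(w * dirs[i, ])^2
  }, numeric(1))
  list(point = p, rms = sqrt(mean(pmax(d2, 0))))
}

# Seeded uniform sampling of ray aim points on the entrance disk (anterior
# cornea vertex plane); the pupil stop discards over-filled rays during the
# trace, matching "rays emitted" semantics.
entrance_aim_points <- function(eye, n_rays, overfill = 1.15) {
  r_max <- eye$pupil_radius * overfill
  u1 <- stats::runif(n_rays); u2 <- stats::runif(n_rays)
  rho <- r_max * sqrt(u1); tau <- 2 * pi * u2
  cbind(rho * cos(tau), rho * sin(tau), 0)
}

object_point <- function(distance_um = 1e5, off_axis_deg = 0) {
  a <- off_axis_deg * pi / 180
  c(distance_um * sin(a), 0, -distance_um * cos(a))
}

# Focus-versus-retina objective: trace a bundle, take the least-squares focal
# point of the surviving rays, return |distance(focus, retina center) - R_ret|
# (the focus-to-retinal-surface distance along the surface normal).
focus_objective <- function(eye, origins, dirs, lens, step = 5) {
  tr <- trace_eye_rays(eye, origins, dirs, lens, step = step)
  ok <- tr$status == 0L
  if (sum(ok) < max(10, 0.02 * nrow(origins))) return(1e6)
  fp <- focal_point(tr$exit_pos[ok, , drop = FALSE],
                    tr$exit_dir[ok, , drop = FALSE])
  g <- eye_geom_vector(eye)
  abs(sqrt(sum((fp$point - c(0, 0, g[["cz_ret"]]))^2)) - g[["R_ret"]])
}

#' Optimize the GRIN lens of the schematic eye
#'
#' Three stages, each focusing a bundle of rays emitted from an object 10 cm
#' away: (1) a constant lens index \code{n_c} is optimized so the on-axis
#' bundle focuses on the retina; (2) a gradient model \code{n_g = 1.333 + c u}
#' (with \code{u} the Poisson profile of \code{\link{grin_poisson_profile}})
#' is optimized over the gradient strength \code{c} for the same criterion;
#' (3) the final lens is the blend \code{alpha n_c + (1 - alpha) n_g} with
#' \code{alpha} optimized on a bundle from 10 cm away and 45 degrees off the
#' optical axis.
#'
#' @param eye \code{schematic_eye}.
#' @param n_rays rays per bundle (default 10000).
#' @param seed RNG seed for the entrance-disk sampling.
#' @param grin_step GRIN propagation step, um.
#' @return the eye with \code{lens} set (type \code{"grin"}, fields
#'   \code{values}, \code{lattice}, \code{n_c}, \code{c_grad}, \code{alpha})
#'   and a \code{report} entry: per-stage focus-to-retina distances (um),
#'   lens-body index extrema, and the stage parameters.
#' @export
optimize_lens <- function(eye, n_rays = 10000, seed = 1, grin_step = 5) {
  set.seed(seed)
  aims_on <- entrance_aim_points(eye, n_rays)
  aims_off <- entrance_aim_points(eye, n_rays)
  p_on <- object_point(1e5, 0)
  p_off <- object_point(1e5, 45)
  org_on <- matrix(p_on, n_rays, 3, byrow = TRUE)
  dir_on <- aims_on - org_on
  org_off <- matrix(p_off, n_rays, 3, byrow = TRUE)
  dir_off <- aims_off - org_off

  # stage 1: constant index
  f1 <- function(nc) focus_objective(eye, org_on, dir_on,
                                     list(type = "const", n = nc))
  o1 <- stats::optimize(f1, c(1.40, 1.90), tol = 1e-6)
  n_c <- o1$minimum

  # stage 2: gradient strength
  pois <- grin_poisson_profile(eye)
  u_max <- max(pois$u)
  grin_lens <- function(vals) list(type = "grin", values = vals,
                                   lattice = pois$lattice)
  f2 <- function(cg) focus_objective(eye, org_on, dir_on,
                                     grin_lens(blend_lattice(n_c, cg, 0, pois$u)),
                                     step = grin_step)
  c_max <- 0.267 / u_max
  o2 <- stats::optimize(f2, c(0, c_max), tol = 1e-4 * c_max)
  c_grad <- o2$minimum

  # stage 3: blend weight on the off-axis bundle
  f3 <- function(a) focus_objective(eye, org_off, dir_off,
                                    grin_lens(blend_lattice(n_c, c_grad, a, pois$u)),
                                    step = grin_step)
  o3 <- stats::optimize(f3, c(0, 1), tol = 1e-4)
  alpha <- o3$minimum

  vals <- blend_lattice(n_c, c_grad, alpha, pois$u)
  lens <- list(type = "grin", values = vals, lattice = pois$lattice,
               mask = pois$mask, u = pois$u, n_c = n_c, c_grad = c_grad,
               alpha = alpha, step = grin_step)
  eye$lens <- lens
  eye$report <- list(
    n_c = n_c, c_grad = c_grad, alpha = alpha,
    focus_dist_stage1 = o1$objective,
    focus_dist_stage2 = o2$objective,
    focus_dist_offaxis = o3$objective,
    focus_dist_onaxis_final = focus_objective(eye, org_on, dir_on,
                                              lens, step = grin_step),
    index_range = range(vals[pois$mask]))
  eye
}

#' Trace a deterministic meridional fan through the eye
#'
#' A fan of \code{n} rays from an object point, aimed at equally spaced points
#' across the pupil diameter in the meridional plane. Used for the
#' sensitivity scan.
#'
#' @param eye optimized \code{schematic_eye}.
#' @param off_axis_deg object direction off the optical axis (degrees).
#' @param n number of rays.
#' @param distance_um object distance.
#' @return list with per-ray \code{status}, \code{retina_pos} and
#'   \code{elevation} (radial retinal elevation, degrees: polar angle of the
#'   retinal hit about the optical axis, seen from the retinal sphere center).
#' @export
trace_fan <- function(eye, off_axis_deg = 45, n = 45, distance_um = 1e5) {
  if (is.null(eye$lens)) stop("eye has no lens; run optimize_lens() first")
  p0 <- object_point(distance_um, off_axis_deg)
  aims <- cbind(seq(-eye$pupil_radius, eye$pupil_radius, length.out = n), 0, 0)
  org <- matrix(p0, n, 3, byrow = TRUE)
  tr <- trace_eye_rays(eye, org, aims - org, eye$lens,
                       step = eye$lens$step %||% 5)
  g <- eye_geom_vector(eye)
  ct <- (tr$retina_pos[, 3] - g[["cz_ret"]]) / g[["R_ret"]]
  elev <- rad2deg(acos(pmax(-1, pmin(1, ct))))
  elev[tr$status != 0L] <- NA_real_
  list(status = tr$status, retina_pos = tr$retina_pos, elevation = elev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The nine geometric parameters scanned for sensitivity.
eye_scan_params <- function() {
  list(list(kind = "radius", name = "anterior_cornea"),
       list(kind = "radius", name = "posterior_cornea"),
       list(kind = "radius", name = "anterior_lens"),
       list(kind = "radius", name = "posterior_lens"),
       list(kind = "radius", name = "retina"),
       list(kind = "thickness", name = "cornea"),
       list(kind = "thickness", name = "anterior_chamber"),
       list(kind = "thickness", name = "lens"),
       list(kind = "thickness", name = "vitreous"))
}

perturb_eye <- function(eye, param, delta_um) {
  if (param$kind == "radius") {
    eye$radii[[param$name]] <- sign(eye$radii[[param$name]]) *
      (abs(eye$radii[[param$name]]) + delta_um)
  } else {
    eye$thicknesses[[param$name]] <- eye$thicknesses[[param$name]] + delta_um
  }
  eye$lens <- NULL
  eye$report <- NULL
  eye
}

#' Sensitivity of the retinal image to the eye-model geometry
#'
#' Perturbs each surface radius of curvature and each component thickness by
#' the given deltas, re-optimizes the lens for every perturbed geometry, traces
#' the deterministic 45-ray fan from the 10 cm, 45-degree off-axis object, and
#' reports the change in radial retinal elevation against the unperturbed
#' model.
#'
#' @param eye \code{schematic_eye} (lens state ignored; the baseline is
#'   re-optimized internally so all models share the optimization settings).
#' @param deltas_um perturbation magnitudes, um.
#' @param n_rays rays in the traced fan.
#' @param n_rays_opt rays per optimization bundle for the re-optimizations.
#' @param seed RNG seed shared by all optimizations.
#' @param grin_step GRIN step, um.
#' @return list with \code{table} (one row per parameter x delta: maximum
#'   per-ray deviation and bundle-centroid deviation, degrees) and
#'   \code{max_by_delta} (named vector: maximum per-ray deviation across
#'   parameters for each delta).
#' @export
sensitivity_scan <- function(eye, deltas_um = c(10, 50, 100), n_rays = 45,
                             n_rays_opt = 3000, seed = 1, grin_step = 5) {
  base <- optimize_lens(eye, n_rays = n_rays_opt, seed = seed,
                        grin_step = grin_step)
  fan0 <- trace_fan(base, n = n_rays)
  params <- eye_scan_params()
  rows <- list()
  for (pm in params) {
    for (d in deltas_um) {
      ep <- perturb_eye(eye, pm, d)
      dev <- tryCatch({
        opt <- optimize_lens(ep, n_rays = n_rays_opt, seed = seed,
                             grin_step = grin_step)
        fan <- trace_fan(opt, n = n_rays)
        keep <- !is.na(fan$elevation) & !is.na(fan0$elevation)
        c(max_dev = max(abs(fan$elevation[keep] - fan0$elevation[keep])),
          centroid_dev = abs(mean(fan$elevation[keep]) -
                               mean(fan0$elevation[keep])))
      }, error = function(e) c(max_dev = NA_real_, centroid_dev = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = pm$name, kind = pm$kind, delta_um = d,
        max_dev_deg = dev[["max_dev"]], centroid_dev_deg = dev[["centroid_dev"]])
    }
  }
  tab <- do.call(rbind, rows)
  mx <- vapply(deltas_um, function(d) {
    max(tab$max_dev_deg[tab$delta_um == d], na.rm = TRUE)
  }, numeric(1))
  names(mx) <- paste0("delta_", deltas_um, "um")
  list(table = tab, max_by_delta = mx, baseline = base)
}

#' Monte-Carlo projection of a retinal point to the cornea
#'
#' Back-traces rays emitted from a retinal point through the optics. Emission
#' polar angles follow a cosine-weighted (Lambertian) law about the local
#' inward surface normal; rays hitting any opaque surface (iris, lens
#' equator, sclera) are discarded, rays passing the anterior cornea are
#' accepted.
#'
#' @param eye optimized \code{schematic_eye}.
#' @param retinal_point 3-vector on the retinal surface (um) or a polar angle
#'   (degrees, scalar) interpreted as retinal eccentricity from the optical
#'   axis in the x-z meridian.
#' @param n_samples rays to emit.
#' @param seed RNG seed.
#' @param mode \code{"lambertian"} (pdf of polar angle proportional to
#'   cos(theta) sin(theta)) or \code{"plain-cosine"} (proportional to
#'   cos(theta)).
#' @return list with \code{mean_direction} (unit vector, world side, pointing
#'   from the eye toward the visual direction of the point),
#'   \code{angular_spread_deg}, \code{acceptance}, and the accepted
#'   \code{exit_dirs}.
#' @export
retina_to_cornea_mc <- function(eye, retinal_point, n_samples = 4000,
                                seed = 1, mode = c("lambertian", "plain-cosine")) {
  mode <- match.arg(mode)
  if (is.null(eye$lens)) stop("eye has no lens; run optimize_lens() first")
  g <- eye_geom_vector(eye)
  if (length(retinal_point) == 1) {
    a <- deg2rad(retinal_point)
    retinal_point <- c(0, 0, g[["cz_ret"]]) +
      g[["R_ret"]] * c(sin(a), 0, cos(a))
  }
  set.seed(seed)
  nrm <- unit3(c(0, 0, g[["cz_ret"]]) - retinal_point)  # inward normal
  e1 <- unit3(cross3(nrm, if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- cross3(nrm, e1)
  u <- stats::runif(n_samples)
  th <- if (mode == "lambertian") asin(sqrt(u)) else asin(u)
  ph <- 2 * pi * stats::runif(n_samples)
  dirs <- outer(cos(th), nrm) +
    outer(sin(th) * cos(ph), e1) + outer(sin(th) * sin(ph), e2)
  org <- matrix(retinal_point, n_samples, 3, byrow = TRUE)
  tr <- trace_eye_rays(eye, org, dirs, eye$lens, step = eye$lens$step %||% 5,
                       backward = TRUE)
  ok <- tr$status == 0L
  if (!any(ok)) stop("no path: no emitted ray passed the anterior cornea")
  ex <- tr$exit_dir[ok, , drop = FALSE]
  m <- colMeans(ex)
  md <- unit3(m)
  ang <- rad2deg(acos(pmax(-1, pmin(1, ex %*% md))))
  list(mean_direction = md, angular_spread_deg = mean(ang),
       acceptance = mean(ok), exit_dirs = ex,
       sampled_theta = th)
}

# Corneal coordinates of a visual direction (unit vector, z < 0 hemisphere):
# radial angle off the optical axis and rotational angle about it.
direction_to_corneal <- function(d) {
  d <- unit3(d)
  c(radial = rad2deg(acos(max(-1, min(1, -d[3])))),
    rotation = rad2deg(atan2(d[2], d[1])))
}

#' Project retinal contours through the eye model to the cornea
#'
#' Flat-mount contour vertices (arc-length coordinates about the optic-disc
#' center, um) are placed on the retinal sphere with the optic-disc center at
#' the intersection of the optical axis and the retina (azimuthal-equidistant
#' unfolding), then each vertex is back-projected through the optics by
#' \code{\link{retina_to_cornea_mc}}; the corneal location is the mean exit
#' direction. The eye model is rotationally symmetric, so no further
#' alignment is applied.
#'
#' @param eye optimized \code{schematic_eye}.
#' @param contours list of N x 2 matrices (flat-mount x, y in um of arc
#'   length from the optic-disc center; the optic disc is the origin).
#' @param n_samples rays per vertex.
#' @param seed RNG seed.
#' @return list of data frames with columns \code{radial}, \code{rotation}
#'   (degrees, corneal coordinates), \code{flagged} (no accepted rays;
#'   interpolated across up to 2 consecutive flags).
#' @export
project_retinal_contours <- function(eye, contours, n_samples = 800, seed = 1) {
  g <- eye_geom_vector(eye)
  cret <- c(0, 0, g[["cz_ret"]])
  lapply(contours, function(poly) {
    poly <- as.matrix(poly)
    n <- nrow(poly)
    out <- matrix(NA_real_, n, 2)
    flagged <- logical(n)
    for (i in seq_len(n)) {
      rho <- sqrt(sum(poly[i, ]^2))
      gam <- rho / g[["R_ret"]]
      tau <- atan2(poly[i, 2], poly[i, 1])
      pt <- cret + g[["R_ret"]] *
        c(sin(gam) * cos(tau), sin(gam) * sin(tau), cos(gam))
      res <- tryCatch(retina_to_cornea_mc(eye, pt, n_samples = n_samples,
                                          seed = seed + i),
                      error = function(e) NULL)
      if (is.null(res)) { flagged[i] <- TRUE; next }
      out[i, ] <- direction_to_corneal(res$mean_direction)
    }
    # interpolate across short runs of flagged vertices
    if (any(flagged) && any(!flagged)) {
      r <- rle(flagged)
      pos <- cumsum(c(1, r$lengths))
      for (k in seq_along(r$values)) {
        if (!r$values[k] || r$lengths[k] > 2) next
        i0 <- pos[k] - 1; i1 <- pos[k] + r$lengths[k]
        if (i0 < 1 || i1 > n) next
        for (j in seq(pos[k], pos[k] + r$lengths[k] - 1)) {
          w <- (j - i0) / (i1 - i0)
          out[j, ] <- (1 - w) * out[i0, ] + w * out[i1, ]
        }
      }
    }
    data.frame(radial = out[, 1], rotation = out[, 2], flagged = flagged)
  })
}
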