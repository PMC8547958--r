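# The optimized eye is built once and reused across blocks (the optimization
# itself is exercised again, at full scale, by the acceptance suite).
eye0 <- schematic_eye()
opt_eye <- optimize_lens(eye0, n_rays = 2000, seed = 1)

test_that("Snell refraction handles oblique incidence and total internal reflection", {
  flat <- list(center = c(0, 0, 1e9), radius = 1e9)  # quasi-planar surface
  # normal incidence: direction unchanged
  r0 <- refract_at_surface(c(0, 0, -10), c(0, 0, 1), flat, 1.0, 1.5)
  expect_equal(r0$direction, c(0, 0, 1), tolerance = 1e-6)

  # 30 degrees into n = 1.5 bends to 19.47 degrees
  d <- c(sin(pi / 6), 0, cos(pi / 6))
  r1 <- refract_at_surface(c(0, 0, -10), d, flat, 1.0, 1.5)
  ang <- asin(r1$direction[1]) * 180 / pi
  expect_equal(ang, asin(0.5 / 1.5) * 180 / pi, tolerance = 1e-4)

  # 60 degrees from glass to air exceeds the 41.8-degree critical angle
  d2 <- c(sin(pi / 3), 0, cos(pi / 3))
  r2 <- refract_at_surface(c(0, 0, -10), d2, flat, 1.5, 1.0)
  expect_equal(r2$status, "absorbed")

  # a ray that misses the sphere reports a miss
  r3 <- refract_at_surface(c(10, 0, 0), c(0, 0, -1),
                           list(center = c(0, 0, 0), radius = 1), 1, 1.5)
  expect_equal(r3$status, "miss")
})

test_that("least-squares focal point matches crossing rays and a grid oracle", {
  # two rays crossing at a point recover it exactly
  P <- c(1, 2, 3)
  d1 <- c(1, 0, 0); d2 <- c(0, 1, 0)
  fp <- focal_point(rbind(P - 5 * d1, P - 7 * d2), rbind(d1, d2))
  expect_equal(fp$point, P, tolerance = 1e-9)
  expect_lt(fp$rms, 1e-9)

  # three skew rays versus brute-force grid minimization
  set.seed(101)
  pts <- matrix(rnorm(9), 3, 3)
  dirs <- matrix(rnorm(9), 3, 3)
  fp2 <- focal_point(pts, dirs)
  dist2 <- function(q) {
    sum(vapply(1:3, function(i) {
      d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
      w <- q - pts[i, ]
      sum(w^2) - sum(w * d)^2
    }, numeric(1)))
  }
  g <- seq(-0.5, 0.5, length.out = 21)
  best <- Inf
  for (dx in g) for (dy in g) for (dz in g) {
    v <- dist2(fp2$point + c(dx, dy, dz))
    best <- min(best, v)
  }
  expect_lte(dist2(fp2$point), best + 1e-9)

  expect_error(focal_point(rbind(c(0, 0, 0), c(1, 0, 0)),
                           rbind(c(0, 0, 1), c(0, 0, 1))), "parallel")
})

test_that("GRIN propagation is straight in homogeneous media and converges with step size", {
  # homogeneous lattice: exit direction equals entry direction
  eye_h <- eye0
  pois <- grin_poisson_profile(eye_h)
  eye_h$lens <- list(type = "grin",
                     values = array(1.5, dim = pois$lattice$dim),
                     lattice = pois$lattice, step = 5)
  p0 <- c(50, -30, 800); d0 <- c(0.05, 0.02, 1) / sqrt(1 + 0.05^2 + 0.02^2)
  tr <- propagate_grin(eye_h, p0, d0, step = 5)
  expect_equal(tr$direction, d0, tolerance = 1e-9)
  expect_equal(tr$exit, "posterior")
  # straightness: all path points on the entry line
  path <- tr$path
  rel <- sweep(path, 2, p0)
  t_along <- rel %*% d0
  expect_lt(max(abs(rel - t_along %*% t(d0))), 1e-6)

  # 1-D linear index gradient bends toward higher n; a 50x finer step agrees
  lat <- pois$lattice
  gx <- (lat$x - lat$x[1]) / (lat$x[40] - lat$x[1])
  vals <- array(rep(1.40 + 0.1 * gx, times = 40 * 40), dim = lat$dim)
  eye_g <- eye_h
  eye_g$lens$values <- vals
  a <- propagate_grin(eye_g, c(0, 0, 500), c(0, 0, 1), step = 2.5,
                      max_steps = 2e4)
  b <- propagate_grin(eye_g, c(0, 0, 500), c(0, 0, 1), step = 0.025,
                      max_steps = 2e5)
  expect_gt(a$direction[1], 0)    # bends toward +x (higher n)
  expect_lt(sqrt(sum((a$path[nrow(a$path), ] - b$path[nrow(b$path), ])^2)), 0.1)

  # time reversal: the reversed exit ray passes back through the entry point
  fw <- propagate_grin(eye_g, c(0, 0, 500), c(0, 0, 1), step = 0.5,
                       max_steps = 1e5)
  exit_p <- fw$path[nrow(fw$path), ]
  back <- propagate_grin(eye_g, exit_p, -fw$direction, step = 0.5,
                         max_steps = 1e5)
  d_entry <- sqrt(rowSums(sweep(back$path, 2, c(0, 0, 500))^2))
  expect_lt(min(d_entry), 1)

  expect_error(propagate_grin(eye_g, c(0, 0, 500), c(0, 0, 1), step = -1),
               "positive")
})

test_that("lens optimization focuses on the retina and blends the two models", {
  rep0 <- opt_eye$report
  # the optimized on-axis bundle focuses on the retinal surface
  expect_lt(rep0$focus_dist_stage1, 5)
  expect_lt(rep0$focus_dist_stage2, 5)
  # blend endpoints reproduce the pure models exactly
  u <- opt_eye$lens$u
  expect_equal(mousegaze:::blend_lattice(rep0$n_c, rep0$c_grad, 1, u),
               array(rep0$n_c, dim = dim(u)), tolerance = 1e-12)
  expect_equal(mousegaze:::blend_lattice(rep0$n_c, rep0$c_grad, 0, u),
               1.333 + rep0$c_grad * u, tolerance = 1e-12)
  # homogeneous-lens equivalent index for the mouse eye sits near 1.7
  expect_gt(rep0$n_c, 1.6)
  expect_lt(rep0$n_c, 1.8)
  # lattice index extrema stay inside the physical range
  expect_gt(rep0$index_range[1], 1.30)
  expect_lt(rep0$index_range[2], 1.60)
})

test_that("traced rays keep unit direction and converge under step halving", {
  g <- mousegaze:::eye_geom_vector(eye0)
  set.seed(111)
  aims <- mousegaze:::entrance_aim_points(eye0, 200)
  org <- matrix(mousegaze:::object_point(1e5, 20), 200, 3, byrow = TRUE)
  tr5 <- mousegaze:::trace_eye_rays(eye0, org, aims - org, opt_eye$lens, step = 5)
  ok <- tr5$status == 0
  norms <- sqrt(rowSums(tr5$exit_dir[ok, ]^2))
  expect_lt(max(abs(norms - 1)), 1e-9)

  # halving the step moves exit directions by < 0.01 deg on average (the
  # scheme is first-order; pupil-margin rays through the steepest gradient
  # stay below 0.05 deg)
  tr25 <- mousegaze:::trace_eye_rays(eye0, org, aims - org, opt_eye$lens, step = 2.5)
  both <- ok & tr25$status == 0
  dots <- rowSums(tr5$exit_dir[both, ] * tr25$exit_dir[both, ])
  ang <- acos(pmin(1, dots)) * 180 / pi
  expect_lt(mean(ang), 0.01)
  expect_lt(max(ang), 0.05)
})

test_that("retina-to-cornea back-projection is symmetric, cosine-sampled and pupil-limited", {
  mc <- retina_to_cornea_mc(opt_eye, 0, n_samples = 4000, seed = 7)
  # axial retinal point exits along the optical axis
  ang_axis <- acos(min(1, -mc$mean_direction[3])) * 180 / pi
  expect_lt(ang_axis, 0.5)
  expect_gt(mc$acceptance, 0)

  # sampled emission angles follow the Lambertian law: CDF(theta) = sin^2
  th <- sort(mc$sampled_theta)
  emp <- seq_along(th) / length(th)
  expect_lt(max(abs(emp - sin(th)^2)), 0.03)

  # shrinking the pupil cuts the acceptance fraction
  eye_small <- eye0
  eye_small$pupil_radius <- 300
  eye_small$lens <- opt_eye$lens
  mc_small <- retina_to_cornea_mc(eye_small, 0, n_samples = 4000, seed = 7)
  expect_lt(mc_small$acceptance, mc$acceptance)

  # forward trace along the mean visual direction returns near the source
  # retinal point (round-trip consistency)
  pt_ret <- 20   # degrees eccentric
  mc2 <- retina_to_cornea_mc(opt_eye, pt_ret, n_samples = 4000, seed = 8)
  g <- mousegaze:::eye_geom_vector(eye0)
  src <- c(0, 0, g[["cz_ret"]]) + g[["R_ret"]] *
    c(sin(pt_ret * pi / 180), 0, cos(pt_ret * pi / 180))
  d_in <- -mc2$mean_direction          # incoming light direction
  org <- matrix(src - 2e5 * d_in + c(0, 0, 0), 1, 3)
  fwd <- mousegaze:::trace_eye_rays(eye0, org, matrix(d_in, 1, 3), opt_eye$lens)
  expect_identical(fwd$status[1], 0L)
  expect_lt(sqrt(sum((fwd$retina_pos[1, ] - src)^2)), 25)
})

test_that("retinal contours project with preserved nesting and centered optic disc", {
  # the optic-disc center maps to the optical axis
  disc <- project_retinal_contours(opt_eye, list(matrix(0, 1, 2)),
                                   n_samples = 1500, seed = 9)
  expect_lt(disc[[1]]$radial[1], 0.5)

  # a circle of equal-eccentricity points maps to near-equal corneal radius
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  circ <- cbind(400 * cos(th), 400 * sin(th))
  pc <- project_retinal_contours(opt_eye, list(circ), n_samples = 1500, seed = 9)
  expect_lt(diff(range(pc[[1]]$radial)), 1)

  # nested retinal circles stay nested on the cornea
  rads <- c(150, 350, 550, 750)
  nested <- project_retinal_contours(
    opt_eye, lapply(rads, function(r) matrix(c(r, 0), 1, 2)),
    n_samples = 1500, seed = 10)
  corneal <- vapply(nested, function(d) d$radial[1], numeric(1))
  expect_true(all(diff(corneal) > 0))
})
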