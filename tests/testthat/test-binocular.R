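mk_series <- function(rots, label = "left_eye") {
  rotation_series(seq_along(rots), array(unlist(rots), c(3, 3, length(rots))),
                  label)
}

test_that("cross-eye projection follows the zero-baseline sphere geometry", {
  set.seed(131)
  Rl <- replicate(6, random_rotation(), simplify = FALSE)
  # identical orientations: the projected direction is u itself
  l <- mk_series(Rl); r <- mk_series(Rl, "right_eye")
  u <- c(0.3, -0.2, -0.9) / sqrt(sum(c(0.3, -0.2, -0.9)^2))
  p <- project_across_eyes(u, r, l)
  expect_lt(max(abs(sweep(p, 2, u))), 1e-12)

  # a fixed inter-eye rotation gives a constant (but shifted) projection
  delta <- rotation_about_axis(c(1, 2, 0), 17)
  r2 <- mk_series(lapply(Rl, function(R) R %*% delta), "right_eye")
  p2 <- project_across_eyes(u, r2, l)
  expect_lt(max(dist(p2)), 1e-12)
  expect_gt(vec_angle(p2[1, ], u), 1)

  # u on the inter-eye rotation axis is a fixed point
  ax <- c(1, 2, 0) / sqrt(5)
  p3 <- project_across_eyes(ax, r2, l)
  expect_lt(max(abs(sweep(p3, 2, ax))), 1e-9)
})

test_that("the alignment statistic is the mean chord angle to the normalized mean", {
  u <- c(0, 0, -1)
  # all equal: zero
  expect_equal(alignment_statistic(matrix(u, 5, 3, byrow = TRUE))$mean_deg, 0,
               tolerance = 1e-12)

  # alternating +/- delta about a mean direction: statistic = delta exactly
  delta <- 7
  pp <- rbind(as.numeric(rotation_about_axis(c(1, 0, 0), delta) %*% u),
              as.numeric(rotation_about_axis(c(1, 0, 0), -delta) %*% u))
  p <- pp[rep(1:2, 10), ]
  expect_equal(alignment_statistic(p)$mean_deg, delta, tolerance = 1e-9)

  # invariant under a global rotation of all directions
  G <- random_rotation()
  expect_equal(alignment_statistic(p %*% t(G))$mean_deg, delta,
               tolerance = 1e-9)

  # concentrated random sample: statistic equals the directly computed mean
  # angle to the mean direction
  set.seed(141)
  w <- matrix(rnorm(3 * 500, sd = 0.03), 500, 3)
  p4 <- t(vapply(seq_len(500), function(i) {
    as.numeric(rotation_exp(57.29578 * w[i, ]) %*% u)
  }, numeric(3)))
  st <- alignment_statistic(p4)
  m <- colMeans(p4); m <- m / sqrt(sum(m^2))
  direct <- mean(acos(pmin(1, p4 %*% m)) * 180 / pi)
  expect_equal(st$mean_deg, direct, tolerance = 0.02)

  expect_error(alignment_statistic(rbind(u, -u)), "antipodal")
})

test_that("static binocular overlap equals the analytic spherical lune", {
  g <- spherical_grid(201)
  mk1 <- function(az, lab) {
    rotation_series(0, array(mousegaze:::eye_reference_orientation(az, 0, 0),
                             c(3, 3, 1)), lab)
  }
  # both eyes share an axis: the full shared hemisphere overlaps
  same <- overlap_probability_map(mk1(0, "left_eye"), mk1(0, "right_eye"), g)
  gg <- mousegaze:::grid_geometry(g)
  inner <- matrix(gg$radial_deg < 89, 201, 201)
  expect_true(all(same[inner] == 1, na.rm = TRUE))
  expect_true(all(same >= 0 & same <= 1, na.rm = TRUE))

  # axes 60 degrees apart: lune fraction (pi - delta)/pi = 2/3 of one field
  l <- mk1(30, "left_eye"); r <- mk1(-30, "right_eye")
  om <- overlap_probability_map(l, r, g)
  w <- grid_solid_angle(g)
  frac <- sum(w[om > 0.5], na.rm = TRUE) / sum(w[!is.na(om)], na.rm = TRUE)
  expect_equal(frac, 2 / 3, tolerance = 0.01)

  # antipodal axes leave only the boundary great circle (measure zero)
  anti <- overlap_probability_map(mk1(90, "left_eye"), mk1(-90, "right_eye"), g)
  frac0 <- sum(w[anti > 0.5], na.rm = TRUE) / sum(w[!is.na(anti)], na.rm = TRUE)
  expect_lt(frac0, 0.02)
})

test_that("freezing eye-rotation components is definitional and idempotent", {
  # constant series: freezing changes nothing
  R0 <- compose_eye_rotation(4, -7, 3)$rotation
  cst <- rotation_series(1:5, array(rep(R0, 5), c(3, 3, 5)), "left_eye")
  fz <- freeze_eye_rotations(cst, "all")
  expect_equal(fz$rotations, cst$rotations, tolerance = 1e-9)

  # freeze torsion: phi and theta kept, psi replaced by its mean
  set.seed(151)
  ang <- cbind(phi = runif(8, -10, 10), theta = runif(8, -10, 10),
               psi = runif(8, -10, 10))
  rots <- array(vapply(1:8, function(i) {
    compose_eye_rotation(ang[i, 1], ang[i, 2], ang[i, 3])$rotation
  }, numeric(9)), c(3, 3, 8))
  ser <- rotation_series(1:8, rots, "left_eye")
  fz2 <- freeze_eye_rotations(ser, "torsion", reference = diag(3))
  dec <- t(vapply(1:8, function(i) decompose_eye_rotation(fz2$rotations[, , i]),
                  numeric(3)))
  expect_equal(dec[, "phi"], ang[, "phi"], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(dec[, "theta"], ang[, "theta"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(dec[, "psi"], rep(mean(ang[, "psi"]), 8), tolerance = 1e-9,
               ignore_attr = TRUE)

  # idempotence
  fz3 <- freeze_eye_rotations(fz2, "torsion", reference = diag(3))
  expect_equal(fz3$rotations, fz2$rotations, tolerance = 1e-9)
})

test_that("compensation gain recovers programmed gains and detects their absence", {
  for (g in c(-1, -0.5, 0)) {
    sim <- simulate_vor_head_eye(simulation_config(seed = 17, gain_pitch = g,
                                                   gain_roll = -0.4,
                                                   duration_s = 8))
    eye_rs <- resample_rotation_series(sim$left, sim$head$timestamps)
    fit <- compensation_gain(sim$head, eye_rs, axis = "X")
    expect_equal(fit$slope, g, tolerance = 0.02)
  }
  # 2-degree angular noise widens the tolerance to 0.05
  simn <- simulate_vor_head_eye(simulation_config(seed = 18, gain_pitch = -0.5,
                                                  angle_noise_deg = 2,
                                                  duration_s = 8))
  eye_n <- resample_rotation_series(simn$left, simn$head$timestamps)
  fitn <- compensation_gain(simn$head, eye_n, axis = "X")
  expect_equal(fitn$slope, -0.5, tolerance = 0.05)

  # eye uncorrelated with head: slope within 3 standard errors of zero
  set.seed(161)
  nh <- length(simn$head)
  rnd <- array(vapply(seq_len(nh), function(i) {
    rotation_exp(rnorm(3, sd = 4))
  }, numeric(9)), c(3, 3, nh))
  fit0 <- compensation_gain(simn$head,
                            rotation_series(simn$head$timestamps, rnd, "left_eye"),
                            axis = "X")
  expect_lt(abs(fit0$slope), 3 * fit0$slope_se)

  # the binned summary curve brackets the fitted line
  expect_true(all(diff(fitn$curve$center) > 0))

  expect_error(compensation_gain(
    rotation_series(1:5, array(rep(diag(3), 5), c(3, 3, 5))),
    rotation_series(1:5, array(rep(diag(3), 5), c(3, 3, 5)), "left_eye")),
    "insufficient")
})

test_that("freezing the compensating axis reduces the gain magnitude", {
  sim <- simulate_vor_head_eye(simulation_config(seed = 19, duration_s = 8))
  eye_rs <- resample_rotation_series(sim$left, sim$head$timestamps)
  ctrl_x <- compensation_gain(sim$head, eye_rs, axis = "X")$slope
  ctrl_y <- compensation_gain(sim$head, eye_rs, axis = "Y")$slope
  fz_t <- compensation_gain(sim$head, freeze_eye_rotations(eye_rs, "torsion"),
                            axis = "X")$slope
  fz_v <- compensation_gain(sim$head, freeze_eye_rotations(eye_rs, "vertical"),
                            axis = "Y")$slope
  expect_lt(abs(fz_t), abs(ctrl_x))   # pitch compensation carried by torsion
  expect_lt(abs(fz_v), abs(ctrl_y))   # roll compensation carried by vertical
})
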