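test_that("head frame follows the anatomical construction and the 40-degree tilt", {
  lm <- anatomical_landmarks(c(-1, 0, 0), c(1, 0, 0), c(-0.1, 2, 0), c(0.1, 2, 0))
  hf <- build_head_frame(lm)
  expect_equal(hf$forward, c(0, cos(40 * pi / 180), sin(40 * pi / 180)),
               tolerance = 1e-9)
  expect_equal(abs(hf$left), c(1, 0, 0), tolerance = 1e-9)
  expect_so3(hf$rotation)

  # zero tilt leaves forward in the eyes-nose plane
  hf0 <- build_head_frame(lm, tilt_deg = 0)
  plane_normal <- c(0, 0, 1)
  expect_lt(abs(sum(hf0$forward * plane_normal)), 1e-9)

  # degenerate landmarks are rejected
  expect_error(anatomical_landmarks(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0.1, 1, 0)),
               "coincide")
  expect_error(build_head_frame(
    anatomical_landmarks(c(-1, 0, 0), c(1, 0, 0), c(-0.05, 0, 0), c(0.05, 0, 0))),
    "invalid geometry")
})

test_that("head frame is equivariant under global rigid motion", {
  set.seed(11)
  base <- list(lc = c(-1, 0.1, 0.2), rc = c(1, 0, 0.1),
               ln = c(-0.1, 2, 0.3), rn = c(0.1, 2.1, 0.2))
  hf <- build_head_frame(do.call(anatomical_landmarks, unname(base)))
  for (k in 1:20) {
    R <- random_rotation(); tr <- rnorm(3)
    mv <- lapply(base, function(p) as.numeric(R %*% p) + tr)
    hf2 <- build_head_frame(do.call(anatomical_landmarks, unname(mv)))
    expect_equal(hf2$forward, as.numeric(R %*% hf$forward), tolerance = 1e-9)
    expect_equal(hf2$up, as.numeric(R %*% hf$up), tolerance = 1e-9)
  }
})

test_that("eye rotation composition matches the printed matrix product", {
  id <- compose_eye_rotation(0, 0, 0)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$gaze, c(0, 0, -1), tolerance = 1e-12)

  # pure torsion spins about the gaze: gaze unchanged
  for (psi in c(-120, 13, 45, 180)) {
    expect_equal(compose_eye_rotation(0, 0, psi)$gaze, c(0, 0, -1),
                 tolerance = 1e-12)
  }
  # horizontal 90 degrees: row 1 of R_theta is (cos, 0, -sin), so the gaze
  # lands on +x
  expect_equal(compose_eye_rotation(0, 90, 0)$gaze, c(1, 0, 0),
               tolerance = 1e-12)

  set.seed(21)
  for (k in 1:25) {
    ang <- runif(3, -80, 80)
    er <- compose_eye_rotation(ang[1], ang[2], ang[3])
    expect_so3(er$rotation)
    expect_equal(unname(decompose_eye_rotation(er$rotation)), ang,
                 tolerance = 1e-9)
  }
})

test_that("geodesic interpolation keeps the gaze on the great circle with proportional angle", {
  R1 <- diag(3); R2 <- rotation_about_axis(c(1, 0, 0), 90)
  expect_equal(interpolate_rotation(R1, R2, 0.5),
               rotation_about_axis(c(1, 0, 0), 45), tolerance = 1e-12)
  expect_equal(interpolate_rotation(R1, R2, 1e-12), R1, tolerance = 1e-9)
  expect_equal(interpolate_rotation(R1, R2, 1 - 1e-12), R2, tolerance = 1e-9)

  set.seed(31)
  u <- c(0, 0, -1)
  for (k in 1:100) {
    A <- random_rotation(); B <- random_rotation()
    v1 <- A %*% u; v2 <- B %*% u
    full <- vec_angle(v1, v2)
    if (full > 179) next
    s <- runif(1, 0.05, 0.95)
    Rs <- interpolate_rotation(A, B, s)
    expect_so3(Rs)
    expect_lt(abs(vec_angle(Rs %*% u, v1) - s * full), 1e-9)
  }

  # composing partial interpolants equals the direct midpoint
  A <- random_rotation(); B <- random_rotation()
  q <- interpolate_rotation(A, B, 0.25)
  half <- interpolate_rotation(q, B, 1 / 3)
  expect_equal(half, interpolate_rotation(A, B, 0.5), tolerance = 1e-9)

  expect_error(interpolate_rotation(diag(3), rotation_about_axis(c(1, 0, 0), 180), 0.5),
               "antipodal")
})

test_that("rigid registration recovers exact and noisy transforms", {
  set.seed(41)
  src <- matrix(rnorm(30), 10, 3)
  expect_equal(register_point_sets(src, src)$rotation, diag(3), tolerance = 1e-12)

  R <- random_rotation(); tr <- rnorm(3)
  dst <- src %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)
  reg <- register_point_sets(src, dst)
  expect_lt(max(abs(reg$rotation - R)), 1e-9)
  expect_lt(max(abs(reg$translation - tr)), 1e-9)
  expect_lt(reg$rms, 1e-9)

  # Monte Carlo: per-axis mean absolute residual of sigma-noise registration
  # approaches sigma * sqrt(2/pi)
  sigma <- 1e-3
  acc <- replicate(300, {
    noisy <- dst + matrix(rnorm(30, 0, sigma), 10, 3)
    mean(register_point_sets(src, noisy)$mean_abs_axis)
  })
  expect_equal(mean(acc), sigma * sqrt(2 / pi), tolerance = 0.05)

  expect_error(register_point_sets(src[1:2, ], dst[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(register_point_sets(line, line %*% t(R)), "collinear")
})

test_that("registration matches a brute-force Procrustes oracle on small instances", {
  set.seed(51)
  for (k in 1:4) {
    n <- sample(4:6, 1)
    src <- matrix(rnorm(3 * n), n, 3)
    dst <- src %*% t(random_rotation()) +
      matrix(rnorm(3), n, 3, byrow = TRUE) + matrix(rnorm(3 * n, 0, 0.1), n, 3)
    reg <- register_point_sets(src, dst)
    sse <- sum(reg$residuals^2)
    expect_lte(sse, procrustes_sse_oracle(src, dst) + 1e-8)
  }
})

test_that("horizon alignment zeroes mean pitch and roll, preserves amplitude and yaw", {
  n <- 80
  t <- (1:n) / 50
  mk <- function(yaw, pitch, roll) {
    rotation_series(t, array(vapply(seq_len(n), function(i) {
      head_from_euler(yaw[i], pitch[i], roll[i])
    }, numeric(9)), c(3, 3, n)), "head")
  }
  # constant offsets vanish
  cs <- mk(rep(5, n), rep(10, n), rep(-5, n))
  out <- horizon_align(cs)
  ang <- t(vapply(seq_len(n), function(i) head_euler(out$rotations[, , i]),
                  numeric(3)))
  expect_lt(max(abs(ang[, "pitch"])), 1e-9)
  expect_lt(max(abs(ang[, "roll"])), 1e-9)
  expect_equal(ang[, "yaw"], rep(5, n), tolerance = 1e-9, ignore_attr = TRUE)

  # sinusoidal pitch: mean removed, amplitude preserved
  pitch <- 7 + 4 * sin(2 * pi * t)
  sine <- mk(10 * sin(t), pitch, rep(0, n))
  out2 <- horizon_align(sine)
  ang2 <- t(vapply(seq_len(n), function(i) head_euler(out2$rotations[, , i]),
                   numeric(3)))
  expect_lt(abs(mean(ang2[, "pitch"])), 1e-7)
  expect_equal(diff(range(ang2[, "pitch"])), diff(range(pitch)), tolerance = 1e-7)

  # idempotent on an already aligned series
  out3 <- horizon_align(out2)
  expect_equal(out3$rotations, out2$rotations, tolerance = 1e-9)
})

test_that("differential rotations are deviations from the chordal mean", {
  t <- 1:10
  cst <- rotation_series(t, array(rep(rotation_about_axis(c(1, 1, 0), 30), 10),
                                  c(3, 3, 10)))
  d <- differential_rotations(cst)
  for (i in 1:10) expect_equal(d$deltas[, , i], diag(3), tolerance = 1e-9)

  pair <- rotation_series(1:2, array(c(rotation_about_axis(c(1, 0, 0), 10),
                                       rotation_about_axis(c(1, 0, 0), -10)),
                                     c(3, 3, 2)))
  dp <- differential_rotations(pair)
  expect_equal(dp$mean, diag(3), tolerance = 1e-9)
  expect_equal(dp$deltas[, , 1], rotation_about_axis(c(1, 0, 0), 10),
               tolerance = 1e-9)

  # chordal mean agrees with a brute-force Frobenius minimizer
  set.seed(61)
  R0 <- random_rotation()
  rots <- array(0, c(3, 3, 40))
  for (i in 1:40) rots[, , i] <- rotation_exp(rnorm(3, sd = 15)) %*% R0
  M <- chordal_mean(rots)
  M_oracle <- chordal_mean_oracle(rots)
  expect_lt(max(abs(M - M_oracle)), 1e-5)
})
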