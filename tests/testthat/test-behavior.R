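test_that("Gaussian smoothing preserves constants, mass and the variance formula", {
  dt <- 1 / 200
  expect_equal(smooth_series(rep(4.2, 100), dt), rep(4.2, 100), tolerance = 1e-12)

  # impulse response: the (renormalized) kernel, summing to 1
  imp <- c(rep(0, 50), 1, rep(0, 50))
  resp <- smooth_series(imp, dt)
  expect_equal(sum(resp), 1, tolerance = 1e-9)
  expect_equal(which.max(resp), 51L)

  # white-noise variance shrinks by the kernel sum of squares
  half <- floor((0.05 / dt) / 2)
  w <- exp(-((-half):half)^2 / (2 * (half / 2)^2)); w <- w / sum(w)
  set.seed(171)
  x <- rnorm(1e5)
  v_ratio <- var(smooth_series(x, dt)) / var(x)
  expect_equal(v_ratio, sum(w^2), tolerance = 0.05)

  expect_warning(smooth_series(1:5, dt = 1), "unchanged")
})

test_that("target bearing is the signed horizontal-plane angle", {
  hf <- list(origin = c(0, 0, 0), forward = c(0, 1, 0), left = c(-1, 0, 0))
  expect_equal(target_bearing(hf, c(0, 2, 0.5)), 0, tolerance = 1e-9)
  expect_equal(abs(target_bearing(hf, c(0, -3, 0))), 180, tolerance = 1e-9)
  # a cricket to the animal's left is positive
  expect_equal(target_bearing(hf, c(-2, 0, 0)), 90, tolerance = 1e-9)
  expect_error(target_bearing(hf, c(0, 0, 1)), "directly above")
})

test_that("epoch classification recovers scripted boundaries, escapes and exclusions", {
  dt <- 1 / 200
  for (seed in c(3, 4)) {
    for (esc in c(FALSE, TRUE)) {
      sim <- simulate_pursuit(simulation_config(seed = seed), with_escape = esc)
      seg <- classify_epochs(sim$trajectory, sim$manual_capture_end)
      tru <- sim$truth
      ep <- seg$epochs
      g <- function(kind, col) ep[[col]][ep$kind == kind][1]
      expect_equal(g("detect", "t_end"), tru$detect_t_end, tolerance = dt + 1e-9)
      expect_equal(g("detect", "t_start"), tru$detect_t_start,
                   tolerance = dt + 1e-9)
      expect_equal(g("track", "t_start"), tru$track_t_start,
                   tolerance = dt + 1e-9)
      expect_equal(g("track", "t_end"), tru$track_t_end, tolerance = dt + 1e-9)
      expect_identical(nrow(seg$escapes), tru$n_escapes)
      if (esc) {
        expect_equal(seg$escapes$t_escape[1], tru$t_escape, tolerance = dt + 1e-9)
        expect_equal(g("capture", "t_start"), tru$capture_t_start,
                     tolerance = dt + 1e-9)
      }
      # whisker-zone mask flags only close frames
      d <- sqrt(rowSums((sim$trajectory$mouse - sim$trajectory$cricket)^2))
      expect_identical(seg$close_mask, d <= 0.03)
    }
  }

  # the 20 cm initial-distance inclusion rule
  shortr <- simulate_pursuit(simulation_config(seed = 5),
                             initial_distance_m = 0.15)
  seg_s <- classify_epochs(shortr$trajectory, shortr$manual_capture_end)
  expect_true(seg_s$epochs$excluded[seg_s$epochs$kind == "track"])
})

test_that("classification is invariant to time shifts and arena rotation", {
  sim <- simulate_pursuit(simulation_config(seed = 6), with_escape = TRUE)
  seg0 <- classify_epochs(sim$trajectory, sim$manual_capture_end)

  tr <- sim$trajectory
  shifted <- pursuit_trajectory(tr$timestamps + 10, tr$mouse, tr$cricket,
                                tr$bearing_deg)
  seg1 <- classify_epochs(shifted, sim$manual_capture_end + 10)
  expect_equal(seg1$epochs$t_end - 10, seg0$epochs$t_end, tolerance = 1e-9)

  R <- rotation_about_axis(c(0, 0, 1), 73)
  rot <- pursuit_trajectory(tr$timestamps, tr$mouse %*% t(R),
                            tr$cricket %*% t(R), tr$bearing_deg)
  seg2 <- classify_epochs(rot, sim$manual_capture_end)
  expect_equal(seg2$epochs$t_end, seg0$epochs$t_end, tolerance = 1e-9)
  expect_identical(nrow(seg2$escapes), nrow(seg0$escapes))
})

test_that("straightness metrics follow chord geometry and scale linearly", {
  # straight path: all metrics zero
  straight <- cbind(seq(0, 0.5, length.out = 100), 0)
  m0 <- straightness_metrics(straight)
  expect_equal(m0$max_dev_cm, 0, tolerance = 1e-9)
  expect_equal(m0$area_cm2, 0, tolerance = 1e-9)
  expect_equal(m0$dev_at_20cm_cm, 0, tolerance = 1e-9)

  # isoceles detour: 40 cm chord, 5 cm apex -> max dev 5 cm, area 100 cm^2
  apex <- rbind(c(0, 0), c(0.2, 0.05), c(0.4, 0))
  m1 <- straightness_metrics(apex)
  expect_equal(m1$max_dev_cm, 5, tolerance = 1e-9)
  expect_equal(m1$area_cm2, 100, tolerance = 1e-9)
  expect_equal(m1$dev_at_20cm_cm, 5, tolerance = 1e-9)

  # mirror image: identical unsigned metrics
  m2 <- straightness_metrics(cbind(apex[, 1], -apex[, 2]))
  expect_equal(m2$max_dev_cm, m1$max_dev_cm, tolerance = 1e-12)
  expect_equal(m2$area_cm2, m1$area_cm2, tolerance = 1e-12)

  # metrics scale with the path
  m3 <- straightness_metrics(apex * 2)
  expect_equal(m3$max_dev_cm, 2 * m1$max_dev_cm, tolerance = 1e-9)
  expect_equal(m3$area_cm2, 4 * m1$area_cm2, tolerance = 1e-9)

  # short chord: the fixed-point metric is unavailable
  m4 <- straightness_metrics(apex * 0.25)
  expect_true(is.na(m4$dev_at_20cm_cm))
})

test_that("prey density maps conserve mass and weight sequences equally", {
  g <- spherical_grid(65)
  one <- matrix(c(30, 45), 1, 2)
  dm <- prey_density_map(one, g)
  expect_equal(sum(dm$mass), 1, tolerance = 1e-12)
  expect_identical(sum(dm$mass > 0), 1L)
  hc <- hdr_contours(dm, 50)
  expect_identical(sum(hc[[1]]$region), 1L)

  # unequal-length sequences are averaged with equal weight
  a <- matrix(c(20, 0), 1, 2)
  b <- matrix(rep(c(60, 90), 10), 10, 2, byrow = TRUE)
  dm2 <- prey_density_map(list(a, b), g)
  expect_equal(max(dm2$mass), 0.5, tolerance = 1e-9)

  # smoothing preserves total mass
  set.seed(181)
  pts <- cbind(runif(500, 0, 80), runif(500, -180, 180))
  dm3 <- prey_density_map(pts, g, smooth_px = 1.5)
  expect_equal(sum(dm3$mass), 1, tolerance = 1e-9)

  expect_error(prey_density_map(matrix(0, 0, 2), g), "empty")
})

test_that("highest-density regions hold the stated mass with nesting and components", {
  g <- spherical_grid(65)
  # von Mises-Fisher-type density evaluated directly on the grid
  gg <- mousegaze:::grid_geometry(g)
  kappa <- 12
  mu <- c(sin(35 * pi / 180), 0, -cos(35 * pi / 180))
  pdf <- exp(kappa * as.numeric(gg$dirs %*% mu))
  w <- grid_solid_angle(g)
  mass <- matrix(pdf, 65, 65) * w
  mass[is.na(w)] <- NA
  mass <- mass / sum(mass, na.rm = TRUE)
  dm <- structure(list(mass = mass, density = mass / w, grid = g),
                  class = "density_map")
  hc <- hdr_contours(dm, c(50, 75, 90, 95))
  for (k in seq_along(hc)) {
    expect_equal(hc[[k]]$mass, hc[[k]]$level / 100, tolerance = 0.01)
  }
  # nesting: each region contains the previous
  for (k in 2:4) expect_true(all(hc[[k]]$region[hc[[k - 1]]$region]))
  # the 50 percent region center sits at the mode
  expect_equal(unname(hc[[1]]$center[["radial"]]), 35, tolerance = 2)

  # quadrature oracle: the HDR threshold recovers half the mass of the
  # continuous vMF density on a fine latitude-longitude grid
  thr_rel <- hc[[1]]$threshold / max(dm$density, na.rm = TRUE)
  th <- seq(1e-4, pi, length.out = 600)
  ph <- seq(-pi, pi, length.out = 1200)
  dirs_th <- cos(th)   # polar angle from mu by symmetry
  f <- exp(kappa * cos(th))
  Z <- sum(f * sin(th)) * diff(th)[1] * 2 * pi
  inside <- f / max(f) >= thr_rel
  frac <- sum((f * sin(th))[inside]) * diff(th)[1] * 2 * pi / Z
  expect_equal(frac, 0.5, tolerance = 0.02)

  # two equal blobs: the 50 percent region splits into two components
  mass2 <- matrix(0, 65, 65)
  mass2[20, 33] <- 0.5; mass2[46, 33] <- 0.5
  dm2 <- structure(list(mass = mass2, density = mass2 / w, grid = g),
                   class = "density_map")
  hc2 <- hdr_contours(dm2, 75)
  expect_identical(sum(hc2[[1]]$region), 2L)
  expect_false(any(hc2[[1]]$region[21:45, 33]))

  expect_error(hdr_contours(dm, 101), "parameter|level")
})

test_that("per-trial medians are robust one-number summaries", {
  expect_equal(unname(per_trial_median(c(1, 2, 100), rep("a", 3))["a"]), 2)
  x <- c(rnorm(1000), rep(1e6, 50))
  tr <- rep("t1", 1050)
  expect_lt(abs(per_trial_median(x, tr)[["t1"]]), 0.2)
  out <- per_trial_median(c(1, 2, NA), c("a", "a", "b"))
  expect_true(is.na(out[["b"]]))
})
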