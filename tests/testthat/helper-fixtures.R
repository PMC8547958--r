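# Shared fixtures and small independent oracles.

random_rotation <- function() {
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 180))
}

expect_so3 <- function(R, tol = 1e-9) {
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_lt(abs(det(R) - 1), tol)
}

# Brute-force rigid Procrustes oracle: best SSE over many random-start
# axis-angle optimizations (independent of the closed-form SVD path).
procrustes_sse_oracle <- function(src, dst, starts = 12) {
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  f <- function(w) {
    R <- rotation_exp(w)
    sum((A %*% t(R) - B)^2)
  }
  best <- Inf
  for (k in seq_len(starts)) {
    o <- stats::optim(stats::rnorm(3, sd = 60), f, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Brute-force chordal-mean oracle: minimize sum ||R_i - M||_F^2 over M in
# SO(3) by axis-angle optimization.
chordal_mean_oracle <- function(rotations) {
  f <- function(w) {
    M <- rotation_exp(w)
    s <- 0
    for (i in seq_len(dim(rotations)[3])) s <- s + sum((rotations[, , i] - M)^2)
    s
  }
  best <- NULL; bv <- Inf
  for (k in 1:8) {
    o <- stats::optim(stats::rnorm(3, sd = 40), f, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (o$value < bv) { bv <- o$value; best <- o$par }
  }
  rotation_exp(best)
}

# Cube-map rendering oracle: five 90-degree perspective faces then
# nearest-neighbor resampling into the spherical chart. Shares only the raw
# triangle caster with the package's azimuthal-equidistant path.
cubemap_depth_oracle <- function(mesh, eye_position, eye_rotation, grid,
                                 face_res = 96) {
  # face axes (eye frame): forward = optical axis -z, plus four side faces
  faces <- list(
    fwd = cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, -1)),
    xp = cbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)),
    xm = cbind(c(0, 0, -1), c(0, 1, 0), c(-1, 0, 0)),
    yp = cbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)),
    ym = cbind(c(1, 0, 0), c(0, 0, -1), c(0, -1, 0)))
  depth_faces <- lapply(faces, function(ax) {
    u <- seq(-1 + 1 / face_res, 1 - 1 / face_res, length.out = face_res)
    pix <- as.matrix(expand.grid(u = u, v = u))
    dirs_eye <- t(ax %*% rbind(pix[, 1], pix[, 2], rep(1, nrow(pix))))
    dirs_eye <- dirs_eye / sqrt(rowSums(dirs_eye^2))
    dw <- dirs_eye %*% t(eye_rotation)
    hit <- mousegaze:::ray_cast_cpp(as.numeric(eye_position), dw,
                                    mesh$vertices, mesh$faces - 1L)
    matrix(hit$t, face_res, face_res)
  })
  gg <- mousegaze:::grid_geometry(grid)
  n <- grid$resolution
  out <- rep(NA_real_, n * n)
  for (k in seq_len(n * n)) {
    if (!gg$inside[k]) next
    d <- gg$dirs[k, ]
    # pick the face whose axis has the largest positive projection
    proj <- c(fwd = -d[3], xp = d[1], xm = -d[1], yp = d[2], ym = -d[2])
    fc <- names(which.max(proj))
    ax <- faces[[fc]]
    loc <- as.numeric(t(ax) %*% d)
    u <- loc[1] / loc[3]; v <- loc[2] / loc[3]
    iu <- min(max(round((u + 1) / 2 * face_res + 0.5), 1), face_res)
    iv <- min(max(round((v + 1) / 2 * face_res + 0.5), 1), face_res)
    out[k] <- depth_faces[[fc]][iu, iv]
  }
  matrix(out, n, n)
}
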