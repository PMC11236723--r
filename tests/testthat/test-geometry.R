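test_that("Euler-angle DCM matches the elementary-rotation product and special cases", {
  expect_equal(rotation_from_euler(0, 0, 0), diag(3), tolerance = 1e-12)
  Ry <- rotation_from_euler(0, 0, pi / 2)
  expect_lt(abs(Ry[1, 1]), 1e-12)
  expect_equal(Ry[1, 2], 1, tolerance = 1e-12)
  # entry-wise oracle: product of the three elementary rotations
  set.seed(42)
  for (i in 1:20) {
    phi <- runif(1, -3, 3); theta <- runif(1, -1.5, 1.5); psi <- runif(1, -3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(phi), sin(phi), 0, -sin(phi), cos(phi)), 3, byrow = TRUE)
    Rp <- matrix(c(cos(theta), 0, -sin(theta), 0, 1, 0, sin(theta), 0, cos(theta)), 3, byrow = TRUE)
    Rz <- matrix(c(cos(psi), sin(psi), 0, -sin(psi), cos(psi), 0, 0, 0, 1), 3, byrow = TRUE)
    expect_equal(rotation_from_euler(phi, theta, psi), Rx %*% Rp %*% Rz, tolerance = 1e-12)
  }
  expect_error(rotation_from_euler(NA, 0, 0))
})

test_that("every produced rotation is orthonormal with unit determinant", {
  set.seed(7)
  for (i in 1:50) {
    R <- random_rotation()
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("euler extraction round-trips and rejects gimbal lock", {
  expect_equal(unlist(euler_from_rotation(diag(3))), c(phi = 0, theta = 0, psi = 0))
  e <- euler_from_rotation(rotation_from_euler(0.3, -0.2, 1.1))
  expect_equal(unlist(e), c(phi = 0.3, theta = -0.2, psi = 1.1), tolerance = 1e-9)
  set.seed(8)
  for (i in 1:50) {
    R <- random_rotation()
    e <- euler_from_rotation(R)
    expect_equal(rotation_from_euler(e$phi, e$theta, e$psi), R, tolerance = 1e-9)
  }
  Rlock <- rotation_from_euler(0, -pi / 2, 0)
  expect_error(euler_from_rotation(Rlock), "gimbal")
})

test_that("gyro integration reproduces closed-form single-axis and matrix-exponential rotations", {
  # zero rate: orientation unchanged
  Rs <- integrate_gyro(diag(3), matrix(0, 10, 3), 0.01)
  expect_equal(Rs[[11]], diag(3), tolerance = 1e-12)
  # constant yaw rate 0.5 rad/s for 2 s
  n <- 20000
  Rs <- integrate_gyro(diag(3), matrix(rep(c(0, 0, 0.5), n), ncol = 3, byrow = TRUE), 1e-4)
  expect_equal(euler_from_rotation(Rs[[n + 1]])$psi, 1.0, tolerance = 1e-3)
  # general constant rate vs matrix exponential
  w <- c(0.3, -0.2, 0.4)
  S <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, byrow = TRUE)
  Rs <- integrate_gyro(diag(3), matrix(rep(w, 10000), ncol = 3, byrow = TRUE), 1e-4)
  expect_equal(Rs[[10001]], t(as.matrix(Matrix::expm(S))), tolerance = 1e-6)
  expect_error(integrate_gyro(diag(3), matrix(0, 2, 3), 0), "dt")
})

test_that("gaze-screen intersection satisfies the plane equation and matches a ray-marching oracle", {
  cfg <- geometry_config()
  pt <- gaze_screen_intersection(diag(3), cfg)
  expect_lt(abs(cfg$y0 * (pt[1] - cfg$x0) + cfg$x0 * pt[2]), 1e-9)

  ray_march <- function(R, cfg) {
    p0 <- as.numeric(R %*% cfg$p0); d <- as.numeric(R %*% cfg$d)
    resid <- function(m) cfg$y0 * (p0[1] + m * d[1] - cfg$x0) + cfg$x0 * (p0[2] + m * d[2])
    lo <- 0; hi <- 0.1
    while (sign(resid(lo)) == sign(resid(hi)) && hi < 1e12) hi <- hi * 2
    if (sign(resid(lo)) == sign(resid(hi))) return(NULL)  # near-parallel ray
    m <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
    p0 + m * d
  }
  set.seed(12)
  n_ok <- 0
  for (i in 1:1000) {
    R <- rotation_from_euler(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5), runif(1, -0.5, 0.5))
    cfg <- geometry_config(x0 = runif(1, 10, 40), y0 = runif(1, 10, 40),
                           p0 = runif(3, -1, 1))
    pt <- tryCatch(gaze_screen_intersection(R, cfg), error = function(e) NULL)
    if (is.null(pt)) next
    oracle <- ray_march(R, cfg)
    if (is.null(oracle)) next
    expect_equal(pt, oracle, tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 900)
  # parallel ray
  cfg <- geometry_config(x0 = 20, y0 = 20, d = c(1, -1, 0))
  expect_error(gaze_screen_intersection(diag(3), cfg), "parallel")
  # pointing away
  cfg <- geometry_config(x0 = 20, y0 = 20, d = c(-1, 0, 0))
  expect_error(gaze_screen_intersection(diag(3), cfg), "behind")
})

test_that("Rodrigues rotation about z preserves norm and matches the axis-angle matrix", {
  v <- c(0.3, -1.2, 0.7)
  expect_equal(rodrigues_rotate(v, 0), v, tolerance = 1e-12)
  expect_equal(rodrigues_rotate(c(1, 0, 0), pi / 2), c(0, 1, 0), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(3); b <- runif(1, -pi, pi)
    Rz <- matrix(c(cos(b), -sin(b), 0, sin(b), cos(b), 0, 0, 0, 1), 3, byrow = TRUE)
    expect_equal(rodrigues_rotate(v, b), as.numeric(Rz %*% v), tolerance = 1e-12)
    expect_equal(sqrt(sum(rodrigues_rotate(v, b)^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
})

test_that("eye-in-head correction applies the model and validates its output", {
  d <- c(1, 0, 0)
  idm <- eye_correction_model("identity")
  expect_equal(eye_in_head_correction(d, 0.2, 0.1, 0.5, idm), d)
  # gain-1 compensatory yaw cancels head yaw in the lab frame
  comp <- eye_correction_model("compensatory_yaw", gain = 1)
  psi <- 0.4
  R <- rotation_from_euler(0, 0, psi)
  d_corr <- eye_in_head_correction(d, 0, 0, psi, comp)
  lab <- as.numeric(R %*% d_corr)
  expect_equal(atan2(lab[2], lab[1]), 0, tolerance = 1e-9)
  bad <- function(phi, theta, psi) matrix(2, 3, 3)
  expect_error(eye_in_head_correction(d, 0, 0, 0, bad), "invalid model")
})

test_that("gaze paths from single-axis head rotations land on the matching screen axis", {
  cfg <- geometry_config()
  flat <- make_sta()
  p <- project_displacement_to_gaze_path(flat, cfg)
  expect_equal(max(abs(p$h)), 0, tolerance = 1e-9)
  expect_equal(max(abs(p$v)), 0, tolerance = 1e-9)

  yawp <- project_displacement_to_gaze_path(make_sta(yaw = ramp_curve(15)), cfg)
  expect_lt(max(abs(yawp$v)), 1e-6)
  expect_gt(max(abs(yawp$h)), 1)
  ang <- gaze_preferred_direction(yawp)
  expect_lt(min(abs(c(ang, ang - 180, ang - 360))), 1)

  pitchp <- project_displacement_to_gaze_path(make_sta(pitch = ramp_curve(15)), cfg)
  expect_lt(max(abs(pitchp$h)), 1e-6)
  expect_gt(max(abs(pitchp$v)), 1)

  # compensatory gain 1: pure yaw produces no horizontal gaze motion
  cfgc <- geometry_config(correction = eye_correction_model("compensatory_yaw", gain = 1))
  yawc <- project_displacement_to_gaze_path(make_sta(yaw = ramp_curve(15)), cfgc)
  expect_lt(max(abs(yawc$h)), 1e-6)
})
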