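#' 3D head-rotation kinematics and gaze-to-screen projection
#'
#' The geometry layer models the head as a rigid body whose orientation is
#' parameterised by aerospace ZYX Euler angles (yaw \eqn{\psi} about the lab
#' \eqn{\hat z}, pitch \eqn{\theta}, roll \eqn{\phi}), builds the direction
#' cosine matrix, integrates gyroscope angular rates, and projects a gaze ray
#' fixed in the head frame onto a vertical stimulus-screen plane in the lab
#' frame. All angles are radians internally; degrees appear only at I/O
#' boundaries.
#'
#' @name geometry
NULL

#' Direction cosine matrix from ZYX Euler angles
#'
#' Builds the 3x3 rotation matrix for roll \code{phi}, pitch \code{theta},
#' yaw \code{psi} in the ZYX (yaw-pitch-roll) convention, with
#' \code{R[1,3] = -sin(theta)}, \code{R[2,3] = sin(phi) cos(theta)},
#' \code{R[3,3] = cos(phi) cos(theta)}.
#'
#' @param phi roll angle (rad)
#' @param theta pitch angle (rad)
#' @param psi yaw angle (rad)
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
rotation_from_euler <- function(phi, theta, psi) {
  stopifnot(is.finite(phi), is.finite(theta), is.finite(psi))
  cphi <- cos(phi); sphi <- sin(phi)
  cth <- cos(theta); sth <- sin(theta)
  cpsi <- cos(psi); spsi <- sin(psi)
  matrix(c(
    cth * cpsi,                     cth * spsi,                    -sth,
    sphi * sth * cpsi - cphi * spsi, sphi * sth * spsi + cphi * cpsi, sphi * cth,
    cphi * sth * cpsi + sphi * spsi, cphi * sth * spsi - sphi * cpsi, cphi * cth
  ), nrow = 3, byrow = TRUE)
}

#' Euler angles from a direction cosine matrix
#'
#' Inverse of [rotation_from_euler()]: \code{phi = atan2(R23, R33)},
#' \code{theta = -asin(R13)}, \code{psi = atan2(R12, R11)}. Pitch is confined
#' to (-pi/2, pi/2); the gimbal-lock configurations \code{|R13| ~ 1} are
#' rejected because roll and yaw are then not separately identifiable.
#'
#' @param R 3x3 rotation matrix
#' @return list with elements \code{phi}, \code{theta}, \code{psi} (rad).
#' @export
euler_from_rotation <- function(R) {
  assert_rotation(R)
  if (abs(R[1, 3]) >= 1 - 1e-9) {
    stop("degenerate orientation: |R13| ~ 1 (gimbal lock), pitch at +/-90 deg")
  }
  list(phi = atan2(R[2, 3], R[3, 3]),
       theta = -asin(R[1, 3]),
       psi = atan2(R[1, 2], R[1, 1]))
}

assert_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || !all(is.finite(R))) {
    stop("invalid rotation matrix: expected finite 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("invalid rotation matrix: not orthonormal with det +1")
  }
  invisible(R)
}

#' Project a matrix to the nearest rotation (polar decomposition via SVD)
#' @keywords internal
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    s$v[, 3] <- -s$v[, 3]
    R <- s$u %*% t(s$v)
  }
  R
}

skew <- function(w) {
  matrix(c(0, -w[3], w[2],
           w[3], 0, -w[1],
           -w[2], w[1], 0), nrow = 3, byrow = TRUE)
}

#' Integrate body-frame gyroscope rates into an orientation time series
#'
#' Applies the first-order update
#' \code{t(R)(t+dt) = t(R)(t) (I + [w]x dt)} at each sample and then projects
#' back to the nearest rotation matrix (the raw first-order step drifts off
#' SO(3)).
#'
#' @param R0 initial rotation matrix
#' @param omega n x 3 matrix of body-frame angular rates (rad/s), one row per step
#' @param dt time step (s), > 0
#' @return list of n+1 rotation matrices (including \code{R0}).
#' @export
integrate_gyro <- function(R0, omega, dt) {
  assert_rotation(R0)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("invalid argument: dt must be a positive scalar")
  }
  omega <- matrix(omega, ncol = 3)
  out <- vector("list", nrow(omega) + 1)
  out[[1]] <- R0
  Rt <- t(R0)
  for (i in seq_len(nrow(omega))) {
    Rt <- Rt %*% (diag(3) + skew(omega[i, ]) * dt)
    Rt <- nearest_rotation(Rt)
    out[[i + 1]] <- t(Rt)
  }
  out
}

#' Screen-plane and gaze defaults
#'
#' The screen is a vertical plane (it contains the lab \eqn{\hat z} direction)
#' anchored at lab-frame points \code{(x0, 0, .)} and \code{(0, y0, .)}, i.e.
#' the plane \code{y0 (x - x0) + x0 y = 0}. The default places the screen
#' 20 cm from the resting eye along the resting gaze direction \code{(1,0,0)},
#' with angular extents of 31 degrees down, 42 up, 45 nasal and 59 temporal
#' around the calibration centre. The pupil offset \code{p0} and resting gaze
#' \code{d} are declared defaults (head-frame), not measured quantities.
#'
#' @param x0,y0 lab-frame plane anchors (cm); both non-zero together
#' @param p0 pupil position in the head frame (cm)
#' @param d resting gaze direction in the head frame (unit vector)
#' @param correction eye-in-head correction model; see [eye_correction_model()]
#' @return list of class \code{geometry_config}.
#' @export
geometry_config <- function(x0 = 20, y0 = 20,
                            p0 = c(0, 0, 0),
                            d = c(1, 0, 0),
                            correction = eye_correction_model("identity")) {
  if (x0 == 0 && y0 == 0) stop("screen plane anchor (x0, y0) must not be (0, 0)")
  d <- d / sqrt(sum(d^2))
  structure(list(x0 = x0, y0 = y0, p0 = as.numeric(p0), d = as.numeric(d),
                 extent_deg = c(down = 31, up = 42, nasal = 45, temporal = 59),
                 correction = correction),
            class = "geometry_config")
}

#' Rotate a vector about the lab z-axis (Rodrigues formula)
#'
#' \code{v_rot = v cos(beta) + (z x v) sin(beta) + z (z . v) (1 - cos(beta))}.
#' Used with \code{beta = asin(y0 / sqrt(x0^2 + y0^2))} to re-express screen
#' intersection points in screen-aligned coordinates (screen parallel to the
#' lab x-z plane).
#'
#' @param v 3-vector
#' @param beta rotation angle about \eqn{\hat z} (rad)
#' @return rotated 3-vector, same norm as \code{v}.
#' @export
rodrigues_rotate <- function(v, beta) {
  stopifnot(all(is.finite(v)), is.finite(beta), length(v) == 3)
  z <- c(0, 0, 1)
  zxv <- c(-v[2], v[1], 0)
  v * cos(beta) + zxv * sin(beta) + z * v[3] * (1 - cos(beta))
}

#' Screen-alignment angle for a plane anchored at (x0, y0)
#' @keywords internal
screen_beta <- function(x0, y0) asin(y0 / sqrt(x0^2 + y0^2))

#' Intersect a head-fixed gaze ray with the screen plane
#'
#' Rotates the pupil position \code{p0} and gaze direction \code{d} from the
#' head frame into the lab frame with \code{R}, then solves the plane equation
#' \code{y0 (x - x0) + x0 y = 0} for the ray scale \code{m}.
#'
#' @param R head orientation (rotation matrix)
#' @param config a [geometry_config()] (supplies plane, pupil, gaze)
#' @param d optional gaze direction overriding \code{config$d} (head frame)
#' @return lab-frame 3-vector of the intersection point.
#' @export
gaze_screen_intersection <- function(R, config, d = NULL) {
  assert_rotation(R)
  if (is.null(d)) d <- config$d
  p0_lab <- as.numeric(R %*% config$p0)
  dir_lab <- as.numeric(R %*% d)
  x0 <- config$x0; y0 <- config$y0
  denom <- y0 * dir_lab[1] + x0 * dir_lab[2]
  if (abs(denom) < 1e-12) stop("no intersection: gaze ray parallel to the screen plane")
  m <- (y0 * x0 - y0 * p0_lab[1] - x0 * p0_lab[2]) / denom
  if (m < 0) stop("behind screen: gaze ray points away from the screen plane")
  p0_lab + m * dir_lab
}

#' Eye-in-head correction models
#'
#' The gaze direction is not strictly head-fixed: the eye counter-rotates in
#' the head. The correction model maps the instantaneous head Euler angles to
#' a rotation applied to the head-frame gaze direction before projection.
#' \code{"identity"} applies no correction; \code{"compensatory_yaw"} rotates
#' the gaze by \code{-gain * psi} about the head z-axis (gain 1 makes the
#' lab-frame gaze azimuth invariant to yaw).
#'
#' @param type \code{"identity"} or \code{"compensatory_yaw"}
#' @param gain compensation gain (dimensionless), used by
#'   \code{"compensatory_yaw"}
#' @return function \code{(phi, theta, psi) -> 3x3 rotation matrix} of class
#'   \code{eye_correction_model}.
#' @export
eye_correction_model <- function(type = c("identity", "compensatory_yaw"), gain = 1) {
  type <- match.arg(type)
  f <- switch(type,
    identity = function(phi, theta, psi) diag(3),
    compensatory_yaw = function(phi, theta, psi) rotation_from_euler(0, 0, -gain * psi)
  )
  structure(f, class = c("eye_correction_model", "function"), type = type, gain = gain)
}

#' Apply an eye-in-head correction to a gaze direction
#'
#' @param direction head-frame gaze direction (3-vector)
#' @param phi,theta,psi current head Euler angles (rad)
#' @param model an [eye_correction_model()] or any function returning a
#'   rotation matrix
#' @return corrected head-frame gaze direction.
#' @export
eye_in_head_correction <- function(direction, phi, theta, psi, model) {
  Rc <- model(phi, theta, psi)
  ok <- is.matrix(Rc) && all(dim(Rc) == c(3, 3)) && all(is.finite(Rc)) &&
    max(abs(crossprod(Rc) - diag(3))) < 1e-6 && abs(det(Rc) - 1) < 1e-6
  if (!ok) stop("invalid model: correction did not return a rotation matrix")
  as.numeric(Rc %*% direction)
}

#' Project STA head displacements to a 2D gaze track on the screen
#'
#' Treats the per-bin cumulative Euler displacements of a spike-triggered
#' average as the head orientation at each lag (head at rest at the spike,
#' t = 0), projects the gaze ray to the screen at each bin, rotates into
#' screen-aligned coordinates, and returns the 2D track relative to the
#' calibration centre (the t = 0 intersection).
#'
#' @param sta an \code{sta_result} from [compute_sta()] (displacements in deg)
#' @param config a [geometry_config()]
#' @return data.frame of class \code{gaze_path} with columns \code{t},
#'   \code{h} (screen horizontal) and \code{v} (screen vertical), possibly
#'   truncated (with a warning) at the first bin whose ray misses the screen.
#' @export
project_displacement_to_gaze_path <- function(sta, config) {
  stopifnot(inherits(sta, "sta_result"))
  n <- length(sta$time)
  beta <- screen_beta(config$x0, config$y0)
  h <- v <- numeric(n)
  keep <- n
  for (i in seq_len(n)) {
    phi <- sta$displacement[i, "roll"] * pi / 180
    theta <- sta$displacement[i, "pitch"] * pi / 180
    psi <- sta$displacement[i, "yaw"] * pi / 180
    R <- rotation_from_euler(phi, theta, psi)
    d <- eye_in_head_correction(config$d, phi, theta, psi, config$correction)
    pt <- tryCatch(gaze_screen_intersection(R, config, d = d), error = function(e) NULL)
    if (is.null(pt)) { keep <- i - 1L; break }
    pr <- rodrigues_rotate(pt, beta)
    h[i] <- pr[1]; v[i] <- pr[3]
  }
  if (keep < n) warning(sprintf("gaze ray missed the screen at bin %d; path truncated", keep + 1L))
  if (keep < 1) stop("gaze ray misses the screen at the calibration centre")
  i0 <- which.min(abs(sta$time))
  out <- data.frame(t = sta$time[seq_len(keep)],
                    h = h[seq_len(keep)] - h[i0],
                    v = v[seq_len(keep)] - v[i0])
  class(out) <- c("gaze_path", "data.frame")
  out
}
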