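#' Three-layer collicular network simulator
#'
#' A feedforward rate model of one superior colliculus: a layer of spatial
#' receptive-field (ssRF) neurons, a layer of direction-selective (DS)
#' neurons tuned to concentric motion, and a motor layer anti-aligned with
#' the DS layer, driving an agent that intercepts a target moving in its
#' visual field. Two pathway variants route drive to the DS layer: the
#' kinetic pathway computes DS input directly from stimulus motion, the
#' static pathway relays ssRF-layer rates. Positions are expressed in
#' normalized field units (degrees / 100), so the naso-temporal (NT) x
#' ventro-dorsal (VD) field extents [0, 140] x [0, 70] degrees become
#' [0, 1.4] x [0, 0.7].
#'
#' @name scsim
NULL

#' Network and simulation configuration
#'
#' @param n_per_layer neurons per layer (default 500)
#' @param extent field extents c(NT, VD) in normalized units; default
#'   c(1.4, 0.7) (140 x 70 deg)
#' @param kappa tuning concentration (default 40)
#' @param sigma_noise s.d. of the Gaussian input noise (default 0.1)
#' @param tau_neural neural time constant (s, default 0.010)
#' @param dt Euler step (s, default 5e-4)
#' @param tau_m motor gain time constant (s, default 0.250)
#' @param pathway \code{"kinetic"} or \code{"static"}
#' @param alignment_shift motor-layer mis-alignment (rad, default 0 =
#'   anti-aligned DS/motor, i.e. motor direction equals the RF angle)
#' @param rf_gain peak RF drive (default 1.5)
#' @param rf_width_factor multiplies kappa in the RF exponent (default 0.6)
#' @param t_max simulation horizon (s, default 2.5)
#' @param intercept_radius interception distance (normalized units,
#'   default 0.24 = 24 deg)
#' @param motion_limit agent-motion termination bounds c(NT, VD) (normalized
#'   units, default c(2, 1) = 200/100 deg)
#' @return list of class \code{sc_config}.
#' @export
sc_config <- function(n_per_layer = 500, extent = c(1.4, 0.7), kappa = 40,
                      sigma_noise = 0.1, tau_neural = 0.010, dt = 5e-4,
                      tau_m = 0.250, pathway = c("kinetic", "static"),
                      alignment_shift = 0, rf_gain = 1.5, rf_width_factor = 0.6,
                      t_max = 2.5, intercept_radius = 0.24,
                      motion_limit = c(2, 1)) {
  pathway <- match.arg(pathway)
  stopifnot(n_per_layer > 0, all(extent > 0), kappa > 0, sigma_noise >= 0,
            tau_neural > 0, dt > 0, tau_m > 0, t_max > 0)
  structure(as.list(environment()), class = "sc_config")
}

#' Build the neuron layout for a configuration
#'
#' RF centres tile the field on a quasi-uniform grid. Per neuron, the RF
#' angle is the angular position of its centre, the DS preferred direction
#' is opposite (concentric motion, towards the agent), and the motor
#' direction is opposite the DS direction plus the alignment shift - so at
#' zero shift the motor direction equals the RF angle.
#'
#' @param config an [sc_config()]
#' @return list of class \code{sc_layout}: \code{z} (n x 2 RF centres),
#'   \code{theta_rf}, \code{theta_ds}, \code{theta_m} (rad), \code{m}
#'   (n x 2 unit motor vectors).
#' @export
build_network <- function(config) {
  n <- config$n_per_layer
  aspect <- config$extent[1] / config$extent[2]
  divs <- which(n %% seq_len(n) == 0)
  nx <- divs[which.min(abs(divs^2 / n - aspect))]  # nx/ny closest to the aspect
  ny <- n / nx
  gx <- (seq_len(nx) - 0.5) / nx * config$extent[1]
  gy <- (seq_len(ny) - 0.5) / ny * config$extent[2]
  z <- as.matrix(expand.grid(nt = gx, vd = gy))
  theta_rf <- atan2(z[, 2], z[, 1])
  theta_ds <- theta_rf + pi
  theta_m <- theta_ds + pi + config$alignment_shift
  structure(list(z = z, theta_rf = theta_rf, theta_ds = theta_ds,
                 theta_m = theta_m,
                 m = cbind(cos(theta_m), sin(theta_m))),
            class = "sc_layout")
}

#' Gaussian receptive-field drive for a stimulus location
#' @param s stimulus location (2-vector, normalized units, egocentric)
#' @param layout an \code{sc_layout}
#' @param config the configuration
#' @return drive per RF neuron, \code{rf_gain * exp(-rf_width_factor * kappa
#'   * |s - z|^2)}.
#' @export
rf_drive <- function(s, layout, config) {
  d2 <- (layout$z[, 1] - s[1])^2 + (layout$z[, 2] - s[2])^2
  config$rf_gain * exp(-config$rf_width_factor * config$kappa * d2)
}

#' DS-layer drive
#'
#' Static pathway: the DS input is the RF-layer rate vector. Kinetic
#' pathway: \code{gamma * exp(kappa * (cos(theta_s - theta_ds + pi) - 1))}
#' where \code{theta_s} is the stimulus angle in the field and the
#' concentricity \code{gamma = [-(s . sdot) / (|s| |sdot|)]_+} rectifies to
#' zero for receding motion (and for zero position or velocity).
#'
#' @param s stimulus location (2-vector)
#' @param sdot stimulus velocity relative to the agent (2-vector)
#' @param r_rf RF-layer rates (used by the static pathway)
#' @param layout,config layout and configuration
#' @return drive per DS neuron.
#' @export
ds_drive <- function(s, sdot, r_rf, layout, config) {
  if (config$pathway == "static") return(r_rf)
  ns <- sqrt(sum(s^2)); nv <- sqrt(sum(sdot^2))
  gamma <- if (ns < 1e-12 || nv < 1e-12) 0 else max(0, -sum(s * sdot) / (ns * nv))
  if (gamma == 0) return(numeric(length(layout$theta_ds)))
  theta_s <- atan2(s[2], s[1])
  gamma * exp(config$kappa * (cos(theta_s - layout$theta_ds + pi) - 1))
}

#' One Euler step of the rate dynamics
#'
#' \code{r <- [r + (dt / tau_neural) (-r + x + eps)]_+} with rectification.
#'
#' @param r current rates
#' @param x inputs
#' @param config configuration
#' @param noise optional pre-drawn noise vector \code{eps} (defaults to
#'   \code{N(0, sigma_noise^2)} i.i.d. per neuron)
#' @return updated non-negative rates.
#' @export
step_rates <- function(r, x, config, noise = NULL) {
  if (is.null(noise)) {
    noise <- if (config$sigma_noise > 0) stats::rnorm(length(r), 0, config$sigma_noise) else 0
  }
  pmax(r + (config$dt / config$tau_neural) * (-r + x + noise), 0)
}

#' Agent displacement from motor-layer rates
#' @param r_motor motor-layer rates
#' @param layout,config layout and configuration
#' @return displacement increment \code{(dt / tau_m) sum_i r_i m_i}
#'   (2-vector, normalized units).
#' @export
agent_step <- function(r_motor, layout, config) {
  (config$dt / config$tau_m) * c(sum(r_motor * layout$m[, 1]),
                                 sum(r_motor * layout$m[, 2]))
}

#' Run one interception simulation
#'
#' Euler loop: RF drive from the egocentric target position, DS drive per
#' pathway, motor drive = DS rates, rate updates, agent step, and egocentric
#' position update \code{s <- s + sdot dt - da}. Terminates on timeout
#' (\code{t_max}), the target leaving the field, the agent motion exceeding
#' the NT/VD limits, or interception (egocentric distance below
#' \code{intercept_radius}).
#'
#' @param config an [sc_config()]
#' @param s0 initial egocentric target position (2-vector, normalized units)
#' @param velocity target velocity (2-vector, normalized units / s)
#' @param layout optional prebuilt layout
#' @param store_trajectory keep the per-step relative trajectory
#' @return list of class \code{sc_sim}: \code{termination_reason} (timeout /
#'   left_field / motion_limit / intercept), \code{intercept},
#'   \code{final_distance_deg}, \code{energy}, \code{duration},
#'   \code{agent_displacement}, and optionally \code{trajectory}.
#' @export
run_simulation <- function(config, s0, velocity, layout = NULL,
                           store_trajectory = FALSE) {
  if (is.null(layout)) layout <- build_network(config)
  n <- config$n_per_layer
  r_rf <- r_ds <- r_m <- numeric(n)
  s <- as.numeric(s0); v <- as.numeric(velocity)
  a <- c(0, 0)
  energy <- 0
  n_steps <- ceiling(config$t_max / config$dt)
  traj <- if (store_trajectory) matrix(NA_real_, n_steps, 2) else NULL
  reason <- "timeout"
  steps_done <- 0L
  for (k in seq_len(n_steps)) {
    x_rf <- rf_drive(s, layout, config)
    x_ds <- ds_drive(s, v, r_rf, layout, config)
    x_m <- r_ds
    r_rf <- step_rates(r_rf, x_rf, config)
    r_ds <- step_rates(r_ds, x_ds, config)
    r_m <- step_rates(r_m, x_m, config)
    da <- agent_step(r_m, layout, config)
    a <- a + da
    energy <- energy + sqrt(sum(da^2))
    s <- s + v * config$dt - da
    steps_done <- k
    if (store_trajectory) traj[k, ] <- s
    if (sqrt(sum(s^2)) < config$intercept_radius) { reason <- "intercept"; break }
    if (s[1] < 0 || s[1] > config$extent[1] || s[2] < 0 || s[2] > config$extent[2]) {
      reason <- "left_field"; break
    }
    if (abs(a[1]) > config$motion_limit[1] || abs(a[2]) > config$motion_limit[2]) {
      reason <- "motion_limit"; break
    }
  }
  structure(list(termination_reason = reason,
                 intercept = reason == "intercept",
                 final_distance_deg = 100 * sqrt(sum(s^2)),
                 energy = energy,
                 duration = steps_done * config$dt,
                 agent_displacement = a,
                 trajectory = if (store_trajectory) traj[seq_len(steps_done), , drop = FALSE]),
            class = "sc_sim")
}

#' Reference agent speed for a configuration
#'
#' Measured as the mean agent speed over a short noiseless radial-approach
#' chase at the supplied \code{tau_m}; used to express target speeds as
#' relative speeds (target speed / agent reference speed). Agent speed
#' scales as \code{1 / tau_m}, so the value at any other \code{tau_m}
#' follows by rescaling.
#'
#' @param config an [sc_config()]
#' @return reference speed (normalized units / s).
#' @export
calibrate_agent_speed <- function(config) {
  cal <- config
  cal$sigma_noise <- 0
  cal$pathway <- "kinetic"
  cal$t_max <- 0.5
  cal$intercept_radius <- 0      # measure the chase itself, not its endpoint
  cal$motion_limit <- c(Inf, Inf)
  layout <- build_network(cal)
  centre <- cal$extent / 2
  s0 <- centre / sqrt(sum(centre^2)) * 0.6
  res <- run_simulation(cal, s0 = s0, velocity = -s0 / sqrt(sum(s0^2)) * 0.2,
                        layout = layout)
  if (res$duration <= 10 * cal$dt) stop("calibration run terminated too early")
  res$energy / res$duration
}

#' Sweep specification
#'
#' The model-comparison sweep crosses both pathways with
#' \code{n_speeds} relative speeds (evenly spaced over
#' \code{speed_range}), \code{n_starts} start positions on a ring and
#' \code{n_directions} movement directions spanning 360 degrees.
#'
#' @param pathways character vector of pathway names
#' @param n_speeds,speed_range relative-speed grid (default 40 values,
#'   0.15 to 6)
#' @param n_starts start positions on a ring about the field centre
#' @param n_directions target-motion directions spanning 360 deg
#' @param start_radius ring radius (normalized units)
#' @param target_speed fixed target speed (normalized units / s); relative
#'   speed is realized by adjusting \code{tau_m}
#' @return list of class \code{sweep_spec}.
#' @export
sweep_spec <- function(pathways = c("kinetic", "static"), n_speeds = 40,
                       speed_range = c(0.15, 6), n_starts = 10,
                       n_directions = 15, start_radius = 0.3,
                       target_speed = 0.3) {
  structure(list(pathways = pathways,
                 relative_speeds = seq(speed_range[1], speed_range[2],
                                       length.out = n_speeds),
                 n_starts = n_starts, n_directions = n_directions,
                 start_radius = start_radius, target_speed = target_speed),
            class = "sweep_spec")
}

#' Enumerate the runs of a sweep
#'
#' @param spec a [sweep_spec()]
#' @param config an [sc_config()] (supplies the field centre)
#' @return data.frame with one row per run: pathway, relative speed, start
#'   position and direction indices, start coordinates and velocity.
#' @export
enumerate_sweep <- function(spec, config = sc_config()) {
  centre <- config$extent / 2
  start_angles <- seq(0, 2 * pi, length.out = spec$n_starts + 1)[seq_len(spec$n_starts)]
  dir_angles <- seq(0, 2 * pi, length.out = spec$n_directions + 1)[seq_len(spec$n_directions)]
  g <- expand.grid(pathway = spec$pathways,
                   relative_speed = spec$relative_speeds,
                   start = seq_len(spec$n_starts),
                   direction = seq_len(spec$n_directions),
                   stringsAsFactors = FALSE)
  g$s0_nt <- centre[1] + spec$start_radius * cos(start_angles[g$start])
  g$s0_vd <- centre[2] + spec$start_radius * sin(start_angles[g$start])
  g$v_nt <- spec$target_speed * cos(dir_angles[g$direction])
  g$v_vd <- spec$target_speed * sin(dir_angles[g$direction])
  g
}

#' Execute a sweep
#'
#' Runs every enumerated simulation. Relative speed is realized by scaling
#' \code{tau_m}: the reference agent speed is calibrated once at the default
#' \code{tau_m} and scales as \code{1 / tau_m}.
#'
#' @param spec a [sweep_spec()]
#' @param config base [sc_config()]
#' @return the enumeration table with per-run \code{intercept},
#'   \code{energy}, \code{final_distance_deg}, \code{termination_reason} and
#'   the \code{tau_m} used.
#' @export
run_sweep <- function(spec, config = sc_config()) {
  runs <- enumerate_sweep(spec, config)
  v_ref0 <- calibrate_agent_speed(config)
  runs$tau_m <- config$tau_m * v_ref0 * runs$relative_speed / spec$target_speed
  runs$intercept <- NA
  runs$energy <- NA_real_
  runs$final_distance_deg <- NA_real_
  runs$termination_reason <- NA_character_
  layouts <- lapply(stats::setNames(nm = spec$pathways), function(p) {
    cfg <- config; cfg$pathway <- p; build_network(cfg)
  })
  for (i in seq_len(nrow(runs))) {
    cfg <- config
    cfg$pathway <- runs$pathway[i]
    cfg$tau_m <- runs$tau_m[i]
    res <- run_simulation(cfg, s0 = c(runs$s0_nt[i], runs$s0_vd[i]),
                          velocity = c(runs$v_nt[i], runs$v_vd[i]),
                          layout = layouts[[runs$pathway[i]]])
    runs$intercept[i] <- res$intercept
    runs$energy[i] <- res$energy
    runs$final_distance_deg[i] <- res$final_distance_deg
    runs$termination_reason[i] <- res$termination_reason
  }
  runs
}

#' Alignment-shift experiment
#'
#' Runs radially approaching targets (motion towards the agent) under the
#' kinetic pathway for each DS-to-motor alignment shift, by default 12
#' shifts at 30-degree steps. Anti-alignment corresponds to shift 0.
#'
#' @param config base [sc_config()] (pathway forced to kinetic)
#' @param shifts_deg shift grid (deg); default \code{seq(0, 330, by = 30)}
#' @param n_starts start positions on a ring
#' @param start_radius ring radius (normalized units)
#' @param target_speed approach speed (normalized units / s)
#' @return data.frame per shift: \code{shift_deg},
#'   \code{mean_final_distance_deg}, \code{intercept_rate},
#'   \code{mean_energy}.
#' @export
run_shift_experiment <- function(config = sc_config(sigma_noise = 0),
                                 shifts_deg = seq(0, 330, by = 30),
                                 n_starts = 5, start_radius = 0.55,
                                 target_speed = 0.3) {
  centre <- config$extent / 2
  start_angles <- seq(0, 2 * pi, length.out = n_starts + 1)[seq_len(n_starts)]
  rows <- lapply(shifts_deg, function(sh) {
    cfg <- config
    cfg$pathway <- "kinetic"
    cfg$alignment_shift <- sh * pi / 180
    layout <- build_network(cfg)
    res <- lapply(start_angles, function(a) {
      s0 <- centre + start_radius * c(cos(a), sin(a))
      s0 <- pmin(pmax(s0, 0.05), cfg$extent - 0.05)
      run_simulation(cfg, s0 = s0,
                     velocity = -s0 / sqrt(sum(s0^2)) * target_speed,
                     layout = layout)
    })
    data.frame(shift_deg = sh,
               mean_final_distance_deg = mean(vapply(res, `[[`, 0, "final_distance_deg")),
               intercept_rate = mean(vapply(res, `[[`, TRUE, "intercept")),
               mean_energy = mean(vapply(res, `[[`, 0, "energy")))
  })
  do.call(rbind, rows)
}
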