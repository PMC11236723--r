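#' Synthetic sessions with planted ground truth
#'
#' Generators emulating the statistical structure each analysis stage
#' assumes: 50 Hz Euler-angle foraging traces with stereotyped planted head
#' displacements, motor units whose spikes precede those displacements,
#' visual units with planted von Mises direction tuning or Gaussian ssRFs
#' responding to standard stimulus protocols, compensatory eye traces with
#' saccades, and whole anti-aligned visuo-motor populations. Every generator
#' is deterministic given the R random seed in force.
#'
#' @name synthgen
NULL

#' Standard stimulus schedules
#'
#' Builds the full randomized event list for one of the standard protocols:
#' \describe{
#' \item{gratings}{12 directions (30-deg steps) x 9 presentations; each
#'   presentation 1 s static, 2 s drifting, 1 s stop. Responses are scored
#'   on the 2 s drifting epoch.}
#' \item{squares}{flashing 750 ms black/white squares on a 15 x 11 grid
#'   (165 locations), both colours, 3 repeats each.}
#' \item{gabor}{moving Gabor patches at 24 locations (6 x 4) x 8 directions
#'   (45-deg steps) x 3 repeats = 576 presentations of 1.5 s.}
#' \item{spots}{a moving spot from 8 starting points (corners and edge
#'   midpoints), 3 per trial x 3 trials.}
#' \item{optotag}{30 bursts of 30 x 5 ms light pulses at 30 Hz with 9 s
#'   rests: 900 pulses over 300 s.}
#' }
#'
#' @param kind protocol name
#' @param isi inter-presentation gap (s) where the protocol does not fix one
#' @return data.frame of class \code{stim_schedule} with columns
#'   \code{onset}, \code{offset} and protocol-specific parameter columns.
#' @export
make_schedule <- function(kind = c("gratings", "squares", "gabor", "spots", "optotag"),
                          isi = 0.5) {
  kind <- match.arg(kind)
  ev <- switch(kind,
    gratings = {
      dirs <- rep(seq(0, 330, by = 30), times = 9)
      dirs <- sample(dirs)
      dur <- 4  # 1 s static + 2 s drift + 1 s stop
      onset <- seq_along(dirs) * (dur + isi) - dur
      data.frame(onset = onset + 1, offset = onset + 3, angle = dirs,
                 static_onset = onset, static_offset = onset + 1)
    },
    squares = {
      g <- expand.grid(x = 1:15, y = 1:11, colour = c("black", "white"),
                       rep = 1:3, stringsAsFactors = FALSE)
      g <- g[sample(nrow(g)), ]
      onset <- seq_len(nrow(g)) * (0.75 + isi) - 0.75
      data.frame(onset = onset, offset = onset + 0.75,
                 x = g$x, y = g$y, colour = g$colour)
    },
    gabor = {
      g <- expand.grid(x = 1:6, y = 1:4, angle = seq(0, 315, by = 45),
                       rep = 1:3)
      g <- g[sample(nrow(g)), ]
      onset <- seq_len(nrow(g)) * (1.5 + isi) - 1.5
      data.frame(onset = onset, offset = onset + 1.5,
                 x = g$x, y = g$y, angle = g$angle)
    },
    spots = {
      g <- expand.grid(start = 1:8, per_trial = 1:3, trial = 1:3)
      g <- g[order(g$trial, sample(nrow(g))), ]
      dur <- 2.5  # 1 s approach + 0.5 s static + 1 s retreat
      onset <- seq_len(nrow(g)) * (dur + isi) - dur
      data.frame(onset = onset, offset = onset + dur,
                 start = g$start, trial = g$trial)
    },
    optotag = {
      burst_start <- (0:29) * 10  # 1 s burst + 9 s rest, 30 bursts over 300 s
      pulse <- rep(burst_start, each = 30) + rep((0:29) / 30, times = 30)
      data.frame(onset = pulse, offset = pulse + 0.005,
                 burst = rep(1:30, each = 30), pulse = rep(1:30, times = 30))
    })
  attr(ev, "kind") <- kind
  class(ev) <- c("stim_schedule", "data.frame")
  ev
}

#' Smooth raised-cosine ramp used for planted head displacements
#' @keywords internal
smooth_ramp <- function(n) (1 - cos(pi * seq(0, 1, length.out = n))) / 2

#' Simulate a 50 Hz head-orientation trace
#'
#' Ornstein-Uhlenbeck wander per Euler axis plus optional planted
#' stereotyped displacements (smooth raised-cosine ramps whose net angular
#' change equals the planted amplitude exactly).
#'
#' @param duration trace length (s)
#' @param fs sampling rate (Hz, default 50)
#' @param ou_sd stationary s.d. of the wander (deg); default 10
#' @param ou_tau wander autocorrelation time (s); default 2
#' @param events optional data.frame with \code{time}, \code{axis}
#'   (\code{yaw/pitch/roll}), \code{amplitude} (deg), \code{duration} (s)
#' @return a [head_trace()]; planted events in \code{attr(, "events")}.
#' @export
simulate_head_trace <- function(duration, fs = 50, ou_sd = 10, ou_tau = 2,
                                events = NULL) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  ou <- function() {
    a <- exp(-1 / (fs * ou_tau))
    x <- numeric(n)
    innov <- stats::rnorm(n, 0, ou_sd * sqrt(1 - a^2))
    x[1] <- stats::rnorm(1, 0, ou_sd)
    for (i in 2:n) x[i] <- a * x[i - 1] + innov[i]
    x
  }
  ang <- list(yaw = ou(), pitch = ou(), roll = ou())
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      i0 <- round(events$time[i] * fs) + 1
      len <- max(2, round(events$duration[i] * fs))
      if (i0 + len - 1 > n) next
      ramp <- smooth_ramp(len) * events$amplitude[i]
      ax <- events$axis[i]
      seg <- i0:(i0 + len - 1)
      ang[[ax]][seg] <- ang[[ax]][seg] + ramp
      if (i0 + len <= n) ang[[ax]][(i0 + len):n] <- ang[[ax]][(i0 + len):n] + events$amplitude[i]
    }
  }
  out <- head_trace(t, ang$yaw, ang$pitch, ang$roll)
  attr(out, "events") <- events
  out
}

#' Simulate a motor unit: spikes preceding planted head displacements
#'
#' Inhomogeneous Poisson spiking with rate elevated in a window preceding
#' each planted displacement event, over a homogeneous baseline.
#'
#' @param duration trial length (s)
#' @param events planted displacement events (as in
#'   [simulate_head_trace()]); may be NULL for an untuned unit
#' @param baseline_rate baseline rate (Hz)
#' @param gain multiplicative rate elevation in the pre-movement window
#' @param lead_window window before movement onset with elevated rate (s),
#'   default c(0.3, 0.1) (0.3 to 0.1 s before onset)
#' @return sorted spike times (s).
#' @export
simulate_motor_unit <- function(duration, events = NULL, baseline_rate = 5,
                                gain = 8, lead_window = c(0.3, 0.1)) {
  dt <- 0.002
  n <- round(duration / dt)
  rate <- rep(baseline_rate, n)
  if (!is.null(events) && gain > 0) {
    for (tt in events$time) {
      i0 <- max(1, round((tt - lead_window[1]) / dt))
      i1 <- max(1, round((tt - lead_window[2]) / dt))
      if (i0 <= n) rate[i0:min(i1, n)] <- baseline_rate * (1 + gain)
    }
  }
  k <- stats::rpois(n, rate * dt)
  st <- rep((seq_len(n) - 1) * dt, k) + stats::runif(sum(k), 0, dt)
  sort(st[st < duration])
}

#' Simulate a visual unit's responses to a stimulus schedule
#'
#' Per-event Poisson spike counts with mean
#' \code{baseline_rate * duration * (1 + gain * tuning(event))}; the tuning
#' factor is a von Mises bump in direction space (DS), the sum of two
#' opposite lobes (OS), a 2D Gaussian over grid location (ssRF), or 1
#' (untuned). Spikes are placed uniformly within each event window; baseline
#' spiking fills the gaps.
#'
#' @param schedule a [make_schedule()] result (gratings/gabor for DS/OS,
#'   squares for ssRF)
#' @param kind \code{"DS"}, \code{"OS"}, \code{"ssRF"} or \code{"untuned"}
#' @param preferred_deg preferred direction (DS) or orientation (OS), deg
#' @param centre ssRF centre c(x, y) in grid cells
#' @param kappa von Mises concentration (default 2)
#' @param sigma ssRF width (cells, default 1.5)
#' @param gain peak response gain over baseline (default 3)
#' @param baseline_rate baseline rate (Hz, default 5)
#' @return sorted spike times (s) spanning the schedule.
#' @export
simulate_visual_unit <- function(schedule, kind = c("DS", "OS", "ssRF", "untuned"),
                                 preferred_deg = 0, centre = c(8, 6),
                                 kappa = 2, sigma = 1.5, gain = 3,
                                 baseline_rate = 5) {
  kind <- match.arg(kind)
  if (kind %in% c("DS", "OS") && is.null(schedule$angle)) {
    stop("invalid argument: DS/OS units need a schedule with an angle column")
  }
  if (kind == "ssRF" && is.null(schedule$x)) {
    stop("invalid argument: ssRF units need a gridded schedule")
  }
  tuning <- switch(kind,
    DS = {
      dth <- (schedule$angle - preferred_deg) * pi / 180
      exp(kappa * (cos(dth) - 1))
    },
    OS = {
      dth <- (schedule$angle - preferred_deg) * pi / 180
      (exp(kappa * (cos(dth) - 1)) + exp(kappa * (cos(dth + pi) - 1)))
    },
    ssRF = exp(-((schedule$x - centre[1])^2 + (schedule$y - centre[2])^2) / (2 * sigma^2)),
    untuned = rep(0, nrow(schedule)))
  dur <- schedule$offset - schedule$onset
  lambda <- baseline_rate * dur * (1 + gain * tuning)
  k <- stats::rpois(nrow(schedule), lambda)
  st <- rep(schedule$onset, k) + stats::runif(sum(k), 0, rep(dur, k))
  total <- max(schedule$offset) + 1
  covered <- sum(dur)
  n_base <- stats::rpois(1, baseline_rate * max(0, total - covered))
  gaps <- stats::runif(2 * n_base, 0, total)
  in_event <- vapply(gaps, function(g) any(g >= schedule$onset & g < schedule$offset), TRUE)
  st <- c(st, gaps[!in_event][seq_len(min(n_base, sum(!in_event)))])
  sort(st)
}

#' Simulate a compensatory eye-position trace with planted saccades
#'
#' Eye position counter-rotates against the head (yaw -> horizontal,
#' pitch -> vertical) with the given gain, plus brief planted saccades whose
#' peak angular speed exceeds the standard detection threshold, plus white
#' noise.
#'
#' @param head a [head_trace()]
#' @param gain compensatory gain in [0, 1.5]
#' @param saccade_times saccade onset times (s); NULL for none
#' @param saccade_amp_deg saccade amplitude (deg, default 8)
#' @param noise_sd measurement noise (deg, default 0)
#' @return data.frame with \code{t}, \code{x} (horizontal, deg), \code{y}
#'   (vertical, deg).
#' @export
simulate_eye_trace <- function(head, gain = 1, saccade_times = NULL,
                               saccade_amp_deg = 8, noise_sd = 0) {
  stopifnot(gain >= 0, gain <= 1.5)
  fs <- attr(head, "fs")
  x <- -gain * head$yaw
  y <- -gain * head$pitch
  if (!is.null(saccade_times)) {
    for (tt in saccade_times) {
      i0 <- round(tt * fs) + 1
      if (i0 + 1 > length(x)) next
      x[(i0 + 1):length(x)] <- x[(i0 + 1):length(x)] + saccade_amp_deg
    }
  }
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise_sd)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  data.frame(t = head$t, x = x, y = y)
}

#' Simulate an anti-aligned visuo-motor population
#'
#' For each unit: draw a planted head-displacement direction (mixture of yaw
#' and pitch amplitudes), synthesize a foraging head trace with those
#' planted movements and a motor unit spiking ahead of them; run the STA and
#' the geometric projection to obtain the unit's gaze direction on the
#' screen; set the planted grating preference to that gaze direction plus
#' 180 degrees plus von Mises jitter; and synthesize grating responses. The
#' per-unit ground truth is returned alongside the data.
#'
#' @param n_units population size (>= 5)
#' @param jitter_kappa von Mises concentration of the anti-alignment jitter
#'   (default 2); \code{Inf} for exact anti-alignment
#' @param geometry a [geometry_config()]
#' @param trace_duration per-unit foraging-trace length (s, default 120)
#' @param n_events planted movements per trace (default 40)
#' @param amplitude_deg planted displacement amplitude (deg, default 20)
#' @param grating_gain,grating_kappa,baseline_rate visual-response parameters
#' @return list of class \code{vm_population}: \code{units} (list with head
#'   trace, spike times, grating schedule/spikes), \code{ground_truth}
#'   (data.frame of planted directions and preferences).
#' @export
simulate_visuomotor_population <- function(n_units = 33, jitter_kappa = 2,
                                           geometry = geometry_config(),
                                           trace_duration = 120, n_events = 40,
                                           amplitude_deg = 20,
                                           grating_gain = 3, grating_kappa = 2,
                                           baseline_rate = 5) {
  stopifnot(n_units >= 5)
  units <- vector("list", n_units)
  gt <- data.frame(unit = seq_len(n_units), motor_dir_deg = NA_real_,
                   theta_gaze_deg = NA_real_, theta_gratings_deg = NA_real_)
  for (u in seq_len(n_units)) {
    motor_dir <- stats::runif(1, 0, 360)
    # yaw drives screen-horizontal, pitch screen-vertical gaze motion
    amp_yaw <- amplitude_deg * cos(motor_dir * pi / 180)
    amp_pitch <- amplitude_deg * sin(motor_dir * pi / 180)
    gap <- (trace_duration - 6) / n_events
    times <- seq(2, trace_duration - 4, length.out = n_events) +
      stats::runif(n_events, -min(0.5, gap / 6), min(0.5, gap / 6))  # aperiodic onsets
    # outward movement (spike-locked) plus a return sweep keeps the trace stationary
    ev <- rbind(
      data.frame(time = times, axis = "yaw", amplitude = amp_yaw, duration = 0.5),
      data.frame(time = times, axis = "pitch", amplitude = amp_pitch, duration = 0.5),
      data.frame(time = times + 1.5, axis = "yaw", amplitude = -amp_yaw, duration = 0.5),
      data.frame(time = times + 1.5, axis = "pitch", amplitude = -amp_pitch, duration = 0.5))
    head <- simulate_head_trace(trace_duration, ou_sd = 3, events = ev)
    spikes <- simulate_motor_unit(trace_duration, events = data.frame(time = times))
    sta <- compute_sta(spikes, head)
    path <- suppressWarnings(project_displacement_to_gaze_path(sta, geometry))
    theta_gaze <- gaze_preferred_direction(path)
    jit <- if (is.infinite(jitter_kappa)) 0 else
      rvonmises(1, 0, jitter_kappa) * 180 / pi
    theta_gratings <- wrap_angle(theta_gaze + 180 + jit, degrees = TRUE)
    sched <- make_schedule("gratings")
    vspikes <- simulate_visual_unit(sched, "DS", preferred_deg = theta_gratings,
                                    kappa = grating_kappa, gain = grating_gain,
                                    baseline_rate = baseline_rate)
    units[[u]] <- list(head = head, motor_spikes = spikes, sta = sta,
                       schedule = sched, visual_spikes = vspikes)
    gt$motor_dir_deg[u] <- motor_dir
    gt$theta_gaze_deg[u] <- theta_gaze
    gt$theta_gratings_deg[u] <- theta_gratings
  }
  structure(list(units = units, ground_truth = gt, geometry = geometry,
                 baseline_rate = baseline_rate),
            class = "vm_population")
}

#' Analyse a synthetic visuo-motor population end to end
#'
#' Recovers each unit's gaze direction (STA -> geometric projection ->
#' velocity-weighted direction) and grating preference (per-angle responses
#' -> selectivity), forms the per-unit alignment offsets, and summarizes the
#' population.
#'
#' @param pop a [simulate_visuomotor_population()] result
#' @param n_boot bootstrap replicates for the population summary
#' @return list: \code{deltas_deg}, \code{population}
#'   (a \code{population_alignment}), \code{ww} (Watson-Williams table),
#'   \code{per_unit} (data.frame).
#' @export
analyze_vm_population <- function(pop, n_boot = 1000) {
  n <- length(pop$units)
  per <- data.frame(unit = seq_len(n), theta_gaze = NA_real_,
                    theta_gratings = NA_real_, delta = NA_real_)
  for (u in seq_len(n)) {
    unit <- pop$units[[u]]
    path <- suppressWarnings(project_displacement_to_gaze_path(unit$sta, pop$geometry))
    tg <- gaze_preferred_direction(path)
    gr <- grating_responses(unit$visual_spikes, unit$schedule, pop$baseline_rate)
    sel <- selectivity(gr$mean_response, gr$angles, "direction")
    per$theta_gaze[u] <- tg
    per$theta_gratings[u] <- sel$preferred_deg
    per$delta[u] <- alignment_offset(tg, sel$preferred_deg)
  }
  popstats <- population_stats(per$delta, n_boot = n_boot)
  ww <- watson_williams_vs_controls(per$delta)
  list(deltas_deg = per$delta, population = popstats, ww = ww, per_unit = per)
}
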