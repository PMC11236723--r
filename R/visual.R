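#' Visual selectivity, tuning classification and receptive-field mapping
#'
#' Direction/orientation selectivity is the modulus of the response-weighted
#' circular vector sum over the probed angles; the preferred angle is its
#' argument. Tuning decisions combine the selectivity index, the
#' trial-to-trial angular deviation of preferred angles, and the rank of the
#' index within a circular-shift shuffled null. Static spatial receptive
#' fields (ssRFs) are mapped from flashing-square responses via z-scored
#' response matrices and a 2D Gaussian fit.
#'
#' @name visual
NULL

#' Selectivity index and preferred angle
#'
#' \code{SI = |sum_k R(theta_k) e^(i m theta_k) / sum_k R(theta_k)|} with
#' \code{m = 1} in direction space (angles span 360 deg, typically 12) and
#' \code{m = 2} in orientation space (180 deg, typically 6 distinct
#' orientations). Negative baseline-normalized responses are clipped to zero
#' before the vector sum. The preferred angle is the quadrant-corrected
#' argument of the sum, mapped back to the half-period for orientation.
#'
#' @param responses mean responses \code{R(theta_k)} (baseline-normalized
#'   firing rates), length K
#' @param angles_deg probed angles (deg), length K
#' @param space \code{"direction"} or \code{"orientation"}
#' @return list with \code{si} in [0, 1], \code{preferred_deg} in [0, 360)
#'   (direction) or [0, 180) (orientation), and \code{space}.
#' @export
selectivity <- function(responses, angles_deg, space = c("direction", "orientation")) {
  space <- match.arg(space)
  stopifnot(length(responses) == length(angles_deg))
  r <- pmax(responses, 0)
  if (sum(r) <= 0) stop("undefined selectivity: all responses zero")
  m <- if (space == "direction") 1 else 2
  th <- angles_deg * pi / 180
  z <- sum(r * exp(1i * m * th)) / sum(r)
  pref <- wrap_angle(Arg(z) / m, degrees = FALSE) * 180 / pi
  pref <- pref %% (360 / m)
  list(si = Mod(z), preferred_deg = pref, space = space)
}

#' Mean per-angle responses from spikes and a grating schedule
#'
#' Counts spikes during each presentation's moving epoch, converts to rate,
#' and normalizes to the baseline rate.
#'
#' @param spike_times spike times (s)
#' @param events data.frame with columns \code{onset}, \code{offset},
#'   \code{angle} (deg)
#' @param baseline_rate baseline firing rate (Hz)
#' @return list: \code{angles} (sorted unique angles), \code{mean_response}
#'   (baseline-normalized), \code{per_presentation} (presentations x 1 with
#'   angle column: data.frame angle, response).
#' @export
grating_responses <- function(spike_times, events, baseline_rate) {
  counts <- event_spike_counts(spike_times, events$onset, events$offset)
  rate <- counts / (events$offset - events$onset)
  resp <- rate / baseline_rate
  ang <- sort(unique(events$angle))
  mean_resp <- vapply(ang, function(a) mean(resp[events$angle == a]), 0)
  list(angles = ang, mean_response = mean_resp,
       per_presentation = data.frame(angle = events$angle, response = resp))
}

#' Count spikes in each [onset, offset) window (sorted spike times)
#' @keywords internal
event_spike_counts <- function(spike_times, onset, offset) {
  findInterval(offset, spike_times) - findInterval(onset, spike_times)
}

#' Classify visual tuning from per-trial responses and shuffled nulls
#'
#' Three criteria per space: selectivity index at least \code{si_threshold};
#' trial-to-trial angular deviation of per-trial preferred angles at most
#' \code{deviation_threshold} (rad); null rank of the index above
#' \code{rank_threshold}. A unit is tuned in a space when at least two of the
#' three hold. When tuned, the unit is DS if the direction-space index
#' exceeds the orientation-space index, OS otherwise.
#'
#' @param trial_responses trials x angles matrix of baseline-normalized
#'   responses (rows = trials, >= 3 for the deviation criterion)
#' @param angles_deg probed angles (deg)
#' @param null_dsi,null_osi shuffled index samples for the two spaces
#' @param si_threshold,deviation_threshold,rank_threshold criteria (defaults
#'   0.1, 0.8 rad, 0.95)
#' @return list with \code{tuned}, \code{class} (DS/OS/untuned), per-space
#'   selectivity and criteria.
#' @export
classify_visual_tuning <- function(trial_responses, angles_deg, null_dsi, null_osi,
                                   si_threshold = 0.1, deviation_threshold = 0.8,
                                   rank_threshold = 0.95) {
  if (!is.matrix(trial_responses) || nrow(trial_responses) < 2) {
    stop("insufficient replication: need >= 2 trials of per-angle responses")
  }
  mean_resp <- colMeans(trial_responses)
  eval_space <- function(space, null_si) {
    sel <- selectivity(mean_resp, angles_deg, space)
    m <- if (space == "direction") 1 else 2
    prefs <- apply(trial_responses, 1, function(r) {
      tryCatch(selectivity(r, angles_deg, space)$preferred_deg, error = function(e) NA_real_)
    })
    prefs <- prefs[is.finite(prefs)]
    dev <- if (length(prefs) >= 2) {
      circ_angular_deviation(prefs * m * pi / 180) / m
    } else Inf
    rank <- null_rank(sel$si, null_si)
    crit <- c(si = sel$si >= si_threshold,
              deviation = dev <= deviation_threshold,
              rank = rank > rank_threshold)
    list(si = sel$si, preferred_deg = sel$preferred_deg,
         angular_deviation = dev, null_rank = rank,
         criteria = crit, tuned = sum(crit) >= 2)
  }
  dir <- eval_space("direction", null_dsi)
  ori <- eval_space("orientation", null_osi)
  tuned <- dir$tuned || ori$tuned
  cls <- if (!tuned) "untuned" else if (dir$si > ori$si) "DS" else "OS"
  list(tuned = tuned, class = cls, direction = dir, orientation = ori)
}

#' Map a static spatial receptive field from flashing-square responses
#'
#' Per grid location, the firing rate during flashes is divided by the
#' baseline rate; the location x response matrix is z-scored. The map is
#' significant when its maximal z exceeds \code{z_threshold} and ranks above
#' \code{rank_threshold} among maxima of circularly shuffled spike trains.
#' Significant maps get a least-squares elliptical 2D Gaussian fit (widths
#' bounded below at 0.5 cell, initialized at the argmax cell); if the fit
#' fails to converge the argmax cell is reported as centre with
#' \code{fitted = FALSE}.
#'
#' @param spike_times spike times (s)
#' @param events data.frame with \code{onset}, \code{offset}, \code{x},
#'   \code{y} (1-based grid indices) for one square colour
#' @param baseline_rate baseline firing rate (Hz)
#' @param duration trial duration (s) for the shuffled null
#' @param grid_dim c(nx, ny); default c(15, 11)
#' @param n_shuffles null replicates (default 1000)
#' @param z_threshold,rank_threshold significance criteria
#' @return list of class \code{rf_map}: \code{z} (nx x ny matrix),
#'   \code{significant}, \code{centre} (x, y; fitted Gaussian centre or
#'   argmax), \code{fitted}, \code{fit} (parameters when fitted),
#'   \code{max_z}, \code{null_rank}.
#' @export
map_ssrf <- function(spike_times, events, baseline_rate, duration,
                     grid_dim = c(15, 11), n_shuffles = 1000,
                     z_threshold = 2, rank_threshold = 0.95) {
  zmat <- function(st) {
    counts <- event_spike_counts(st, events$onset, events$offset)
    resp <- counts / (events$offset - events$onset) / baseline_rate
    m <- matrix(0, grid_dim[1], grid_dim[2])
    cnt <- matrix(0, grid_dim[1], grid_dim[2])
    for (i in seq_along(resp)) {
      m[events$x[i], events$y[i]] <- m[events$x[i], events$y[i]] + resp[i]
      cnt[events$x[i], events$y[i]] <- cnt[events$x[i], events$y[i]] + 1
    }
    m <- m / pmax(cnt, 1)
    (m - mean(m)) / stats::sd(m)
  }
  z <- zmat(sort(spike_times))
  max_z <- max(z)
  null <- shuffle_null(spike_times, duration, function(st) max(zmat(st)),
                       n = n_shuffles)
  rank <- null_rank(max_z, unlist(null$samples))
  significant <- is.finite(max_z) && max_z > z_threshold && rank > rank_threshold
  centre <- as.numeric(which(z == max_z, arr.ind = TRUE)[1, ])
  fitted <- FALSE; fit <- NULL
  if (significant) {
    g <- fit_gaussian2d(z, init_centre = centre)
    if (!is.null(g)) { fitted <- TRUE; fit <- g; centre <- c(g$x0, g$y0) }
  }
  structure(list(z = z, significant = significant, centre = centre,
                 fitted = fitted, fit = fit, max_z = max_z, null_rank = rank),
            class = "rf_map")
}

#' Elliptical 2D Gaussian least-squares fit to a matrix
#' @keywords internal
fit_gaussian2d <- function(z, init_centre) {
  nx <- nrow(z); ny <- ncol(z)
  gx <- rep(seq_len(nx), ny); gy <- rep(seq_len(ny), each = nx)
  zz <- as.vector(z)
  resid_fun <- function(p) {
    mu <- p[1] * exp(-((gx - p[2])^2 / (2 * p[4]^2) + (gy - p[3])^2 / (2 * p[5]^2))) + p[6]
    mu - zz
  }
  start <- c(A = max(z) - stats::median(z), x0 = init_centre[1], y0 = init_centre[2],
             sx = 1.5, sy = 1.5, off = stats::median(z))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       lower = c(0, 0.5, 0.5, 0.5, 0.5, -Inf),
                       upper = c(Inf, nx + 0.5, ny + 0.5, nx, ny, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5, 9)) return(NULL)
  p <- stats::coef(fit)
  list(amplitude = p[["A"]], x0 = p[["x0"]], y0 = p[["y0"]],
       sigma_x = p[["sx"]], sigma_y = p[["sy"]], offset = p[["off"]])
}

#' Partition stimulus presentations into run and rest trials
#'
#' The wheel angular-velocity trace is low-pass filtered (2nd-order
#' Butterworth, 1 Hz) and averaged over each presentation window; trials
#' whose mean speed exceeds the threshold are labelled run.
#'
#' @param wheel data.frame with \code{t} (s) and \code{v} (deg/s)
#' @param presentations data.frame with \code{onset}, \code{offset} (s)
#' @param threshold run criterion (deg/s); default 20
#' @param cutoff_hz low-pass cutoff; default 1
#' @return logical vector, TRUE = run trial; mean speeds in
#'   \code{attr(, "mean_speed")}.
#' @export
split_by_running <- function(wheel, presentations, threshold = 20, cutoff_hz = 1) {
  fs <- 1 / mean(diff(wheel$t))
  if (min(presentations$onset) < min(wheel$t) - 1e-9 ||
      max(presentations$offset) > max(wheel$t) + 1e-9) {
    stop("invalid input: wheel trace does not cover every presentation window")
  }
  v <- wheel$v
  if (cutoff_hz < fs / 2) {
    bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
    v <- as.numeric(signal::filtfilt(bf, v))
  }
  ms <- mapply(function(a, b) mean(v[wheel$t >= a & wheel$t < b]),
               presentations$onset, presentations$offset)
  out <- ms > threshold
  attr(out, "mean_speed") <- ms
  out
}
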