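#' Spike and kinematic containers
#'
#' `spike_train` holds sorted spike times for one unit across named trials;
#' `head_trace` is a uniformly sampled (nominally 50 Hz) Euler-angle series
#' in degrees. Motion tuning is quantified by spike-triggered averages (STAs)
#' of head displacement: around each spike the angular trajectory is zeroed
#' at spike onset and averaged over spikes, per Euler axis.
#'
#' @name sta
NULL

#' Construct a spike train for one unit
#'
#' @param unit_id identifier
#' @param trials named list of numeric spike-time vectors (s), each sorted
#'   strictly increasing, non-negative
#' @param durations named numeric vector of trial durations (s)
#' @return object of class \code{spike_train}.
#' @export
spike_train <- function(unit_id, trials, durations) {
  stopifnot(is.list(trials), all(names(trials) %in% names(durations)))
  for (nm in names(trials)) {
    tt <- trials[[nm]]
    if (length(tt)) {
      if (any(!is.finite(tt)) || any(tt < 0) || any(diff(tt) <= 0) ||
          max(tt) > durations[[nm]]) {
        stop(sprintf("invalid spike times in trial '%s': must be sorted, non-negative, within duration", nm))
      }
    }
  }
  structure(list(unit_id = unit_id, trials = trials,
                 durations = durations[names(trials)]),
            class = "spike_train")
}

#' Construct a head-orientation trace
#'
#' @param t sample times (s), uniform grid
#' @param yaw,pitch,roll Euler angles (deg)
#' @return data.frame of class \code{head_trace}; sampling rate in
#'   \code{attr(, "fs")}.
#' @export
head_trace <- function(t, yaw, pitch, roll) {
  stopifnot(length(t) == length(yaw), length(t) == length(pitch),
            length(t) == length(roll), length(t) >= 2)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6) stop("head trace must be uniformly sampled")
  out <- data.frame(t = t, yaw = yaw, pitch = pitch, roll = roll)
  attr(out, "fs") <- 1 / dt[1]
  class(out) <- c("head_trace", "data.frame")
  out
}

#' Spike-triggered average of angular displacement
#'
#' For each spike with a complete window of \code{pre_bins} samples before
#' and \code{post_bins} after, the angle on each axis is zeroed at spike
#' onset (equivalently, the per-bin angular velocities are cumulatively
#' summed from the spike) and averaged over spikes. Defaults give a 0.5 s
#' pre / 1 s post window at 50 Hz.
#'
#' @param spike_times numeric vector of spike times (s) on the trace clock
#' @param trace a \code{head_trace}, or any data.frame with a \code{t} column
#'   and one angular column (deg) per axis
#' @param pre_bins,post_bins window half-lengths in samples
#' @return object of class \code{sta_result}: \code{time} (s, relative to the
#'   spike), \code{displacement} and \code{sem} (bins x axes, deg),
#'   \code{n_spikes}.
#' @export
compute_sta <- function(spike_times, trace, pre_bins = 25, post_bins = 50) {
  axes <- setdiff(names(trace), "t")
  fs <- attr(trace, "fs")
  if (is.null(fs)) fs <- 1 / mean(diff(trace$t))
  n <- nrow(trace)
  idx <- round((spike_times - trace$t[1]) * fs) + 1L
  idx <- idx[idx - pre_bins >= 1L & idx + post_bins <= n]
  if (length(idx) == 0) stop("empty result: no spike has a full pre/post window inside the trace")
  offs <- seq(-pre_bins, post_bins)
  win <- outer(idx, offs, `+`)
  disp <- matrix(0, length(offs), length(axes), dimnames = list(NULL, axes))
  sem <- disp
  for (ax in axes) {
    a <- trace[[ax]]
    m <- matrix(a[win], nrow = length(idx)) - a[idx]
    disp[, ax] <- colMeans(m)
    sem[, ax] <- apply(m, 2, stats::sd) / sqrt(length(idx))
  }
  structure(list(time = offs / fs, displacement = disp, sem = sem,
                 n_spikes = length(idx), pre_bins = pre_bins, post_bins = post_bins),
            class = "sta_result")
}

#' Signed displacement vector of an STA curve
#'
#' Magnitude is max minus min of the curve; the sign is positive when the
#' minimum precedes the maximum in time, negative otherwise.
#'
#' @param curve numeric vector of per-bin displacements (deg)
#' @return signed displacement (deg).
#' @export
displacement_vector <- function(curve) {
  stopifnot(length(curve) >= 1)
  mag <- max(curve) - min(curve)
  s <- if (which.min(curve) <= which.max(curve)) 1 else -1
  s * mag
}

#' Per-axis signed displacement vectors of an STA
#' @param sta an \code{sta_result}
#' @return named numeric vector, one signed displacement per axis (deg).
#' @export
sta_displacement_vectors <- function(sta) {
  vapply(colnames(sta$displacement),
         function(ax) displacement_vector(sta$displacement[, ax]), 0)
}

#' Circular-shift shuffled null for any spike-train statistic
#'
#' Each replicate shifts all spike times by a uniform draw from
#' [\code{min_shift}, min(\code{max_shift}, duration - \code{min_shift})] s,
#' wrapping around the trial end. The shift preserves spike count and the
#' circular inter-spike-interval multiset while destroying the relation to
#' the concurrent behaviour/stimulus.
#'
#' @param spike_times spike times (s), sorted
#' @param duration trial duration (s)
#' @param statistic function of a (sorted) spike-time vector
#' @param n number of replicates
#' @param min_shift,max_shift shift range (s)
#' @return list with \code{samples} (list or simplified vector/matrix of
#'   statistic values) and \code{shifts}.
#' @export
shuffle_null <- function(spike_times, duration, statistic, n = 1000,
                         min_shift = 2, max_shift = 180) {
  hi <- min(max_shift, duration - min_shift)
  if (duration < 2 * min_shift || hi <= min_shift) {
    stop("configuration error: trial too short for the requested shift range")
  }
  shifts <- stats::runif(n, min_shift, hi)
  samples <- lapply(shifts, function(s) statistic(sort((spike_times + s) %% duration)))
  simp <- tryCatch(simplify2array(samples), error = function(e) samples)
  list(samples = simp, shifts = shifts, n = n)
}

#' Rank of an observed statistic within its shuffled null
#' @param observed scalar statistic
#' @param null numeric vector of shuffled statistics
#' @return fraction of null values strictly below \code{observed}.
#' @export
null_rank <- function(observed, null) mean(null < observed)

#' Classify motion tuning from light/dark foraging trials
#'
#' A unit is tuned in a condition (light or dark) if at least one Euler axis
#' has a displacement-vector magnitude above \code{threshold_deg} with the
#' same sign in both trials of the condition, and the magnitude ranks above
#' the \code{rank_threshold} quantile of the shuffled null in both trials.
#' A motor unit is one tuned in both light and dark.
#'
#' @param stas named list of \code{sta_result}s for trials
#'   \code{light1, light2, dark1, dark2}
#' @param nulls named list (same trial names) of n_shuffles x axes matrices of
#'   signed shuffled displacement vectors
#' @param threshold_deg displacement threshold (deg); default 5
#' @param rank_threshold null-rank criterion; default 0.95
#' @return list with \code{light}, \code{dark} (logical), \code{class} in
#'   \code{both/light/dark/none}, and per-axis detail.
#' @export
classify_motion_tuning <- function(stas, nulls, threshold_deg = 5,
                                   rank_threshold = 0.95) {
  need <- c("light1", "light2", "dark1", "dark2")
  if (!all(need %in% names(stas)) || !all(need %in% names(nulls))) {
    stop("invalid input: need STAs and nulls for trials ", paste(need, collapse = ", "))
  }
  vecs <- lapply(stas[need], sta_displacement_vectors)
  axes <- names(vecs[[1]])
  axis_pass <- function(trials) {
    vapply(axes, function(ax) {
      v <- vapply(trials, function(tr) vecs[[tr]][ax], 0)
      ranks <- vapply(trials, function(tr) {
        null_rank(abs(vecs[[tr]][ax]), abs(nulls[[tr]][, ax]))
      }, 0)
      all(abs(v) > threshold_deg) && length(unique(sign(v))) == 1 &&
        all(ranks > rank_threshold)
    }, logical(1))
  }
  light_ax <- axis_pass(c("light1", "light2"))
  dark_ax <- axis_pass(c("dark1", "dark2"))
  light <- any(light_ax); dark <- any(dark_ax)
  cls <- if (light && dark) "both" else if (light) "light" else if (dark) "dark" else "none"
  list(light = light, dark = dark, class = cls,
       light_axes = light_ax, dark_axes = dark_ax,
       displacement_vectors = vecs)
}

#' STA-based eye-movement tuning
#'
#' Pupil displacements (length units) are converted to angular amplitude via
#' \code{alpha = atan(d / r)} with \code{r} the eye radius, then passed
#' through the same STA machinery as head displacements. A unit is tuned if
#' at least one component's displacement vector exceeds 1 degree with null
#' rank above 0.95.
#'
#' @param spike_times spike times (s)
#' @param pupil data.frame with columns \code{t}, \code{x}, \code{y}
#'   (pupil-centre position, length units)
#' @param eye_radius eye radius in the same length units
#' @param duration trial duration (s) for the shuffled null
#' @param n_shuffles null replicates
#' @param threshold_deg displacement criterion (deg); default 1
#' @return list with \code{tuned}, per-axis \code{vectors} (deg) and
#'   \code{ranks}, and the \code{sta}.
#' @export
eye_movement_tuning <- function(spike_times, pupil, eye_radius, duration,
                                n_shuffles = 1000, threshold_deg = 1) {
  ang <- data.frame(t = pupil$t,
                    x = atan(pupil$x / eye_radius) * 180 / pi,
                    y = atan(pupil$y / eye_radius) * 180 / pi)
  attr(ang, "fs") <- 1 / mean(diff(pupil$t))
  sta <- compute_sta(spike_times, ang)
  v <- sta_displacement_vectors(sta)
  null <- shuffle_null(spike_times, duration, function(st) {
    abs(sta_displacement_vectors(compute_sta(st, ang)))
  }, n = n_shuffles)
  nm <- t(null$samples)
  ranks <- vapply(names(v), function(ax) null_rank(abs(v[ax]), nm[, ax]), 0)
  list(tuned = any(abs(v) > threshold_deg & ranks > 0.95),
       vectors = v, ranks = ranks, sta = sta)
}

#' Detect binocular saccades from pupil angular-velocity traces
#'
#' A saccade is flagged where both eyes' angular speed exceeds the threshold
#' in the same sample; runs of consecutive suprathreshold samples are merged
#' into single events.
#'
#' @param t sample times (s)
#' @param v_left,v_right angular-speed traces (deg/s), same length as \code{t}
#' @param threshold speed criterion (deg/s); default 350
#' @return numeric vector of event onset times (s).
#' @export
detect_saccades <- function(t, v_left, v_right, threshold = 350) {
  hit <- abs(v_left) > threshold & abs(v_right) > threshold
  if (!any(hit)) return(numeric(0))
  starts <- which(hit & !c(FALSE, hit[-length(hit)]))
  t[starts]
}
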