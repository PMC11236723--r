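# Shared fixtures built in code.

# Minimal sta_result with given per-axis displacement curves (deg) on the
# standard 25-pre / 50-post 50 Hz window, zeroed at the spike bin.
make_sta <- function(yaw = NULL, pitch = NULL, roll = NULL, n = 76, fs = 50) {
  fill <- function(x) if (is.null(x)) rep(0, n) else x
  curves <- cbind(yaw = fill(yaw), pitch = fill(pitch), roll = fill(roll))
  i0 <- 26
  curves <- sweep(curves, 2, curves[i0, ])
  structure(list(time = seq(-25, n - 26) / fs, displacement = curves,
                 sem = curves * 0, n_spikes = 1L, pre_bins = 25, post_bins = n - 26),
            class = "sta_result")
}

# Ramp curve: 0 until the spike bin, then smooth rise to `amp` over the post window.
ramp_curve <- function(amp, n = 76, i0 = 26) {
  c(rep(0, i0), amp * seq(0, 1, length.out = n - i0))
}

# Split a grating schedule's presentations into k pseudo-trials per angle.
trial_responses <- function(spikes, sched, baseline_rate, k = 3) {
  reps <- ave(seq_len(nrow(sched)), sched$angle,
              FUN = function(i) rep_len(rep(seq_len(k), each = ceiling(length(i) / k)), length(i)))
  t(sapply(seq_len(k), function(j) {
    grating_responses(spikes, sched[reps == j, ], baseline_rate)$mean_response
  }))
}

# Statistic closure: direction/orientation SIs of a spike train vs a schedule.
si_stat <- function(sched, baseline_rate) {
  function(st) {
    gr <- grating_responses(st, sched, baseline_rate)
    c(dsi = selectivity(gr$mean_response, gr$angles, "direction")$si,
      osi = selectivity(gr$mean_response, gr$angles, "orientation")$si)
  }
}

# Random rotation matrix from uniform Euler angles away from gimbal lock.
random_rotation <- function() {
  rotation_from_euler(stats::runif(1, -3, 3), stats::runif(1, -1.4, 1.4),
                      stats::runif(1, -3, 3))
}
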