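#' Intracellular response-latency estimators
#'
#' Two latency rules for whole-cell recordings: light-evoked EPSP latency via
#' a linear fit through the 25-30% and 70-75% amplitude bands of the rising
#' slope, and visual-onset latency as the first membrane-potential slope
#' exceeding both 3 s.d. of baseline derivative noise and 0.5 mV/ms.
#'
#' @name latency
NULL

#' EPSP latency from the rising-slope linear fit
#'
#' Finds the (first) EPSP peak after stimulus onset, takes the rising phase
#' up to the first crossing of 75% of peak amplitude, fits a line through the
#' samples whose amplitude lies in the 25-30% and 70-75% bands, and returns
#' the time at which that line crosses the resting potential, minus stimulus
#' onset.
#'
#' @param t time (s)
#' @param v membrane potential (mV)
#' @param stim_onset stimulus onset time (s)
#' @param noise_floor minimal peak amplitude (mV) to accept a response;
#'   default 5 x s.d. of the pre-onset baseline
#' @return latency in ms, or \code{NA} (with attribute \code{reason =
#'   "no_response"}) when the peak is below the noise floor.
#' @export
epsp_latency <- function(t, v, stim_onset, noise_floor = NULL) {
  pre <- t < stim_onset
  if (!any(pre)) stop("need baseline samples before stimulus onset")
  rest <- mean(v[pre])
  if (is.null(noise_floor)) noise_floor <- 5 * stats::sd(v[pre])
  post <- which(t >= stim_onset)
  vp <- v[post] - rest
  pk <- which.max(vp)
  amp <- vp[pk]
  if (!is.finite(amp) || amp <= max(noise_floor, 0)) {
    return(structure(NA_real_, reason = "no_response"))
  }
  frac <- vp / amp
  i75 <- which(frac >= 0.75)[1]
  rise <- seq_len(if (is.na(i75)) pk else i75)
  band <- rise[(frac[rise] >= 0.25 & frac[rise] <= 0.30) |
               (frac[rise] >= 0.70 & frac[rise] <= 0.75)]
  if (length(band) < 2) {
    # sparse sampling: interpolate the two band mid-crossings instead
    f_lo <- 0.275; f_hi <- 0.725
    t_at <- function(f) {
      i <- which(frac[rise] >= f)[1]
      if (is.na(i) || i == 1) return(NA_real_)
      ii <- rise[c(i - 1, i)]
      stats::approx(frac[ii], t[post][ii], xout = f)$y
    }
    t1 <- t_at(f_lo); t2 <- t_at(f_hi)
    if (!is.finite(t1) || !is.finite(t2)) return(structure(NA_real_, reason = "no_response"))
    slope <- amp * (f_hi - f_lo) / (t2 - t1)
    t_cross <- t1 - f_lo * amp / slope
  } else {
    fit <- stats::lm(y ~ x, data = data.frame(x = t[post][band], y = vp[band]))
    co <- stats::coef(fit)
    t_cross <- -co[[1]] / co[[2]]
  }
  (t_cross - stim_onset) * 1000
}

#' Visual-response onset latency from the membrane-potential derivative
#'
#' The derivative (mV/ms) is computed over the whole trace; its s.d. during
#' the baseline window sets the event threshold at
#' \code{max(3 x s.d., 0.5)} mV/ms. The latency is the first post-onset time
#' the derivative exceeds that threshold. Recordings whose baseline membrane
#' potential s.d. exceeds \code{reject_sd_mv} are rejected outright.
#'
#' @param t time (s)
#' @param v membrane potential (mV)
#' @param baseline_window c(start, end) in s (grey-screen epoch)
#' @param stim_onset stimulus onset (s)
#' @param min_slope slope floor (mV/ms); default 0.5
#' @param reject_sd_mv baseline-potential rejection threshold (mV); default 1.5
#' @return latency in ms, \code{NA} with \code{reason = "no_event"} if no
#'   suprathreshold slope occurs.
#' @export
visual_onset_latency <- function(t, v, baseline_window, stim_onset,
                                 min_slope = 0.5, reject_sd_mv = 1.5) {
  base <- t >= baseline_window[1] & t < baseline_window[2]
  if (sum(base) < 3) stop("baseline window contains too few samples")
  if (stats::sd(v[base]) > reject_sd_mv) {
    stop("recording rejected: baseline s.d. exceeds ", reject_sd_mv, " mV")
  }
  dv <- diff(v) / (diff(t) * 1000)  # mV per ms
  tb <- t[-1]
  thr <- max(3 * stats::sd(dv[base[-1]]), min_slope)
  hit <- which(tb >= stim_onset & dv > thr)
  if (length(hit) == 0) return(structure(NA_real_, reason = "no_event"))
  (tb[hit[1]] - stim_onset) * 1000
}
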