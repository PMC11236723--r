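test_that("spike_train validates ordering, sign and duration", {
  expect_s3_class(spike_train("u1", list(a = c(0.5, 1, 2)), c(a = 10)), "spike_train")
  expect_error(spike_train("u1", list(a = c(1, 0.5)), c(a = 10)), "sorted")
  expect_error(spike_train("u1", list(a = c(-1, 2)), c(a = 10)))
  expect_error(spike_train("u1", list(a = c(1, 11)), c(a = 10)))
})

test_that("STA recovers planted displacements, zeroes at the spike, and averages noise away", {
  set.seed(101)
  # spikes at onsets of identical planted yaw ramps
  times <- seq(5, 594, length.out = 400)
  ev <- data.frame(time = times, axis = "yaw", amplitude = 20, duration = 0.5)
  h <- simulate_head_trace(600, ou_sd = 1, events = ev)
  sta <- compute_sta(times, h)
  v <- sta_displacement_vectors(sta)
  expect_equal(unname(v["yaw"]), 20, tolerance = 2)
  expect_lt(abs(v["pitch"]), 2)
  expect_lt(abs(v["roll"]), 2)
  expect_equal(unname(sta$displacement[26, ]), c(0, 0, 0))
  expect_equal(sta$n_spikes, 400L)

  # spikes independent of the wander: displacement vectors shrink to ~0
  set.seed(102)
  h2 <- simulate_head_trace(600, ou_sd = 3)
  sp <- sort(runif(10000, 1, 599))
  v2 <- sta_displacement_vectors(compute_sta(sp, h2))
  expect_lt(max(abs(v2)), 1)

  # constant orientation: all-zero curves
  hc <- head_trace(seq(0, 10, by = 0.02), rep(1, 501), rep(2, 501), rep(3, 501))
  expect_equal(max(abs(compute_sta(c(2, 5, 8), hc)$displacement)), 0)
  expect_error(compute_sta(numeric(0), hc), "empty")
  expect_error(compute_sta(0.1, hc), "empty")
})

test_that("displacement vector signs follow the temporal order of extrema", {
  expect_equal(displacement_vector(seq(0, 20, length.out = 50)), 20)
  expect_equal(displacement_vector(seq(0, -20, length.out = 50)), -20)
  curve <- c(rep(0, 9), -5, rep(0, 49), 15, rep(0, 16))
  expect_equal(displacement_vector(curve), 20)
  expect_equal(displacement_vector(rev(curve)), -20)
})

test_that("circular shuffling preserves spike count and circular ISIs, and shifts are bounded", {
  set.seed(55)
  st <- sort(runif(200, 0, 300))
  nul <- shuffle_null(st, 300, function(x) length(x), n = 50)
  expect_true(all(unlist(nul$samples) == 200))
  expect_true(all(nul$shifts >= 2 & nul$shifts <= 180))
  circ_isi <- function(x, dur) sort(diff(c(x, x[1] + dur)))
  nul2 <- shuffle_null(st, 300, function(x) circ_isi(x, 300), n = 5)
  for (i in 1:5) expect_equal(sort(nul2$samples[, i]), circ_isi(st, 300), tolerance = 1e-9)
  expect_error(shuffle_null(st, 3, length, n = 5), "configuration")
})

test_that("motion-tuning classification separates planted motor, visual-only and untuned units", {
  set.seed(77)
  gen_trial <- function(tuned) {
    times <- seq(5, 295, by = 3) + runif(97, -0.5, 0.5)  # aperiodic movement onsets
    # outward movement (spike-locked) followed by a return sweep: stationary trace
    ev <- rbind(data.frame(time = times, axis = "yaw", amplitude = 20, duration = 0.5),
                data.frame(time = times + 1.5, axis = "yaw", amplitude = -20, duration = 0.5))
    h <- simulate_head_trace(300, ou_sd = 2, events = if (tuned) ev else NULL)
    sp <- simulate_motor_unit(300, events = if (tuned) data.frame(time = times) else NULL,
                              baseline_rate = 5, gain = 12)
    list(h = h, sp = sp)
  }
  run_unit <- function(tuned_in) {
    trials <- list(light1 = gen_trial("light" %in% tuned_in),
                   light2 = gen_trial("light" %in% tuned_in),
                   dark1 = gen_trial("dark" %in% tuned_in),
                   dark2 = gen_trial("dark" %in% tuned_in))
    stas <- lapply(trials, function(tr) compute_sta(tr$sp, tr$h))
    nulls <- lapply(trials, function(tr) {
      t(shuffle_null(tr$sp, 300, function(st) {
        sta_displacement_vectors(compute_sta(st, tr$h))
      }, n = 100)$samples)
    })
    classify_motion_tuning(stas, nulls)
  }
  expect_equal(run_unit(c("light", "dark"))$class, "both")
  expect_equal(run_unit("light")$class, "light")
  expect_equal(run_unit(character(0))$class, "none")
  expect_error(classify_motion_tuning(list(light1 = 1), list(light1 = 1)), "invalid input")
})

test_that("saccade detection requires both eyes and merges consecutive samples", {
  t <- seq(0, 60, by = 0.02)
  vl <- vr <- rep(0, length(t))
  expect_length(detect_saccades(t, vl, vr), 0)
  vl[100:102] <- 400; vr[100:102] <- 420
  expect_equal(detect_saccades(t, vl, vr), t[100])
  # monocular event ignored
  vl2 <- vl; vl2[500] <- 400
  expect_length(detect_saccades(t, vl2, vr), 1)
  # three planted binocular saccades
  for (i in c(1000, 1500, 2000)) { vl[i] <- 500; vr[i] <- 500 }
  expect_length(detect_saccades(t, vl, vr), 4)
})

test_that("eye-movement tuning flags a saccade-locked unit and converts amplitude via atan(d/r)", {
  expect_equal(atan(1) * 180 / pi, 45)  # d = r -> 45 deg
  set.seed(91)
  fs <- 50; dur <- 300
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sacc <- seq(10, 290, by = 4)
  x <- rep(0, length(t))
  for (s in sacc) x[t >= s] <- x[t >= s] + 0.3  # 0.3 length units per saccade
  x <- x - mean(x)
  pupil <- data.frame(t = t, x = x + rnorm(length(t), 0, 0.005),
                      y = rnorm(length(t), 0, 0.005))
  spikes <- sort(sacc - runif(length(sacc), 0.1, 0.3))
  res <- eye_movement_tuning(spikes, pupil, eye_radius = 1.7, duration = dur,
                             n_shuffles = 100)
  expect_true(res$tuned)
  expect_gt(abs(res$vectors["x"]), 1)
})
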