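test_that("stimulus schedules satisfy the printed protocol counts exactly", {
  set.seed(1)
  gr <- make_schedule("gratings")
  expect_equal(nrow(gr), 12 * 9)
  expect_equal(sort(unique(gr$angle)), seq(0, 330, by = 30))
  expect_true(all(table(gr$angle) == 9))
  sq <- make_schedule("squares")
  expect_equal(nrow(unique(sq[, c("x", "y")])), 165)
  expect_equal(nrow(sq), 165 * 2 * 3)
  expect_setequal(unique(sq$colour), c("black", "white"))
  gb <- make_schedule("gabor")
  expect_equal(nrow(gb), 576)
  expect_equal(nrow(unique(gb[, c("x", "y")])), 24)
  expect_equal(length(unique(gb$angle)), 8)
  sp <- make_schedule("spots")
  expect_equal(length(unique(sp$start)), 8)
  expect_equal(nrow(sp), 8 * 3 * 3)
  ot <- make_schedule("optotag")
  expect_equal(nrow(ot), 900)
  expect_equal(max(ot$onset) - min(ot$onset) + 10, 300, tolerance = 1)
  expect_true(all(diff(ot$onset[1:30]) - 1 / 30 < 1e-9))
  expect_error(make_schedule("nope"))
  # events never overlap within a protocol
  for (k in c("gratings", "squares", "gabor", "spots", "optotag")) {
    s <- make_schedule(k)
    s <- s[order(s$onset), ]
    expect_true(all(diff(s$onset) >= (s$offset - s$onset)[-nrow(s)] - 1e-9), info = k)
  }
})

test_that("head-trace generator plants exact displacements and honours its autocorrelation time", {
  set.seed(11)
  flat <- simulate_head_trace(10, ou_sd = 0)
  expect_equal(max(abs(diff(flat$yaw))), 0)
  ev <- data.frame(time = c(5, 20, 40), axis = c("yaw", "pitch", "yaw"),
                   amplitude = c(20, -10, 20), duration = 0.5)
  h <- simulate_head_trace(60, ou_sd = 0, events = ev)
  i <- function(tt) round(tt * 50) + 1
  expect_equal(h$yaw[i(5.5)] - h$yaw[i(5)], 20, tolerance = 1e-9)
  expect_equal(h$pitch[i(20.5)] - h$pitch[i(20)], -10, tolerance = 1e-9)
  # OU wander: lag-1 autocorrelation consistent with the configured time constant
  set.seed(12)
  hw <- simulate_head_trace(600, ou_sd = 10, ou_tau = 2)
  ac <- acf(hw$yaw, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(-1 / (50 * log(ac)), 2, tolerance = 0.4)
})

test_that("motor-unit generator obeys Poisson baseline statistics and inverts the STA logic", {
  set.seed(21)
  st <- simulate_motor_unit(400, events = NULL, baseline_rate = 5, gain = 0)
  expect_lt(abs(length(st) - 2000), 3 * sqrt(2000))
  expect_length(simulate_motor_unit(100, baseline_rate = 0, gain = 0), 0)
  # planted unit: STA recovers axis and sign of the planted displacement
  hits <- replicate(10, {
    times <- seq(5, 290, by = 4)
    ev <- data.frame(time = times, axis = "yaw", amplitude = 20, duration = 0.5)
    h <- simulate_head_trace(300, ou_sd = 2, events = ev)
    sp <- simulate_motor_unit(300, events = data.frame(time = times))
    v <- sta_displacement_vectors(compute_sta(sp, h))
    v["yaw"] > 5 && abs(v["yaw"]) > abs(v["pitch"]) && abs(v["yaw"]) > abs(v["roll"])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("visual-unit generator produces recoverable DS tuning and flat untuned responses", {
  set.seed(31)
  sched <- make_schedule("gratings")
  hits <- replicate(10, {
    sp <- simulate_visual_unit(sched, "DS", preferred_deg = 90, kappa = 2, gain = 3)
    gr <- grating_responses(sp, sched, 5)
    s <- selectivity(gr$mean_response, gr$angles, "direction")
    d <- abs(((s$preferred_deg - 90 + 180) %% 360) - 180)
    d < 15
  })
  expect_gte(mean(hits), 0.9)
  spu <- simulate_visual_unit(sched, "untuned")
  gru <- grating_responses(spu, sched, 5)
  expect_lt(selectivity(gru$mean_response, gru$angles, "direction")$si, 0.15)
  expect_error(simulate_visual_unit(make_schedule("squares"), "DS"), "angle")
})

test_that("eye-trace generator cancels head yaw at gain 1 and plants detectable saccades", {
  set.seed(41)
  h <- simulate_head_trace(120, ou_sd = 5, ou_tau = 2)
  eye <- simulate_eye_trace(h, gain = 1)
  expect_equal(max(abs(eye$x + h$yaw)), 0, tolerance = 1e-9)
  sacc <- c(20, 50, 80)
  eye2 <- simulate_eye_trace(h, gain = 0, saccade_times = sacc, saccade_amp_deg = 10)
  fs <- 50
  v <- c(0, diff(eye2$x)) * fs
  ev <- detect_saccades(eye2$t, v, v, threshold = 350)
  expect_length(ev, 3)
})

test_that("generators are deterministic given the seed", {
  make <- function() {
    set.seed(99)
    h <- simulate_head_trace(30, ou_sd = 5)
    s <- simulate_motor_unit(30, baseline_rate = 5, gain = 0)
    sc <- make_schedule("gratings")
    list(h = h, s = s, sc = sc)
  }
  expect_identical(make(), make())
})
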