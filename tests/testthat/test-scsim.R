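cfg0 <- sc_config(sigma_noise = 0)

test_that("network layout ties RF, DS and motor angles together", {
  lay <- build_network(cfg0)
  expect_equal(nrow(lay$z), 500)
  expect_true(all(lay$z[, 1] >= 0 & lay$z[, 1] <= cfg0$extent[1]))
  expect_true(all(lay$z[, 2] >= 0 & lay$z[, 2] <= cfg0$extent[2]))
  # zero shift: motor direction equals the RF angular position (mod 2pi)
  expect_lt(max(abs(sin(lay$theta_m - lay$theta_rf))), 1e-12)
  expect_equal(max(abs(sqrt(rowSums(lay$m^2)) - 1)), 0, tolerance = 1e-12)
  # pi shift: motor opposite the RF angle
  cfg_pi <- sc_config(sigma_noise = 0, alignment_shift = pi)
  lay_pi <- build_network(cfg_pi)
  expect_lt(max(abs(cos(lay_pi$theta_m - lay_pi$theta_rf) + 1)), 1e-12)
})

test_that("RF drive is a Gaussian bump peaking at the nearest centre", {
  lay <- build_network(cfg0)
  x <- rf_drive(lay$z[137, ], lay, cfg0)
  expect_equal(x[137], 1.5)
  expect_equal(which.max(x), 137)
  far <- rf_drive(c(100, 100), lay, cfg0)
  expect_lt(max(far), 1e-10)
  # half-max radius check: kappa = 40, |s - z| = 0.17
  expect_equal(1.5 * exp(-0.6 * 40 * 0.17^2), 0.75, tolerance = 0.02)
})

test_that("DS drive implements concentricity gating and the static relay", {
  lay <- build_network(cfg0)
  s <- c(1.0, 0.5)
  # receding motion: gamma = 0
  expect_equal(ds_drive(s, s / sqrt(sum(s^2)), numeric(500), lay, cfg0),
               numeric(500))
  # approaching motion: gamma = 1, peak at the neuron with theta_DS = theta_S + pi
  x <- ds_drive(s, -s, numeric(500), lay, cfg0)
  theta_s <- atan2(s[2], s[1])
  best <- which.max(x)
  d_ang <- ((lay$theta_ds[best] - (theta_s + pi) + pi) %% (2 * pi)) - pi
  expect_lt(abs(d_ang), 0.2)
  # value matches the von Mises factor at gamma = 1 for every neuron
  expect_equal(x, exp(cfg0$kappa * (cos(theta_s - lay$theta_ds + pi) - 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero velocity: gamma defined as 0
  expect_equal(ds_drive(s, c(0, 0), numeric(500), lay, cfg0), numeric(500))
  # static pathway relays RF rates untouched
  cfg_s <- sc_config(sigma_noise = 0, pathway = "static")
  r <- runif(500)
  expect_identical(ds_drive(s, c(1, 1), r, lay, cfg_s), r)
})

test_that("rate dynamics converge to the input fixed point, decay with tau, and rectify", {
  cfg <- sc_config(sigma_noise = 0, n_per_layer = 10)
  x <- runif(10, 0, 2)
  r <- numeric(10)
  for (i in seq_len(round(100 * cfg$tau_neural / cfg$dt))) r <- step_rates(r, x, cfg)
  expect_lt(max(abs(r - x)), 1e-6)
  # exponential decay with tau_neural = 10 ms (discrete closed form, ~ e^-1)
  r <- rep(1, 10)
  n_tau <- round(cfg$tau_neural / cfg$dt)
  for (i in seq_len(n_tau)) r <- step_rates(r, numeric(10), cfg)
  expect_equal(unique(r), (1 - cfg$dt / cfg$tau_neural)^n_tau, tolerance = 1e-12)
  expect_equal(unique(r), exp(-1), tolerance = 0.05)
  # negative transients clip at zero
  expect_true(all(step_rates(numeric(10), rep(-5, 10), cfg) == 0))
})

test_that("agent step is the scaled motor vector sum", {
  lay <- build_network(cfg0)
  expect_equal(agent_step(numeric(500), lay, cfg0), c(0, 0))
  # single active neuron with theta_M = 0, rate 1: da = (0.002, 0) at the defaults
  toy <- list(m = rbind(c(1, 0), c(-1, 0)))
  expect_equal(agent_step(c(1, 0), toy, cfg0), c(0.5e-3 / 0.250, 0), tolerance = 1e-15)
  # two equal-rate neurons at theta_M = 0 and pi cancel
  expect_equal(agent_step(c(1, 1), toy, cfg0), c(0, 0))
})

test_that("noiseless simulations are reproducible and energy is additive and non-negative", {
  s0 <- c(1.0, 0.5)
  v <- -s0 / sqrt(sum(s0^2)) * 0.3
  a <- run_simulation(cfg0, s0, v)
  b <- run_simulation(cfg0, s0, v)
  expect_identical(a$energy, b$energy)
  expect_identical(a$final_distance_deg, b$final_distance_deg)
  expect_gte(a$energy, 0)
  # seeded noisy runs reproduce
  cfgn <- sc_config(sigma_noise = 0.1)
  set.seed(5); n1 <- run_simulation(cfgn, s0, v)
  set.seed(5); n2 <- run_simulation(cfgn, s0, v)
  expect_identical(n1$energy, n2$energy)
})

test_that("kinetic pathway intercepts approaching targets and ignores receding ones", {
  s0 <- c(1.0, 0.5)
  app <- run_simulation(cfg0, s0, -s0 / sqrt(sum(s0^2)) * 0.3)
  expect_true(app$intercept)
  expect_lt(app$final_distance_deg, 24)
  rec <- run_simulation(cfg0, s0, s0 / sqrt(sum(s0^2)) * 0.3)
  expect_false(rec$intercept)
  expect_lt(rec$energy, 0.05 * app$energy)
  # static pathway intercepts a static target
  cfg_s <- sc_config(sigma_noise = 0, pathway = "static")
  st <- run_simulation(cfg_s, c(0.9, 0.45), c(0, 0))
  expect_true(st$intercept)
  # purely kinetic drive cannot catch a static target (gamma = 0 throughout)
  k0 <- run_simulation(cfg0, c(0.9, 0.45), c(0, 0))
  expect_false(k0$intercept)
  expect_equal(k0$energy, 0)
})

test_that("sweep enumeration yields the full cross product and the shift grid", {
  spec <- sweep_spec()
  runs <- enumerate_sweep(spec, cfg0)
  expect_equal(nrow(runs), 2 * 40 * 10 * 15)
  expect_equal(length(unique(runs$relative_speed)), 40)
  small <- sweep_spec(n_speeds = 2, n_starts = 2, n_directions = 3)
  expect_equal(nrow(enumerate_sweep(small, cfg0)), 2 * 2 * 2 * 3)
  res <- run_sweep(small, cfg0)
  expect_true(all(res$termination_reason %in%
                    c("timeout", "left_field", "motion_limit", "intercept")))
  expect_true(all(res$energy >= 0))
})
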