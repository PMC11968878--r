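# Synthetic-data generator: configs, noise calibration, kinematics,
# spiking, calcium and paired-recording simulation.

test_that("truncated-normal moments match numerical integration", {
  cases <- list(c(55, 15, 40, 90), c(12, 4, 5, 20), c(0, 1, -1, 2))
  for (cs in cases) {
    m <- truncnorm_moments(cs[1], cs[2], cs[3], cs[4])
    z <- pnorm(cs[4], cs[1], cs[2]) - pnorm(cs[3], cs[1], cs[2])
    mu <- integrate(function(x) x * dnorm(x, cs[1], cs[2]) / z,
                    cs[3], cs[4])$value
    v <- integrate(function(x) (x - mu)^2 * dnorm(x, cs[1], cs[2]) / z,
                   cs[3], cs[4])$value
    expect_equal(m$mean, mu, tolerance = 1e-6)
    expect_equal(m$var, v, tolerance = 1e-6)
  }
})

test_that("head-noise calibration has the stated closed form and limits", {
  expect_equal(calibrate_head_noise(0.6, 50, 1), 0)       # noiseless limit
  expect_equal(calibrate_head_noise(1, 100, 0.5), 10)     # symmetric case
  expect_error(calibrate_head_noise(1, 100, 0), "target_r2")
  expect_error(calibrate_head_noise(1, -1, 0.5), "amp_variance")
})

test_that("calibrated noise reproduces the target R-squared at large n", {
  cfg <- kinematics_config()
  mom <- truncnorm_moments(cfg$steer_amp$mean, cfg$steer_amp$sd,
                           cfg$steer_amp$lo, cfg$steer_amp$hi)
  sigma <- calibrate_head_noise(cfg$head_slope, mom$var,
                                cfg$head_r2[["steering"]])
  set.seed(99)
  n <- 1e6
  a <- qnorm(pnorm(cfg$steer_amp$lo, cfg$steer_amp$mean, cfg$steer_amp$sd) +
               runif(n) * (pnorm(cfg$steer_amp$hi, cfg$steer_amp$mean, cfg$steer_amp$sd) -
                             pnorm(cfg$steer_amp$lo, cfg$steer_amp$mean, cfg$steer_amp$sd)),
             cfg$steer_amp$mean, cfg$steer_amp$sd)
  y <- cfg$head_slope * a + rnorm(n, 0, sigma)
  r2 <- cor(a, y)^2
  expect_equal(r2, cfg$head_r2[["steering"]], tolerance = 0.01)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(kinematics_config(explore_amp = amp_dist(12, 4, 5, 45)),
               "overlap")
  expect_error(circuit_config(data.frame(id = "x", side = "up",
                                         class = "steering", theta = 40,
                                         gain = 0.2)),
               "side")
  expect_error(calcium_config(tau_rise = 2, tau_decay = 1), "tau")
  expect_error(paired_config(rate_khz = 5), "resolve")
  expect_error(paired_config(delay_mean = 0), "delay_mean")
})

test_that("zero bout rate yields a flat trace and empty truth table", {
  tr <- generate_trial(kinematics_config(bout_rate = 0, trial_duration = 5),
                       seed = 1)
  expect_equal(tr$trace$tail_angle, rep(0, 5 * 250))
  expect_equal(nrow(tr$bouts), 0)
  expect_error(generate_trial(kinematics_config(trial_duration = 0.1)),
               "too short")
})

test_that("trials are seed-deterministic and follow the documented RNG protocol", {
  cfg <- kinematics_config(trial_duration = 10)
  a <- generate_trial(cfg, seed = 7)
  b <- generate_trial(cfg, seed = 7)
  expect_identical(a, b)
  # oracle: re-draw the Poisson bout stream with the documented order
  set.seed(7)
  n_raw <- rpois(1, cfg$bout_rate * cfg$trial_duration)
  f1 <- sort(round(runif(n_raw, 0, cfg$trial_duration) * cfg$fps))
  nframes <- round(cfg$trial_duration * cfg$fps)
  f1 <- f1[f1 >= 9 & f1 <= nframes - 31 - cfg$head_lag]
  keep <- c(); last <- -Inf
  for (f in f1) if (f - last >= 41) { keep <- c(keep, f); last <- f }
  expect_equal(a$bouts$f1, as.integer(keep))
})

test_that("bout waveform peaks at the drawn amplitude and class supports hold", {
  trial <- generate_bouts(500, kinematics_config(), seed = 21)
  bs <- segment_bouts(trial$trace)
  m <- match(bs$features$f1, trial$bouts$f1)
  expect_true(all(!is.na(m)))
  rel_err <- abs(bs$features$max_tail_amplitude - trial$bouts$amplitude[m]) /
    trial$bouts$amplitude[m]
  expect_true(all(rel_err < 0.01))
  cls <- trial$bouts$class[m]
  expect_true(all(bs$features$max_tail_amplitude[cls == "exploratory"] < 20))
  expect_true(all(bs$features$max_tail_amplitude[cls == "steering"] >= 40))
  # amplitude supports respected over 1e4 direct draws of each class
  u <- runif(1e4)
  st <- steerscope:::qtruncnorm(u, 55, 15, 40, 90)
  ex <- steerscope:::qtruncnorm(u, 12, 4, 5, 20)
  expect_true(all(st >= 40 & st <= 90))
  expect_true(all(ex >= 5 & ex < 20))
})

test_that("head angle steps by slope * amplitude plus the drawn noise", {
  trial <- generate_trial(kinematics_config(trial_duration = 60), seed = 3)
  bs <- segment_bouts(trial$trace)
  m <- match(bs$features$f1, trial$bouts$f1)
  b <- trial$bouts[m, ]
  sgn <- ifelse(b$side == "right", 1, -1)
  expected <- sgn * trial$cfg$head_slope * b$amplitude + b$head_noise
  expect_equal(bs$features$head_change, expected, tolerance = 1e-10)
  expect_true(all(bs$features$peak_to_head_delay == trial$cfg$head_lag))
})

test_that("spike counts follow the threshold-gated gain rule", {
  b <- data.frame(bout_id = 1:4, amplitude = c(35, 50, 41, 70),
                  side = c("right", "right", "right", "left"),
                  f1 = c(100, 200, 300, 400))
  circ <- circuit_config(data.frame(id = "sR", side = "right",
                                    class = "steering", theta = 40, gain = 0.2))
  rec <- simulate_spikes(b, circ)$sR
  # sub-threshold 35 deg -> silent; 50 deg at gain 0.2 -> 2 spikes;
  # just supra-threshold fires; contralateral silent
  expect_equal(rec$bouts$count, c(0L, 2L, 1L, 0L))
  circ0 <- circuit_config(data.frame(id = "sR", side = "right",
                                     class = "steering", theta = 40, gain = 0))
  expect_true(all(simulate_spikes(b, circ0)$sR$bouts$count == 0))
  expect_error(simulate_spikes(data.frame(bout_id = 1, amplitude = 50,
                                          side = "up", f1 = 10), circ),
               "side")
})

test_that("spike count is non-decreasing in bout amplitude", {
  b <- data.frame(bout_id = 1:200, amplitude = seq(5, 90, length.out = 200),
                  side = "right", f1 = seq(10, by = 50, length.out = 200))
  circ <- circuit_config(data.frame(id = "sR", side = "right",
                                    class = "steering", theta = 40, gain = 0.2))
  counts <- simulate_spikes(b, circ)$sR$bouts$count
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts >= 0))
  expect_true(all(counts == as.integer(counts)))
})

test_that("calcium transients superpose linearly and peak at the kernel maximum", {
  cfg <- calcium_config(noise_sd = 0)
  flat <- simulate_calcium(numeric(0), cfg, duration_s = 10)
  expect_equal(flat$F, rep(cfg$Fb + cfg$F0_cell, length(flat$F)))
  one <- simulate_calcium(2, cfg, duration_s = 20)
  # oracle: unit-peak kernel evaluated at the trace's own sample times
  t <- seq(0, 20, by = 1 / cfg$rate)
  tpk <- kernel_peak_time(cfg$tau_rise, cfg$tau_decay)
  knorm <- exp(-tpk / cfg$tau_decay) - exp(-tpk / cfg$tau_rise)
  kern <- ifelse(t >= 2, (exp(-(t - 2) / cfg$tau_decay) -
                            exp(-(t - 2) / cfg$tau_rise)) / knorm, 0)
  expect_equal(max(one$F) - (cfg$Fb + cfg$F0_cell),
               cfg$amplitude * max(kern), tolerance = 1e-10)
  two <- simulate_calcium(c(2, 2), cfg, duration_s = 20)
  expect_equal(two$F - (cfg$Fb + cfg$F0_cell),
               2 * (one$F - (cfg$Fb + cfg$F0_cell)), tolerance = 1e-10)
  expect_error(simulate_calcium(30, cfg, duration_s = 10), "duration")
})

test_that("paired sweeps carry the configured delay, sign and jitter", {
  det <- simulate_paired_recording(paired_config(delay_jitter_sd = 0,
                                                 noise_sd_mv = 0, sweeps = 5))
  d <- psp_delays(det)
  expect_equal(length(unique(round(d, 10))), 1)  # jitter 0: identical onsets
  ipsp <- simulate_paired_recording(paired_config(sign = -1, noise_sd_mv = 0,
                                                  sweeps = 3), seed = 4)
  v <- ipsp$sweeps_mv[1, ]
  expect_lt(min(v), ipsp$cfg$baseline_mv)
  expect_equal(max(v), ipsp$cfg$baseline_mv, tolerance = 1e-9)
  # drawn delays average to the configured mean within 3 SE (direct oracle)
  rec <- simulate_paired_recording(paired_config(), seed = 11)
  se <- rec$cfg$delay_jitter_sd / sqrt(rec$cfg$sweeps)
  expect_lt(abs(mean(rec$delays_ms) - rec$cfg$delay_mean), 3 * se)
  expect_identical(simulate_paired_recording(paired_config(), seed = 5),
                   simulate_paired_recording(paired_config(), seed = 5))
})
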