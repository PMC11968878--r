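# Spike detection, recruitment-angle estimation, count regressions,
# PSP/delay measurement and coupling coefficients.

# Voltage ramp with a known dV/dt profile: quadratic rise so the 10 V/s
# crossing happens at an analytically known sample.
make_ap_trace <- function(rate_khz = 20, onset_vm = -45) {
  dt <- 1 / rate_khz
  t <- seq(0, 20, by = dt)
  vm <- rep(-65, length(t))
  ap_start <- which(t >= 10)[1]
  rise <- seq(onset_vm, 30, length.out = 21)     # fast depolarization
  pre <- seq(-65, onset_vm, length.out = 200)    # slow sub-10 V/s ramp
  vm[(ap_start - 199):ap_start] <- pre
  vm[(ap_start + 1):(ap_start + 21)] <- rise
  vm[(ap_start + 22):(ap_start + 60)] <- seq(30, -65, length.out = 39)
  list(vm = vm, rate = rate_khz, onset_vm = onset_vm,
       onset_ms = t[ap_start + 1])
}

test_that("spike detection is silent on flat traces and rejects slow sampling", {
  s <- detect_spikes(rep(-65, 1000), rate_khz = 20)
  expect_equal(s$n, 0L)
  expect_error(detect_spikes(rep(-65, 100), rate_khz = 5), "coarse")
})

test_that("firing threshold is the Vm where dV/dt first exceeds 10 V/s", {
  ap <- make_ap_trace()
  s <- detect_spikes(ap$vm, ap$rate)
  expect_equal(s$n, 1L)
  # slow pre-ramp: 20 mV over 10 ms = 2 V/s stays sub-threshold, so the
  # onset lands within one sample of the start of the fast rise
  expect_lt(abs(s$threshold_mv - ap$onset_vm), 5)  # one sample of the rise
  expect_lt(abs(s$onset_ms - ap$onset_ms), 2 / ap$rate)
  peak_vm <- ap$vm[round(s$peak_ms * ap$rate) + 1]
  expect_equal(peak_vm, 30)
})

test_that("onsets inside the refractory window merge into one event", {
  rate <- 20; dt <- 1 / rate
  v <- rep(-65, 400)
  spike <- c(seq(-65, 20, length.out = 6), seq(20, -65, length.out = 6))
  v[100:111] <- spike
  v[120:131] <- spike   # 1 ms later: inside the 2-ms refractory window
  v[300:311] <- spike   # 10 ms later: separate event
  s <- detect_spikes(v, rate)
  expect_equal(s$n, 2L)
})

test_that("recruitment threshold is recovered from synthetic bouts", {
  set.seed(20)
  b <- data.frame(bout_id = 1:200, amplitude = runif(200, 10, 80),
                  side = "right", f1 = seq(10, by = 50, length.out = 200))
  circ <- circuit_config(data.frame(id = "sR", side = "right",
                                    class = "steering", theta = 40, gain = 0.2))
  rc <- recruitment_curve(simulate_spikes(b, circ)$sR)
  expect_true(rc$fired)
  expect_lt(abs(rc$estimated_threshold - 40), 2)
  expect_gte(rc$min_recruitment_angle, 40)
})

test_that("recruitment-curve edge cases and bracket invariant hold", {
  # neuron firing on every bout: minimal recruitment angle = smallest bout
  every <- recruitment_curve(data.frame(bout_id = 1:5, count = c(1, 2, 1, 3, 2),
                                        angle = c(12, 30, 8, 50, 22)))
  expect_equal(every$min_recruitment_angle, 8)
  expect_true(is.na(every$estimated_threshold))  # no silent bout below
  none <- recruitment_curve(data.frame(bout_id = 1:3, count = c(0, 0, 0),
                                       angle = c(10, 20, 30)))
  expect_false(none$fired)
  expect_true(is.na(none$min_recruitment_angle))
  # property: the estimate is bracketed by (largest silent, smallest active)
  for (s in 1:20) {
    set.seed(400 + s)
    ang <- runif(60, 5, 85)
    cnt <- ifelse(ang > 37.5, pmax(1, round(0.2 * (ang - 37.5))), 0)
    rc <- recruitment_curve(data.frame(bout_id = seq_along(ang),
                                       count = cnt, angle = ang))
    if (rc$fired && !is.na(rc$estimated_threshold)) {
      silent_below <- max(ang[cnt == 0 & ang < rc$min_recruitment_angle])
      expect_gte(rc$estimated_threshold, silent_below)
      expect_lte(rc$estimated_threshold, rc$min_recruitment_angle)
    }
  }
})

test_that("count regressions match closed-form OLS and detect the null", {
  lin <- recruitment_curve(data.frame(bout_id = 1:6, angle = c(40, 48, 56, 64, 72, 80),
                                      count = c(0, 2, 4, 6, 8, 10)))
  r <- spikes_vs_angle(lin, active_only = TRUE)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 0.25)
  # hand-computable five-point set against the normal equations
  x <- c(41, 50, 55, 63, 77); y <- c(1, 2, 2, 5, 7)
  r5 <- spikes_vs_angle(recruitment_curve(
    data.frame(bout_id = 1:5, angle = x, count = y)), active_only = TRUE)
  o <- ols_brute(x, y)
  expect_equal(r5$slope, o$slope, tolerance = 1e-12)
  expect_equal(r5$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(r5$r_squared, o$r_squared, tolerance = 1e-12)
  # spike count carries no information about beat frequency by construction
  circ <- circuit_config(data.frame(id = "sR", side = "right",
                                    class = "steering", theta = 40, gain = 0.2))
  r2s <- vapply(1:50, function(s) {
    set.seed(500 + s)
    b <- data.frame(bout_id = 1:200, amplitude = runif(200, 42, 85),
                    side = "right", f1 = seq(10, by = 50, length.out = 200))
    cnt <- simulate_spikes(b, circ)$sR$bouts$count
    freqs <- runif(200, 15, 25)
    spikes_vs_frequency(cnt, freqs)$r_squared
  }, numeric(1))
  expect_lt(median(r2s), 0.05)
})

test_that("PSP measurement recovers amplitude, sign and inserted delay", {
  det <- simulate_paired_recording(
    paired_config(delay_jitter_sd = 0, noise_sd_mv = 0, sweeps = 1),
    seed = 1)
  m <- measure_psp(det, average = FALSE)
  expect_equal(m$amplitude_mv, det$cfg$amplitude_mv, tolerance = 1e-4)
  expect_equal(m$sign, 1)
  expect_lt(abs(m$delay_ms - det$cfg$delay_mean), 1 / det$cfg$rate_khz)
  ipsp <- simulate_paired_recording(
    paired_config(sign = -1, delay_jitter_sd = 0, noise_sd_mv = 0, sweeps = 4))
  mi <- measure_psp(ipsp)
  expect_equal(mi$sign, -1)
  expect_gt(mi$amplitude_mv, 0)
  expect_lt(abs(mi$delay_ms - ipsp$cfg$delay_mean), 1 / ipsp$cfg$rate_khz)
})

test_that("mean measured delay tracks the drawn delays within one sample", {
  rec <- simulate_paired_recording(paired_config(), seed = 7)
  d <- psp_delays(rec)
  expect_length(d, 50)
  expect_lt(abs(mean(d) - mean(rec$delays_ms)), 1 / rec$cfg$rate_khz)
})

test_that("sweep averaging shrinks noise like one over root N", {
  set.seed(30)
  n_sweeps <- 50; n_samp <- 400; sigma <- 0.5
  rec <- structure(list(
    time_ms = seq(0, by = 0.05, length.out = n_samp),
    sweeps_mv = matrix(rnorm(n_sweeps * n_samp, -65, sigma), n_sweeps),
    ap_time_ms = 15, delays_ms = numeric(0), cfg = NULL),
    class = "paired_recording")
  avg_sd <- sd(colMeans(rec$sweeps_mv))
  expect_lt(abs(avg_sd - sigma / sqrt(n_sweeps)) / (sigma / sqrt(n_sweeps)), 0.2)
  # an amplitude at the noise floor is flagged unreliable
  m <- measure_psp(rec)
  expect_false(m$reliable)
})

test_that("coupling coefficient matches the two-resistor circuit solution", {
  expect_equal(coupling_coefficient(10, 0), 0)
  expect_equal(coupling_coefficient(10, 10), 1)
  expect_error(coupling_coefficient(0, 1), "non-zero")
  # steady-state two-cell model: leak g1, g2 and junctional gc (nS); current
  # I into cell 1. Solve the Kirchhoff system and compare CC = gc/(g2+gc).
  g1 <- 5; g2 <- 8; gc <- 2; I <- 100
  A <- matrix(c(g1 + gc, -gc, -gc, g2 + gc), 2, byrow = TRUE)
  v <- solve(A, c(I, 0))
  expect_equal(coupling_coefficient(v[1], v[2]), gc / (g2 + gc),
               tolerance = 1e-12)
})
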