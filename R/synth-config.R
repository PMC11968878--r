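# Configuration objects and noise calibration for the synthetic-data
# generator. Defaults encode the study conditions: steering turns draw peak
# tail amplitudes from a truncated normal on [40, 90] degrees, exploratory
# turns from one on [5, 20) degrees, head change is linear in tail amplitude
# (slope 0.6) with per-class noise calibrated so the population R-squared of
# head change on amplitude matches the reported regressions (0.3916 steering,
# 0.1163 exploratory).

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and variance of a normal distribution with the given
#' `mean` and `sd`, truncated to the interval `[lo, hi]`.
#'
#' @param mean,sd Parameters of the parent normal distribution.
#' @param lo,hi Truncation bounds.
#' @return List with elements `mean` and `var`.
#' @export
truncnorm_moments <- function(mean, sd, lo, hi) {
  stopifnot(sd > 0, lo < hi)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  if (z <= 0) stop("empty truncation interval")
  phi_a <- dnorm(a)
  phi_b <- dnorm(b)
  m <- mean + sd * (phi_a - phi_b) / z
  v <- sd^2 * (1 + (a * phi_a - b * phi_b) / z - ((phi_a - phi_b) / z)^2)
  list(mean = m, var = v)
}

# Inverse-CDF transform of uniforms to a truncated normal; used so the
# generator's RNG stream is a single documented runif() draw per bout.
qtruncnorm <- function(p, mean, sd, lo, hi) {
  pa <- pnorm(lo, mean, sd)
  pb <- pnorm(hi, mean, sd)
  qnorm(pa + p * (pb - pa), mean, sd)
}

#' Calibrate head-angle noise for a target coupling R-squared
#'
#' For the linear head--tail model `head_change = a * amplitude + eps`, with
#' `eps ~ N(0, sigma^2)`, returns the noise standard deviation `sigma` such
#' that the population coefficient of determination of head change regressed
#' on amplitude equals `target_r2`:
#' `sigma = sqrt(a^2 * amp_variance * (1 - R2) / R2)`.
#'
#' @param a Head slope, degrees of head change per degree of tail amplitude.
#' @param amp_variance Variance of the per-bout peak amplitude, degrees^2.
#' @param target_r2 Desired population R-squared, in (0, 1].
#' @return Noise standard deviation in degrees.
#' @examples
#' calibrate_head_noise(1, 100, 0.5)  # 10
#' calibrate_head_noise(0.6, 50, 1)   # 0: noiseless limit
#' @export
calibrate_head_noise <- function(a, amp_variance, target_r2) {
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 > 1)
    stop("target_r2 must be in (0, 1]")
  if (!is.numeric(amp_variance) || amp_variance <= 0)
    stop("amp_variance must be positive")
  sqrt(a^2 * amp_variance * (1 - target_r2) / target_r2)
}

amp_dist <- function(mean, sd, lo, hi) {
  stopifnot(is.numeric(mean), sd > 0, lo < hi, lo >= 0)
  list(mean = mean, sd = sd, lo = lo, hi = hi)
}

#' Kinematics generator configuration
#'
#' Parameters of the synthetic tail/head kinematics generator. Bouts arrive
#' as a Poisson process (thinned so bout windows never overlap); each bout is
#' a damped tail oscillation whose peak amplitude is drawn from a class-
#' specific truncated normal, with a stepwise head-direction change of
#' `head_slope * amplitude` (plus class-specific Gaussian noise) applied
#' `head_lag` frames after the tail peak, toward the turn side.
#'
#' @param fps Video frame rate, frames per second.
#' @param trial_duration Trial length in seconds.
#' @param bout_rate Mean bout rate, bouts per second (Poisson arrivals).
#' @param steering_fraction Probability that a bout is a steering turn.
#' @param steer_amp,explore_amp Truncated-normal amplitude distributions
#'   (lists with `mean`, `sd`, `lo`, `hi`, degrees) for the two bout classes.
#'   The supports must not overlap.
#' @param beat_freq Tail-beat frequency within a bout, Hz.
#' @param head_slope Degrees of head change per degree of peak tail
#'   amplitude (both classes).
#' @param head_r2 Named numeric vector (`steering`, `exploratory`) of target
#'   population R-squared values for the head-on-amplitude regression; used
#'   to calibrate `head_noise_sd` when it is not supplied.
#' @param head_noise_sd Optional named vector (`steering`, `exploratory`) of
#'   head-noise standard deviations in degrees; computed from `head_r2` via
#'   [calibrate_head_noise()] when `NULL`.
#' @param decay_frames Exponential decay constant of the tail oscillation,
#'   in frames.
#' @param head_lag Frames between the tail peak and the head-direction step.
#' @return An object of class `kinematics_config`.
#' @export
kinematics_config <- function(fps = 250,
                              trial_duration = 60,
                              bout_rate = 1,
                              steering_fraction = 0.5,
                              steer_amp = amp_dist(55, 15, 40, 90),
                              explore_amp = amp_dist(12, 4, 5, 20),
                              beat_freq = 20,
                              head_slope = 0.6,
                              head_r2 = c(steering = 0.3916, exploratory = 0.1163),
                              head_noise_sd = NULL,
                              decay_frames = 8,
                              head_lag = 3) {
  stopifnot(fps > 0, trial_duration > 0, bout_rate >= 0,
            steering_fraction >= 0, steering_fraction <= 1,
            beat_freq > 0, decay_frames > 0, head_lag >= 0)
  if (explore_amp$hi > steer_amp$lo)
    stop("amplitude supports overlap: exploratory upper bound must not exceed steering lower bound")
  steer_amp <- do.call(amp_dist, as.list(unlist(steer_amp)))
  explore_amp <- do.call(amp_dist, as.list(unlist(explore_amp)))
  head_r2 <- unlist(head_r2)
  if (is.null(names(head_r2)))
    names(head_r2) <- c("steering", "exploratory")
  if (!is.null(head_noise_sd)) {
    head_noise_sd <- unlist(head_noise_sd)
    if (is.null(names(head_noise_sd)))
      names(head_noise_sd) <- c("steering", "exploratory")
  }
  if (is.null(head_noise_sd)) {
    head_noise_sd <- c(
      steering = calibrate_head_noise(
        head_slope, truncnorm_moments(steer_amp$mean, steer_amp$sd,
                                      steer_amp$lo, steer_amp$hi)$var,
        head_r2[["steering"]]),
      exploratory = calibrate_head_noise(
        head_slope, truncnorm_moments(explore_amp$mean, explore_amp$sd,
                                      explore_amp$lo, explore_amp$hi)$var,
        head_r2[["exploratory"]])
    )
  }
  if (any(head_noise_sd < 0)) stop("head_noise_sd must be non-negative")
  structure(list(fps = fps, trial_duration = trial_duration,
                 bout_rate = bout_rate, steering_fraction = steering_fraction,
                 steer_amp = steer_amp, explore_amp = explore_amp,
                 beat_freq = beat_freq, head_slope = head_slope,
                 head_r2 = head_r2, head_noise_sd = head_noise_sd,
                 decay_frames = decay_frames, head_lag = head_lag),
            class = "kinematics_config")
}

#' Circuit configuration for the spiking model
#'
#' Describes the simulated brainstem neurons. Each neuron has a side, a
#' class, a recruitment threshold `theta` (degrees of ipsilateral peak tail
#' amplitude) and a spike gain `gain` (spikes per degree above threshold).
#' Steering-class neurons fire only on ipsilateral bouts whose peak
#' amplitude exceeds `theta`; exploratory-class neurons fire only on
#' ipsilateral exploratory bouts.
#'
#' @param neurons Data frame with columns `id`, `side` ("left"/"right"),
#'   `class` ("steering"/"exploratory"), `theta`, `gain`. The default is one
#'   steering pair (threshold 40 degrees, gain 0.2) and one exploratory pair
#'   (threshold 0, gain 0.2).
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(neurons = NULL) {
  if (is.null(neurons)) {
    neurons <- data.frame(
      id = c("steer_L", "steer_R", "expl_L", "expl_R"),
      side = c("left", "right", "left", "right"),
      class = c("steering", "steering", "exploratory", "exploratory"),
      theta = c(40, 40, 0, 0),
      gain = c(0.2, 0.2, 0.2, 0.2),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(neurons),
            all(c("id", "side", "class", "theta", "gain") %in% names(neurons)))
  if (!all(neurons$side %in% c("left", "right")))
    stop("unknown side label: sides must be 'left' or 'right'")
  if (!all(neurons$class %in% c("steering", "exploratory")))
    stop("neuron class must be 'steering' or 'exploratory'")
  if (any(neurons$theta < 0) || any(neurons$gain < 0))
    stop("theta and gain must be non-negative")
  structure(list(neurons = neurons), class = "circuit_config")
}

#' Calcium-indicator configuration
#'
#' Parameters of the fluorescence model
#' `F(t) = Fb + F0_cell + A * sum_s k(t - t_s) + noise`, with `k` a
#' double-exponential kernel normalized to unit peak (GCaMP6s-like slow
#' kinetics by default).
#'
#' @param tau_rise,tau_decay Kernel rise and decay time constants, seconds.
#' @param amplitude Fluorescence units added per spike at the kernel peak.
#' @param Fb Background fluorescence, arbitrary units.
#' @param F0_cell Baseline cellular fluorescence above background, units.
#' @param noise_sd Additive Gaussian noise SD, units.
#' @param rate Imaging rate, volumes per second.
#' @return An object of class `calcium_config`.
#' @export
calcium_config <- function(tau_rise = 0.1, tau_decay = 1.8, amplitude = 20,
                           Fb = 10, F0_cell = 100, noise_sd = 0, rate = 7.5) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("require tau_decay > tau_rise > 0")
  stopifnot(Fb >= 0, F0_cell > 0, noise_sd >= 0, rate > 0, amplitude >= 0)
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 amplitude = amplitude, Fb = Fb, F0_cell = F0_cell,
                 noise_sd = noise_sd, rate = rate),
            class = "calcium_config")
}

#' Paired-recording configuration
#'
#' Parameters of the simulated paired recording: each sweep holds one
#' presynaptic action-potential marker and a postsynaptic potential whose
#' onset follows the marker by a jittered synaptic delay.
#'
#' @param delay_mean Mean synaptic delay, ms.
#' @param delay_jitter_sd Per-sweep delay jitter SD, ms.
#' @param rise_ms,decay_ms PSP shape time constants (alpha-like
#'   `(1 - exp(-t/rise)) * exp(-t/decay)`, normalized to unit peak), ms.
#' @param amplitude_mv PSP peak amplitude, mV.
#' @param sign `+1` for EPSPs, `-1` for IPSPs.
#' @param rate_khz Sampling rate, kHz (must be at least 10 so that
#'   sub-millisecond delays are resolvable).
#' @param sweeps Number of consecutive sweeps.
#' @param noise_sd_mv Additive recording noise SD, mV.
#' @param ap_time_ms Presynaptic AP-peak marker time within each sweep, ms.
#' @param duration_ms Sweep duration, ms.
#' @param baseline_mv Resting membrane potential, mV.
#' @return An object of class `paired_config`.
#' @export
paired_config <- function(delay_mean = 0.8, delay_jitter_sd = 0.05,
                          rise_ms = 0.2, decay_ms = 5, amplitude_mv = 2,
                          sign = 1, rate_khz = 20, sweeps = 50,
                          noise_sd_mv = 0.02, ap_time_ms = 5,
                          duration_ms = 20, baseline_mv = -65) {
  if (delay_mean <= 0) stop("delay_mean must be positive")
  if (rate_khz < 10)
    stop("sampling interval exceeds 0.1 ms: cannot resolve sub-millisecond delays")
  stopifnot(delay_jitter_sd >= 0, rise_ms > 0, decay_ms > rise_ms,
            amplitude_mv > 0, sign %in% c(-1, 1), sweeps >= 1,
            noise_sd_mv >= 0, ap_time_ms > 0, duration_ms > ap_time_ms)
  structure(list(delay_mean = delay_mean, delay_jitter_sd = delay_jitter_sd,
                 rise_ms = rise_ms, decay_ms = decay_ms,
                 amplitude_mv = amplitude_mv, sign = sign,
                 rate_khz = rate_khz, sweeps = sweeps,
                 noise_sd_mv = noise_sd_mv, ap_time_ms = ap_time_ms,
                 duration_ms = duration_ms, baseline_mv = baseline_mv),
            class = "paired_config")
}
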