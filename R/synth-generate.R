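# Synthetic trial generation: tail/head kinematics with ground truth,
# threshold-gated spiking, fluorescence transients, and paired recordings.
#
# RNG protocol (documented so oracle re-draws are possible): a call to
# generate_trial(cfg, seed) sets the seed once and then consumes, in order,
#   1. rpois(1, .)            - raw bout count
#   2. runif(n_raw)           - bout times (seconds)
#   3. runif(n_kept)          - side draws (< 0.5 => right)
#   4. runif(n_kept)          - class draws (< steering_fraction => steering)
#   5. runif(n_kept)          - amplitude quantiles (inverse-CDF truncated normal)
#   6. rnorm(n_kept)          - head-noise draws (scaled per class)

side_sign <- function(side) ifelse(side == "right", 1, -1)

# Unit-peak bout waveform over the 40-frame window (relative frames 0..39,
# peak at relative frame 9): half-sine rise, damped cosine decay.
bout_waveform <- function(cfg) {
  rel <- 0:39
  w <- numeric(40)
  w[rel <= 9] <- sin(pi * rel[rel <= 9] / 18)
  d <- rel[rel > 9] - 9
  w[rel > 9] <- cos(2 * pi * cfg$beat_freq * d / cfg$fps) * exp(-d / cfg$decay_frames)
  w
}

#' Generate one synthetic kinematics trial
#'
#' Simulates a tail/head angle trace with Poisson bout arrivals (thinned so
#' that successive bout peaks are at least 41 frames apart and every
#' 40-frame bout window lies inside the trace). Each bout is a damped tail
#' oscillation signed toward its side whose peak sample equals the drawn
#' amplitude exactly; the head angle steps by
#' `head_slope * amplitude + noise` toward the bout side, `head_lag` frames
#' after the tail peak. Identical `(cfg, seed)` give identical output.
#'
#' @param cfg A [kinematics_config()].
#' @param seed Integer RNG seed (optional; omit to continue the current
#'   RNG stream).
#' @return An object of class `sim_trial`: a list with `trace` (a
#'   [tail_trace()]) and `bouts`, the ground-truth table with columns
#'   `bout_id`, `f1` (0-based peak frame), `time_s`, `side`, `class`,
#'   `amplitude` (degrees) and `head_noise` (degrees).
#' @export
generate_trial <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "kinematics_config"))
  nframes <- round(cfg$trial_duration * cfg$fps)
  if (nframes < 41) stop("trial too short for one 40-frame bout window")
  if (!is.null(seed)) set.seed(seed)

  n_raw <- rpois(1, cfg$bout_rate * cfg$trial_duration)
  if (n_raw == 0 || cfg$bout_rate == 0) {
    trace <- tail_trace(numeric(nframes), numeric(nframes), fps = cfg$fps)
    bouts <- data.frame(bout_id = integer(0), f1 = integer(0),
                        time_s = numeric(0), side = character(0),
                        class = character(0), amplitude = numeric(0),
                        head_noise = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(trace = trace, bouts = bouts, cfg = cfg),
                     class = "sim_trial"))
  }

  f1_raw <- sort(round(runif(n_raw, 0, cfg$trial_duration) * cfg$fps))
  f1_raw <- f1_raw[f1_raw >= 9 & f1_raw <= nframes - 31 - cfg$head_lag]
  # thin to >= 41-frame peak separation so bout windows never overlap
  keep <- logical(length(f1_raw))
  last <- -Inf
  for (i in seq_along(f1_raw)) {
    if (f1_raw[i] - last >= 41) {
      keep[i] <- TRUE
      last <- f1_raw[i]
    }
  }
  f1 <- f1_raw[keep]
  n <- length(f1)

  side <- ifelse(runif(n) < 0.5, "right", "left")
  cls <- ifelse(runif(n) < cfg$steering_fraction, "steering", "exploratory")
  u <- runif(n)
  amp <- numeric(n)
  st <- cls == "steering"
  amp[st] <- qtruncnorm(u[st], cfg$steer_amp$mean, cfg$steer_amp$sd,
                        cfg$steer_amp$lo, cfg$steer_amp$hi)
  amp[!st] <- qtruncnorm(u[!st], cfg$explore_amp$mean, cfg$explore_amp$sd,
                         cfg$explore_amp$lo, cfg$explore_amp$hi)
  noise_sd <- ifelse(st, cfg$head_noise_sd[["steering"]],
                     cfg$head_noise_sd[["exploratory"]])
  head_noise <- rnorm(n) * noise_sd

  tail <- numeric(nframes)
  dhead <- numeric(nframes)
  w <- bout_waveform(cfg)
  sgn <- side_sign(side)
  for (i in seq_len(n)) {
    idx <- (f1[i] - 9):(f1[i] + 30) + 1L  # 0-based frames -> R indices
    tail[idx] <- sgn[i] * amp[i] * w
    dhead[f1[i] + cfg$head_lag + 1L] <-
      sgn[i] * (cfg$head_slope * amp[i]) + head_noise[i]
  }
  head <- cumsum(dhead)

  trace <- tail_trace(tail, head, fps = cfg$fps)
  bouts <- data.frame(bout_id = seq_len(n), f1 = f1, time_s = f1 / cfg$fps,
                      side = side, class = cls, amplitude = amp,
                      head_noise = head_noise, stringsAsFactors = FALSE)
  structure(list(trace = trace, bouts = bouts, cfg = cfg), class = "sim_trial")
}

#' Simulate threshold-gated spiking from bout amplitudes
#'
#' For each configured neuron and each bout: an ipsilateral steering-class
#' neuron emits `ceiling(gain * (amplitude - theta))` spikes when the bout's
#' peak ipsilateral tail amplitude exceeds `theta` (so firing begins at the
#' recruitment threshold), and none otherwise; an exploratory-class neuron
#' fires `round(gain * amplitude)` spikes on ipsilateral exploratory bouts
#' only. Contralateral bouts never elicit spikes. Spikes are placed
#' deterministically, evenly spaced over the 30 frames after the bout peak.
#'
#' @param bouts A `sim_trial` or a bout table (data frame) with columns
#'   `side`, `amplitude` (or `max_tail_amplitude`) and `f1`, and optionally
#'   `class` (required when exploratory-class neurons are configured) and
#'   `bout_id`.
#' @param circuit A [circuit_config()].
#' @param fps Frame rate used to convert peak frames to spike times, ignored
#'   when `bouts` is a `sim_trial`.
#' @return Named list of `spike_record` objects, one per neuron, each with
#'   the neuron parameters, a per-bout table (`bout_id`, `amplitude`,
#'   `side`, `count`), spike times in seconds and per-bout spike-time lists.
#' @export
simulate_spikes <- function(bouts, circuit = circuit_config(), fps = 250) {
  stopifnot(inherits(circuit, "circuit_config"))
  if (inherits(bouts, "sim_trial")) {
    fps <- bouts$trace$fps
    bouts <- bouts$bouts
  }
  stopifnot(is.data.frame(bouts))
  if (!"amplitude" %in% names(bouts) && "max_tail_amplitude" %in% names(bouts))
    bouts$amplitude <- bouts$max_tail_amplitude
  stopifnot(all(c("amplitude", "side", "f1") %in% names(bouts)))
  if (!all(bouts$side %in% c("left", "right")))
    stop("unknown side label: sides must be 'left' or 'right'")
  if (is.null(bouts$bout_id)) bouts$bout_id <- seq_len(nrow(bouts))

  records <- lapply(seq_len(nrow(circuit$neurons)), function(j) {
    nrn <- circuit$neurons[j, ]
    ipsi <- bouts$side == nrn$side
    if (nrn$class == "steering") {
      supra <- ipsi & bouts$amplitude > nrn$theta
      count <- ifelse(supra,
                      ceiling(nrn$gain * (bouts$amplitude - nrn$theta)), 0)
    } else {
      if (is.null(bouts$class))
        stop("bout table needs a 'class' column for exploratory-class neurons")
      fire <- ipsi & bouts$class == "exploratory"
      count <- ifelse(fire, round(nrn$gain * bouts$amplitude), 0)
    }
    count <- as.integer(pmax(0, count))
    times <- lapply(seq_len(nrow(bouts)), function(i) {
      if (count[i] == 0) return(numeric(0))
      t_peak <- bouts$f1[i] / fps
      t_peak + seq_len(count[i]) / (count[i] + 1) * (30 / fps)
    })
    structure(list(
      neuron = nrn,
      bouts = data.frame(bout_id = bouts$bout_id, amplitude = bouts$amplitude,
                         side = bouts$side, count = count,
                         stringsAsFactors = FALSE),
      spike_times_s = unlist(times),
      bout_spike_times = times
    ), class = "spike_record")
  })
  names(records) <- circuit$neurons$id
  records
}

# Double-exponential kernel normalized to unit peak.
calcium_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  knorm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / knorm
  out
}

#' Simulate an ROI fluorescence trace from spike times
#'
#' Fluorescence model `F(t) = Fb + F0_cell + A * sum_s k(t - t_s) + noise`
#' with `k` a double-exponential kernel normalized to unit peak. With
#' `noise_sd = 0` the output is exactly reproducible and spike transients
#' superpose linearly.
#'
#' @param spikes A `spike_record` or a numeric vector of spike times in
#'   seconds.
#' @param cfg A [calcium_config()].
#' @param seed Optional RNG seed for the noise draw.
#' @param duration_s Trace duration; defaults to the last spike time plus
#'   five decay time constants (minimum 20 s).
#' @param roi_id,side ROI annotations carried into the returned trace.
#' @return A [roi_trace()].
#' @export
simulate_calcium <- function(spikes, cfg = calcium_config(), seed = NULL,
                             duration_s = NULL, roi_id = "roi1",
                             side = "right") {
  stopifnot(inherits(cfg, "calcium_config"))
  ts <- if (inherits(spikes, "spike_record")) spikes$spike_times_s else spikes
  if (is.null(duration_s))
    duration_s <- max(20, if (length(ts)) max(ts) + 5 * cfg$tau_decay else 0)
  if (length(ts) && any(ts < 0 | ts > duration_s))
    stop("spike times must lie within the trace duration")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = 1 / cfg$rate)
  f <- rep(cfg$Fb + cfg$F0_cell, length(t))
  for (s in ts)
    f <- f + cfg$amplitude * calcium_kernel(t - s, cfg$tau_rise, cfg$tau_decay)
  if (cfg$noise_sd > 0) f <- f + rnorm(length(t), 0, cfg$noise_sd)
  roi_trace(F = f, Fb = cfg$Fb, rate = cfg$rate, roi_id = roi_id, side = side)
}

#' Simulate a paired recording (presynaptic AP markers + postsynaptic PSPs)
#'
#' Each sweep contains one presynaptic action-potential marker at
#' `ap_time_ms` and a postsynaptic potential whose onset follows the marker
#' by an independent Gaussian delay draw (`delay_mean`, `delay_jitter_sd`).
#' IPSP sweeps (`sign = -1`) deflect negative.
#'
#' @param cfg A [paired_config()].
#' @param seed Optional RNG seed.
#' @return An object of class `paired_recording`: `time_ms`, a
#'   `sweeps x samples` voltage matrix `sweeps_mv`, `ap_time_ms`, the
#'   ground-truth per-sweep `delays_ms`, and the generating `cfg`.
#' @export
simulate_paired_recording <- function(cfg = paired_config(), seed = NULL) {
  stopifnot(inherits(cfg, "paired_config"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / cfg$rate_khz
  t <- seq(0, cfg$duration_ms, by = dt)
  delays <- rnorm(cfg$sweeps, cfg$delay_mean, cfg$delay_jitter_sd)
  shape <- function(x) {
    g <- numeric(length(x))
    pos <- x >= 0
    g[pos] <- (1 - exp(-x[pos] / cfg$rise_ms)) * exp(-x[pos] / cfg$decay_ms)
    g
  }
  tpk <- -cfg$rise_ms * log(cfg$rise_ms / (cfg$rise_ms + cfg$decay_ms))
  gmax <- (1 - exp(-tpk / cfg$rise_ms)) * exp(-tpk / cfg$decay_ms)
  sweeps <- matrix(0, nrow = cfg$sweeps, ncol = length(t))
  for (i in seq_len(cfg$sweeps)) {
    v <- cfg$baseline_mv +
      cfg$sign * cfg$amplitude_mv * shape(t - cfg$ap_time_ms - delays[i]) / gmax
    if (cfg$noise_sd_mv > 0) v <- v + rnorm(length(t), 0, cfg$noise_sd_mv)
    sweeps[i, ] <- v
  }
  structure(list(time_ms = t, sweeps_mv = sweeps, ap_time_ms = cfg$ap_time_ms,
                 delays_ms = delays, cfg = cfg),
            class = "paired_recording")
}

#' Generate a fixed number of bouts of one or both classes
#'
#' Convenience wrapper around [generate_trial()] that keeps generating
#' trials (with seeds derived from `seed`) until at least `n` bouts exist,
#' then truncates to exactly `n`. Used for calibration and recovery
#' analyses that are stated in bouts rather than in trial time.
#'
#' @param n Number of bouts required.
#' @param cfg A [kinematics_config()]; set `steering_fraction` to 1 or 0 for
#'   a single-class sample.
#' @param seed Integer seed; chunk `i` uses `seed + i - 1`.
#' @return A `sim_trial`-like list whose `trace` is the concatenation of the
#'   chunk traces and whose `bouts` table has exactly `n` rows (with `f1`
#'   re-expressed in the concatenated trace).
#' @export
generate_bouts <- function(n, cfg = kinematics_config(), seed = 1) {
  stopifnot(n >= 1)
  chunk_s <- max(60, ceiling(1.3 * n / max(cfg$bout_rate, 1e-9)))
  cfg_chunk <- cfg
  cfg_chunk$trial_duration <- chunk_s
  tails <- list(); heads <- list(); bouts <- list()
  got <- 0L; offset <- 0L; i <- 1L
  while (got < n) {
    tr <- generate_trial(cfg_chunk, seed = seed + i - 1L)
    b <- tr$bouts
    b$f1 <- b$f1 + offset
    b$time_s <- b$f1 / cfg$fps
    tails[[i]] <- tr$trace$tail_angle
    heads[[i]] <- tr$trace$head_angle
    bouts[[i]] <- b
    got <- got + nrow(b)
    offset <- offset + length(tr$trace$tail_angle)
    i <- i + 1L
  }
  all_bouts <- do.call(rbind, bouts)
  all_bouts <- all_bouts[seq_len(n), ]
  all_bouts$bout_id <- seq_len(n)
  nkeep <- all_bouts$f1[n] + 31L + cfg$head_lag
  tail <- unlist(tails)[seq_len(nkeep)]
  head <- unlist(heads)[seq_len(nkeep)]
  structure(list(trace = tail_trace(tail, head, fps = cfg$fps),
                 bouts = all_bouts, cfg = cfg),
            class = "sim_trial")
}
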