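# Intracellular-recording analysis: dV/dt spike detection, recruitment-
# angle estimation, spike-count regressions, PSP amplitude and synaptic
# delay, and gap-junction coupling coefficients.

#' Detect action potentials by the dV/dt criterion
#'
#' Spike onsets are the first samples of each excursion where the membrane-
#' potential derivative (central differences; mV/ms equals V/s) exceeds
#' `dvdt_threshold`. The firing threshold is the membrane potential at the
#' onset sample; the spike time is the subsequent AP peak. Onsets closer
#' than `refractory_ms` to the previous one are merged into a single event.
#'
#' @param vm Membrane potential, mV.
#' @param rate_khz Sampling rate, kHz (at least 10, so that dV/dt is
#'   resolvable).
#' @param dvdt_threshold Onset criterion, V/s.
#' @param refractory_ms Merge window, ms.
#' @return List with `onset_ms`, `peak_ms` (spike times), `threshold_mv`
#'   (firing threshold per spike) and `n`.
#' @export
detect_spikes <- function(vm, rate_khz, dvdt_threshold = 10,
                          refractory_ms = 2) {
  stopifnot(is.numeric(vm), dvdt_threshold > 0)
  if (rate_khz < 10)
    stop("sampling too coarse to estimate dV/dt (need >= 10 kHz)")
  n <- length(vm)
  if (n < 3)
    return(list(onset_ms = numeric(0), peak_ms = numeric(0),
                threshold_mv = numeric(0), n = 0L))
  dt <- 1 / rate_khz
  dvdt <- c(NA, (vm[3:n] - vm[1:(n - 2)]) / (2 * dt), NA)  # mV/ms = V/s
  supra <- !is.na(dvdt) & dvdt > dvdt_threshold
  onsets <- which(supra & !c(FALSE, supra[-n]))  # first sample of each run
  if (!length(onsets))
    return(list(onset_ms = numeric(0), peak_ms = numeric(0),
                threshold_mv = numeric(0), n = 0L))
  merged <- onsets[c(TRUE, diff(onsets) * dt >= refractory_ms)]
  peak_win <- max(1L, round(refractory_ms / dt))
  peaks <- vapply(merged, function(i) {
    j <- i:min(n, i + peak_win)
    j[which.max(vm[j])]
  }, numeric(1))
  list(onset_ms = (merged - 1) * dt, peak_ms = (peaks - 1) * dt,
       threshold_mv = vm[merged], n = length(merged))
}

#' Per-bout recruitment curve and threshold estimate
#'
#' Pairs each bout's peak tail amplitude with the neuron's spike count in
#' that bout. The minimal recruitment angle is the smallest amplitude among
#' active bouts (count > 0). The recruitment threshold is estimated as the
#' midpoint between the largest silent amplitude below the smallest active
#' amplitude and that smallest active amplitude, so the estimate is always
#' bracketed by the two. Both are `NA` when the neuron never fires; the
#' threshold is also `NA` when no silent bout lies below the first active
#' one.
#'
#' @param spikes A `spike_record` (from [simulate_spikes()]) or a data
#'   frame with columns `bout_id` and `count`.
#' @param bouts Optional bout feature table with `bout_id` and
#'   `max_tail_amplitude` (or `amplitude`); not needed when `spikes`
#'   already carries per-bout amplitudes.
#' @return An object of class `recruitment_curve`: `pairs` (data frame
#'   `angle`, `count`), `min_recruitment_angle`, `estimated_threshold`,
#'   `fired` (logical).
#' @export
recruitment_curve <- function(spikes, bouts = NULL) {
  if (inherits(spikes, "spike_record")) {
    pairs <- data.frame(bout_id = spikes$bouts$bout_id,
                        angle = spikes$bouts$amplitude,
                        count = spikes$bouts$count)
  } else {
    stopifnot(is.data.frame(spikes), all(c("bout_id", "count") %in% names(spikes)))
    pairs <- spikes
    if (!"angle" %in% names(pairs)) {
      stopifnot(!is.null(bouts))
      amp_col <- if ("max_tail_amplitude" %in% names(bouts))
        "max_tail_amplitude" else "amplitude"
      m <- match(pairs$bout_id, bouts$bout_id)
      pairs$angle <- bouts[[amp_col]][m]
    }
  }
  active <- pairs$count > 0
  if (!any(active)) {
    return(structure(list(pairs = pairs[, c("angle", "count")],
                          min_recruitment_angle = NA_real_,
                          estimated_threshold = NA_real_, fired = FALSE),
                     class = "recruitment_curve"))
  }
  min_active <- min(pairs$angle[active])
  silent_below <- pairs$angle[!active & pairs$angle < min_active]
  thr <- if (length(silent_below)) (max(silent_below) + min_active) / 2
         else NA_real_
  structure(list(pairs = pairs[, c("angle", "count")],
                 min_recruitment_angle = min_active,
                 estimated_threshold = thr, fired = TRUE),
            class = "recruitment_curve")
}

#' Spike count versus tail angle / beat frequency regressions
#'
#' Ordinary least squares of per-bout spike count on the bout's peak tail
#' amplitude (`spikes_vs_angle`; active bouts only by default, matching how
#' recruitment plots are drawn from firing events) or on tail-beat
#' frequency (`spikes_vs_frequency`).
#'
#' @param curve A [recruitment_curve()].
#' @param active_only Restrict to bouts with at least one spike.
#' @return A [linear_regression()] result.
#' @export
spikes_vs_angle <- function(curve, active_only = TRUE) {
  stopifnot(inherits(curve, "recruitment_curve"))
  d <- curve$pairs
  if (active_only) d <- d[d$count > 0, ]
  if (nrow(d) < 3) stop("need at least 3 active bouts")
  linear_regression(d$angle, d$count)
}

#' @rdname spikes_vs_angle
#' @param counts Per-bout spike counts.
#' @param freqs Per-bout tail-beat frequencies, Hz.
#' @export
spikes_vs_frequency <- function(counts, freqs) {
  stopifnot(length(counts) == length(freqs))
  linear_regression(freqs, counts)
}

#' Measure PSP amplitude, onset and synaptic delay
#'
#' Sweeps (aligned on the presynaptic AP marker) are averaged (or measured
#' singly with `average = FALSE` / a one-sweep recording). The baseline is
#' the mean voltage before the AP marker; the PSP extremum after the marker
#' sets the sign (EPSP up, IPSP down) and the amplitude (absolute
#' baseline-to-peak deflection, mV). The onset is the first crossing,
#' linearly interpolated between samples, of baseline plus `onset_frac` of
#' the amplitude in the PSP direction, and the synaptic delay is onset
#' minus AP time. When the amplitude is below `noise_mult` baseline SDs the
#' delay is flagged unreliable.
#'
#' @param rec A `paired_recording` (see [simulate_paired_recording()]).
#' @param average Average all sweeps before measuring.
#' @param onset_frac Onset criterion as a fraction of the PSP amplitude.
#' @param noise_mult Reliability criterion in baseline-SD units.
#' @return List with `amplitude_mv`, `sign`, `onset_ms`, `delay_ms`,
#'   `baseline_mv`, `reliable`, and `n_sweeps`.
#' @export
measure_psp <- function(rec, average = TRUE, onset_frac = 0.1,
                        noise_mult = 5) {
  stopifnot(inherits(rec, "paired_recording"))
  v <- if (average) colMeans(rec$sweeps_mv) else {
    if (nrow(rec$sweeps_mv) != 1)
      stop("set average = TRUE for multi-sweep recordings")
    rec$sweeps_mv[1, ]
  }
  t <- rec$time_ms
  pre <- t < rec$ap_time_ms
  if (!any(pre)) stop("no pre-AP baseline samples")
  baseline <- mean(v[pre])
  bl_sd <- sd(v[pre])
  post <- which(t >= rec$ap_time_ms)
  dev <- v[post] - baseline
  ext <- which.max(abs(dev))
  psp_sign <- sign(dev[ext])
  amplitude <- abs(dev[ext])
  reliable <- !is.na(bl_sd) && bl_sd > 0 && amplitude > noise_mult * bl_sd ||
    (!is.na(bl_sd) && bl_sd == 0 && amplitude > 0)
  thr <- onset_frac * amplitude
  sdev <- psp_sign * dev
  i <- which(sdev >= thr)[1]
  onset <- NA_real_
  if (!is.na(i)) {
    if (i == 1) {
      onset <- t[post[1]]
    } else {
      d0 <- sdev[i - 1]; d1 <- sdev[i]
      frac <- if (d1 > d0) (thr - d0) / (d1 - d0) else 0
      onset <- t[post[i - 1]] + frac * (t[post[i]] - t[post[i - 1]])
    }
  }
  list(amplitude_mv = amplitude, sign = psp_sign, onset_ms = onset,
       delay_ms = onset - rec$ap_time_ms, baseline_mv = baseline,
       reliable = isTRUE(reliable), n_sweeps = nrow(rec$sweeps_mv))
}

#' Per-sweep synaptic delays
#'
#' Applies [measure_psp()] to each sweep of a paired recording and returns
#' the vector of measured delays.
#'
#' @param rec A `paired_recording`.
#' @param ... Passed to [measure_psp()].
#' @return Numeric vector of per-sweep delays, ms.
#' @export
psp_delays <- function(rec, ...) {
  stopifnot(inherits(rec, "paired_recording"))
  vapply(seq_len(nrow(rec$sweeps_mv)), function(i) {
    one <- rec
    one$sweeps_mv <- rec$sweeps_mv[i, , drop = FALSE]
    measure_psp(one, average = FALSE, ...)$delay_ms
  }, numeric(1))
}

#' Gap-junction coupling coefficient
#'
#' Ratio of the postsynaptic to the presynaptic steady-state voltage
#' deflection during current injection, reported separately for
#' depolarizing and hyperpolarizing pulses when vectors are supplied.
#'
#' @param delta_pre Steady-state presynaptic deflection(s), mV (non-zero).
#' @param delta_post Steady-state postsynaptic deflection(s), mV.
#' @return Numeric coupling coefficient(s) `delta_post / delta_pre`.
#' @export
coupling_coefficient <- function(delta_pre, delta_post) {
  stopifnot(length(delta_pre) == length(delta_post))
  if (any(delta_pre == 0)) stop("presynaptic deflection must be non-zero")
  delta_post / delta_pre
}
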