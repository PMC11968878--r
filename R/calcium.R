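# Calcium dF/F, smoothing, responsiveness and recruitment summaries.
#
# For each ROI the background-subtracted fluorescence F' = F - Fb is
# referenced to a baseline F0, the mean of F' over the contiguous 5-s
# window with the smallest rolling mean (the quietest stretch of the
# trace), giving dF/F(t) = (F'(t) - F0) / F0. The dF/F series is smoothed
# (Gaussian kernel, then Savitzky-Golay), and the calcium signal amplitude
# Fa is the smoothed peak minus the smoothed baseline over the same quiet
# window. ROIs with Fa strictly exceeding 0.3 count as responsive.

#' Construct an ROI fluorescence trace
#'
#' @param F Raw fluorescence per frame, arbitrary units.
#' @param Fb Background fluorescence: a scalar or a per-frame vector.
#' @param rate Imaging rate, frames (volumes) per second.
#' @param roi_id ROI identifier.
#' @param side `"left"` or `"right"`, relative to the midline.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(F, Fb, rate = 7.5, roi_id = "roi1", side = "right") {
  stopifnot(is.numeric(F), is.numeric(Fb), rate > 0)
  if (length(Fb) != 1 && length(Fb) != length(F))
    stop("Fb must be a scalar or match F in length")
  stopifnot(side %in% c("left", "right"))
  structure(list(F = as.numeric(F), Fb = Fb, rate = rate,
                 roi_id = roi_id, side = side),
            class = "roi_trace")
}

# Index window (start, length w) of the contiguous w-sample stretch of x
# with minimal mean, via cumulative sums.
min_mean_window <- function(x, w) {
  n <- length(x)
  if (w > n) stop("trace shorter than the inactivity window")
  cs <- cumsum(c(0, x))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  start <- which.min(means)
  list(start = start, idx = start:(start + w - 1L), mean = means[start])
}

#' Compute dF/F and baseline for an ROI trace
#'
#' `F' = F - Fb`; `F0` is the mean of `F'` over the contiguous window of
#' `inactivity_seconds` with the smallest rolling mean; the returned series
#' is `dff(t) = (F'(t) - F0) / F0`. dF/F is invariant to scaling `F'` by
#' any positive constant and to adding the same constant to `F` and `Fb`.
#'
#' @param trace A [roi_trace()].
#' @param inactivity_seconds Length of the baseline window, seconds.
#' @return List with `dff`, `F0`, `baseline_idx` (frames of the selected
#'   window) and the input's `rate`.
#' @export
compute_dff <- function(trace, inactivity_seconds = 5) {
  stopifnot(inherits(trace, "roi_trace"), inactivity_seconds > 0)
  fprime <- trace$F - trace$Fb
  w <- max(1L, round(inactivity_seconds * trace$rate))
  win <- min_mean_window(fprime, w)
  f0 <- win$mean
  if (f0 <= 0)
    stop("invalid background: baseline F0 is non-positive after subtraction")
  list(dff = (fprime - f0) / f0, F0 = f0, baseline_idx = win$idx,
       rate = trace$rate)
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  n <- length(x)
  if (r >= n) stop("Gaussian kernel longer than the trace")
  pad <- c(x[(r + 1):2], x, x[(n - 1):(n - r)])  # reflective boundaries
  as.numeric(stats::filter(pad, kern, sides = 2))[(r + 1):(r + n)]
}

#' Smooth a dF/F series
#'
#' Gaussian kernel convolution (reflective boundaries, kernel truncated at
#' three sigma) followed by a Savitzky-Golay filter. A constant series
#' passes through unchanged, and polynomials up to `sg_poly` are preserved
#' exactly by the Savitzky-Golay stage.
#'
#' @param dff Numeric series.
#' @param gaussian_sigma Gaussian SD in frames; 0 disables the first stage.
#' @param sg_window Savitzky-Golay window length (odd, greater than
#'   `sg_poly`); 0 disables the second stage.
#' @param sg_poly Savitzky-Golay polynomial order.
#' @return Smoothed numeric series of the same length.
#' @export
smooth_dff <- function(dff, gaussian_sigma = 2, sg_window = 7, sg_poly = 3) {
  x <- gaussian_smooth(dff, gaussian_sigma)
  if (sg_window > 0) {
    if (sg_window %% 2 != 1 || sg_window <= sg_poly)
      stop("sg_window must be odd and greater than sg_poly")
    if (sg_window > length(x)) stop("sg_window longer than the trace")
    x <- as.numeric(signal::sgolayfilt(x, p = sg_poly, n = sg_window))
  }
  x
}

#' Full per-ROI calcium metrics
#'
#' Computes dF/F, the smoothed series, the peak `Fmax`, the calcium signal
#' amplitude `Fa = Fmax - F0_dff` (with `F0_dff` the smoothed-dF/F mean
#' over the detected inactivity window, approximately 0), and the
#' responsiveness flag `Fa > threshold` (strict).
#'
#' @inheritParams compute_dff
#' @inheritParams smooth_dff
#' @param threshold Responsiveness cutoff on `Fa` (dF/F units).
#' @return One-row data frame: `roi_id`, `side`, `F0`, `Fmax`, `Fa`,
#'   `responsive`.
#' @export
roi_metrics <- function(trace, inactivity_seconds = 5, gaussian_sigma = 2,
                        sg_window = 7, sg_poly = 3, threshold = 0.3) {
  d <- compute_dff(trace, inactivity_seconds)
  sm <- smooth_dff(d$dff, gaussian_sigma, sg_window, sg_poly)
  fmax <- max(sm)
  f0_dff <- mean(sm[d$baseline_idx])
  fa <- fmax - f0_dff
  data.frame(roi_id = trace$roi_id, side = trace$side, F0 = d$F0,
             Fmax = fmax, Fa = fa, responsive = responsive(fa, threshold),
             stringsAsFactors = FALSE)
}

#' Responsiveness criterion on the calcium signal amplitude
#'
#' An ROI is responsive iff its `Fa` strictly exceeds the threshold:
#' `Fa = 0.31` is responsive at the default cutoff, `Fa = 0.30` is not.
#'
#' @param fa Calcium signal amplitude(s), dF/F units.
#' @param threshold Cutoff, default 0.3.
#' @return Logical vector.
#' @export
responsive <- function(fa, threshold = 0.3) {
  as.logical(fa > threshold)
}

#' Normalize Fa to the trial maximum
#'
#' Adds `fa_norm = Fa / max(Fa)` across the ROIs of one trial, so
#' normalized amplitudes lie between 0 and 1.
#'
#' @param metrics Data frame of [roi_metrics()] rows from one trial.
#' @return The input with an `fa_norm` column.
#' @export
normalize_fa <- function(metrics) {
  stopifnot(is.data.frame(metrics), "Fa" %in% names(metrics))
  mx <- max(metrics$Fa)
  metrics$fa_norm <- if (mx > 0) metrics$Fa / mx else 0 * metrics$Fa
  metrics
}

#' Recruitment summary over an ROI population
#'
#' Counts responsive ROIs (`n1`) among all ROIs (`n`), the response rate
#' `n1 / n`, and the per-side mean normalized amplitude over responsive
#' ROIs.
#'
#' @param metrics Data frame of [roi_metrics()] rows (with `fa_norm`; it is
#'   added via [normalize_fa()] when missing).
#' @return An object of class `recruitment_summary`: list with `n`, `n1`,
#'   `rate` and `mean_fa_norm` (named by side).
#' @export
recruitment_summary <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) == 0) stop("no ROIs to summarize")
  if (!"fa_norm" %in% names(metrics)) metrics <- normalize_fa(metrics)
  n <- nrow(metrics)
  n1 <- sum(metrics$responsive)
  resp <- metrics[metrics$responsive, ]
  mean_norm <- c(left = NA_real_, right = NA_real_)
  for (s in c("left", "right")) {
    v <- resp$fa_norm[resp$side == s]
    if (length(v)) mean_norm[[s]] <- mean(v)
  }
  structure(list(n = n, n1 = n1, rate = n1 / n, mean_fa_norm = mean_norm),
            class = "recruitment_summary")
}

#' Ipsilateral/contralateral recruitment asymmetry
#'
#' `delta_rate = ipsi$rate - contra$rate`;
#' `delta_fa_norm` is the difference of the mean normalized amplitudes
#' (pooled over sides within each summary). Positive values mean
#' ipsilateral dominance.
#'
#' @param ipsi,contra [recruitment_summary()] objects from the same trial.
#' @return List with `delta_rate` and `delta_fa_norm`.
#' @export
side_asymmetry <- function(ipsi, contra) {
  stopifnot(inherits(ipsi, "recruitment_summary"),
            inherits(contra, "recruitment_summary"))
  pooled <- function(s) {
    v <- s$mean_fa_norm[is.finite(s$mean_fa_norm)]
    if (length(v)) mean(v) else 0
  }
  list(delta_rate = ipsi$rate - contra$rate,
       delta_fa_norm = pooled(ipsi) - pooled(contra))
}
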