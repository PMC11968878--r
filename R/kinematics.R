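# Bout segmentation and kinematic features.
#
# Conventions: frames are 0-based in every user-facing table (the `frame`
# column of kinematics CSVs starts at 0) and are converted to R's 1-based
# indexing only at the point of subscripting. Angles are degrees throughout;
# positive tail angle means a rightward bend, and "ipsilateral" downstream
# means matching this sign. A bout window is the closed frame interval
# [f1 - 9, f1 + 30]: ten frames up to and including the tail-angle peak f1,
# then thirty frames after it, 40 samples in all.

#' Construct a tail/head angle trace
#'
#' @param tail_angle Signed tail angle per frame, degrees (positive =
#'   rightward bend).
#' @param head_angle Head angle per frame, degrees.
#' @param fps Frame rate, frames per second.
#' @param trial_id Identifier carried through downstream tables.
#' @return An object of class `tail_trace`.
#' @export
tail_trace <- function(tail_angle, head_angle, fps = 250, trial_id = "trial1") {
  stopifnot(is.numeric(tail_angle), is.numeric(head_angle), fps > 0)
  if (length(tail_angle) != length(head_angle))
    stop("tail and head series must have equal length")
  if (any(!is.finite(tail_angle)) || any(!is.finite(head_angle)))
    stop("angle series must be finite")
  structure(list(tail_angle = as.numeric(tail_angle),
                 head_angle = as.numeric(head_angle),
                 fps = fps, trial_id = trial_id),
            class = "tail_trace")
}

#' Detect bout peaks in a tail-angle trace
#'
#' Local maxima of the rectified tail angle `|tail_angle|` with height at
#' least `min_height` and pairwise separation of at least `min_distance`
#' frames. When two candidate peaks are closer than `min_distance`, the
#' higher one is kept (candidates are resolved in decreasing height order).
#' Plateau ties resolve to the earlier frame.
#'
#' @param trace A [tail_trace()].
#' @param min_height Minimum peak height, degrees.
#' @param min_distance Minimum separation between kept peaks, frames.
#' @return Integer vector of 0-based peak frames `f1`, ascending. May be
#'   empty.
#' @export
detect_bout_peaks <- function(trace, min_height = 5, min_distance = 40) {
  stopifnot(inherits(trace, "tail_trace"))
  x <- abs(trace$tail_angle)
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[x[i] >= min_height & x[i] > x[i - 1] & x[i] >= x[i + 1]]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]  # height desc, earlier frame on ties
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_distance))
      kept <- c(kept, p)
  }
  sort(kept) - 1L  # back to 0-based frames
}

#' Extract one bout event around a peak frame
#'
#' The window is the closed interval `[f1 - 9, f1 + 30]` (0-based): the ten
#' frames up to and including the peak and the thirty frames after it,
#' exactly 40 samples. Peaks whose window would leave the trace are
#' discarded (`NULL` is returned) rather than padded, so every bout segment
#' has length 40.
#'
#' @param trace A [tail_trace()].
#' @param f1 0-based peak frame.
#' @return An object of class `bout_event` (fields `f1`, `window`,
#'   `tail_segment`, `head_segment`, `side`, `fps`, `trial_id`), or `NULL`
#'   when the window falls outside the trace.
#' @export
extract_bout <- function(trace, f1) {
  stopifnot(inherits(trace, "tail_trace"))
  n <- length(trace$tail_angle)
  if (f1 < 9 || f1 + 30 > n - 1) return(NULL)  # discarded boundary bout
  idx <- (f1 - 9):(f1 + 30) + 1L
  tail_seg <- trace$tail_angle[idx]
  structure(list(
    f1 = as.integer(f1),
    window = c(f1 - 9L, f1 + 30L),
    tail_segment = tail_seg,
    head_segment = trace$head_angle[idx],
    side = if (tail_seg[10] >= 0) "right" else "left",
    fps = trace$fps,
    trial_id = trace$trial_id
  ), class = "bout_event")
}

#' Kinematic features of one bout
#'
#' `mean_bout_angle` is the signed arithmetic mean of the tail segment (the
#' discrete integral of the tail oscillation normalized by the window
#' length); `max_tail_amplitude` is the maximum rectified tail angle;
#' `head_change` is the head angle at the end of the window minus the head
#' angle at its start; `peak_to_head_delay` is the number of frames from the
#' tail peak to the half-rise crossing of the head change (NA when the head
#' change is negligible, < 1e-9 degrees).
#'
#' @param bout A `bout_event` as returned by [extract_bout()].
#' @return A one-row data frame with columns `f1`, `side`,
#'   `mean_bout_angle`, `max_tail_amplitude`, `head_change`,
#'   `peak_to_head_delay`.
#' @export
compute_features <- function(bout) {
  stopifnot(inherits(bout, "bout_event"), length(bout$tail_segment) == 40)
  h <- bout$head_segment
  dh <- h[40] - h[1]
  delay <- NA_real_
  if (abs(dh) > 1e-9) {
    cross <- which(abs(h - h[1]) >= abs(dh) / 2)[1]
    delay <- (bout$window[1] + cross - 1L) - bout$f1
  }
  data.frame(
    f1 = bout$f1,
    side = bout$side,
    mean_bout_angle = mean(bout$tail_segment),
    max_tail_amplitude = max(abs(bout$tail_segment)),
    head_change = dh,
    peak_to_head_delay = delay,
    stringsAsFactors = FALSE
  )
}

#' Segment a trace into a bout-feature table
#'
#' Runs peak detection, window extraction (boundary bouts discarded) and
#' feature computation, returning both the scalar feature table and the
#' 40-sample tail segments needed for time-series classification.
#'
#' @inheritParams detect_bout_peaks
#' @return An object of class `bout_set`: list with `features` (data frame:
#'   `trial_id`, `bout_id`, `f1`, `side`, `mean_bout_angle`,
#'   `max_tail_amplitude`, `head_change`, `peak_to_head_delay`), `segments`
#'   (numeric matrix, one 40-sample tail segment per row), `head_segments`,
#'   `fps`, and `n_discarded` (peaks whose window left the trace).
#' @export
segment_bouts <- function(trace, min_height = 5, min_distance = 40) {
  peaks <- detect_bout_peaks(trace, min_height, min_distance)
  events <- lapply(peaks, function(p) extract_bout(trace, p))
  dropped <- sum(vapply(events, is.null, logical(1)))
  events <- Filter(Negate(is.null), events)
  if (!length(events)) {
    feats <- data.frame(trial_id = character(0), bout_id = integer(0),
                        f1 = integer(0), side = character(0),
                        mean_bout_angle = numeric(0),
                        max_tail_amplitude = numeric(0),
                        head_change = numeric(0),
                        peak_to_head_delay = numeric(0),
                        stringsAsFactors = FALSE)
    return(structure(list(features = feats,
                          segments = matrix(numeric(0), 0, 40),
                          head_segments = matrix(numeric(0), 0, 40),
                          fps = trace$fps, n_discarded = dropped),
                     class = "bout_set"))
  }
  feats <- do.call(rbind, lapply(events, compute_features))
  feats <- cbind(data.frame(trial_id = trace$trial_id,
                            bout_id = seq_len(nrow(feats)),
                            stringsAsFactors = FALSE),
                 feats)
  structure(list(
    features = feats,
    segments = do.call(rbind, lapply(events, `[[`, "tail_segment")),
    head_segments = do.call(rbind, lapply(events, `[[`, "head_segment")),
    fps = trace$fps,
    n_discarded = dropped
  ), class = "bout_set")
}

#' Cumulative head-direction change
#'
#' Running sum of frame-to-frame head-angle increments; the first value is 0
#' and the final value equals `head_angle[last] - head_angle[first]`.
#'
#' @param trace A [tail_trace()].
#' @return Numeric vector, same length as the trace.
#' @export
cumulative_heading <- function(trace) {
  stopifnot(inherits(trace, "tail_trace"))
  cumsum(c(0, diff(trace$head_angle)))
}
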