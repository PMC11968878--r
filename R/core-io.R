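# Shared regression utility, file formats, configuration and reporting.
# All tabular I/O is CSV with documented headers; configurations are YAML;
# reports are JSON.

#' Ordinary least-squares regression with R-squared and slope test
#'
#' Fits `y ~ x` by ordinary least squares (via [stats::lm()]) and reports
#' the slope, intercept, coefficient of determination
#' `R^2 = 1 - SSE/SST`, the two-sided p-value of the slope, and `n`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, with `var(x) > 0`.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (var(x) == 0) stop("zero-variance predictor")
  if (var(y) == 0)  # degenerate: flat response, no variance to explain
    return(list(slope = 0, intercept = y[1], r_squared = 0,
                p_value = NA_real_, n = length(x)))
  fit <- lm(y ~ x)
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {  # exact fits are legitimate here (R^2 = 1)
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- s$coefficients
  p <- if (nrow(co) > 1) co["x", "Pr(>|t|)"] else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, p_value = unname(p), n = length(x))
}

# ---- CSV formats -----------------------------------------------------------

#' Read and write the pipeline's CSV formats
#'
#' Kinematics CSV columns: `frame` (0-based), `time_s`, `tail_angle_deg`,
#' `head_angle_deg`. Bout CSV columns: `trial_id`, `bout_id`, `f1`, `side`,
#' `mean_bout_angle`, `max_tail_amplitude`, `head_change`,
#' `peak_to_head_delay` (plus `label` once classified). Spike CSV columns:
#' `neuron_id`, `spike_time_s`. ROI CSV columns: `frame`, `roi_id`, `side`,
#' `F`, `Fb`.
#'
#' @param trace A [tail_trace()].
#' @param path File path.
#' @return Readers return the corresponding object or data frame; writers
#'   return `path` invisibly.
#' @export
write_kinematics_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tail_trace"))
  n <- length(trace$tail_angle)
  write.csv(data.frame(frame = seq_len(n) - 1L,
                       time_s = (seq_len(n) - 1L) / trace$fps,
                       tail_angle_deg = trace$tail_angle,
                       head_angle_deg = trace$head_angle),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @param fps Frame rate to attach (recovered from `time_s` when `NULL`).
#' @param trial_id Trial identifier to attach.
#' @export
read_kinematics_csv <- function(path, fps = NULL, trial_id = "trial1") {
  d <- read.csv(path)
  stopifnot(all(c("frame", "tail_angle_deg", "head_angle_deg") %in% names(d)))
  if (is.null(fps)) {
    fps <- if ("time_s" %in% names(d) && nrow(d) > 1)
      1 / mean(diff(d$time_s)) else 250
  }
  tail_trace(d$tail_angle_deg, d$head_angle_deg, fps = fps,
             trial_id = trial_id)
}

#' @rdname write_kinematics_csv
#' @param features Bout feature table (from [segment_bouts()] or
#'   [classify_pipeline()]).
#' @export
write_bouts_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @export
read_bouts_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_kinematics_csv
#' @param spikes A list of `spike_record` objects (see
#'   [simulate_spikes()]).
#' @export
write_spikes_csv <- function(spikes, path) {
  rows <- do.call(rbind, lapply(spikes, function(r) {
    if (!length(r$spike_times_s)) return(NULL)
    data.frame(neuron_id = r$neuron$id, spike_time_s = r$spike_times_s,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(neuron_id = character(0), spike_time_s = numeric(0))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @param rois A list of [roi_trace()] objects.
#' @export
write_rois_csv <- function(rois, path) {
  rows <- do.call(rbind, lapply(rois, function(r) {
    n <- length(r$F)
    data.frame(frame = seq_len(n) - 1L, roi_id = r$roi_id, side = r$side,
               F = r$F, Fb = if (length(r$Fb) == 1) rep(r$Fb, n) else r$Fb,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @param rate Imaging rate attached to the ROI traces read back.
#' @export
read_rois_csv <- function(path, rate = 7.5) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "roi_id", "side", "F", "Fb") %in% names(d)))
  lapply(split(d, d$roi_id), function(g) {
    g <- g[order(g$frame), ]
    fb <- if (length(unique(g$Fb)) == 1) g$Fb[1] else g$Fb
    roi_trace(g$F, fb, rate = rate, roi_id = g$roi_id[1], side = g$side[1])
  })
}

# ---- YAML configuration ----------------------------------------------------

config_sections <- c("seed", "out_dir", "kinematics", "circuit", "calcium",
                     "paired", "segment", "classify", "calcium_analysis")

#' Read / write a pipeline configuration
#'
#' The configuration is a YAML file with optional sections `seed`,
#' `out_dir`, `kinematics`, `circuit`, `calcium`, `paired`, `segment`,
#' `classify` and `calcium_analysis`; unknown top-level keys (and unknown
#' keys within the generator sections) are rejected rather than silently
#' ignored. Values round-trip losslessly through [write_pipeline_config()].
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: a named list of resolved configuration
#'   objects (generator sections become their `*_config()` objects).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- list(seed = raw$seed %||% 1L, out_dir = raw$out_dir %||% ".")
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) return(ctor())
    known <- names(formals(ctor))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop("unknown keys in '", section, "': ", paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  out$kinematics <- build("kinematics", kinematics_config)
  out$calcium <- build("calcium", calcium_config)
  out$paired <- build("paired", paired_config)
  out$circuit <- if (is.null(raw$circuit)) circuit_config() else
    circuit_config(do.call(rbind.data.frame, raw$circuit))
  out$segment <- modifyList(list(min_height = 5, min_distance = 40),
                            raw$segment %||% list())
  out$classify <- modifyList(list(knn_k = 10, p = 3, signed = FALSE),
                             raw$classify %||% list())
  out$calcium_analysis <- modifyList(
    list(threshold = 0.3, inactivity = 5, gaussian_sigma = 2,
         sg_window = 7, sg_poly = 3),
    raw$calcium_analysis %||% list())
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pipeline_config
#' @param cfg A configuration list (as returned by
#'   [read_pipeline_config()], or hand-built from the `*_config()`
#'   constructors).
#' @export
write_pipeline_config <- function(cfg, path) {
  strip <- function(x) {
    if (inherits(x, c("kinematics_config", "calcium_config",
                      "paired_config")))
      return(lapply(unclass(x), strip))
    if (inherits(x, "circuit_config")) {
      rows <- x$neurons
      return(lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ])))
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  yaml::write_yaml(lapply(cfg, strip), path)
  invisible(path)
}

# ---- Report ----------------------------------------------------------------

#' Gather pipeline outputs into a single JSON report
#'
#' Collects per-class bout counts and feature summaries, the head-on-tail
#' regressions, and any recruitment summaries into one deterministic JSON
#' document. An empty bout table yields a report with zero counts rather
#' than an error.
#'
#' @param features Labeled bout feature table (a `label` column is
#'   optional; unlabeled bouts are counted as `"unlabeled"`).
#' @param recruitment Optional named list of [recruitment_summary()]
#'   objects.
#' @param regressions Optional named list of [linear_regression()] results.
#' @param path Optional file to write the JSON to.
#' @return The report as a list (invisibly when written to file).
#' @export
run_report <- function(features, recruitment = NULL, regressions = NULL,
                       path = NULL) {
  stopifnot(is.data.frame(features))
  if (!"label" %in% names(features) && nrow(features) > 0)
    features$label <- "unlabeled"
  counts <- if (nrow(features)) as.list(table(features$label)) else list()
  summaries <- if (nrow(features)) {
    cs <- class_summary(features)
    lapply(split(cs, cs$label), function(r) as.list(r[1, , drop = TRUE]))
  } else list()
  report <- list(
    n_bouts = nrow(features),
    class_counts = counts,
    class_summaries = summaries,
    regressions = lapply(regressions %||% list(), unclass),
    recruitment = lapply(recruitment %||% list(), function(s) {
      list(n = s$n, n1 = s$n1, rate = s$rate,
           mean_fa_norm = as.list(s$mean_fa_norm))
    })
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
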