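# Two-stage turn classification: unsupervised DTW time-series k-means on
# the 40-sample tail segments, then a supervised cubic (Minkowski p = 3)
# k-nearest-neighbour classifier on the two scalar kinematic features
# (mean bout angle, maximum tail amplitude).

#' Dynamic-time-warping distance and alignment path
#'
#' Minimal cumulative cost over monotone warping paths with step set
#' `{(1,0), (0,1), (1,1)}` and local cost `|x_i - y_j|` (or
#' `(x_i - y_j)^2` when `squared = TRUE`, the variant used inside the
#' k-means stage). Ties between steps prefer the diagonal, making the
#' returned path deterministic. The distance is symmetric and zero iff the
#' optimal alignment has zero cost (in particular `dtw_distance(x, x)` is 0).
#'
#' @param x,y Non-empty numeric series.
#' @param squared Use squared local cost instead of absolute differences.
#' @return An object of class `dtw_result`: `distance` (non-negative
#'   accumulated cost) and `path`, a two-column integer matrix of aligned
#'   (1-based) index pairs from `(1, 1)` to `(length(x), length(y))`.
#' @export
dtw_distance <- function(x, y, squared = FALSE) {
  if (!length(x) || !length(y)) stop("series must be non-empty")
  r <- .dtw_cpp(as.numeric(x), as.numeric(y), squared = squared,
                want_path = TRUE)
  structure(list(distance = r$distance, path = r$path), class = "dtw_result")
}

#' Time-series k-means with DTW assignment and barycenter averaging
#'
#' Lloyd-style alternation: series are assigned to the nearest centroid
#' under squared-cost DTW, then each centroid is updated by one
#' DTW-barycenter-averaging step (each centroid sample becomes the mean of
#' all member samples aligned onto it). With squared local cost and
#' mean-based updates the inertia (sum of assigned squared-cost DTW
#' distances) is non-increasing across iterations. Initial centroids are
#' `k` series sampled under the given seed, so a fixed seed gives
#' identical assignments.
#'
#' @param series Numeric matrix, one series per row (all the same length;
#'   40 samples for bout segments).
#' @param k Number of clusters (at most `nrow(series)`).
#' @param seed Integer seed for centroid initialization.
#' @param max_iter Maximum Lloyd iterations.
#' @return List with `assignment` (integer vector), `centroids` (k x L
#'   matrix), `inertia`, `inertia_history` (one value per assignment step),
#'   `iterations` and `converged`.
#' @export
tskmeans_fit <- function(series, k, seed = 1, max_iter = 30) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (k > n) stop("k exceeds the number of series")
  stopifnot(k >= 1)
  set.seed(seed)
  centroids <- series[sample.int(n, k), , drop = FALSE]
  assignment <- rep(0L, n)
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- .dtw_cdist_cpp(series, centroids, squared = TRUE)
    new_assign <- max.col(-d, ties.method = "first")
    history <- c(history, sum(d[cbind(seq_len(n), new_assign)]))
    if (iter > 1L && all(new_assign == assignment)) {
      assignment <- new_assign
      converged <- TRUE
      break
    }
    assignment <- new_assign
    for (c in seq_len(k)) {
      members <- which(assignment == c)
      if (!length(members)) {
        # re-seed an empty cluster with the series farthest from its centroid
        far <- which.max(d[cbind(seq_len(n), assignment)])
        centroids[c, ] <- series[far, ]
      } else {
        centroids[c, ] <- .dba_update_cpp(series[members, , drop = FALSE],
                                          centroids[c, ], squared = TRUE)
      }
    }
  }
  list(assignment = assignment, centroids = centroids,
       inertia = history[length(history)], inertia_history = history,
       iterations = iter, converged = converged)
}

minkowski_dist <- function(query, points, p) {
  (rowSums(abs(sweep(points, 2, query))^p))^(1 / p)
}

#' Fit a cubic k-nearest-neighbour turn classifier
#'
#' Stores the training features (standardized to zero mean, unit variance),
#' their labels, and the Minkowski exponent. Prediction takes the majority
#' label of the `k` nearest training points under Minkowski-`p` distance on
#' standardized features; vote ties are broken by the label of the single
#' nearest neighbour.
#'
#' @param features Numeric matrix or data frame of two columns
#'   (`mean_bout_angle`, `max_tail_amplitude`).
#' @param labels Character vector of class labels, one per row.
#' @param k Number of neighbours.
#' @param p Minkowski exponent (3 = the "cubic" metric).
#' @return An object of class `turn_knn`.
#' @export
knn_fit <- function(features, labels, k = 10, p = 3) {
  x <- as.matrix(features)
  stopifnot(ncol(x) == 2, nrow(x) == length(labels), k >= 1, p > 0)
  if (k > nrow(x)) stop("k exceeds the training-set size")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  structure(list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"),
                 labels = as.character(labels), k = k, p = p,
                 center = ctr, scale = scl),
            class = "turn_knn")
}

#' @rdname knn_fit
#' @param model A fitted `turn_knn`.
#' @param newdata Feature matrix/data frame to classify (same two columns).
#' @return `knn_predict`: character vector of predicted labels.
#' @export
knn_predict <- function(model, newdata) {
  stopifnot(inherits(model, "turn_knn"))
  q <- as.matrix(newdata)
  stopifnot(ncol(q) == 2)
  q <- sweep(sweep(q, 2, model$center), 2, model$scale, "/")
  vapply(seq_len(nrow(q)), function(i) {
    d <- minkowski_dist(q[i, ], model$x, model$p)
    ord <- order(d)                   # stable: row order breaks exact ties
    nb <- model$labels[ord[seq_len(model$k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else nb[1]  # vote tie -> nearest neighbour
  }, character(1))
}

#' Two-stage steering/exploratory classification pipeline
#'
#' Stage 1 clusters the 40-sample tail segments (rectified to `|angle|`
#' unless `signed = TRUE`, so left and right turns cluster together) with
#' DTW time-series k-means, `k = 2`; the cluster with the larger median
#' maximum tail amplitude is labelled `"steering"`, the other
#' `"exploratory"`. Stage 2 trains the cubic KNN on the two scalar features
#' with those labels (or with `labels` when a manual annotation is
#' supplied), and the reported bout labels are the KNN predictions.
#'
#' When the two clusters' median amplitudes differ by less than
#' `min_separation` the bouts are treated as a single class: all bouts get
#' the label implied by the overall median amplitude, with a warning, and
#' no KNN model is fitted.
#'
#' @param bouts A [segment_bouts()] `bout_set` (at least 10 bouts).
#' @param knn_k,p KNN neighbour count and Minkowski exponent.
#' @param seed Seed for the k-means initialization.
#' @param signed Cluster signed instead of rectified segments.
#' @param labels Optional manual per-bout labels overriding the stage-1
#'   cluster annotation.
#' @param min_separation Minimum between-cluster gap in median maximum tail
#'   amplitude (degrees) for a two-class solution.
#' @return List with `features` (the feature table plus a `label` column),
#'   `model` (the `turn_knn`, or `NULL` in the degenerate single-class
#'   case), `kmeans` (stage-1 fit), and `class_summary` (per-class feature
#'   means, SDs and quantiles).
#' @export
classify_pipeline <- function(bouts, knn_k = 10, p = 3, seed = 1,
                              signed = FALSE, labels = NULL,
                              min_separation = 10) {
  stopifnot(inherits(bouts, "bout_set"))
  n <- nrow(bouts$features)
  if (n == 0) stop("no bouts to classify")
  if (n < 10) stop("need at least 10 bouts to classify")
  segs <- if (signed) bouts$segments else abs(bouts$segments)
  if (nrow(unique(segs)) == 1)
    stop("un-classifiable: all bouts are identical")

  km <- tskmeans_fit(segs, k = 2, seed = seed)
  amp <- bouts$features$max_tail_amplitude
  med <- tapply(amp, factor(km$assignment, levels = 1:2), median)
  med[is.na(med)] <- -Inf

  feats <- bouts$features
  x <- feats[, c("mean_bout_angle", "max_tail_amplitude")]

  if (is.null(labels)) {
    if (abs(med[1] - med[2]) < min_separation || any(!is.finite(med))) {
      warning("stage 1 found no two amplitude-separated clusters; ",
              "returning a single-label output")
      lab <- if (median(amp) >= 30) "steering" else "exploratory"
      feats$label <- rep(lab, n)
      return(list(features = feats, model = NULL, kmeans = km,
                  class_summary = class_summary(feats)))
    }
    steer_cluster <- which.max(med)
    labels <- ifelse(km$assignment == steer_cluster, "steering", "exploratory")
  } else {
    stopifnot(length(labels) == n)
  }

  model <- knn_fit(x, labels, k = min(knn_k, n), p = p)
  feats$label <- knn_predict(model, x)
  list(features = feats, model = model, kmeans = km,
       class_summary = class_summary(feats))
}

class_summary <- function(feats) {
  do.call(rbind, lapply(split(feats, feats$label), function(d) {
    data.frame(
      label = d$label[1], n = nrow(d),
      mean_amp = mean(d$max_tail_amplitude),
      sd_amp = sd(d$max_tail_amplitude),
      q25_amp = unname(quantile(d$max_tail_amplitude, 0.25)),
      median_amp = median(d$max_tail_amplitude),
      q75_amp = unname(quantile(d$max_tail_amplitude, 0.75)),
      mean_bout_angle = mean(d$mean_bout_angle),
      mean_head_change = mean(abs(d$head_change)),
      stringsAsFactors = FALSE
    )
  }))
}

#' Serialize / restore a fitted turn classifier
#'
#' The model (standardized training features, labels, `k`, `p`,
#' standardization parameters) is written as JSON so a classifier trained
#' on annotated data can be reused on new bouts.
#'
#' @param model A `turn_knn`.
#' @param path File path.
#' @export
write_turn_model <- function(model, path) {
  stopifnot(inherits(model, "turn_knn"))
  jsonlite::write_json(
    list(x = model$x, labels = model$labels, k = model$k, p = model$p,
         center = model$center, scale = model$scale),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_turn_model
#' @return `read_turn_model`: the restored `turn_knn`.
#' @export
read_turn_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x = as.matrix(o$x), labels = o$labels, k = o$k, p = o$p,
                 center = o$center, scale = o$scale),
            class = "turn_knn")
}
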