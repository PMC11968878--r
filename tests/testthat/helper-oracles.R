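# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DTW oracle enumerates warping paths
# recursively with no dynamic-programming table, and the regression oracle
# solves the normal equations directly.

# Exhaustive DTW: minimum cumulative |x_i - y_j| over all monotone paths.
dtw_brute <- function(x, y) {
  rec <- function(i, j) {
    c0 <- abs(x[i] - y[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    c0 + best
  }
  rec(length(x), length(y))
}

# Closed-form simple-regression coefficients from the normal equations.
ols_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Peak time and value of the unit-peak double-exponential calcium kernel,
# from the closed form for the extremum of exp(-t/td) - exp(-t/tr).
kernel_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

# All integer-valued series of length 1..max_len over the given alphabet.
all_short_series <- function(max_len = 4, values = 0:2) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(values), len))
    for (r in seq_len(nrow(grid))) out[[length(out) + 1]] <- as.numeric(grid[r, ])
  }
  out
}

# Small default-condition mixed trial used by several tests.
make_mixed_bouts <- function(n = 200, seed = 42, steering_fraction = 0.5) {
  cfg <- kinematics_config(steering_fraction = steering_fraction)
  trial <- generate_bouts(n, cfg, seed = seed)
  bs <- segment_bouts(trial$trace)
  truth <- trial$bouts$class[match(bs$features$f1, trial$bouts$f1)]
  list(trial = trial, bouts = bs, truth = truth)
}
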