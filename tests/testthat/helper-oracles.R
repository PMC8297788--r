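# Independent brute-force oracles and small fixture builders.

# Exhaustive application of the sharp-peak rule: a sample m is an apex iff it
# is a local maximum (earliest sample of a plateau) and there exist a rise
# index j and a fall index k within L samples with x[m]-x[j] >= th and
# x[m]-x[k] >= th. Deliberately written as plain loops, independently of
# detect_peaks().
brute_force_apex_indices <- function(x, th, L) {
  n <- length(x)
  apices <- integer(0)
  for (m in seq_len(n)) {
    if (m == 1L || m == n) next
    if (!(x[m] > x[m - 1] && x[m] >= x[m + 1])) next
    rise <- FALSE
    for (j in max(1L, m - L):(m - 1L)) {
      if (x[m] - x[j] >= th) rise <- TRUE
    }
    fall <- FALSE
    for (k in (m + 1L):min(n, m + L)) {
      if (x[m] - x[k] >= th) fall <- TRUE
    }
    if (rise && fall) apices <- c(apices, m)
  }
  apices
}

# Per-point confusion tally, independent of confusion().
brute_force_confusion <- function(pred, truth) {
  counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in seq_along(pred)) {
    key <- if (pred[i] && truth[i]) "TP"
    else if (pred[i] && !truth[i]) "FP"
    else if (!pred[i] && !truth[i]) "TN"
    else "FN"
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Wrap a numeric vector as a pressure trace on the 0.5 s grid.
as_trace <- function(values, cow_id = "cowT") {
  sch <- rumipress::behavior_schedule("other", length(values) * 0.5, cow_id)
  s <- rumipress::generate_session(
    sch,
    rumipress::generator_config(noise_sd = 0, baseline_drift_sd = 0),
    templates = list(other = rumipress::contraction_template(2, peak_amplitude = 0)),
    intervals = list(other = rumipress::default_interval_params("other")),
    seed = 1
  )
  tr <- s$trace
  tr$values <- as.numeric(values)
  tr
}

# Lay sharp triangular peaks (rise over rise_s, symmetric fall) of the given
# amplitude at the given apex times on an otherwise flat trace.
triangle_trace <- function(total_s, apex_times, amplitude = 3, rise_s = 1.5) {
  t <- seq(0, total_s - 0.5, by = 0.5)
  x <- numeric(length(t))
  for (a in apex_times) {
    tri <- pmax(0, 1 - abs(t - a) / rise_s)
    x <- pmax(x, amplitude * tri)
  }
  as_trace(x)
}

# Toy feature matrix: n rows of iid noise features, positives for `behavior`
# shifted by `shift` on the first feature. Balanced across two cows.
toy_features <- function(n = 200, behavior = "rumination", shift = 5,
                         seed = 1) {
  set.seed(seed)
  fn <- rumipress::feature_names()
  df <- as.data.frame(matrix(rnorm(n * length(fn)), nrow = n,
                             dimnames = list(NULL, fn)))
  pos <- seq_len(n) <= n / 2
  df[[fn[1]]][pos] <- df[[fn[1]]][pos] + shift
  df$label <- ifelse(pos, behavior, "other")
  df$cow_id <- rep(c("c1", "c2", "c3", "c4"), length.out = n)
  df$window_end_s <- seq_len(n) * 0.5
  df
}
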