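#' Feature-extraction configuration
#'
#' Windows are 120 s long (240 samples at 0.5 s) and slide by one sample, so
#' consecutive windows overlap by 119.5 s. Each window yields 30 features:
#' 10 Fourier magnitudes (discrete-Fourier bins 1-10 of the mean-removed
#' window; bin spacing 1/120 Hz, spanning the contraction band around
#' 0.02-0.03 Hz), 10 band-averaged powers of a Hann-tapered periodogram over
#' ten equal-width bands covering (0, 0.1] Hz, and 10 sample autocorrelations
#' at lags 5, 10, ..., 50 s (straddling all behaviors' mean inter-cycle gaps).
#'
#' @param window_length_s Window length in seconds.
#' @param n_fft Number of leading Fourier-magnitude features.
#' @param psd_band_max_hz Upper edge of the PSD band range.
#' @param n_psd Number of equal-width PSD bands.
#' @param acf_lags_s Autocorrelation lags in seconds.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(window_length_s = 120,
                           n_fft = 10,
                           psd_band_max_hz = 0.1,
                           n_psd = 10,
                           acf_lags_s = seq(5, 50, by = 5)) {
  n_samples <- window_length_s / SAMPLING_INTERVAL
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("window_length_s must be a multiple of 0.5 s", call. = FALSE)
  }
  structure(
    list(window_length_s = window_length_s,
         window_samples = as.integer(round(n_samples)),
         n_fft = as.integer(n_fft),
         psd_band_max_hz = psd_band_max_hz,
         n_psd = as.integer(n_psd),
         acf_lags_s = acf_lags_s),
    class = "feature_config"
  )
}

#' @rdname feature_config
#' @export
feature_names <- function(config = feature_config()) {
  c(sprintf("fft_%02d", seq_len(config$n_fft)),
    sprintf("psd_%02d", seq_len(config$n_psd)),
    sprintf("acf_%02ds", as.integer(config$acf_lags_s)))
}

#' Normalize a pressure trace
#'
#' Per-session z-scoring: the returned trace has mean 0 and standard
#' deviation 1. Both analysis pipelines run on normalized traces; working on
#' raw traces makes the peak detector sensitive to baseline level and gain.
#'
#' @param trace A `pressure_trace` with at least 2 samples and non-zero
#'   variance.
#' @return The normalized `pressure_trace`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  x <- as.numeric(trace$values)
  if (length(x) < 2L) stop("trace too short to normalize", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot normalize a constant (zero-variance) trace", call. = FALSE)
  }
  trace$values <- (x - mean(x)) / s
  trace
}

#' Cut a trace into 240-sample sliding windows
#'
#' @param trace A `pressure_trace` with at least 240 samples.
#' @param config A [feature_config()].
#' @return A list with `values` (matrix, one row per window, 240 columns) and
#'   `end_s` (time of each window's final sample). Consecutive windows share
#'   239 samples (119.5 s overlap).
#' @export
make_windows <- function(trace, config = feature_config()) {
  stopifnot(inherits(trace, "pressure_trace"))
  n <- config$window_samples
  x <- trace$values
  if (length(x) < n) {
    stop("trace has ", length(x), " samples; at least ", n, " required",
         call. = FALSE)
  }
  w <- stats::embed(x, n)[, n:1, drop = FALSE]
  times <- trace_times(trace)
  list(values = w, end_s = times[n:length(x)])
}

## Hann taper and its squared-sum; length n.
hann_taper <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

## One-sided modified periodogram of a mean-removed window: power at bins
## 0..n/2 scaled so that with a rectangular taper the bin powers sum to the
## window's population variance (discrete Parseval).
modified_periodogram <- function(xc, taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  n <- length(xc)
  w <- if (taper == "hann") hann_taper(n) else rep(1, n)
  X <- fft(xc * w)
  k <- 0:(n %/% 2)
  coef <- ifelse(k == 0 | (n %% 2 == 0 & k == n %/% 2), 1, 2)
  p <- coef * Mod(X[k + 1])^2 / (n * sum(w^2))
  names(p) <- k
  p
}

## Bin indices (k >= 1) of each PSD band over (0, band_max] Hz.
psd_band_bins <- function(config) {
  n <- config$window_samples
  fs <- 1 / SAMPLING_INTERVAL
  k_max <- floor(config$psd_band_max_hz * n / fs + 1e-9)
  freqs <- (1:k_max) * fs / n
  width <- config$psd_band_max_hz / config$n_psd
  band <- pmin(config$n_psd, ceiling(freqs / width - 1e-9))
  split(1:k_max, factor(band, levels = seq_len(config$n_psd)))
}

#' Extract the 30 spectral features of one window
#'
#' Reference (per-window) implementation of the feature definitions in
#' [feature_config()]. Zero-variance windows yield an all-zero feature vector
#' by convention (the mean-removed signal is identically zero, and the
#' autocorrelation of a zero-variance window is defined as 0).
#'
#' @param window Numeric vector of exactly 240 finite samples.
#' @param config A [feature_config()].
#' @return Named numeric vector of length 30.
#' @export
extract_features <- function(window, config = feature_config()) {
  n <- config$window_samples
  if (length(window) != n) {
    stop("window must contain exactly ", n, " samples", call. = FALSE)
  }
  if (any(!is.finite(window))) stop("window contains non-finite values", call. = FALSE)
  out <- numeric(config$n_fft + config$n_psd + length(config$acf_lags_s))
  names(out) <- feature_names(config)
  xc <- window - mean(window)
  v <- mean(xc^2)
  if (v <= 1e-12) return(out)

  X <- fft(xc)
  out[seq_len(config$n_fft)] <- 2 * Mod(X[2:(config$n_fft + 1)]) / n

  p <- modified_periodogram(xc, "hann")
  bands <- psd_band_bins(config)
  out[config$n_fft + seq_len(config$n_psd)] <-
    vapply(bands, function(k) mean(p[k + 1]), numeric(1))

  lags <- as.integer(round(config$acf_lags_s / SAMPLING_INTERVAL))
  denom <- sum(xc^2)
  out[config$n_fft + config$n_psd + seq_along(lags)] <-
    vapply(lags, function(l) {
      sum(xc[seq_len(n - l)] * xc[(l + 1):n]) / denom
    }, numeric(1))
  out
}

#' Label of the window ending at a given time
#'
#' Windows are matched to behavior by their final timepoint (a causal
#' convention suitable for online monitoring).
#'
#' @param labels A `behavior_labels` object.
#' @param window_end_time Time in seconds of the window's final sample.
#' @return The behavior class at that time.
#' @export
window_label <- function(labels, window_end_time) {
  stopifnot(inherits(labels, "behavior_labels"))
  i <- which(abs(labels$times - window_end_time) < 1e-9)
  if (length(i) != 1L) {
    stop("no label at window end time ", window_end_time, " s", call. = FALSE)
  }
  labels$labels[i]
}

## Sliding-window feature computation for one normalized trace, algebraically
## identical to applying extract_features() to every window but O(n * p)
## via rolling sums and sliding dot products (stats::filter).
rolling_features <- function(x, config) {
  n <- config$window_samples
  N <- length(x)
  nwin <- N - n + 1L
  fs <- 1 / SAMPLING_INTERVAL

  S1 <- roll_sum(x, n)
  S2 <- roll_sum(x^2, n)
  m <- S1 / n
  varpop <- pmax(S2 / n - m^2, 0)
  zero <- varpop <= 1e-12

  slide_dot <- function(kern) {
    y <- stats::filter(x, rev(kern), method = "convolution", sides = 1)
    as.numeric(y[n:N])
  }

  feats <- matrix(0, nrow = nwin, ncol = config$n_fft + config$n_psd +
                    length(config$acf_lags_s))
  colnames(feats) <- feature_names(config)

  idx <- 0:(n - 1)
  for (k in seq_len(config$n_fft)) {
    ck <- cos(2 * pi * k * idx / n)
    sk <- sin(2 * pi * k * idx / n)
    A <- slide_dot(ck)
    B <- slide_dot(sk)
    feats[, k] <- 2 * sqrt(A^2 + B^2) / n
  }

  w <- hann_taper(n)
  sum_w2 <- sum(w^2)
  bands <- psd_band_bins(config)
  k_needed <- sort(unique(unlist(bands)))
  p_by_k <- matrix(0, nrow = nwin, ncol = max(k_needed))
  for (k in k_needed) {
    ck <- w * cos(2 * pi * k * idx / n)
    sk <- w * sin(2 * pi * k * idx / n)
    ReW <- sum(ck)
    ImW <- sum(sk)
    A <- slide_dot(ck) - m * ReW
    B <- slide_dot(sk) - m * ImW
    p_by_k[, k] <- 2 * (A^2 + B^2) / (n * sum_w2)
  }
  for (j in seq_along(bands)) {
    kk <- bands[[j]]
    feats[, config$n_fft + j] <- rowMeans(p_by_k[, kk, drop = FALSE])
  }

  denom <- S2 - n * m^2
  lags <- as.integer(round(config$acf_lags_s / SAMPLING_INTERVAL))
  for (j in seq_along(lags)) {
    l <- lags[j]
    z <- x[seq_len(N - l)] * x[(l + 1):N]
    Z <- roll_sum(z, n - l)[seq_len(nwin)]
    Sx <- roll_sum(x, n - l)
    Sa <- Sx[seq_len(nwin)]
    Sb <- Sx[seq_len(nwin) + l]
    num <- Z - m * (Sa + Sb) + (n - l) * m^2
    r <- ifelse(zero, 0, num / denom)
    feats[, config$n_fft + config$n_psd + j] <- r
  }

  feats[zero, ] <- 0
  feats
}

#' Build the per-window feature matrix for one or more sessions
#'
#' Normalizes each session's trace, slides the 120 s window at 0.5 s steps
#' and computes the 30 features per window, matching each window to the
#' behavior label at its final timepoint and carrying the cow identifier
#' through (required by leave-one-animal-out validation). Uses a rolling
#' computation that is algebraically identical to calling
#' [extract_features()] on every window.
#'
#' @param sessions A `session_data` object, a `list(trace=, labels=)` pair,
#'   or a list of either.
#' @param config A [feature_config()].
#' @return Data frame with 30 feature columns plus `window_end_s`, `label`
#'   and `cow_id`, one row per window, ordered by window end time within each
#'   session.
#' @export
build_feature_matrix <- function(sessions, config = feature_config()) {
  if (inherits(sessions, "session_data") ||
      (is.list(sessions) && !is.null(sessions$trace))) {
    sessions <- list(sessions)
  }
  out <- lapply(sessions, function(s) {
    trace <- normalize_trace(s$trace)
    labels <- s$labels
    n <- config$window_samples
    if (length(trace$values) < n) {
      stop("session shorter than one window", call. = FALSE)
    }
    times <- trace_times(trace)
    if (length(labels$labels) != length(trace$values) ||
        any(abs(labels$times - times) > 1e-9)) {
      stop("trace and labels are not aligned; see align_session()", call. = FALSE)
    }
    feats <- rolling_features(trace$values, config)
    df <- as.data.frame(feats)
    df$window_end_s <- times[n:length(times)]
    df$label <- labels$labels[n:length(times)]
    df$cow_id <- trace$cow_id
    df
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
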