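#' Peak-detection configuration
#'
#' A sharp peak is a local maximum that rises by at least `rise_threshold`
#' (normalized pressure units) within `rise_timespan` seconds and then falls
#' by at least the same amount within the same timespan. Peaks whose apices
#' are at most `max_intra_cycle_gap` apart belong to one contraction cycle.
#' Intermediate window features and the rumination rule use a trailing
#' `feature_window` of 75 s. A two-peak cycle counts as rumination when its
#' span is within `two_peak_span_tolerance` (fractional) of the running
#' median three-peak cycle span.
#'
#' @param rise_threshold Required rise/fall, normalized pressure units. The
#'   default 1.5 sits several noise standard deviations above the measurement
#'   noise of a z-scored session yet well below contraction amplitudes, so
#'   noise and baseline drift fail the rule while contraction peaks pass.
#' @param rise_timespan Time within which the rise/fall must occur, seconds.
#' @param max_intra_cycle_gap Maximum apex-to-apex gap within a cycle, seconds.
#' @param feature_window Trailing window length for window features and the
#'   rumination rule, seconds.
#' @param two_peak_span_tolerance Fractional span tolerance for the two-peak
#'   rumination exception.
#' @param median_init_cycles Number of three-peak cycles needed to initialize
#'   the running median span before the two-peak exception activates.
#' @return An object of class `peak_config`.
#' @export
peak_config <- function(rise_threshold = 1.5,
                        rise_timespan = 3.0,
                        max_intra_cycle_gap = 12.0,
                        feature_window = 75,
                        two_peak_span_tolerance = 0.2,
                        median_init_cycles = 5L) {
  if (rise_threshold <= 0 || rise_timespan <= 0 || max_intra_cycle_gap <= 0 ||
      feature_window <= 0) {
    stop("thresholds, timespans and windows must be positive", call. = FALSE)
  }
  if (two_peak_span_tolerance <= 0 || two_peak_span_tolerance >= 1) {
    stop("two_peak_span_tolerance must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(rise_threshold = rise_threshold,
         rise_timespan = rise_timespan,
         max_intra_cycle_gap = max_intra_cycle_gap,
         feature_window = feature_window,
         two_peak_span_tolerance = two_peak_span_tolerance,
         median_init_cycles = as.integer(median_init_cycles)),
    class = "peak_config"
  )
}

#' Detect sharp pressure peaks
#'
#' Scans a (normalized) pressure trace for local maxima that rise by at least
#' `rise_threshold` within `rise_timespan` before the apex and fall by at
#' least `rise_threshold` within `rise_timespan` after it. The apex is the
#' local maximum between the qualifying rise and fall (earliest sample on
#' plateaus). Onset is the earliest qualifying rise start within the
#' timespan, offset the latest qualifying fall end; where supports of
#' consecutive peaks overlap, they are trimmed at the interior valley so
#' peaks never overlap.
#'
#' @param trace A normalized `pressure_trace` (see [normalize_trace()]).
#' @param config A [peak_config()].
#' @return Data frame with columns `apex_time`, `onset_time`, `offset_time`,
#'   `apex_value`, ordered by apex time; zero rows for flat traces.
#' @export
detect_peaks <- function(trace, config = peak_config()) {
  stopifnot(inherits(trace, "pressure_trace"))
  x <- trace$values
  n <- length(x)
  L <- as.integer(round(config$rise_timespan / SAMPLING_INTERVAL))
  th <- config$rise_threshold
  times <- trace_times(trace)
  empty <- data.frame(apex_time = numeric(0), onset_time = numeric(0),
                      offset_time = numeric(0), apex_value = numeric(0))
  if (n < 3L) return(empty)

  ## local maxima (earliest sample of a plateau)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                x[2:(n - 1)] >= x[3:n], FALSE)

  ## min over the L samples strictly before / after each position
  shift_min <- function(k) c(rep(Inf, k), x[seq_len(n - k)])
  shift_min_fwd <- function(k) c(x[(k + 1):n], rep(Inf, k))
  min_before <- shift_min(1L)
  min_after <- shift_min_fwd(1L)
  if (L >= 2L) {
    for (k in 2:L) {
      min_before <- pmin(min_before, shift_min(k))
      min_after <- pmin(min_after, shift_min_fwd(k))
    }
  }
  qualifies <- is_max & (x - min_before >= th) & (x - min_after >= th)
  apex_idx <- which(qualifies)
  if (!length(apex_idx)) return(empty)

  onset_idx <- integer(length(apex_idx))
  offset_idx <- integer(length(apex_idx))
  for (i in seq_along(apex_idx)) {
    m <- apex_idx[i]
    back <- max(1L, m - L):(m - 1L)
    onset_idx[i] <- back[which(x[m] - x[back] >= th)[1L]]
    fwd <- (m + 1L):min(n, m + L)
    qual <- which(x[m] - x[fwd] >= th)
    offset_idx[i] <- fwd[qual[length(qual)]]
  }

  ## trim overlapping supports at the interior valley
  if (length(apex_idx) > 1L) {
    for (i in seq_len(length(apex_idx) - 1L)) {
      if (offset_idx[i] >= onset_idx[i + 1L]) {
        between <- apex_idx[i]:apex_idx[i + 1L]
        valley <- between[which.min(x[between])]
        offset_idx[i] <- valley
        onset_idx[i + 1L] <- valley
      }
    }
  }

  data.frame(apex_time = times[apex_idx],
             onset_time = times[onset_idx],
             offset_time = times[offset_idx],
             apex_value = x[apex_idx])
}

#' Group detected peaks into contraction cycles
#'
#' Maximal runs of consecutive peaks whose apex-to-apex gaps are at most
#' `max_intra_cycle_gap` form one contraction cycle; an isolated peak forms a
#' one-peak cycle.
#'
#' @param peaks Data frame from [detect_peaks()] (time-ordered).
#' @param config A [peak_config()].
#' @return Data frame with columns `cycle_id`, `start_time` (onset of first
#'   peak), `end_time` (offset of last peak), `span`, `n_peaks`, plus a
#'   `peak_times` list attribute of apex times per cycle.
#' @export
group_cycles <- function(peaks, config = peak_config()) {
  empty <- data.frame(cycle_id = integer(0), start_time = numeric(0),
                      end_time = numeric(0), span = numeric(0),
                      n_peaks = integer(0))
  attr(empty, "peak_times") <- list()
  if (nrow(peaks) == 0L) return(empty)
  gaps <- diff(peaks$apex_time)
  new_cycle <- c(TRUE, gaps > config$max_intra_cycle_gap)
  cyc <- cumsum(new_cycle)
  first <- match(unique(cyc), cyc)
  last <- length(cyc) + 1L - match(unique(cyc), rev(cyc))
  out <- data.frame(
    cycle_id = seq_along(first),
    start_time = peaks$onset_time[first],
    end_time = peaks$offset_time[last],
    span = peaks$offset_time[last] - peaks$onset_time[first],
    n_peaks = last - first + 1L
  )
  attr(out, "peak_times") <- lapply(seq_along(first), function(i)
    peaks$apex_time[first[i]:last[i]])
  out
}

#' Peak-free gaps between consecutive contraction cycles
#'
#' The inter-cycle interval is defined as the time with no peaks: the gap
#' from the end of one cycle to the start of the next (not apex-to-apex).
#'
#' @param cycles Data frame from [group_cycles()] (time-ordered).
#' @return Numeric vector of gap durations, length `nrow(cycles) - 1`.
#' @export
intercycle_intervals <- function(cycles) {
  if (nrow(cycles) < 2L) return(numeric(0))
  cycles$start_time[-1] - cycles$end_time[-nrow(cycles)]
}

#' Intermediate window features of the peak-detection algorithm
#'
#' For each 0.5 s timepoint, summarises the trailing 75 s window: the time
#' and value of the highest apex in the window, the baseline (median of
#' peak-free samples, i.e. samples outside every peak's onset-offset
#' support), and the most recent inter-cycle gap whose bounding cycles both
#' end within the window (`NA` until two complete cycles are visible).
#' Windows at the session start are clipped to the available data.
#'
#' @param trace A normalized `pressure_trace`, at least 75 s long.
#' @param cycles Data frame from [group_cycles()] run on the same trace.
#' @param peaks Data frame from [detect_peaks()] run on the same trace.
#' @param config A [peak_config()].
#' @return Data frame with one row per timepoint: `window_end_time`,
#'   `highest_peak`, `peak_value`, `baseline`, `contraction_interval`.
#' @export
cycle_window_features <- function(trace, cycles, peaks,
                                  config = peak_config()) {
  stopifnot(inherits(trace, "pressure_trace"))
  x <- trace$values
  n <- length(x)
  W <- as.integer(round(config$feature_window / SAMPLING_INTERVAL))
  if (n < W) stop("trace shorter than the 75 s feature window", call. = FALSE)
  times <- trace_times(trace)

  in_peak <- rep(FALSE, n)
  if (nrow(peaks)) {
    on_i <- match_time_index(peaks$onset_time, trace)
    off_i <- match_time_index(peaks$offset_time, trace)
    for (i in seq_len(nrow(peaks))) in_peak[on_i[i]:off_i[i]] <- TRUE
  }
  apex_i <- if (nrow(peaks)) match_time_index(peaks$apex_time, trace) else integer(0)

  gaps <- intercycle_intervals(cycles)

  highest <- rep(NA_real_, n)
  peakval <- rep(NA_real_, n)
  baseline <- rep(NA_real_, n)
  interval <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - W + 1L)
    win <- lo:t
    free <- win[!in_peak[win]]
    baseline[t] <- if (length(free)) median(x[free]) else NA_real_
    inwin <- apex_i >= lo & apex_i <= t
    if (any(inwin)) {
      vals <- peaks$apex_value[inwin]
      j <- which(inwin)[which.max(vals)]
      highest[t] <- peaks$apex_time[j]
      peakval[t] <- peaks$apex_value[j]
    }
    if (length(gaps)) {
      ## gap i ends at cycles$start_time[i+1]; use the latest pair whose
      ## second cycle has ended within the window
      done <- which(cycles$end_time[-1] <= times[t] &
                      cycles$end_time[-1] > times[t] - config$feature_window)
      if (length(done)) interval[t] <- gaps[max(done)]
    }
  }
  data.frame(window_end_time = times,
             highest_peak = highest,
             peak_value = peakval,
             baseline = baseline,
             contraction_interval = interval)
}

## index of each time on the trace grid (nearest sample)
match_time_index <- function(t, trace) {
  i <- as.integer(round((t - trace$start_time) / trace$sampling_interval)) + 1L
  pmin(pmax(i, 1L), length(trace$values))
}

#' Rule-based per-timepoint rumination classification
#'
#' Flags a 0.5 s timepoint as rumination when its trailing 75 s window
#' contains (any part of) at least one qualifying contraction cycle. A cycle
#' qualifies if it has exactly three peaks (the triphasic rumination
#' signature), or exactly two peaks with a span within
#' `two_peak_span_tolerance` of the running median three-peak span (the
#' occasional two-peak rumination cycle whose inner timing matches the
#' three-peak pattern). The running median is initialized once
#' `median_init_cycles` three-peak cycles have been seen; before that the
#' two-peak exception is inactive. Windows at the session start are clipped
#' to the available data.
#'
#' @param trace A normalized `pressure_trace`, at least 75 s long.
#' @param config A [peak_config()].
#' @return Logical vector, one flag per 0.5 s timepoint. The detected cycles
#'   are attached as the `cycles` attribute.
#' @export
classify_rumination <- function(trace, config = peak_config()) {
  stopifnot(inherits(trace, "pressure_trace"))
  n <- length(trace$values)
  if (n * SAMPLING_INTERVAL < config$feature_window) {
    stop("trace shorter than the 75 s feature window", call. = FALSE)
  }
  peaks <- detect_peaks(trace, config)
  cycles <- group_cycles(peaks, config)
  qualifies <- qualifying_cycles(cycles, config)

  flags <- rep(FALSE, n)
  times <- trace_times(trace)
  for (i in which(qualifies)) {
    lo <- match_time_index(cycles$start_time[i], trace)
    hi <- match_time_index(cycles$end_time[i] + config$feature_window, trace)
    flags[lo:hi] <- TRUE
  }
  attr(flags, "cycles") <- cycles
  flags
}

## Apply the 3-peak rule and the 2-peak span exception, tracking the running
## median of 3-peak spans in cycle order.
qualifying_cycles <- function(cycles, config) {
  n_cyc <- nrow(cycles)
  qual <- logical(n_cyc)
  spans3 <- numeric(0)
  for (i in seq_len(n_cyc)) {
    if (cycles$n_peaks[i] == 3L) {
      qual[i] <- TRUE
      spans3 <- c(spans3, cycles$span[i])
    } else if (cycles$n_peaks[i] == 2L &&
               length(spans3) >= config$median_init_cycles) {
      med <- median(spans3)
      qual[i] <- abs(cycles$span[i] - med) <= config$two_peak_span_tolerance * med
    }
  }
  qual
}
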