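#' Contraction waveform template
#'
#' Describes the pressure signature of one primary reticular contraction cycle
#' (A-wave) as a train of Gaussian peaks. Eating, drinking, sleeping and
#' "other" use the biphasic (two-peak) template; rumination gains a third
#' reticular contraction, giving the triphasic (three-peak) signature the
#' rule-based detector keys on.
#'
#' @param peaks_per_cycle Number of peaks per contraction cycle, 2 or 3.
#' @param peak_amplitude Apex height above baseline, in pressure units
#'   (arbitrary device units; the analysis pipelines normalize per session).
#' @param amplitude_jitter Multiplicative per-peak jitter fraction; each peak's
#'   amplitude is drawn uniformly in `peak_amplitude * (1 +/- amplitude_jitter)`.
#' @param peak_width Full width at half maximum of one peak, seconds.
#' @param peak_spacing Time between successive peak apices within a cycle,
#'   seconds. Must exceed `peak_width / 2` so apices stay distinct.
#' @return An object of class `contraction_template`.
#' @seealso [generate_cycle_waveform()], [default_templates()]
#' @export
contraction_template <- function(peaks_per_cycle,
                                 peak_amplitude = 1.0,
                                 amplitude_jitter = 0.1,
                                 peak_width = 2.0,
                                 peak_spacing = 4.0) {
  if (!peaks_per_cycle %in% c(2L, 3L)) {
    stop("peaks_per_cycle must be 2 or 3", call. = FALSE)
  }
  if (peak_width <= 0) stop("peak_width must be positive", call. = FALSE)
  if (peak_spacing <= peak_width / 2) {
    stop("peak_spacing must exceed peak_width / 2", call. = FALSE)
  }
  if (peak_amplitude < 0 || amplitude_jitter < 0 || amplitude_jitter >= 1) {
    stop("peak_amplitude must be >= 0 and amplitude_jitter in [0, 1)",
         call. = FALSE)
  }
  structure(
    list(peaks_per_cycle = as.integer(peaks_per_cycle),
         peak_amplitude = peak_amplitude,
         amplitude_jitter = amplitude_jitter,
         peak_width = peak_width,
         peak_spacing = peak_spacing),
    class = "contraction_template"
  )
}

## Waveform support extends 1.5 * FWHM beyond the outer apices, where the
## Gaussian has fallen below 0.2% of its amplitude; cycle start/end times in
## the ground truth refer to these support edges.
template_support <- function(template) 1.5 * template$peak_width

template_span <- function(template) {
  (template$peaks_per_cycle - 1) * template$peak_spacing +
    2 * template_support(template)
}

#' Default contraction templates per behavior
#'
#' Rumination uses the triphasic (three-peak) template; all other behaviors
#' use the biphasic template, since only rumination shows the third reticular
#' contraction.
#'
#' @return Named list of [contraction_template()] objects, one per behavior.
#' @export
default_templates <- function() {
  tpl <- lapply(BEHAVIOR_CLASSES, function(b) {
    contraction_template(peaks_per_cycle = if (b == "rumination") 3L else 2L)
  })
  names(tpl) <- BEHAVIOR_CLASSES
  tpl
}

#' Inter-cycle interval distribution parameters
#'
#' The peak-free time between the end of one contraction cycle and the start
#' of the next is modelled as a Normal distribution truncated below at
#' `min_gap`. [default_interval_params()] returns the per-behavior means and
#' standard deviations observed in the underlying study.
#'
#' @param behavior Behavior class (see [BEHAVIOR_CLASSES]).
#' @param mean_gap Mean gap, seconds.
#' @param sd_gap Standard deviation of the gap, seconds.
#' @param min_gap Truncation floor, seconds; gaps below this are never drawn.
#' @return An object of class `interval_params`.
#' @export
interval_params <- function(behavior, mean_gap, sd_gap, min_gap = 5) {
  check_behavior(behavior)
  if (mean_gap <= 0 || sd_gap < 0 || min_gap <= 0) {
    stop("mean_gap and min_gap must be positive, sd_gap non-negative",
         call. = FALSE)
  }
  structure(
    list(behavior = behavior, mean_gap = mean_gap, sd_gap = sd_gap,
         min_gap = min_gap),
    class = "interval_params"
  )
}

# Observed inter-cycle gap mean (SD) in seconds per behavior.
.default_gaps <- list(
  rumination = c(48, 12.1),
  eating     = c(34, 12.7),
  drinking   = c(35, 12.9),
  sleeping   = c(41, 11.4),
  other      = c(40, 23.1)
)

#' @rdname interval_params
#' @export
default_interval_params <- function(behavior) {
  check_behavior(behavior)
  g <- .default_gaps[[behavior]]
  interval_params(behavior, mean_gap = g[1], sd_gap = g[2])
}

default_intervals <- function() {
  iv <- lapply(BEHAVIOR_CLASSES, default_interval_params)
  names(iv) <- BEHAVIOR_CLASSES
  iv
}

#' Behavior schedule for one session
#'
#' An ordered sequence of (behavior, duration) segments for one cow-session,
#' standing in for the video-scored behavior timeline.
#'
#' @param behaviors Character vector of behavior classes.
#' @param durations_s Segment durations in seconds; each must be a positive
#'   multiple of the 0.5 s sampling interval.
#' @param cow_id Animal identifier.
#' @return An object of class `behavior_schedule` (a data frame with columns
#'   `behavior` and `duration_s`, plus a `cow_id` attribute).
#' @export
behavior_schedule <- function(behaviors, durations_s, cow_id = "cow1") {
  if (length(behaviors) == 0L || length(behaviors) != length(durations_s)) {
    stop("behaviors and durations_s must be non-empty and equal length",
         call. = FALSE)
  }
  for (b in behaviors) check_behavior(b)
  if (any(durations_s <= 0)) stop("durations must be positive", call. = FALSE)
  steps <- durations_s / SAMPLING_INTERVAL
  if (any(abs(steps - round(steps)) > 1e-9)) {
    stop("durations must be multiples of 0.5 s", call. = FALSE)
  }
  structure(
    data.frame(behavior = behaviors, duration_s = durations_s,
               stringsAsFactors = FALSE),
    cow_id = cow_id,
    class = c("behavior_schedule", "data.frame")
  )
}

#' Session generator configuration
#'
#' @param baseline_level Baseline pressure level, pressure units.
#' @param baseline_drift_sd Per-sample standard deviation of the Gaussian
#'   random-walk baseline drift, pressure units.
#' @param noise_sd Standard deviation of additive white measurement noise,
#'   pressure units.
#' @param multi_compartment If `TRUE`, [generate_multicompartment()] may derive
#'   lagged cranial/dorsal/ventral traces from the reticulum trace.
#' @param compartment_lags Named numeric vector of per-compartment lags in
#'   seconds (reticulum, cranial, dorsal, ventral). Must be strictly
#'   increasing, reflecting the caudal propagation of the A-wave, and
#'   multiples of 0.5 s.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(baseline_level = 0,
                             baseline_drift_sd = 0.002,
                             noise_sd = 0.05,
                             multi_compartment = FALSE,
                             compartment_lags = c(reticulum = 0, cranial = 3,
                                                  dorsal = 8, ventral = 14)) {
  if (noise_sd < 0 || baseline_drift_sd < 0) {
    stop("noise_sd and baseline_drift_sd must be non-negative", call. = FALSE)
  }
  if (multi_compartment) {
    if (length(compartment_lags) != 4L || any(diff(compartment_lags) <= 0) ||
        compartment_lags[[1]] != 0) {
      stop("compartment_lags must be 4 strictly increasing lags starting at 0",
           call. = FALSE)
    }
    steps <- compartment_lags / SAMPLING_INTERVAL
    if (any(abs(steps - round(steps)) > 1e-9)) {
      stop("compartment_lags must be multiples of 0.5 s", call. = FALSE)
    }
  }
  structure(
    list(sampling_interval = SAMPLING_INTERVAL,
         baseline_level = baseline_level,
         baseline_drift_sd = baseline_drift_sd,
         noise_sd = noise_sd,
         multi_compartment = multi_compartment,
         compartment_lags = compartment_lags),
    class = "generator_config"
  )
}

#' Generate the noise-free waveform of one contraction cycle
#'
#' Evaluates the template's Gaussian peak train on the 0.5 s grid, from the
#' cycle's support start (time 0) to its support end. Per-peak amplitudes are
#' jittered using the current RNG state.
#'
#' @param template A [contraction_template()].
#' @return Numeric vector of pressure values above baseline, with attributes
#'   `apex_s` (apex times relative to cycle start) and `span_s`.
#' @export
generate_cycle_waveform <- function(template) {
  stopifnot(inherits(template, "contraction_template"))
  support <- template_support(template)
  span <- template_span(template)
  apices <- support + (seq_len(template$peaks_per_cycle) - 1) * template$peak_spacing
  t <- seq(0, span, by = SAMPLING_INTERVAL)
  sigma <- template$peak_width / (2 * sqrt(2 * log(2)))
  j <- template$amplitude_jitter
  amps <- template$peak_amplitude *
    (1 + runif(template$peaks_per_cycle, -j, j))
  values <- numeric(length(t))
  for (k in seq_along(apices)) {
    values <- values + amps[k] * exp(-(t - apices[k])^2 / (2 * sigma^2))
  }
  structure(values, apex_s = apices, span_s = span, amplitudes = amps)
}

new_pressure_trace <- function(values, cow_id, compartment = "reticulum",
                               start_time = 0) {
  structure(
    list(cow_id = cow_id, compartment = compartment, start_time = start_time,
         sampling_interval = SAMPLING_INTERVAL, values = as.numeric(values)),
    class = "pressure_trace"
  )
}

#' Sample times of a pressure trace
#'
#' Samples are timestamped at the start of each 0.5 s interval.
#'
#' @param trace A `pressure_trace`.
#' @return Numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) * trace$sampling_interval
}

new_behavior_labels <- function(times, labels, cow_id) {
  structure(
    list(cow_id = cow_id, times = as.numeric(times),
         labels = as.character(labels)),
    class = "behavior_labels"
  )
}

#' Generate one labeled synthetic pressure session
#'
#' Simulates a reticular pressure trace on the 0.5 s grid for a behavior
#' schedule. Within each behavior segment, contraction cycles are laid down
#' sequentially: a peak-free gap is drawn from the behavior's truncated-Normal
#' interval distribution, then a cycle waveform from the behavior's template
#' is added; cycles never straddle a segment boundary (cycle placement
#' restarts at each segment). Baseline drift (Gaussian random walk) and white
#' measurement noise are added on top.
#'
#' @param schedule A [behavior_schedule()].
#' @param config A [generator_config()].
#' @param templates Named list of [contraction_template()] per behavior.
#' @param intervals Named list of [interval_params()] per behavior.
#' @param seed Integer seed; identical seeds give bitwise-identical sessions.
#' @return An object of class `session_data`: list with elements `trace`
#'   (`pressure_trace`), `labels` (`behavior_labels`), `truth_cycles` (data
#'   frame with columns cycle_id, behavior, start_s, end_s, n_peaks and a
#'   `peak_times` list attribute), `clean_train` (the noise-free cycle train,
#'   used for multi-compartment derivation), `schedule` and `config`.
#' @export
generate_session <- function(schedule,
                             config = generator_config(),
                             templates = default_templates(),
                             intervals = default_intervals(),
                             seed = 1L) {
  stopifnot(inherits(schedule, "behavior_schedule"))
  for (b in unique(schedule$behavior)) {
    check_behavior(b)
    if (is.null(templates[[b]]) || is.null(intervals[[b]])) {
      stop("no template or interval params for behavior '", b, "'",
           call. = FALSE)
    }
  }
  set.seed(as.integer(seed))

  n_total <- as.integer(round(sum(schedule$duration_s) / SAMPLING_INTERVAL))
  times <- (seq_len(n_total) - 1) * SAMPLING_INTERVAL
  labels <- rep(schedule$behavior,
                times = as.integer(round(schedule$duration_s / SAMPLING_INTERVAL)))

  clean <- numeric(n_total)
  cyc_behavior <- character(0)
  cyc_start <- cyc_end <- numeric(0)
  cyc_npeaks <- integer(0)
  peak_times <- list()

  seg_end_times <- cumsum(schedule$duration_s)
  seg_start_times <- c(0, head(seg_end_times, -1))
  sigma_by_behavior <- vapply(templates, function(tp)
    tp$peak_width / (2 * sqrt(2 * log(2))), numeric(1))

  for (s in seq_len(nrow(schedule))) {
    b <- schedule$behavior[s]
    tpl <- templates[[b]]
    iv <- intervals[[b]]
    span <- template_span(tpl)
    support <- template_support(tpl)
    sigma <- sigma_by_behavior[[b]]
    pos <- seg_start_times[s]
    repeat {
      gap <- rtrunc_norm(1, iv$mean_gap, iv$sd_gap, iv$min_gap)
      start <- pos + gap
      if (start + span > seg_end_times[s]) break
      apices <- start + support +
        (seq_len(tpl$peaks_per_cycle) - 1) * tpl$peak_spacing
      jf <- tpl$amplitude_jitter
      amps <- tpl$peak_amplitude *
        (1 + runif(tpl$peaks_per_cycle, -jf, jf))
      for (k in seq_along(apices)) {
        lo <- max(1L, as.integer(ceiling((apices[k] - support) /
                                           SAMPLING_INTERVAL)) + 1L)
        hi <- min(n_total, as.integer(floor((apices[k] + support) /
                                              SAMPLING_INTERVAL)) + 1L)
        idx <- lo:hi
        clean[idx] <- clean[idx] +
          amps[k] * exp(-(times[idx] - apices[k])^2 / (2 * sigma^2))
      }
      cyc_behavior <- c(cyc_behavior, b)
      cyc_start <- c(cyc_start, start)
      cyc_end <- c(cyc_end, start + span)
      cyc_npeaks <- c(cyc_npeaks, tpl$peaks_per_cycle)
      peak_times[[length(peak_times) + 1L]] <- apices
      pos <- start + span
    }
  }

  drift <- cumsum(rnorm(n_total, 0, config$baseline_drift_sd))
  noise <- rnorm(n_total, 0, config$noise_sd)
  values <- config$baseline_level + clean + drift + noise

  cow_id <- attr(schedule, "cow_id")
  truth <- data.frame(
    cycle_id = seq_along(cyc_start),
    behavior = cyc_behavior,
    start_s = cyc_start,
    end_s = cyc_end,
    n_peaks = cyc_npeaks,
    stringsAsFactors = FALSE
  )
  attr(truth, "peak_times") <- peak_times

  structure(
    list(trace = new_pressure_trace(values, cow_id),
         labels = new_behavior_labels(times, labels, cow_id),
         truth_cycles = truth,
         clean_train = clean,
         schedule = schedule,
         config = config,
         seed = as.integer(seed)),
    class = "session_data"
  )
}

#' Peak-free gaps between consecutive ground-truth cycles
#'
#' Gap i is the time from the support end of cycle i to the support start of
#' cycle i+1, computed only between cycles of the same behavior segment run
#' (a behavior change resets cycle placement, so cross-segment gaps are not
#' draws from either segment's interval distribution).
#'
#' @param session A `session_data` object.
#' @param behavior Optional behavior class to restrict to.
#' @return Numeric vector of gap durations in seconds.
#' @export
truth_gaps <- function(session, behavior = NULL) {
  tc <- session$truth_cycles
  if (nrow(tc) < 2) return(numeric(0))
  same_run <- tc$behavior[-1] == tc$behavior[-nrow(tc)]
  gaps <- tc$start_s[-1] - tc$end_s[-nrow(tc)]
  keep <- same_run
  if (!is.null(behavior)) keep <- keep & tc$behavior[-1] == behavior
  gaps[keep]
}

#' Derive lagged multi-compartment traces
#'
#' The primary contraction cycle originates in the reticulum and propagates
#' caudally over the cranial, dorsal and ventral rumen sacs. This shifts the
#' session's noise-free reticular cycle train by each compartment's lag and
#' adds independent drift and measurement noise, yielding one trace per
#' compartment with strictly increasing per-cycle apex times.
#'
#' @param session A `session_data` from [generate_session()].
#' @param config A [generator_config()] with `multi_compartment = TRUE`.
#' @param seed Optional integer seed for the independent noise draws.
#' @return The session with a `traces` element (named list of four
#'   `pressure_trace`s) and `compartment_lags` recorded.
#' @export
generate_multicompartment <- function(session, config, seed = NULL) {
  stopifnot(inherits(session, "session_data"))
  if (!isTRUE(config$multi_compartment)) {
    stop("config must have multi_compartment = TRUE", call. = FALSE)
  }
  lags <- config$compartment_lags
  if (any(diff(lags) <= 0)) {
    stop("compartment_lags must be strictly increasing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  clean <- session$clean_train
  if (is.null(clean)) stop("session lacks the noise-free cycle train", call. = FALSE)
  n <- length(clean)
  traces <- vector("list", length(lags))
  names(traces) <- names(lags)
  for (i in seq_along(lags)) {
    shift <- as.integer(round(lags[[i]] / SAMPLING_INTERVAL))
    shifted <- c(numeric(shift), clean)[seq_len(n)]
    vals <- config$baseline_level + shifted +
      cumsum(rnorm(n, 0, config$baseline_drift_sd)) +
      rnorm(n, 0, config$noise_sd)
    traces[[i]] <- new_pressure_trace(vals, session$trace$cow_id,
                                      compartment = names(lags)[i])
  }
  session$traces <- traces
  session$compartment_lags <- lags
  session
}

#' @export
print.session_data <- function(x, ...) {
  cat("<session_data> cow", x$trace$cow_id, "-",
      length(x$trace$values), "samples (",
      length(x$trace$values) * SAMPLING_INTERVAL, "s ),",
      nrow(x$truth_cycles), "truth cycles\n")
  invisible(x)
}
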