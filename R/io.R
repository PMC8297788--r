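#' Write a labeled session to CSV
#'
#' Writes the session dialect: columns `time_s` (multiples of 0.5), one
#' pressure column per compartment (`pressure` for a single reticulum trace,
#' `pressure_<compartment>` when multi-compartment), `label` and `cow_id`.
#' Optionally writes a sidecar ground-truth cycles CSV (cycle_id, start_s,
#' end_s, n_peaks, behavior).
#'
#' @param session A `session_data` object.
#' @param path Output CSV path.
#' @param truth_path Optional path for the truth-cycles sidecar CSV.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, truth_path = NULL) {
  stopifnot(inherits(session, "session_data"))
  times <- trace_times(session$trace)
  df <- data.frame(time_s = times, stringsAsFactors = FALSE)
  if (!is.null(session$traces)) {
    for (comp in names(session$traces)) {
      df[[paste0("pressure_", comp)]] <- as.numeric(session$traces[[comp]]$values)
    }
  } else {
    df$pressure <- as.numeric(session$trace$values)
  }
  df$label <- session$labels$labels
  df$cow_id <- session$trace$cow_id
  write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path)) {
    tc <- session$truth_cycles
    write.csv(tc[, c("cycle_id", "start_s", "end_s", "n_peaks", "behavior")],
              truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a labeled session from CSV
#'
#' Parses the session CSV dialect written by [write_session()], verifying the
#' 0.5 s sampling grid and the closed behavior label set. Extra columns are
#' tolerated and ignored.
#'
#' @param path Path to the session CSV.
#' @return A list with `trace` (a `pressure_trace`, or a named list `traces`
#'   of them for multi-compartment files) and `labels` (`behavior_labels`).
#' @export
read_session <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "label", "cow_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("session CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pcols <- grep("^pressure(_|$)", names(df), value = TRUE)
  if (!length(pcols)) {
    stop("session CSV is missing column(s): pressure", call. = FALSE)
  }
  steps <- diff(df$time_s)
  bad <- which(abs(steps - SAMPLING_INTERVAL) > 1e-9)
  if (length(bad)) {
    stop("irregular sampling: step of ", steps[bad[1]], " s between rows ",
         bad[1], " and ", bad[1] + 1L, " (expected 0.5 s)", call. = FALSE)
  }
  unknown <- setdiff(unique(df$label), BEHAVIOR_CLASSES)
  if (length(unknown)) {
    stop("unknown label(s) in session CSV: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(as.matrix(df[pcols])))) {
    stop("non-finite pressure values in session CSV", call. = FALSE)
  }
  cow_id <- as.character(df$cow_id[1])
  start <- df$time_s[1]
  labels <- new_behavior_labels(df$time_s, df$label, cow_id)
  if (length(pcols) == 1L && pcols == "pressure") {
    trace <- new_pressure_trace(df$pressure, cow_id, start_time = start)
    list(trace = trace, labels = labels)
  } else {
    traces <- lapply(pcols, function(pc) {
      new_pressure_trace(df[[pc]], cow_id,
                         compartment = sub("^pressure_", "", pc),
                         start_time = start)
    })
    names(traces) <- sub("^pressure_", "", pcols)
    list(traces = traces, labels = labels)
  }
}

#' Expand 1 s behavior labels onto the 0.5 s sample grid
#'
#' Video-scored behavior is recorded once per second; pressure is sampled
#' every 0.5 s. Each 1 s label is duplicated onto the two 0.5 s samples it
#' covers.
#'
#' @param labels A `behavior_labels` object on a strict 1 s grid.
#' @return A `behavior_labels` object on the 0.5 s grid, twice as long.
#' @export
expand_labels <- function(labels) {
  stopifnot(inherits(labels, "behavior_labels"))
  n <- length(labels$times)
  if (n == 0L) return(new_behavior_labels(numeric(0), character(0), labels$cow_id))
  if (n > 1L && any(abs(diff(labels$times) - 1) > 1e-9)) {
    stop("labels are not on a 1 s grid", call. = FALSE)
  }
  times <- rep(labels$times, each = 2L) + rep(c(0, 0.5), n)
  new_behavior_labels(times, rep(labels$labels, each = 2L), labels$cow_id)
}

#' Align a pressure trace with a label stream
#'
#' Truncates both series to their common time span on the shared 0.5 s grid,
#' so every retained sample has exactly one label. No labels are fabricated.
#'
#' @param trace A `pressure_trace`.
#' @param labels A `behavior_labels` on the same grid phase.
#' @return List with the truncated `trace` and `labels`, equal length.
#' @export
align_session <- function(trace, labels) {
  stopifnot(inherits(trace, "pressure_trace"),
            inherits(labels, "behavior_labels"))
  t_tr <- trace_times(trace)
  t_lb <- labels$times
  lo <- max(t_tr[1], t_lb[1])
  hi <- min(t_tr[length(t_tr)], t_lb[length(t_lb)])
  if (lo > hi) stop("trace and labels have disjoint time spans", call. = FALSE)
  keep_tr <- t_tr >= lo - 1e-9 & t_tr <= hi + 1e-9
  keep_lb <- t_lb >= lo - 1e-9 & t_lb <= hi + 1e-9
  if (sum(keep_tr) != sum(keep_lb)) {
    stop("trace and labels are not on the same 0.5 s grid phase", call. = FALSE)
  }
  trace$values <- trace$values[keep_tr]
  trace$start_time <- lo
  list(trace = trace,
       labels = new_behavior_labels(t_lb[keep_lb], labels$labels[keep_lb],
                                    labels$cow_id))
}
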