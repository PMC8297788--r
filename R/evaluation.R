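#' Confusion matrix of a binary classification
#'
#' @param pred Logical (or 0/1) vector of predictions.
#' @param truth Logical (or 0/1) vector of true states, same length.
#' @return An object of class `confusion_matrix`: list with integer counts
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  if (length(pred) != length(truth) || length(pred) < 1L) {
    stop("pred and truth must have equal positive length", call. = FALSE)
  }
  if (anyNA(pred) || anyNA(truth)) stop("NA in pred or truth", call. = FALSE)
  confusion_matrix(TP = sum(pred & truth), FP = sum(pred & !truth),
                   TN = sum(!pred & !truth), FN = sum(!pred & truth))
}

#' @rdname confusion
#' @param TP,FP,TN,FN Non-negative counts.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Performance metrics from a confusion matrix
#'
#' Computes sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' positive predictive value `PPV = TP/(TP+FP)`, negative predictive value
#' `NPV = TN/(TN+FN)`, `F1 = 2*PPV*Se/(PPV+Se)` (the harmonic mean of PPV and
#' sensitivity) and accuracy `Acc = (TP+TN)/(TP+TN+FP+FN)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0 or 1.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `Se, Sp, PPV, NPV, F1, Acc` at full
#'   precision, of class `performance_metrics`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  se <- safe_div(cm$TP, cm$TP + cm$FN)
  sp <- safe_div(cm$TN, cm$TN + cm$FP)
  ppv <- safe_div(cm$TP, cm$TP + cm$FP)
  npv <- safe_div(cm$TN, cm$TN + cm$FN)
  f1 <- if (!is.na(se) && !is.na(ppv) && (se + ppv) > 0) {
    2 * ppv * se / (ppv + se)
  } else NA_real_
  acc <- (cm$TP + cm$TN) / (cm$TP + cm$TN + cm$FP + cm$FN)
  structure(c(Se = se, Sp = sp, PPV = ppv, NPV = npv, F1 = f1, Acc = acc),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, digits = 2, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Summary statistics of inter-cycle intervals
#'
#' Sample mean, sample SD (n-1 denominator), median and interquartile range
#' (75th minus 25th percentile, linear-interpolation quantiles) of a set of
#' gap durations, in the reporting shape used for per-behavior interval
#' tables.
#'
#' @param gaps Numeric vector of gap durations in seconds, non-empty.
#' @param behavior Behavior class the gaps belong to.
#' @return One-row data frame: `behavior`, `mean`, `sd`, `median`, `iqr`, `n`.
#' @export
interval_summary <- function(gaps, behavior) {
  check_behavior(behavior)
  if (length(gaps) < 1L) stop("no gaps to summarise", call. = FALSE)
  q <- quantile(gaps, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(behavior = behavior,
             mean = mean(gaps),
             sd = if (length(gaps) >= 2L) sd(gaps) else NA_real_,
             median = q[2],
             iqr = if (length(gaps) >= 2L) q[3] - q[1] else NA_real_,
             n = length(gaps))
}

#' Write a metrics table
#'
#' Emits a CSV (and optionally a fixed-width text rendering with thousands
#' separators on counts) in the canonical column order: any count columns
#' TP, FP, TN, FN first, then Se, Sp, PPV, NPV, F1, Acc.
#'
#' @param tab Data frame of metric rows (e.g. from [run_validation()] or
#'   assembled by hand); may be empty.
#' @param path Output CSV path.
#' @param text_path Optional path for a human-readable text table.
#' @return `path`, invisibly.
#' @export
report_metrics <- function(tab, path, text_path = NULL) {
  metric_cols <- c("TP", "FP", "TN", "FN", "Se", "Sp", "PPV", "NPV", "F1", "Acc")
  lead <- setdiff(names(tab), metric_cols)
  tab <- tab[, c(lead, intersect(metric_cols, names(tab))), drop = FALSE]
  num <- vapply(tab, is.numeric, logical(1))
  tab_out <- tab
  tab_out[num] <- lapply(tab[num], function(v) round(v, 6))
  write.csv(tab_out, path, row.names = FALSE)
  if (!is.null(text_path)) {
    txt <- tab
    for (cc in intersect(c("TP", "FP", "TN", "FN"), names(txt))) {
      txt[[cc]] <- format(txt[[cc]], big.mark = ",", trim = TRUE)
    }
    for (cc in intersect(c("Se", "Sp", "PPV", "NPV", "F1", "Acc"), names(txt))) {
      txt[[cc]] <- sprintf("%.2f", txt[[cc]])
    }
    writeLines(capture_table(txt), text_path)
  }
  invisible(path)
}

capture_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}
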