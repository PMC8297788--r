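test_that("a sharp triangle is detected as exactly one peak at its apex", {
  # rises 2.0 normalized units over 1 s, falls symmetrically
  x <- c(rep(0, 20), 1, 2, 1, rep(0, 20))
  pk <- detect_peaks(as_trace(x), peak_config(rise_threshold = 1.5,
                                              rise_timespan = 3))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex_time, 21 * 0.5)
  expect_equal(pk$apex_value, 2)
  expect_lte(pk$onset_time, pk$apex_time)
  expect_gte(pk$offset_time, pk$apex_time)

  flat <- detect_peaks(as_trace(rep(0.3, 100)))
  expect_equal(nrow(flat), 0)

  small <- detect_peaks(as_trace(c(rep(0, 10), 0.25, 0.5, 0.25, rep(0, 10))),
                        peak_config(rise_threshold = 0.8))
  expect_equal(nrow(small), 0)
})

test_that("slow ramps fail the timespan rule even when tall", {
  # rises 3 units but over 20 s: never 1.5 units within 3 s
  x <- c(seq(0, 3, by = 0.15), seq(3, 0, by = -0.15))
  pk <- detect_peaks(as_trace(x), peak_config(rise_threshold = 1.5,
                                              rise_timespan = 3))
  expect_equal(nrow(pk), 0)
})

test_that("detect_peaks matches the brute-force threshold-rule oracle", {
  cfg <- peak_config(rise_threshold = 1.0, rise_timespan = 3)
  L <- 6L
  set.seed(21)
  traces <- list(
    cumsum(rnorm(300, 0, 0.4)),                      # random walk
    rnorm(500),                                      # white noise
    rep(0, 200) + 2 * sin(seq(0, 20 * pi, length.out = 200)),
    as.numeric(scale(generate_session(
      behavior_schedule("rumination", 250, "c"), seed = 9)$trace$values))
  )
  for (x in traces) {
    pk <- detect_peaks(as_trace(x), cfg)
    oracle <- brute_force_apex_indices(x, th = 1.0, L = L)
    expect_equal(pk$apex_time, (oracle - 1) * 0.5)
  }
})

test_that("raising the rise threshold never increases the peak count", {
  set.seed(31)
  for (i in 1:5) {
    s <- generate_session(behavior_schedule("rumination", 600, "c"), seed = i)
    tr <- normalize_trace(s$trace)
    counts <- vapply(seq(0.4, 3, by = 0.2), function(th) {
      nrow(detect_peaks(tr, peak_config(rise_threshold = th)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("peaks group into cycles by the intra-cycle gap rule", {
  mk_peaks <- function(apices) {
    data.frame(apex_time = apices, onset_time = apices - 1,
               offset_time = apices + 1, apex_value = 3)
  }
  cfg <- peak_config(max_intra_cycle_gap = 12)
  cy <- group_cycles(mk_peaks(c(10, 14, 18, 60, 64, 68)), cfg)
  expect_equal(nrow(cy), 2)
  expect_equal(cy$n_peaks, c(3L, 3L))
  expect_equal(cy$start_time, c(9, 59))
  expect_equal(cy$end_time, c(19, 69))

  no_peaks <- detect_peaks(as_trace(rep(0, 50)), cfg)
  expect_equal(nrow(group_cycles(no_peaks, cfg)), 0)
  single <- group_cycles(mk_peaks(42), cfg)
  expect_equal(single$n_peaks, 1L)

  # conservation: every peak belongs to exactly one cycle
  s <- generate_session(behavior_schedule("rumination", 1800, "c"), seed = 4)
  pk <- detect_peaks(normalize_trace(s$trace))
  cy2 <- group_cycles(pk)
  expect_equal(sum(cy2$n_peaks), nrow(pk))
  expect_equal(length(unlist(attr(cy2, "peak_times"))), nrow(pk))
})

test_that("inter-cycle intervals are the peak-free gaps", {
  cy <- data.frame(cycle_id = 1:2, start_time = c(20, 70),
                   end_time = c(60, 110), span = 40, n_peaks = 3L)
  expect_equal(intercycle_intervals(cy), 10)
  expect_length(intercycle_intervals(cy[1, ]), 0)
  cy3 <- data.frame(cycle_id = 1:3, start_time = c(0, 50, 100),
                    end_time = c(20, 70, 120), span = 20, n_peaks = 3L)
  expect_equal(intercycle_intervals(cy3), c(30, 30))
})

test_that("window features report highest peak, baseline and latest gap", {
  # one triangular peak of height 1.4 at t = 50 on an 80 s flat trace
  x <- numeric(160)
  x[99:103] <- c(0.7, 1.05, 1.4, 1.05, 0.7)
  tr <- as_trace(x)
  cfg <- peak_config(rise_threshold = 0.6, rise_timespan = 3)
  pk <- detect_peaks(tr, cfg)
  cy <- group_cycles(pk, cfg)
  cw <- cycle_window_features(tr, cy, pk, cfg)
  i <- which(cw$window_end_time == 60)
  expect_equal(cw$highest_peak[i], 50)
  expect_equal(cw$peak_value[i], 1.4)
  expect_equal(cw$baseline[i], 0)
  expect_true(is.na(cw$contraction_interval[i]))  # fewer than 2 cycles

  # no-peak window: baseline is the window median, peak fields absent
  j <- which(cw$window_end_time == 10)
  expect_true(is.na(cw$highest_peak[j]))
  expect_equal(cw$baseline[j], 0)

  expect_error(cycle_window_features(as_trace(numeric(100)), cy, pk, cfg),
               "75 s")
})

test_that("contraction_interval agrees with intercycle_intervals", {
  s <- generate_session(behavior_schedule("rumination", 600, "c"), seed = 12)
  tr <- normalize_trace(s$trace)
  pk <- detect_peaks(tr)
  cy <- group_cycles(pk)
  gaps <- intercycle_intervals(cy)
  cw <- cycle_window_features(tr, cy, pk)
  # just after cycle k+1 ends, the reported gap is gap k
  for (k in seq_len(min(3, length(gaps)))) {
    t_after <- cy$end_time[k + 1] + 0.5
    i <- which(abs(cw$window_end_time - t_after) < 1e-9)
    expect_equal(cw$contraction_interval[i], gaps[k])
  }
})

test_that("triphasic cycles flag rumination; biphasic sessions stay unflagged", {
  s <- generate_session(behavior_schedule("rumination", 7200, "c"), seed = 1)
  fl <- classify_rumination(normalize_trace(s$trace))
  expect_gte(mean(fl), 0.97)

  s2 <- generate_session(behavior_schedule("eating", 7200, "c"), seed = 1)
  fl2 <- classify_rumination(normalize_trace(s2$trace))
  expect_lte(mean(fl2), 0.10)

  expect_error(classify_rumination(as_trace(numeric(100))), "75 s")
})

test_that("a two-peak cycle with a three-peak span is flagged by the exception", {
  # five triphasic cycles initialize the running median span, then an
  # isolated two-peak cycle whose span matches (apices 10.5 s apart vs the
  # triphasic 8 s + equal support) is flagged; a short two-peak cycle is not.
  starts3 <- c(10, 70, 130, 190, 250)
  apices3 <- as.vector(vapply(starts3, function(s0) s0 + c(0, 4, 8),
                              numeric(3)))
  cfg <- peak_config(rise_threshold = 1.5, rise_timespan = 3,
                     two_peak_span_tolerance = 0.2)

  tr_match <- triangle_trace(600, c(apices3, 420, 430.5))
  fl <- classify_rumination(tr_match, cfg)
  cy <- attr(fl, "cycles")
  expect_equal(cy$n_peaks, c(rep(3L, 5), 2L))
  i <- round(427 / 0.5) + 1
  expect_true(fl[i])

  tr_short <- triangle_trace(600, c(apices3, 420, 424))
  fl2 <- classify_rumination(tr_short, cfg)
  expect_equal(attr(fl2, "cycles")$n_peaks, c(rep(3L, 5), 2L))
  expect_false(fl2[i])

  # before initialization (only 2 triphasic cycles) the exception is inactive
  apices_few <- as.vector(vapply(c(10, 70), function(s0) s0 + c(0, 4, 8),
                                 numeric(3)))
  tr_few <- triangle_trace(600, c(apices_few, 420, 430.5))
  fl3 <- classify_rumination(tr_few, cfg)
  expect_false(fl3[i])
})

test_that("re-classifying a flagged sub-trace reproduces the flags (idempotence)", {
  s <- generate_session(behavior_schedule("rumination", 1200, "c"), seed = 5)
  tr <- normalize_trace(s$trace)
  fl <- classify_rumination(tr)
  # take an interior stretch where windows are complete in both runs
  lo <- 400; hi <- 2000
  sub <- tr
  sub$values <- tr$values[lo:hi]
  sub$start_time <- (lo - 1) * 0.5
  fl_sub <- classify_rumination(sub)
  # compare where the sub-trace's trailing window is complete
  cmp <- 200:length(fl_sub)
  expect_gt(mean(fl_sub[cmp] == fl[lo:hi][cmp]), 0.98)
})
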