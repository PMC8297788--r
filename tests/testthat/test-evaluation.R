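table6_rows <- list(
  rumination = list(cm = c(TP = 37410, FP = 570, TN = 83940, FN = 2196),
                    expected = c(Se = 0.94, Sp = 0.99, PPV = 0.98,
                                 NPV = 0.97, F1 = 0.96, Acc = 0.98)),
  eating     = list(cm = c(TP = 29231, FP = 903, TN = 91006, FN = 2976),
                    expected = c(Se = 0.91, Sp = 0.99, PPV = 0.97,
                                 NPV = 0.97, F1 = 0.94, Acc = 0.97)),
  drinking   = list(cm = c(TP = 467, FP = 17, TN = 454, FN = 4),
                    expected = c(Se = 0.99, Sp = 0.96, PPV = 0.96,
                                 NPV = 0.99, F1 = 0.98, Acc = 0.98)),
  sleeping   = list(cm = c(TP = 3947, FP = 240, TN = 3749, FN = 42),
                    expected = c(Se = 0.99, Sp = 0.94, PPV = 0.94,
                                 NPV = 0.99, F1 = 0.97, Acc = 0.96))
)

test_that("confusion counts partition the series and match a manual tally", {
  cm <- confusion(rep(TRUE, 10), rep(TRUE, 10))
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 10L, FP = 0L, TN = 0L, FN = 0L))

  truth <- rep(c(TRUE, FALSE), 5)
  cm2 <- confusion(!truth, truth)
  expect_equal(unlist(cm2[c("TP", "FP", "TN", "FN")]),
               c(TP = 0L, FP = 5L, TN = 0L, FN = 5L))

  pred6 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  truth6 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  cm3 <- confusion(pred6, truth6)
  expect_equal(unlist(cm3[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 1L, TN = 2L, FN = 1L))

  set.seed(17)
  for (i in 1:20) {
    pred <- runif(50) > 0.5
    truth <- runif(50) > 0.3
    cm <- confusion(pred, truth)
    oracle <- brute_force_confusion(pred, truth)
    expect_identical(unlist(cm[c("TP", "FP", "TN", "FN")]),
                     c(TP = oracle[["TP"]], FP = oracle[["FP"]],
                       TN = oracle[["TN"]], FN = oracle[["FN"]]))
    expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, 50)
  }

  expect_error(confusion(TRUE, c(TRUE, FALSE)), "equal")
})

test_that("the six metrics reproduce every printed 2-dp cell of all four behaviors", {
  for (row in table6_rows) {
    cm <- do.call(confusion_matrix, as.list(row$cm))
    m <- round(unclass(metrics(cm)), 2)
    expect_equal(m, row$expected)
  }
})

test_that("perfect and degenerate confusion matrices are handled", {
  perfect <- metrics(confusion_matrix(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unclass(perfect),
               c(Se = 1, Sp = 1, PPV = 1, NPV = 1, F1 = 1, Acc = 1))

  # zero denominators are undefined, never coerced to 0 or 1
  no_pos <- metrics(confusion_matrix(TP = 0, FP = 0, TN = 10, FN = 0))
  expect_true(is.na(no_pos[["Se"]]))
  expect_true(is.na(no_pos[["PPV"]]))
  expect_equal(no_pos[["Acc"]], 1)
})

test_that("metric monotonicity: more TP raises Se and NPV never falls with TN", {
  se <- vapply(1:20, function(tp)
    metrics(confusion_matrix(tp, 5, 50, 10))[["Se"]], numeric(1))
  expect_true(all(diff(se) > 0))
  npv <- vapply(1:20, function(tn)
    metrics(confusion_matrix(10, 5, tn, 10))[["NPV"]], numeric(1))
  expect_true(all(diff(npv) > 0))
})

test_that("interval summaries use sample SD and interpolated quartiles", {
  s <- interval_summary(c(1, 2, 3), "rumination")
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$iqr, 1)   # type-7 quartiles of 1..3 are 1.5 and 2.5
  expect_equal(s$n, 3)

  set.seed(23)
  draws <- rnorm(10000, 48, 12.1)
  big <- interval_summary(draws, "rumination")
  expect_lt(abs(big$mean - 48), 0.5)
  expect_lt(abs(big$sd - 12.1), 0.5)

  expect_error(interval_summary(numeric(0), "rumination"), "no gaps")
})

test_that("metric tables round-trip through CSV in canonical column order", {
  tab <- do.call(rbind, lapply(names(table6_rows), function(b) {
    cm <- do.call(confusion_matrix, as.list(table6_rows[[b]]$cm))
    cbind(data.frame(Behavior = b, TP = cm$TP, FP = cm$FP, TN = cm$TN,
                     FN = cm$FN),
          as.data.frame(as.list(unclass(metrics(cm)))))
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  report_metrics(tab, path, txt)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("Behavior", "TP", "FP", "TN", "FN",
                     "Se", "Sp", "PPV", "NPV", "F1", "Acc"))
  expect_equal(back$Se, tab$Se, tolerance = 1e-6)
  expect_true(any(grepl("37,410", readLines(txt))))  # thousands separators

  empty <- tab[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  report_metrics(empty, path2)
  expect_equal(nrow(read.csv(path2)), 0)
})
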