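test_that("class rebalancing follows the up/down-sampling arithmetic", {
  df <- toy_features(n = 2000, shift = 0)
  df$label <- c(rep("drinking", 100), rep("other", 1900))
  out <- balance_classes(df, "drinking", upsample_factor = 3,
                         balance_ratio = 1, seed = 2)
  expect_equal(sum(out$label == "drinking"), 300)
  expect_equal(sum(out$label != "drinking"), 300)
  # every original positive row survives balancing
  expect_true(all(df$window_end_s[df$label == "drinking"] %in%
                    out$window_end_s[out$label == "drinking"]))

  even <- toy_features(n = 100)
  bal <- balance_classes(even, "rumination", seed = 1)
  expect_equal(sum(bal$label == "rumination"), 50)
  expect_equal(sum(bal$label != "rumination"), 50)

  none <- toy_features(n = 50)
  none$label <- "other"
  expect_error(balance_classes(none, "rumination"), "no positive rows")
})

test_that("split schemes are exhaustive and exclusive", {
  df <- toy_features(n = 1000)
  hold <- make_split(df, "holdout_70_30", seed = 3)
  test_idx <- hold$test_sets[[1]]
  expect_equal(length(test_idx), 300)
  expect_equal(sort(union(test_idx, setdiff(seq_len(1000), test_idx))),
               seq_len(1000))
  # stratification: 30% of each label stratum within 1 row
  for (lb in unique(df$label)) {
    rows <- which(df$label == lb)
    expect_lte(abs(sum(test_idx %in% rows) - 0.3 * length(rows)), 1)
  }

  scv <- make_split(df, "scv_5fold", seed = 3)
  all_test <- unlist(scv$test_sets)
  expect_equal(sort(all_test), seq_len(1000))   # partition: union = all rows
  expect_equal(anyDuplicated(all_test), 0L)     # pairwise disjoint

  looa <- make_split(df, "looa", seed = 3)
  expect_equal(length(looa$test_sets), 4)
  for (f in seq_along(looa$test_sets)) {
    expect_equal(unique(df$cow_id[looa$test_sets[[f]]]), looa$fold_names[f])
  }
  one_cow <- df
  one_cow$cow_id <- "c1"
  expect_error(make_split(one_cow, "looa"), "2 distinct")
})

test_that("forests separate shifted features and are seed-deterministic", {
  df <- toy_features(n = 400, shift = 5, seed = 7)
  model <- train_one_vs_all(df, "rumination", forest_spec(n_trees = 100))
  pred <- predict(model, df)
  expect_gte(mean(pred == (df$label == "rumination")), 0.99)

  model2 <- train_one_vs_all(df, "rumination", forest_spec(n_trees = 100))
  expect_identical(predict(model2, df), pred)

  single <- df
  single$label <- "rumination"
  expect_error(train_one_vs_all(single, "rumination"), "single class")
})

test_that("prediction binds feature columns by name", {
  df <- toy_features(n = 300, shift = 5, seed = 9)
  model <- train_one_vs_all(df, "rumination", forest_spec(n_trees = 50))
  pred <- predict(model, df)
  expect_length(pred, 300)

  permuted <- df[, sample(ncol(df))]
  expect_identical(predict(model, permuted), pred)

  broken <- df[, -1]
  expect_error(predict(model, broken), "lacks feature column")
})

test_that("validation reports per-fold metrics in the expected shape", {
  df <- toy_features(n = 600, shift = 4, seed = 5)
  scv <- run_validation(df, "rumination", "scv_5fold",
                        forest_spec(n_trees = 50), seed = 2)
  expect_equal(nrow(scv$per_fold), 5)
  expect_named(scv$mean, c("Se", "Sp", "PPV", "NPV", "F1", "Acc"))
  expect_length(scv$sd, 6)

  looa <- run_validation(df, "rumination", "looa",
                         forest_spec(n_trees = 50), seed = 2)
  expect_equal(nrow(looa$per_fold), 4)

  # leaking the label as a feature makes every fold metric exactly 1
  leaked <- df
  leaked$fft_01 <- ifelse(leaked$label == "rumination", 10, -10)
  lv <- run_validation(leaked, "rumination", "scv_5fold",
                       forest_spec(n_trees = 50), seed = 2)
  expect_true(all(abs(as.matrix(lv$per_fold[c("Se", "Sp", "PPV", "NPV",
                                              "F1", "Acc")]) - 1) < 1e-12))
})

test_that("looa approaches scv accuracy when cows are exchangeable", {
  # all cows share identical generating parameters: between-animal
  # generalization should cost little
  df <- toy_features(n = 800, shift = 4, seed = 11)
  scv <- run_validation(df, "rumination", "scv_5fold",
                        forest_spec(n_trees = 50), seed = 4)
  looa <- run_validation(df, "rumination", "looa",
                         forest_spec(n_trees = 50), seed = 4)
  expect_lt(abs(mean(scv$per_fold$Acc) - mean(looa$per_fold$Acc)), 0.05)
})

test_that("the AUC sweep reports one value per forest size", {
  df <- toy_features(n = 300, shift = 3, seed = 13)
  sweep <- auc_sweep(df, "rumination", n_trees_grid = c(20, 50), seed = 1)
  expect_equal(sweep$n_trees, c(20, 50))
  expect_true(all(sweep$auc > 0.9 & sweep$auc <= 1))
})
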