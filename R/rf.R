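#' Random-forest specification
#'
#' Hyperparameters of the one-vs-all random forests. Defaults are
#' conventional: 500 trees, `floor(sqrt(30)) = 5` candidate features per
#' split, minimum node size 1.
#'
#' @param n_trees Number of trees.
#' @param features_per_split Candidate features per split (`mtry`).
#' @param min_leaf Minimum node size.
#' @param seed Integer seed controlling tree growing.
#' @return An object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 500L, features_per_split = 5L,
                        min_leaf = 1L, seed = 1L) {
  if (n_trees < 1L || features_per_split < 1L || features_per_split > 30L) {
    stop("n_trees must be >= 1 and features_per_split in 1..30", call. = FALSE)
  }
  structure(
    list(n_trees = as.integer(n_trees),
         features_per_split = as.integer(features_per_split),
         min_leaf = as.integer(min_leaf),
         seed = as.integer(seed)),
    class = "forest_spec"
  )
}

#' Rebalance classes for one-vs-all training
#'
#' Rows whose label equals `behavior` are the positive class. Positives are
#' replicated `upsample_factor` times (one full copy is always kept; the
#' extra `factor - 1` copies are drawn with replacement), and negatives are
#' down-sampled without replacement to `balance_ratio` times the resulting
#' positive count. The output is shuffled deterministically by `seed`.
#'
#' @param features Feature matrix data frame (see [build_feature_matrix()]).
#' @param behavior Positive behavior class.
#' @param upsample_factor Positive-class replication factor (default 1;
#'   3 mirrors the up-sampling used for rare classes such as drinking and
#'   sleeping).
#' @param balance_ratio Negatives per positive after balancing.
#' @param seed Integer seed.
#' @return The rebalanced feature matrix data frame.
#' @export
balance_classes <- function(features, behavior, upsample_factor = 1L,
                            balance_ratio = 1, seed = 1L) {
  check_behavior(behavior)
  if (upsample_factor < 1L) stop("upsample_factor must be >= 1", call. = FALSE)
  pos <- which(features$label == behavior)
  neg <- which(features$label != behavior)
  if (!length(pos)) stop("no positive rows for behavior '", behavior, "'",
                         call. = FALSE)
  if (!length(neg)) stop("no negative rows", call. = FALSE)
  set.seed(as.integer(seed))
  pos_out <- pos
  if (upsample_factor > 1L) {
    pos_out <- c(pos, sample(pos, (upsample_factor - 1L) * length(pos),
                             replace = TRUE))
  }
  n_neg <- round(balance_ratio * length(pos_out))
  if (n_neg > length(neg)) {
    stop("not enough negative rows to balance at the requested ratio",
         call. = FALSE)
  }
  neg_out <- sample(neg, n_neg, replace = FALSE)
  idx <- sample(c(pos_out, neg_out))
  out <- features[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a validation split plan
#'
#' Three schemes: `holdout_70_30` (label-stratified 70% train / 30% test),
#' `scv_5fold` (five label-stratified folds, each row in exactly one test
#' fold) and `looa` (leave-one-animal-out: one fold per distinct `cow_id`,
#' that animal's rows forming the test set).
#'
#' @param features Feature matrix data frame with `label` and `cow_id`.
#' @param scheme One of `"holdout_70_30"`, `"scv_5fold"`, `"looa"`.
#' @param seed Integer seed for the random assignments.
#' @return An object of class `split_plan`: list with `scheme`, `test_sets`
#'   (list of row-index vectors, one per fold) and `fold_names`.
#' @export
make_split <- function(features, scheme = c("holdout_70_30", "scv_5fold", "looa"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(features)
  set.seed(as.integer(seed))
  if (scheme == "holdout_70_30") {
    test <- unlist(lapply(split(seq_len(n), features$label), function(rows) {
      sample(rows, round(0.30 * length(rows)))
    }), use.names = FALSE)
    test_sets <- list(sort(test))
    fold_names <- "holdout"
  } else if (scheme == "scv_5fold") {
    fold <- integer(n)
    for (rows in split(seq_len(n), features$label)) {
      fold[rows] <- sample(rep_len(1:5, length(rows)))
    }
    test_sets <- lapply(1:5, function(f) which(fold == f))
    fold_names <- paste0("fold", 1:5)
  } else {
    cows <- unique(features$cow_id)
    if (length(cows) < 2L) {
      stop("leave-one-animal-out needs at least 2 distinct cow_ids",
           call. = FALSE)
    }
    test_sets <- lapply(cows, function(cw) which(features$cow_id == cw))
    fold_names <- as.character(cows)
  }
  structure(list(scheme = scheme, test_sets = test_sets,
                 fold_names = fold_names, n_rows = n, seed = as.integer(seed)),
            class = "split_plan")
}

#' Train a one-vs-all random forest
#'
#' Fits a random forest predicting `label == behavior` against the union of
#' all other behaviors, on the 30 spectral features.
#'
#' @param train Feature matrix data frame containing both classes.
#' @param behavior Positive behavior class.
#' @param spec A [forest_spec()].
#' @param config A [feature_config()] naming the feature columns.
#' @return An object of class `ova_forest`.
#' @export
train_one_vs_all <- function(train, behavior, spec = forest_spec(),
                             config = feature_config()) {
  check_behavior(behavior)
  fn <- feature_names(config)
  missing_cols <- setdiff(fn, names(train))
  if (length(missing_cols)) {
    stop("training data lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- factor(ifelse(train$label == behavior, "pos", "neg"),
              levels = c("neg", "pos"))
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  fit <- ranger::ranger(
    x = train[, fn, drop = FALSE], y = y,
    num.trees = spec$n_trees,
    mtry = spec$features_per_split,
    min.node.size = spec$min_leaf,
    probability = TRUE,
    seed = spec$seed,
    num.threads = 1
  )
  structure(list(fit = fit, behavior = behavior, feature_names = fn,
                 spec = spec),
            class = "ova_forest")
}

#' Predict with a one-vs-all forest
#'
#' Feature columns are bound by name (column order in `newdata` is
#' irrelevant). The prediction is positive when the fraction of trees voting
#' positive exceeds 0.5; exact ties predict negative (conservative for
#' monitoring alarms).
#'
#' @param object An `ova_forest`.
#' @param newdata Data frame with the 30 feature columns.
#' @param ... Unused.
#' @return Logical vector of per-row predictions.
#' @export
predict.ova_forest <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  p <- predict(object$fit, data = newdata[, object$feature_names, drop = FALSE],
               num.threads = 1)$predictions[, "pos"]
  p > 0.5
}

#' Run a validation scheme for one behavior
#'
#' Rebalances the feature matrix (see [balance_classes()]), splits it
#' according to the scheme, trains a one-vs-all forest on each fold's
#' training rows and evaluates on its test rows.
#'
#' @param features Feature matrix data frame.
#' @param behavior Positive behavior class.
#' @param scheme Validation scheme, see [make_split()].
#' @param spec A [forest_spec()].
#' @param upsample_factor,balance_ratio Passed to [balance_classes()].
#' @param seed Integer seed for balancing and splitting.
#' @param config A [feature_config()].
#' @return An object of class `rf_validation`: list with `per_fold` (data
#'   frame of TP/FP/TN/FN and the six metrics per fold), `mean` and `sd`
#'   (named metric vectors across folds), `scheme` and `behavior`.
#' @export
run_validation <- function(features, behavior,
                           scheme = c("holdout_70_30", "scv_5fold", "looa"),
                           spec = forest_spec(),
                           upsample_factor = 1L, balance_ratio = 1,
                           seed = 1L, config = feature_config()) {
  scheme <- match.arg(scheme)
  balanced <- balance_classes(features, behavior, upsample_factor,
                              balance_ratio, seed = seed)
  plan <- make_split(balanced, scheme, seed = seed)
  rows <- lapply(seq_along(plan$test_sets), function(f) {
    test_idx <- plan$test_sets[[f]]
    train <- balanced[-test_idx, , drop = FALSE]
    test <- balanced[test_idx, , drop = FALSE]
    model <- train_one_vs_all(train, behavior, spec, config)
    pred <- predict(model, test)
    cm <- confusion(pred, test$label == behavior)
    mt <- metrics(cm)
    cbind(data.frame(fold = plan$fold_names[f], TP = cm$TP, FP = cm$FP,
                     TN = cm$TN, FN = cm$FN),
          as.data.frame(as.list(unclass(mt))))
  })
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("Se", "Sp", "PPV", "NPV", "F1", "Acc")
  structure(
    list(per_fold = per_fold,
         mean = colMeans(per_fold[metric_cols]),
         sd = vapply(per_fold[metric_cols], sd, numeric(1)),
         scheme = scheme, behavior = behavior),
    class = "rf_validation"
  )
}

#' @export
print.rf_validation <- function(x, ...) {
  cat("<rf_validation>", x$behavior, "one-vs-all,", x$scheme, "\n")
  print(x$per_fold, row.names = FALSE)
  if (nrow(x$per_fold) > 1L) {
    cat("mean:", paste(sprintf("%s %.2f", names(x$mean), x$mean),
                       collapse = "  "), "\n")
  }
  invisible(x)
}

#' AUC sweep over forest sizes
#'
#' Utility mirroring hyperparameter choice by visual inspection of AUC
#' curves: fits forests of increasing size on a 70/30 split and reports the
#' out-of-sample AUC of the positive-class vote fraction for each size.
#'
#' @param features Feature matrix data frame.
#' @param behavior Positive behavior class.
#' @param n_trees_grid Integer vector of forest sizes to try.
#' @param seed Integer seed.
#' @param config A [feature_config()].
#' @return Data frame with columns `n_trees` and `auc`.
#' @export
auc_sweep <- function(features, behavior, n_trees_grid = c(50, 100, 250, 500),
                      seed = 1L, config = feature_config()) {
  balanced <- balance_classes(features, behavior, seed = seed)
  plan <- make_split(balanced, "holdout_70_30", seed = seed)
  test_idx <- plan$test_sets[[1]]
  train <- balanced[-test_idx, , drop = FALSE]
  test <- balanced[test_idx, , drop = FALSE]
  truth <- test$label == behavior
  fn <- feature_names(config)
  aucs <- vapply(n_trees_grid, function(nt) {
    model <- train_one_vs_all(train, behavior,
                              forest_spec(n_trees = nt, seed = seed), config)
    p <- predict(model$fit, data = test[, fn, drop = FALSE],
                 num.threads = 1)$predictions[, "pos"]
    ## rank-based AUC (Mann-Whitney)
    r <- rank(p)
    n_pos <- sum(truth)
    n_neg <- sum(!truth)
    (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
  data.frame(n_trees = n_trees_grid, auc = aucs)
}
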