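#' Balanced sampling of negatives
#'
#' Keeps every positive (gene-damaging) example and draws a uniform random
#' sample of negatives of equal size, avoiding class-imbalance bias in
#' training. Deterministic given `seed`.
#'
#' @param positives,negatives data frames (feature columns + `label`)
#' @param seed integer seed
#' @return a data frame with `label` column, positives first
#' @export
balanced_sample <- function(positives, negatives, seed) {
  if (nrow(negatives) < nrow(positives))
    stop("fewer negatives than positives; cannot balance")
  idx <- withr::with_seed(seed, sample.int(nrow(negatives), nrow(positives)))
  out <- rbind(positives, negatives[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Classification performance metrics
#'
#' @param TP,FN,TN,FP non-negative integer counts
#' @return object of class `performance_metrics` with the counts and
#'   `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#'   `precision = TP/(TP+FP)`, `accuracy = (TP+TN)/(TP+FN+TN+FP)`;
#'   a rate with a zero denominator is `NA` and listed in the `undefined`
#'   field
#' @export
compute_metrics <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0)) stop("negative count")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(
    TP = TP, FN = FN, TN = TN, FP = FP,
    sensitivity = rate(TP, TP + FN),
    specificity = rate(TN, TN + FP),
    precision = rate(TP, TP + FP),
    accuracy = rate(TP + TN, TP + FN + TN + FP))
  m$undefined <- names(which(vapply(m[c("sensitivity", "specificity",
                                        "precision", "accuracy")], is.na, TRUE)))
  class(m) <- "performance_metrics"
  m
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf(
    "TP=%d FN=%d TN=%d FP=%d | sens %.3f spec %.3f prec %.3f acc %.3f\n",
    x$TP, x$FN, x$TN, x$FP, x$sensitivity, x$specificity, x$precision,
    x$accuracy))
  invisible(x)
}

confusion_counts <- function(truth, predicted) {
  c(TP = sum(truth == DAMAGING & predicted == DAMAGING),
    FN = sum(truth == DAMAGING & predicted == NEUTRAL),
    TN = sum(truth == NEUTRAL & predicted == NEUTRAL),
    FP = sum(truth == NEUTRAL & predicted == DAMAGING))
}

# default learner: decision tree on the given features
tree_learner <- function(features = NULL, pruning_confidence = 0.25,
                         min_leaf = 2L) {
  function(train) {
    tree <- induce_tree(train, features = features,
                        pruning_confidence = pruning_confidence,
                        min_leaf = min_leaf)
    function(newdata) predict(tree, newdata)
  }
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Rows are partitioned into `k` stratified folds; each fold serves as the
#' test set once while the learner trains on the rest. Confusion counts are
#' pooled over folds (micro-average) before computing the metrics once;
#' set `pooled = FALSE` to average per-fold metrics instead.
#'
#' @param data data frame (feature columns + `label`)
#' @param k number of folds (default 10)
#' @param learner function `train_df -> (newdata -> labels)`; default is a
#'   decision tree on all features
#' @param seed integer seed for the fold assignment
#' @param pooled pool counts over folds (default) or average fold metrics
#' @return [compute_metrics()] result; the fold assignment is attached as
#'   attribute `folds`
#' @export
kfold_cv <- function(data, k = 10L, learner = tree_learner(), seed = 1L,
                     pooled = TRUE) {
  if (k > nrow(data)) stop("k exceeds number of rows")
  fold <- stratified_folds(data$label, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    test <- fold == f
    model <- learner(data[!test, , drop = FALSE])
    confusion_counts(data$label[test], model(data[test, , drop = FALSE]))
  })
  if (pooled) {
    tot <- Reduce(`+`, per_fold)
    m <- compute_metrics(tot[["TP"]], tot[["FN"]], tot[["TN"]], tot[["FP"]])
  } else {
    ms <- lapply(per_fold, function(cc)
      compute_metrics(cc[["TP"]], cc[["FN"]], cc[["TN"]], cc[["FP"]]))
    tot <- Reduce(`+`, per_fold)
    m <- compute_metrics(tot[["TP"]], tot[["FN"]], tot[["TN"]], tot[["FP"]])
    for (nm in c("sensitivity", "specificity", "precision", "accuracy"))
      m[[nm]] <- mean(vapply(ms, `[[`, 0, nm), na.rm = TRUE)
  }
  attr(m, "folds") <- fold
  m
}

#' Repeated cross-validation with negative resampling
#'
#' Each repeat draws a fresh balanced sample of negatives ([balanced_sample()])
#' and runs one stratified k-fold cross-validation; the summary is the mean
#' and sample SD of each metric over repeats. Per-repeat seeds are expanded
#' deterministically from `seed` and recorded in the result.
#'
#' @param positives,negatives data frames (feature columns + `label`)
#' @param n_repeats number of repeats (default 10)
#' @param k folds per repeat (default 10)
#' @param learner as in [kfold_cv()]
#' @param seed master seed
#' @return list with `summary` (data frame: metric, mean, sd), `history`
#'   (per-repeat metric data frame) and `seeds`
#' @export
repeated_cv <- function(positives, negatives, n_repeats = 10L, k = 10L,
                        learner = tree_learner(), seed = 1L) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_repeats))
  rows <- lapply(seq_len(n_repeats), function(r) {
    data <- balanced_sample(positives, negatives, seed = seeds[r])
    m <- kfold_cv(data, k = k, learner = learner, seed = seeds[r])
    data.frame(repeat_id = r, seed = seeds[r],
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, accuracy = m$accuracy)
  })
  history <- do.call(rbind, rows)
  metrics <- c("sensitivity", "specificity", "precision", "accuracy")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(nm) mean(history[[nm]]), 0),
    sd = vapply(metrics, function(nm)
      if (n_repeats < 2) NA_real_ else sd(history[[nm]]), 0))
  if (n_repeats < 2)
    fs_log("repeated_cv: SD undefined with fewer than 2 repeats", level = "WARN")
  list(summary = summary, history = history, seeds = seeds)
}

#' Greedy forward feature selection
#'
#' Starting from an empty selected set S, each iteration evaluates every
#' remaining candidate feature by the cross-validated accuracy of a tree
#' trained on S plus that candidate, and moves the best one into S. The
#' first feature is always accepted (the baseline step); afterwards the
#' procedure stops when the best improvement in accuracy falls below
#' `stop_delta` (fractions: 0.001 = 0.1%). Ties go to the earlier feature
#' in `features` order.
#'
#' @param data balanced labeled data frame (feature columns + `label`)
#' @param features candidate feature names (default: all numeric columns)
#' @param k CV folds (default 10)
#' @param stop_delta minimum accepted accuracy improvement (default 0.001)
#' @param seed integer seed (fold assignment; shared across candidates so
#'   comparisons are paired)
#' @param pruning_confidence,min_leaf tree parameters
#' @return list with `selected` (in order of addition), `available`,
#'   `history` (accuracy after each addition), `trace` (per-iteration
#'   candidate accuracies)
#' @export
greedy_forward_selection <- function(data, features = NULL, k = 10L,
                                     stop_delta = 0.001, seed = 1L,
                                     pruning_confidence = 0.25, min_leaf = 2L) {
  if (is.null(features))
    features <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], "label")
  if (length(features) < 1) stop("no candidate features")
  selected <- character()
  available <- features
  history <- numeric()
  trace <- list()
  current <- -Inf
  while (length(available) > 0) {
    accs <- vapply(available, function(f) {
      learner <- tree_learner(features = c(selected, f),
                              pruning_confidence = pruning_confidence,
                              min_leaf = min_leaf)
      kfold_cv(data, k = k, learner = learner, seed = seed)$accuracy
    }, 0)
    best <- which.max(accs)  # first max wins: tie goes to feature order
    trace[[length(trace) + 1L]] <- accs
    improvement <- accs[best] - max(current, 0)
    if (length(selected) > 0 && improvement < stop_delta) break
    selected <- c(selected, available[best])
    available <- available[-best]
    current <- accs[[best]]
    history <- c(history, current)
    fs_log(sprintf("selection: added %s (CV accuracy %.4f)",
                   tail(selected, 1), current))
  }
  list(selected = selected, available = available, history = history,
       trace = trace)
}
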