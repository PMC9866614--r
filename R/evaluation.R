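#' Confusion counts
#'
#' Binary counts (`TP`, `FP`, `TN`, `FN`) or, via `confusion_matrix()`, a
#' square contingency table for the three-class task. The stress state is
#' the positive class everywhere in the binary task.
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return `confusion_counts` object.
#' @examples
#' accuracy(confusion_counts(TP = 2, TN = 3, FP = 1, FN = 0))  # 5/6
#' f1(confusion_counts(TP = 2, TN = 3, FP = 1, FN = 0))        # 0.8
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param truth,pred Vectors of true and predicted labels.
#' @param positive Positive class for binary counting; `NULL` returns the
#'   full contingency table (three-class use).
#' @export
confusion_matrix <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  if (!is.null(positive)) {
    return(confusion_counts(
      TP = sum(truth == positive & pred == positive),
      FP = sum(truth != positive & pred == positive),
      TN = sum(truth != positive & pred != positive),
      FN = sum(truth == positive & pred != positive)
    ))
  }
  lev <- sort(unique(c(truth, pred)))
  table(factor(truth, lev), factor(pred, lev), dnn = c("truth", "pred"))
}

#' Classification accuracy
#'
#' `(TP + TN) / total` for binary counts; the trace over the total for a
#' contingency table.
#'
#' @param counts A [confusion_counts()] object or a square `table` from
#'   [confusion_matrix()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  if (inherits(counts, "confusion_counts")) {
    total <- counts$TP + counts$TN + counts$FP + counts$FN
    if (total == 0) stop("accuracy undefined for zero total count")
    return((counts$TP + counts$TN) / total)
  }
  if (is.table(counts) || is.matrix(counts)) {
    total <- sum(counts)
    if (total == 0) stop("accuracy undefined for zero total count")
    return(sum(diag(counts)) / total)
  }
  stop("counts must be confusion_counts or a contingency table")
}

#' F1 score
#'
#' Binary: `2 TP / (2 TP + FP + FN)` with stress as the positive class.
#' Three-class (a contingency table): unweighted (macro) mean of per-class
#' one-vs-rest F1. A class with `2 TP + FP + FN == 0` (absent from both
#' truth and prediction) contributes 0 with a warning.
#'
#' @param counts A [confusion_counts()] object or a square `table`.
#' @return F1 in `[0, 1]`.
#' @export
f1 <- function(counts) {
  f1_one <- function(TP, FP, FN) {
    denom <- 2 * TP + FP + FN
    if (denom == 0) {
      warning("degenerate class (no positives in truth or prediction): F1 = 0")
      return(0)
    }
    2 * TP / denom
  }
  if (inherits(counts, "confusion_counts")) {
    return(f1_one(counts$TP, counts$FP, counts$FN))
  }
  if (is.table(counts) || is.matrix(counts)) {
    per_class <- vapply(seq_len(nrow(counts)), function(i) {
      f1_one(counts[i, i], sum(counts[-i, i]), sum(counts[i, -i]))
    }, numeric(1))
    return(mean(per_class))
  }
  stop("counts must be confusion_counts or a contingency table")
}

#' Time to detection
#'
#' Elapsed time between the first and last raw sample a single
#' classification decision consumes: one decision uses `w` consecutive
#' segments of `t_length` seconds spaced `t_step` seconds apart, so
#' `TTD = t_length + (w - 1) t_step`. The headline configuration
#' (48-sample window, 28-sample step at 4 Hz, `w = 7`) gives 54 s.
#'
#' @param t_length_s Segment length, seconds.
#' @param t_step_s Segmentation step, seconds.
#' @param w Sequence window size, segments.
#' @return TTD in seconds.
#' @examples
#' ttd(12, 7, 7)  # 54
#' @export
ttd <- function(t_length_s, t_step_s, w) {
  stopifnot(t_length_s > 0, t_step_s > 0, w >= 1, w == round(w))
  t_length_s + (w - 1) * t_step_s
}

#' Collapse three states to the binary stress task
#'
#' Stress is the positive class; baseline and amusement together form the
#' negative, no-stress class (the convention shared by the WESAD
#' benchmark literature).
#'
#' @param labels Character vector of state codes.
#' @return Factor with levels `no_stress`, `stress`.
#' @export
make_binary <- function(labels) {
  factor(ifelse(as.character(labels) == "stress", "stress", "no_stress"),
         levels = c("no_stress", "stress"))
}

#' Classifier specification
#'
#' The evaluation roster, with the untuned hyperparameters used for every
#' experiment: decision tree of maximum depth 10; 1-NN and 10-NN; random
#' forest of 10 or 100 trees, depth 10, balanced class weights; RBF-kernel
#' SVM with balanced class weights; bagged SVM (10 bootstrap replicates,
#' majority vote); AdaBoost (SAMME) with 10 estimators, each a random
#' forest of 100 trees of depth 10 with balanced class weights.
#'
#' @param kind One of `"decision_tree"`, `"knn"`, `"random_forest"`,
#'   `"svm_rbf"`, `"bagged_svm"`, `"adaboost_rf"`.
#' @param k Neighbour count for kNN.
#' @param n_trees Tree count for the random forest.
#' @param max_depth Tree depth cap.
#' @param n_estimators Ensemble size for bagging / boosting.
#' @param standardize Standardize features with training-fold mean/SD?
#'   Default: yes for the distance- and kernel-based learners (kNN, SVM),
#'   no for the tree ensembles, which are scale-invariant.
#' @param seed Integer seed fanned out deterministically to every
#'   stochastic component (tree ensembles, bagging, kNN tie-breaking).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "decision_tree",
                                     "random_forest", "svm_rbf",
                                     "bagged_svm", "adaboost_rf"),
                            k = 10L, n_trees = 100L, max_depth = 10L,
                            n_estimators = 10L, standardize = NULL,
                            seed = 0L) {
  kind <- match.arg(kind)
  if (is.null(standardize)) {
    standardize <- kind %in% c("knn", "svm_rbf", "bagged_svm")
  }
  structure(
    list(kind = kind, k = as.integer(k), n_trees = as.integer(n_trees),
         max_depth = as.integer(max_depth),
         n_estimators = as.integer(n_estimators),
         standardize = standardize, seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  extra <- switch(x$kind,
    knn = sprintf("k=%d", x$k),
    decision_tree = sprintf("max_depth=%d", x$max_depth),
    random_forest = sprintf("trees=%d depth=%d", x$n_trees, x$max_depth),
    svm_rbf = "radial kernel, balanced weights",
    bagged_svm = sprintf("%d bags", x$n_estimators),
    adaboost_rf = sprintf("%d estimators of RF(%d, depth %d)",
                          x$n_estimators, x$n_trees, x$max_depth))
  cat(sprintf("<classifier_spec> %s (%s), seed %d\n", x$kind, extra, x$seed))
  invisible(x)
}

.balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

# Train on (X_train, y_train), predict labels for X_test.
# All randomness is governed by `seed`.
.fit_predict <- function(spec, X_train, y_train, X_test, seed) {
  set.seed(seed)
  y_train <- droplevels(factor(y_train))
  lev <- levels(y_train)
  majority_vote <- function(votes) {
    # votes: matrix [n_test x n_models] of label strings
    apply(votes, 1L, function(v) {
      tab <- table(factor(v, lev))
      lev[which.max(tab)]
    })
  }
  pred <- switch(
    spec$kind,
    knn = as.character(
      class::knn(X_train, X_test, y_train, k = spec$k)
    ),
    decision_tree = {
      df_tr <- data.frame(.y = y_train, X_train, check.names = FALSE)
      fit <- rpart::rpart(
        .y ~ ., data = df_tr, method = "class",
        control = rpart::rpart.control(maxdepth = spec$max_depth,
                                       xval = 0))
      as.character(predict(fit, data.frame(X_test, check.names = FALSE),
                           type = "class"))
    },
    random_forest = {
      fit <- ranger::ranger(
        x = X_train, y = y_train, num.trees = spec$n_trees,
        max.depth = spec$max_depth,
        class.weights = .balanced_weights(y_train)[lev],
        seed = seed, num.threads = 1L)
      as.character(predict(fit, X_test,
                           num.threads = 1L)$predictions)
    },
    svm_rbf = {
      fit <- e1071::svm(x = X_train, y = y_train, kernel = "radial",
                        class.weights = .balanced_weights(y_train),
                        scale = FALSE)
      as.character(predict(fit, X_test))
    },
    bagged_svm = {
      n <- nrow(X_train)
      votes <- vapply(seq_len(spec$n_estimators), function(b) {
        set.seed(seed + b)
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y_train[idx])) >= 2L) break
        }
        fit <- e1071::svm(x = X_train[idx, , drop = FALSE],
                          y = droplevels(y_train[idx]), kernel = "radial",
                          class.weights =
                            .balanced_weights(droplevels(y_train[idx])),
                          scale = FALSE)
        as.character(predict(fit, X_test))
      }, character(nrow(X_test)))
      majority_vote(matrix(votes, nrow = nrow(X_test)))
    },
    adaboost_rf = {
      # SAMME with random-forest base learners
      n <- nrow(X_train)
      K <- length(lev)
      w <- rep(1 / n, n)
      alphas <- numeric(0)
      test_preds <- list()
      for (m in seq_len(spec$n_estimators)) {
        fit <- ranger::ranger(
          x = X_train, y = y_train, num.trees = spec$n_trees,
          max.depth = spec$max_depth,
          class.weights = .balanced_weights(y_train)[lev],
          case.weights = w, seed = seed + m, num.threads = 1L)
        pr_train <- as.character(predict(fit, X_train,
                                         num.threads = 1L)$predictions)
        err <- sum(w * (pr_train != as.character(y_train))) / sum(w)
        if (err >= 1 - 1 / K) break  # no better than chance: stop
        err <- max(err, 1e-10)
        alpha <- log((1 - err) / err) + log(K - 1)
        alphas <- c(alphas, alpha)
        test_preds[[length(test_preds) + 1L]] <-
          as.character(predict(fit, X_test, num.threads = 1L)$predictions)
        if (err <= 1e-10) break  # perfect fit: further rounds are no-ops
        w <- w * exp(alpha * (pr_train != as.character(y_train)))
        w <- w / sum(w)
      }
      if (!length(test_preds)) {
        # every round failed: fall back to a single forest
        fit <- ranger::ranger(
          x = X_train, y = y_train, num.trees = spec$n_trees,
          max.depth = spec$max_depth, seed = seed, num.threads = 1L)
        as.character(predict(fit, X_test, num.threads = 1L)$predictions)
      } else {
        vote <- matrix(0, nrow(X_test), length(lev),
                       dimnames = list(NULL, lev))
        for (m in seq_along(test_preds)) {
          ij <- cbind(seq_len(nrow(X_test)), match(test_preds[[m]], lev))
          vote[ij] <- vote[ij] + alphas[m]
        }
        lev[max.col(vote, ties.method = "first")]
      }
    }
  )
  factor(pred, levels = lev)
}

.score_fold <- function(truth, pred, task) {
  if (task == "binary") {
    counts <- confusion_matrix(truth, pred, positive = "stress")
    list(accuracy = accuracy(counts), f1 = f1(counts))
  } else {
    lev <- sort(unique(c(as.character(truth), as.character(pred))))
    tab <- table(factor(truth, lev), factor(pred, lev))
    list(accuracy = accuracy(tab), f1 = f1(tab))
  }
}

#' Leave-one-subject-out evaluation
#'
#' For each of the `J` subjects in the feature table, trains the
#' classifier on the other `J - 1` subjects' rows and scores on the
#' held-out subject; per-subject accuracy and F1 are averaged unweighted
#' across subjects. When `spec$standardize` is set, features are centred
#' and scaled using training-fold statistics only (the held-out subject
#' never influences the scaling). Fully seeded: identical inputs and
#' seeds give identical reports.
#'
#' @param features Sequence-feature data frame from
#'   [build_feature_table()] (metadata columns plus numeric features).
#' @param spec A [classifier_spec()].
#' @param task `"binary"` (stress vs no-stress, stress positive) or
#'   `"ternary"` (baseline / stress / amusement, macro F1).
#' @param ttd_seconds Optional TTD to echo in the report.
#' @param config Optional configuration echo (list) for the report.
#' @param verbose Emit one message per fold?
#' @return Object of class `loso_report`: per-subject scores, averaged
#'   `accuracy` and `f1`, task, config echo, `ttd_seconds`.
#' @export
loso_evaluate <- function(features, spec = classifier_spec("knn", k = 10),
                          task = c("binary", "ternary"),
                          ttd_seconds = NA_real_, config = NULL,
                          verbose = FALSE) {
  task <- match.arg(task)
  stopifnot(is.data.frame(features), inherits(spec, "classifier_spec"))
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L) {
    stop_edafreq("single_subject",
                 "LOSO evaluation needs at least 2 subjects")
  }
  feat_cols <- setdiff(names(features), .meta_cols)
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  y <- if (task == "binary") make_binary(features$label) else
    factor(features$label)

  per <- data.frame(subject = subjects, n_train = NA_integer_,
                    n_test = NA_integer_, accuracy = NA_real_,
                    f1 = NA_real_)
  for (j in seq_along(subjects)) {
    test_idx <- features$subject_id == subjects[j]
    X_tr <- X[!test_idx, , drop = FALSE]
    X_te <- X[test_idx, , drop = FALSE]
    if (spec$standardize) {
      mu <- colMeans(X_tr)
      sd_ <- apply(X_tr, 2L, stats::sd)
      sd_[sd_ == 0 | !is.finite(sd_)] <- 1
      X_tr <- sweep(sweep(X_tr, 2L, mu), 2L, sd_, "/")
      X_te <- sweep(sweep(X_te, 2L, mu), 2L, sd_, "/")
    }
    fold_seed <- spec$seed + 104729L * j
    pred <- .fit_predict(spec, X_tr, y[!test_idx], X_te, fold_seed)
    sc <- .score_fold(as.character(y[test_idx]), as.character(pred), task)
    per$n_train[j] <- sum(!test_idx)
    per$n_test[j] <- sum(test_idx)
    per$accuracy[j] <- sc$accuracy
    per$f1[j] <- sc$f1
    if (verbose) {
      message(sprintf(
        "fold %s: train %d rows, test %d rows, accuracy %.4f, F1 %.4f",
        subjects[j], per$n_train[j], per$n_test[j], sc$accuracy, sc$f1))
    }
  }
  structure(
    list(task = task, per_subject = per,
         accuracy = mean(per$accuracy), f1 = mean(per$f1),
         classifier = spec, config = config, ttd_seconds = ttd_seconds),
    class = "loso_report"
  )
}

#' @export
print.loso_report <- function(x, digits = 4, ...) {
  cat(sprintf("<loso_report> %s task, %d subjects (%s)\n", x$task,
              nrow(x$per_subject), x$classifier$kind))
  if (is.finite(x$ttd_seconds)) {
    cat(sprintf("  time to detection: %g s\n", x$ttd_seconds))
  }
  cat(sprintf("  averaged accuracy %.*f, F1 %.*f\n", digits, x$accuracy,
              digits, x$f1))
  invisible(x)
}

#' @export
summary.loso_report <- function(object, ...) {
  print(object, ...)
  cat("  per subject:\n")
  print(object$per_subject, row.names = FALSE)
  invisible(object)
}

#' Fixed-TTD grid search over segmentation geometry
#'
#' Holds the time to detection constant and sweeps the segmentation
#' geometry: for each `(t_length, t_overlap)` pair with
#' `t_overlap < t_length`, the sequence window
#' `w = (TTD - t_length) / t_step + 1` is computed, and the cell is
#' evaluated only when `w` is a positive integer; other cells are marked
#' empty (`NA` scores).
#'
#' @param signals List of [labeled_signal()] objects.
#' @param ttd_target Target TTD, seconds (30 or 60 in the reference
#'   experiments).
#' @param t_lengths,t_overlaps Candidate window lengths and overlaps,
#'   samples.
#' @param spec A [classifier_spec()].
#' @param task Passed to [loso_evaluate()].
#' @param bands,preprocess Passed to [build_feature_table()].
#' @return Data frame with one row per grid cell: geometry, `w`, `kept`,
#'   `ttd_seconds`, `accuracy`, `f1`.
#' @export
fixed_ttd_grid <- function(signals, ttd_target = 60,
                           t_lengths = seq(16L, 96L, by = 16L),
                           t_overlaps = seq(0L, 80L, by = 16L),
                           spec = classifier_spec("knn", k = 10),
                           task = "binary", bands = default_bands(),
                           preprocess = "mean-removal") {
  fs <- signals[[1L]]$fs
  grid <- expand.grid(t_length = t_lengths, t_overlap = t_overlaps)
  grid <- grid[grid$t_overlap < grid$t_length, , drop = FALSE]
  rownames(grid) <- NULL
  grid$t_step <- grid$t_length - grid$t_overlap
  w_exact <- (ttd_target - grid$t_length / fs) / (grid$t_step / fs) + 1
  grid$w <- ifelse(abs(w_exact - round(w_exact)) < 1e-9 & w_exact >= 1,
                   round(w_exact), NA_integer_)
  grid$kept <- !is.na(grid$w)
  grid$ttd_seconds <- ifelse(grid$kept, ttd_target, NA_real_)
  grid$accuracy <- rep(NA_real_, nrow(grid))
  grid$f1 <- rep(NA_real_, nrow(grid))
  for (i in which(grid$kept)) {
    cfg <- segmentation_config(grid$t_length[i], grid$t_overlap[i])
    feats <- build_feature_table(signals, cfg, bands, w = grid$w[i],
                                 preprocess = preprocess)
    if (!nrow(feats) || length(unique(feats$subject_id)) < 2L) next
    rep <- loso_evaluate(feats, spec, task, ttd_seconds = ttd_target)
    grid$accuracy[i] <- rep$accuracy
    grid$f1[i] <- rep$f1
  }
  grid
}

#' Window-size sweep: detection-time / performance trade-off
#'
#' Fixes the segmentation geometry and sweeps the sequence window size
#' `w`, pairing each configuration's LOSO scores with its time to
#' detection. The per-segment features are computed once and re-windowed
#' per `w`.
#'
#' @param signals List of [labeled_signal()] objects.
#' @param w_values Window sizes to evaluate.
#' @param t_length,t_overlap Segmentation geometry, samples.
#' @param spec A [classifier_spec()] (reference choice: 10-NN).
#' @param task Passed to [loso_evaluate()].
#' @param bands,preprocess Passed to [segment_feature_table()].
#' @return Data frame sorted by TTD: `w`, `ttd_seconds`, `accuracy`, `f1`.
#' @export
window_sweep <- function(signals, w_values = 1:10, t_length = 48L,
                         t_overlap = 20L,
                         spec = classifier_spec("knn", k = 10),
                         task = "binary", bands = default_bands(),
                         preprocess = "mean-removal") {
  cfg <- segmentation_config(t_length, t_overlap)
  fs <- signals[[1L]]$fs
  base <- segment_feature_table(signals, cfg, bands,
                                preprocess = preprocess)
  out <- data.frame(w = as.integer(w_values))
  out$ttd_seconds <- vapply(out$w, function(w) {
    ttd(cfg$t_length / fs, cfg$t_step / fs, w)
  }, numeric(1))
  out$accuracy <- NA_real_
  out$f1 <- NA_real_
  for (i in seq_len(nrow(out))) {
    feats <- assemble_sequence_features(base, out$w[i])
    if (!nrow(feats) || length(unique(feats$subject_id)) < 2L) next
    rep <- loso_evaluate(feats, spec, task,
                         ttd_seconds = out$ttd_seconds[i])
    out$accuracy[i] <- rep$accuracy
    out$f1[i] <- rep$f1
  }
  out[order(out$ttd_seconds), ]
}
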