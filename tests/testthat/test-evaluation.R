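test_that("accuracy and F1 match direct arithmetic", {
  c1 <- confusion_counts(TP = 2, TN = 3, FP = 1, FN = 0)
  expect_equal(accuracy(c1), 5 / 6)
  expect_equal(f1(c1), 0.8)  # 2*2 / (2*2 + 1 + 0)
  c2 <- confusion_counts(TP = 1, TN = 1, FP = 1, FN = 1)
  expect_equal(accuracy(c2), 0.5)
  expect_equal(f1(c2), 0.5)
  perfect <- confusion_counts(TP = 4, TN = 6, FP = 0, FN = 0)
  expect_equal(accuracy(perfect), 1.0)
  expect_equal(f1(perfect), 1.0)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "zero total")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("degenerate classes contribute zero F1 with a warning", {
  none <- confusion_counts(TP = 0, TN = 5, FP = 0, FN = 0)
  expect_warning(val <- f1(none), "degenerate")
  expect_equal(val, 0)
})

test_that("three-class metrics use the trace and the macro mean", {
  truth <- c("baseline", "baseline", "stress", "stress", "amusement",
             "amusement")
  pred <- c("baseline", "stress", "stress", "stress", "amusement",
            "baseline")
  tab <- confusion_matrix(truth, pred)
  expect_equal(accuracy(tab), 4 / 6)
  # macro F1 = mean of per-class one-vs-rest F1
  per_class <- c(
    2 * 1 / (2 * 1 + 1 + 1),   # baseline: TP=1 FP=1 FN=1
    2 * 2 / (2 * 2 + 1 + 0),   # stress: TP=2 FP=1 FN=0
    2 * 1 / (2 * 1 + 0 + 1))   # amusement: TP=1 FP=0 FN=1
  expect_equal(f1(tab), mean(per_class))
})

test_that("metrics agree with an independent per-row tally", {
  set.seed(31)
  truth <- sample(c("stress", "baseline", "amusement"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth,
                 sample(c("stress", "baseline", "amusement"), 200,
                        replace = TRUE))
  counts <- confusion_matrix(truth, pred, positive = "stress")
  tb <- make_binary(truth)
  pb <- make_binary(pred)
  expect_equal(accuracy(counts), mean(tb == pb))
  prec <- sum(tb == "stress" & pb == "stress") / sum(pb == "stress")
  rec <- sum(tb == "stress" & pb == "stress") / sum(tb == "stress")
  expect_equal(f1(counts), 2 * prec * rec / (prec + rec))
  expect_equal(accuracy(confusion_matrix(truth, pred)),
               mean(truth == pred))
})

test_that("time to detection follows the window accounting", {
  expect_equal(ttd(12, 7, 7), 54)      # headline configuration
  expect_equal(ttd(12, 7, 1), 12)      # w = 1: a single segment
  expect_equal(ttd(12, 8, 7), 60)
  expect_error(ttd(12, 7, 0))
})

test_that("binary collapse keeps stress positive, the rest negative", {
  out <- make_binary(c("stress", "baseline", "amusement"))
  expect_identical(as.character(out), c("stress", "no_stress", "no_stress"))
  expect_identical(levels(out), c("no_stress", "stress"))
})

test_that("every classifier separates a trivially separable cohort", {
  set.seed(9)
  n <- 40
  mk <- function(sid) {
    df <- data.frame(
      subject_id = sid,
      label = rep(c("stress", "baseline"), each = n / 2),
      segment_start = seq_len(n))
    df$f1 <- rnorm(n, ifelse(df$label == "stress", 5, -5), 0.3)
    df$f2 <- rnorm(n, ifelse(df$label == "stress", -2, 2), 0.3)
    df
  }
  feats <- rbind(mk("A"), mk("B"), mk("C"))
  kinds <- list(
    classifier_spec("knn", k = 1, seed = 1),
    classifier_spec("knn", k = 10, seed = 1),
    classifier_spec("decision_tree", seed = 1),
    classifier_spec("random_forest", n_trees = 10, seed = 1),
    classifier_spec("svm_rbf", seed = 1),
    classifier_spec("bagged_svm", seed = 1),
    classifier_spec("adaboost_rf", n_trees = 10, seed = 1))
  for (spec in kinds) {
    rep_ <- loso_evaluate(feats, spec, "binary")
    expect_gt(rep_$accuracy, 0.95)
    expect_equal(rep_$accuracy, mean(rep_$per_subject$accuracy),
                 tolerance = 1e-12)
  }
})

test_that("LOSO reports are averaged per subject and reproducible", {
  cohort <- simulate_cohort(generator_params(n_subjects = 3, seed = 4))
  feats <- build_feature_table(cohort, w = 7)
  spec <- classifier_spec("knn", k = 10, seed = 2)
  r1 <- loso_evaluate(feats, spec, "binary", ttd_seconds = 54)
  r2 <- loso_evaluate(feats, spec, "binary", ttd_seconds = 54)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$per_subject), 3L)
  expect_equal(r1$accuracy, mean(r1$per_subject$accuracy),
               tolerance = 1e-12)
  expect_equal(r1$f1, mean(r1$per_subject$f1), tolerance = 1e-12)
  expect_true(all(r1$per_subject$accuracy >= 0 &
                    r1$per_subject$accuracy <= 1))
  expect_identical(r1$ttd_seconds, 54)
  expect_error(loso_evaluate(feats[feats$subject_id == "synth01", ], spec),
               class = "edafreq_single_subject")
})

test_that("held-out subjects are isolated from training-fold changes", {
  cohort <- simulate_cohort(generator_params(n_subjects = 4, seed = 6))
  feats <- build_feature_table(cohort, w = 7)
  spec <- classifier_spec("decision_tree", seed = 3)  # no standardization
  full <- loso_evaluate(feats, spec, "binary")
  # dropping one training subject's rows never changes another subject's
  # test rows or labels (fold bookkeeping)
  drop_id <- "synth04"
  reduced <- loso_evaluate(feats[feats$subject_id != drop_id, ], spec,
                           "binary")
  kept <- setdiff(full$per_subject$subject, drop_id)
  expect_identical(reduced$per_subject$subject, kept)
  expect_identical(
    reduced$per_subject$n_test,
    full$per_subject$n_test[match(kept, full$per_subject$subject)])
})

test_that("fixed-TTD grid keeps only integer window counts", {
  cohort <- simulate_cohort(generator_params(n_subjects = 3, seed = 7))
  grid <- fixed_ttd_grid(cohort, ttd_target = 60,
                         t_lengths = c(48L), t_overlaps = c(16L, 20L),
                         spec = classifier_spec("knn", k = 10, seed = 0))
  # (48, 16): step 8 s -> w = (60 - 12)/8 + 1 = 7, kept
  kept <- grid[grid$t_overlap == 16L, ]
  expect_true(kept$kept)
  expect_identical(kept$w, 7)
  expect_false(is.na(kept$accuracy))
  # (48, 20): step 7 s -> w = 7.857..., excluded
  dropped <- grid[grid$t_overlap == 20L, ]
  expect_false(dropped$kept)
  expect_true(is.na(dropped$w))
  expect_true(is.na(dropped$accuracy))
  # t_overlap >= t_length cells never appear
  grid2 <- fixed_ttd_grid(cohort, 60, t_lengths = c(32L),
                          t_overlaps = c(32L, 40L))
  expect_identical(nrow(grid2), 0L)
})

test_that("the 54 s headline cell is kept at its target TTD", {
  cohort <- simulate_cohort(generator_params(n_subjects = 3, seed = 8))
  grid <- fixed_ttd_grid(cohort, ttd_target = 54, t_lengths = 48L,
                         t_overlaps = 20L)
  expect_true(grid$kept)
  expect_identical(grid$w, 7)
})

test_that("window sweep pairs scores with their TTD in order", {
  cohort <- simulate_cohort(generator_params(n_subjects = 3, seed = 9))
  sweep <- window_sweep(cohort, w_values = c(7L, 1L),
                        spec = classifier_spec("knn", k = 10, seed = 0))
  expect_identical(sweep$w, c(1L, 7L))           # sorted by TTD
  expect_equal(sweep$ttd_seconds, c(12, 54))
  expect_true(all(!is.na(sweep$accuracy)))
})
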