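test_that("metric formulas match direct arithmetic", {
  m <- classification_metrics(list(tp = 8, fn = 2, tn = 10, fp = 0))
  expect_equal(m$tpr, 80)
  expect_equal(m$tnr, 100)
  expect_equal(m$accuracy, 90)

  perfect <- classification_metrics(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_equal(unlist(perfect[c("tpr", "tnr", "accuracy")]),
               c(tpr = 100, tnr = 100, accuracy = 100))

  wrong <- classification_metrics(list(tp = 0, fn = 5, tn = 0, fp = 5))
  expect_equal(unlist(wrong[c("tpr", "tnr", "accuracy")]),
               c(tpr = 0, tnr = 0, accuracy = 0))
})

test_that("undefined metrics are flagged instead of propagating NaN", {
  m <- classification_metrics(list(tp = 0, fn = 0, tn = 4, fp = 1))
  expect_true(is.na(m$tpr))
  expect_identical(m$undefined, "tpr")
  expect_equal(m$tnr, 80)
  expect_error(classification_metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)),
               "empty")
})

test_that("confusion counts treat drowsy as the positive class and ignore order", {
  truth <- c("drowsy", "drowsy", "alert", "alert", "alert")
  pred <- c("drowsy", "alert", "alert", "drowsy", "alert")
  cc <- confusion_counts(truth, pred)
  expect_identical(cc, list(tp = 1L, fn = 1L, tn = 2L, fp = 1L))
  perm <- c(4, 2, 5, 1, 3)
  expect_identical(confusion_counts(truth[perm], pred[perm]), cc)
})

test_that("accuracy equals (TPR+TNR)/2 whenever class counts are equal", {
  set.seed(99)
  for (i in 1:100) {
    n_pos <- sample(1:30, 1)
    tp <- sample(0:n_pos, 1)
    tn <- sample(0:n_pos, 1)
    m <- classification_metrics(list(tp = tp, fn = n_pos - tp,
                                     tn = tn, fp = n_pos - tn))
    expect_equal(m$accuracy, (m$tpr + m$tnr) / 2)
  }
})

test_that("k-fold partitions every row exactly once into balanced strata", {
  rows <- toy_separable_rows(50)   # 100 rows, 50/50
  rep_ <- kfold(rows, k = 10, seed = 1, hidden_sizes = 5L)
  expect_identical(sum(rep_$per_fold$tp + rep_$per_fold$fn +
                         rep_$per_fold$tn + rep_$per_fold$fp), 100L)
  sizes <- rep_$per_fold$tp + rep_$per_fold$fn + rep_$per_fold$tn + rep_$per_fold$fp
  expect_true(all(sizes == 10))
  # stratification: 5 of each class per fold
  expect_true(all(rep_$per_fold$tp + rep_$per_fold$fn == 5))
  # pooled counts conservation
  expect_identical(rep_$pooled$tp + rep_$pooled$fn + rep_$pooled$tn +
                     rep_$pooled$fp, 100L)
})

test_that("k-fold is deterministic under a fixed seed and errors when k > rows", {
  rows <- toy_separable_rows(10)
  r1 <- kfold(rows, k = 5, seed = 8, hidden_sizes = 5L)
  r2 <- kfold(rows, k = 5, seed = 8, hidden_sizes = 5L)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$predictions, r2$predictions)
  expect_error(kfold(rows[1:4, ], k = 10, hidden_sizes = 5L), "smaller k")
})

test_that("cohort summary takes unweighted means of per-subject metrics", {
  df <- data.frame(subject_id = c("a", "b"), tpr = c(100, 80),
                   tnr = c(90, 100), accuracy = c(80, 100))
  s <- cohort_summary(df)
  expect_equal(s$mean_tpr, 90)
  expect_equal(s$mean_tnr, 95)
  expect_equal(s$mean_accuracy, 90)

  one <- cohort_summary(df[1, ])
  expect_equal(one$mean_accuracy, 80)
  expect_error(cohort_summary(list()), "at least one")
})

test_that("evaluation reports serialize with per-fold plus pooled rows", {
  rows <- toy_separable_rows(10)
  rep_ <- kfold(rows, k = 5, seed = 1, hidden_sizes = 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep_, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 6L)
  expect_identical(back$fold[6], "pooled")
  expect_equal(back$accuracy[6], rep_$pooled_metrics$accuracy)
})
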