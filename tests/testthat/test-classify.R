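test_that("separable toy data trains perfectly and ties pick the smallest network", {
  rows <- toy_separable_rows(20)
  model <- train_drowsiness_mlp(rows, seed = 7)
  expect_identical(model$hidden_size, 5L)          # all sizes tie at 100%
  expect_true(all(model$sweep$cv_accuracy == 1))
  pred <- predict_drowsiness(model, rows)
  expect_identical(pred$label, rows$label)
  expect_true(all(abs(pred$score) < 1))
})

test_that("training and prediction are deterministic under a fixed seed", {
  rows <- toy_separable_rows(10)
  m1 <- train_drowsiness_mlp(rows, seed = 42)
  m2 <- train_drowsiness_mlp(rows, seed = 42)
  expect_identical(m1$hidden_size, m2$hidden_size)
  grid <- toy_separable_rows(7)
  expect_identical(predict_drowsiness(m1, grid)$score,
                   predict_drowsiness(m2, grid)$score)
})

test_that("prediction is a pointwise map: permuting rows permutes outputs", {
  rows <- toy_separable_rows(10)
  rows[c(3, 17), c("p_iaf", "ratio_r")] <- c(0.2, -0.4, 0.7, 0.1)
  model <- train_drowsiness_mlp(rows, seed = 1)
  perm <- sample(nrow(rows))
  p_all <- predict_drowsiness(model, rows)
  p_perm <- predict_drowsiness(model, rows[perm, , drop = FALSE])
  expect_equal(p_perm$score, p_all$score[perm])
  expect_identical(p_perm$label, p_all$label[perm])
})

test_that("a row at the scaled origin gets a defined label without error", {
  rows <- toy_separable_rows(10)
  model <- train_drowsiness_mlp(rows, seed = 3)
  center_row <- rows[1, ]
  center_row[c("p_iaf", "p_tf", "p_3hz", "p_4hz", "ratio_r")] <-
    as.list(colMeans(rows[c("p_iaf", "p_tf", "p_3hz", "p_4hz", "ratio_r")]))
  pred <- predict_drowsiness(model, center_row)
  expect_true(pred$label %in% c("alert", "drowsy"))
  # a score exactly at the threshold resolves to alert
  model0 <- model
  model0$decision_threshold <- pred$score
  expect_identical(predict_drowsiness(model0, center_row)$label, "alert")
})

test_that("degenerate training inputs are rejected", {
  rows <- toy_separable_rows(5)
  one_class <- rows[rows$label == "alert", ]
  expect_error(train_drowsiness_mlp(one_class, seed = 1), "one-class")
  bad <- rows; bad$p_iaf[1] <- NaN
  expect_error(train_drowsiness_mlp(bad, seed = 1), "non-finite")
  model <- train_drowsiness_mlp(rows, seed = 1)
  expect_error(predict_drowsiness(model, rows[, -4]), "lack column")
})

test_that("models survive a save/load round trip and refuse foreign files", {
  rows <- toy_separable_rows(8)
  model <- train_drowsiness_mlp(rows, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$hidden_size, model$hidden_size)
  expect_identical(predict_drowsiness(back, rows)$score,
                   predict_drowsiness(model, rows)$score)

  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_model(junk), "not a drowseeg model")
})

test_that("the selected model beats the constant-prediction baseline on real features", {
  spec <- subject_spec("cv", iaf_true = 10, alpha_amp_wake = 1,
                       alpha_atten_s1 = 0.3, slow_amp_wake = 0.3,
                       slow_amp_s1 = 0.9, noise_amp = 1,
                       n_wake_epochs = 12, n_s1_epochs = 12)
  feats <- subject_features(spec, seed = 6)$features
  model <- train_drowsiness_mlp(feats, seed = 6)
  baseline <- max(table(feats$label)) / nrow(feats)
  expect_gte(max(model$sweep$cv_accuracy), baseline)
})
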