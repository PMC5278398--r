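test_that("LOSO splits partition the windows by subject", {
  feats <- gaussian_feature_table(30, classes = c("LC", "RC"), n_subjects = 10)
  splits <- make_loso_splits(feats)
  expect_length(splits, 10)
  test_rows <- sort(unlist(lapply(splits, `[[`, "test")))
  expect_identical(test_rows, seq_len(nrow(feats))) # union = all, no dupes
  for (fold in splits) {
    expect_length(intersect(fold$train, fold$test), 0)
    expect_false(fold$subject %in% feats$subject_id[fold$train])
  }
  two <- gaussian_feature_table(4, n_subjects = 2)
  expect_length(make_loso_splits(two), 2)
  one <- two[two$subject_id == "S01", ]
  expect_error(make_loso_splits(one), "2 subjects")
})

test_that("well-separated classes are fit perfectly on the training set", {
  feats <- gaussian_feature_table(20, sep = 8, seed = 2)
  sc <- fit_scaler(feats)
  scaled <- apply_scaler(sc, feats)
  model <- train_svm(scaled, C = 16, gamma = 1 / 84)
  expect_equal(mean(predict_svm(model, scaled) == scaled$label), 1.0)
})

test_that("a vanishing kernel width collapses to majority-class predictions", {
  feats <- gaussian_feature_table(30, sep = 8, seed = 3)
  feats <- feats[c(1:30, 31:40), ] # 30 LC vs 10 RC
  scaled <- apply_scaler(fit_scaler(feats), feats)
  model <- train_svm(scaled, C = 1, gamma = 1e-12)
  pred <- predict_svm(model, scaled)
  expect_gte(mean(pred == "LC"), 0.95)
})

test_that("training-row order does not change predictions", {
  feats <- gaussian_feature_table(25, sep = 4, seed = 4)
  scaled <- apply_scaler(fit_scaler(feats), feats)
  m1 <- train_svm(scaled, C = 4, gamma = 0.01)
  set.seed(9)
  perm <- sample(nrow(scaled))
  m2 <- train_svm(scaled[perm, ], C = 4, gamma = 0.01)
  probe <- gaussian_feature_table(10, sep = 4, seed = 5)
  expect_identical(predict_svm(m1, probe), predict_svm(m2, probe))
})

test_that("training rejects degenerate inputs", {
  feats <- gaussian_feature_table(10, classes = "LC")
  expect_error(train_svm(feats, C = 1, gamma = 0.1), "2 classes")
  bad <- gaussian_feature_table(10)
  bad[1, 1] <- NA
  expect_error(train_svm(bad, C = 1, gamma = 0.1), "finite")
  expect_error(train_svm(gaussian_feature_table(10), C = -1, gamma = 0.1))
})

test_that("grid search picks the best pair and breaks ties simply", {
  feats <- gaussian_feature_table(12, sep = 8, n_subjects = 3, seed = 6)
  single <- grid_search(feats, coarse_C = 2, coarse_gamma = 0.01,
                        two_step = FALSE)
  expect_equal(single$best$C, 2)
  expect_equal(single$best$gamma, 0.01)
  expect_equal(single$best_accuracy, max(single$grid$accuracy))

  # both pairs classify perfectly; the smaller C must win
  res <- grid_search(feats, coarse_C = c(1, 16), coarse_gamma = 0.01,
                     two_step = FALSE)
  expect_equal(res$grid$accuracy[1], res$grid$accuracy[2])
  expect_equal(res$best$C, 1)
  expect_error(grid_search(feats, coarse_C = numeric(0)), "empty grid")
})

test_that("the fine pass searches around the coarse optimum", {
  feats <- gaussian_feature_table(12, sep = 8, n_subjects = 3, seed = 7)
  res <- grid_search(feats, coarse_C = c(1, 4), coarse_gamma = c(0.01, 0.04),
                     fine_octaves = 0.5, fine_step = 0.5)
  fine <- res$grid[res$grid$stage == "fine", ]
  coarse_best <- res$grid[res$grid$stage == "coarse", ]
  coarse_best <- coarse_best[order(-coarse_best$accuracy,
                                   coarse_best$C, coarse_best$gamma)[1], ]
  expect_true(all(fine$C >= coarse_best$C / 2 & fine$C <= coarse_best$C * 2))
  expect_gte(res$best_accuracy, coarse_best$accuracy)
})

test_that("LOSO accuracy is reproducible and leakage-free", {
  cohort <- generate_cohort(3, 5, seed = 40, confusability = 0.3)
  windows <- unlist(lapply(cohort, segment), recursive = FALSE)
  feats <- features_table(windows)
  r1 <- loso_evaluate(feats, C = 16, gamma = 2^-7)
  r2 <- loso_evaluate(feats, C = 16, gamma = 2^-7)
  expect_identical(r1, r2)
  expect_identical(sort(unique(r1$predictions$subject_id)),
                   sort(unique(feats$subject_id)))
  expect_equal(nrow(r1$predictions), nrow(feats))
})

test_that("training accuracy is optimistic relative to held-out accuracy", {
  train_acc <- test_acc <- numeric(10)
  for (s in 1:10) {
    cohort <- generate_cohort(3, 4, seed = 100 + s, confusability = 0.7)
    windows <- unlist(lapply(cohort, segment), recursive = FALSE)
    feats <- features_table(windows)
    scaled <- apply_scaler(fit_scaler(feats), feats)
    model <- train_svm(scaled, C = 16, gamma = 2^-7)
    train_acc[s] <- mean(predict_svm(model, scaled) == scaled$label)
    test_acc[s] <- loso_evaluate(feats, C = 16, gamma = 2^-7)$accuracy
  }
  expect_gte(mean(train_acc), mean(test_acc))
})
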