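test_that("the forest separates an easy planted signal and is seed-deterministic", {
  train <- toy_separable(n = 20)
  test <- toy_separable(n = 30, seed = 123)
  fit <- mld_train(train, n_trees = 25, mtry = 3, seed = 1)

  expect_s3_class(fit, "mld_forest")
  expect_equal(fit$config$n_trees, 25L)
  expect_equal(mean(predict(fit, train)$.pred_label == train$label), 1)

  fit2 <- mld_train(train, n_trees = 25, mtry = 3, seed = 1)
  expect_identical(predict(fit, test), predict(fit2, test))

  fit3 <- mld_train(train, n_trees = 25, mtry = 3, seed = 2)
  expect_false(identical(predict(fit, test)$.pred_score,
                         predict(fit3, test)$.pred_score))
})

test_that("training rejects single-class labels and oversized mtry", {
  train <- toy_separable(n = 20)
  onecls <- dplyr::mutate(train, label = 1L)
  expect_error(mld_train(onecls, n_trees = 5, mtry = 2, seed = 1),
               "both classes", class = "mldppi_error_validation")
  expect_error(mld_train(train, n_trees = 5, mtry = 99, seed = 1),
               "mtry", class = "mldppi_error_config")
})

test_that("prediction scores are tree-vote fractions", {
  train <- toy_separable(n = 24)
  test <- toy_separable(n = 40, seed = 5)

  one <- mld_train(train, n_trees = 1, mtry = 3, seed = 1)
  expect_true(all(predict(one, test)$.pred_score %in% c(0, 1)))

  fit <- mld_train(train, n_trees = 15, mtry = 3, seed = 1)
  p <- predict(fit, test)
  expect_true(all(p$.pred_score >= 0 & p$.pred_score <= 1))
  expect_equal(p$.pred_label, as.integer(p$.pred_score >= 0.5))

  expect_error(predict(fit, test[, 1:4]), class = "mldppi_error_config")
})

test_that("glance and tidy expose OOB accuracy and Gini importances", {
  fit <- mld_train(toy_separable(n = 30), n_trees = 20, mtry = 3, seed = 1)
  g <- glance(fit)
  expect_equal(g$n_trees, 20L)
  expect_true(g$oob_accuracy > 0.8 && g$oob_accuracy <= 1)

  td <- tidy(fit)
  # the two signal features dominate the importance ranking
  expect_setequal(td$feature[1:2], c("f1", "f2"))
})

test_that("the from-scratch Gini tree honours the tree-growing contract", {
  train <- toy_separable(n = 20)
  ref <- gini_tree(train)
  # unpruned: grown to purity, so training error is zero
  expect_equal(predict(ref, train), train$label)

  test <- toy_separable(n = 40, seed = 77)
  expect_equal(predict(ref, test), test$label)  # separable held-out set

  # agrees with the compiled unpruned CART on the same easy data
  rp <- mldppi:::fit_single_tree(train)
  expect_equal(predict(ref, test), mldppi:::predict_single_tree(rp, test)$.pred_label)

  # pure node input: a single leaf predicting the class
  pure <- dplyr::mutate(train, label = 1L)
  expect_true(all(predict(gini_tree(pure), test) == 1L))
})

test_that("bootstrap resamples leave about 36.8% out of bag", {
  set.seed(42)
  fractions <- replicate(200, length(unique(mldppi:::bootstrap_indices(500))) / 500)
  expect_equal(mean(fractions), 1 - exp(-1), tolerance = 0.01)
})

test_that("cross-validation stratifies folds and is reproducible", {
  # 4 pairs, k = 2: every fold must hold one positive and one negative
  tiny <- toy_separable(n = 4)
  cv <- mld_cross_validate(tiny, k = 2, n_trees = 5, mtry = 2, seed = 1)
  expect_equal(nrow(cv$folds), 2L)
  expect_equal(cv$folds$tp + cv$folds$fn, c(1L, 1L))
  expect_equal(cv$folds$tn + cv$folds$fp, c(1L, 1L))

  data <- toy_separable(n = 40)
  cv1 <- mld_cross_validate(data, k = 5, n_trees = 10, mtry = 3, seed = 9)
  cv2 <- mld_cross_validate(data, k = 5, n_trees = 10, mtry = 3, seed = 9)
  expect_identical(cv1$folds, cv2$folds)

  expect_equal(sum(cv1$folds$tp + cv1$folds$fp + cv1$folds$tn + cv1$folds$fn), 40L)
  expect_equal(cv1$summary$metric,
               c("acc", "sn", "spec", "ppv", "npv", "f_score", "mcc"))

  expect_error(mld_cross_validate(tiny, k = 3, n_trees = 5, mtry = 2, seed = 1),
               class = "mldppi_error_config")
  expect_error(mld_cross_validate(tiny, k = 1, n_trees = 5, mtry = 2, seed = 1),
               class = "mldppi_error_config")
})

test_that("cv_report formats metrics as two-decimal percentages", {
  cv <- mld_cross_validate(toy_separable(n = 20), k = 2, n_trees = 5, mtry = 2, seed = 1)
  rep <- cv_report(cv)
  expect_true(all(grepl("^\\d+\\.\\d{2}$", rep$acc)))
  expect_equal(as.numeric(rep$acc), round(100 * cv$folds$acc, 2))
})

test_that("a degenerate sweep equals a single cross-validation", {
  data <- toy_separable(n = 30)
  sw <- mld_sweep(data, m_values = 3, n_values = 10, k = 3, seed = 4)
  cv <- mld_cross_validate(data, k = 3, n_trees = 10, mtry = 3, seed = 4)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$acc, cv$summary$mean[cv$summary$metric == "acc"])
  expect_equal(sw$mcc_sd, cv$summary$sd[cv$summary$metric == "mcc"])

  sw2 <- mld_sweep(data, m_values = c(2, 4), n_values = c(5, 10), k = 3, seed = 4)
  expect_equal(nrow(sw2), 4L)
})

test_that("OOB accuracy tracks held-out accuracy across seeded runs", {
  # runs span easy to impossible problems (signal strength 0/1/2), so both
  # estimates have real between-run variance to correlate over
  oob <- heldout <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_ppi_data(n_positive = 30, n_negative = 30,
                             motif_insertions_per_positive = s %% 3, seed = 100 + s)
    feats <- pair_features(sim$pairs, mld_featurize(sim$proteins))
    set.seed(s)
    idx <- c(sample(which(feats$label == 1), 20), sample(which(feats$label == 0), 20))
    fit <- mld_train(feats[idx, ], n_trees = 30, mtry = 10, seed = s)
    oob[s] <- fit$oob_accuracy
    pred <- predict(fit, feats[-idx, ])
    heldout[s] <- mean(pred$.pred_label == feats$label[-idx])
  }
  rho <- suppressWarnings(stats::cor(oob, heldout, method = "spearman"))
  expect_gt(rho, 0)
})

test_that("autoplot methods return ggplot objects", {
  cv <- mld_cross_validate(toy_separable(n = 20), k = 2, n_trees = 5, mtry = 2, seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
  sw <- mld_sweep(toy_separable(n = 20), m_values = c(2, 3), n_values = 5, k = 2, seed = 1)
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(plot_region_masks(4), "ggplot")
  expect_equal(tidy(cv), cv$folds)
  expect_equal(glance(cv)$k, 2L)
})
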