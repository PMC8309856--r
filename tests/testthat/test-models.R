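cohort_11 <- generate_cohort(cohort_spec(seed = 11))

test_that("the 70/30 split is stratified, disjoint and exhaustive", {
  sp <- split_dataset(cohort_11, seed = 1)
  expect_equal(nrow(sp$train), 56)
  expect_equal(nrow(sp$test), 24)
  expect_equal(as.vector(table(sp$train$label)), c(28, 28))
  expect_equal(as.vector(table(sp$test$label)), c(12, 12))
  key <- function(d) paste(d$driver_id, d$label)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(cohort_11))

  expect_identical(split_dataset(cohort_11, seed = 5),
                   split_dataset(cohort_11, seed = 5))
  expect_error(split_dataset(cohort_11, train_fraction = 1.2),
               class = "respirad_config_error")
  expect_error(split_dataset(cohort_11[1:4, ]),
               class = "respirad_invalid_input_error")
})

test_that("the threshold rule labels low respiration as drowsy, ties as not", {
  expect_equal(as.character(predict_threshold(c(12, 20, 18.5))),
               c("drowsy", "non-drowsy", "non-drowsy"))
  expect_error(predict_threshold(NA_real_),
               class = "respirad_invalid_input_error")
})

test_that("accuracy follows the confusion-count formula", {
  # forced counts: 3 drowsy right, 4 non-drowsy right, 2 false drowsy, 1 missed
  truth <- c(rep("drowsy", 4), rep("non-drowsy", 6))
  pred <- c(rep("drowsy", 3), "non-drowsy",
            rep("drowsy", 2), rep("non-drowsy", 4))
  ev <- respirad:::eval_predictions(pred, truth)
  expect_equal(c(ev$tp, ev$tn, ev$fp, ev$fn), c(3, 4, 2, 1))
  expect_equal(ev$accuracy, 70)

  perfect <- respirad:::eval_predictions(
    rep(c("drowsy", "non-drowsy"), each = 12),
    rep(c("drowsy", "non-drowsy"), each = 12))
  expect_equal(perfect$accuracy, 100)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
})

test_that("a constant all-drowsy predictor scores chance on balanced data", {
  truth <- rep(c("drowsy", "non-drowsy"), 10)
  ev <- respirad:::eval_predictions(rep("drowsy", 20), truth)
  expect_equal(ev$accuracy, 50)
  expect_equal(ev$per_class$recall[ev$per_class$class == "drowsy"], 1)
  expect_equal(ev$per_class$precision[ev$per_class$class == "drowsy"], 0.5)
})

test_that("every backend fits, predicts labels, and is seed-reproducible", {
  sp <- split_dataset(cohort_11, seed = 2)
  for (id in c("SVM", "DT", "ETC", "GBM", "LR", "MLP", "THRESHOLD")) {
    fit <- tune_and_train(sp$train, model_spec(id), seed = 2,
                          grid = list(model_spec(id)))
    pred <- predict(fit, sp$test)
    expect_s3_class(pred, "factor")
    expect_equal(levels(pred), c("non-drowsy", "drowsy"))
    expect_length(pred, 24)
    fit2 <- tune_and_train(sp$train, model_spec(id), seed = 2,
                           grid = list(model_spec(id)))
    expect_identical(pred, predict(fit2, sp$test))
  }
})

test_that("a separable cohort is solved perfectly by SVM and the threshold", {
  sep <- generate_cohort(cohort_spec(noise_sd = 0, seed = 6))
  sp <- split_dataset(sep, seed = 6)
  for (id in c("SVM", "THRESHOLD")) {
    fit <- tune_and_train(sp$train, model_spec(id), seed = 6,
                          grid = list(model_spec(id)))
    expect_equal(evaluate_model(fit, sp$train)$accuracy, 100)
    expect_equal(evaluate_model(fit, sp$test)$accuracy, 100)
  }
})

test_that("cross-validated tuning selects from the declared grid", {
  sp <- split_dataset(cohort_11, seed = 3)
  fit <- tune_and_train(sp$train, model_spec("SVM"), n_folds = 15, seed = 3)
  expect_equal(nrow(fit$cv), 3) # default grid: cost 1 (published), 0.1, 10
  expect_true(all(fit$cv$cv_accuracy >= 0 & fit$cv$cv_accuracy <= 1))
  expect_error(tune_and_train(sp$train, model_spec("SVM"), n_folds = 40,
                              seed = 3),
               class = "respirad_fold_error")
})

test_that("the benchmark reports every model on one shared split", {
  bench <- run_benchmark(cohort_11, seed = 9, tune = FALSE)
  expect_s3_class(bench, "drowsy_benchmark")
  expect_setequal(bench$model,
                  c("SVM", "DT", "ETC", "GBM", "LR", "MLP", "THRESHOLD"))
  expect_true(all(c("accuracy", "precision", "recall", "f1") %in% names(bench)))
  expect_true(all(bench$accuracy >= 0 & bench$accuracy <= 100))
  expect_true(all(bench$tp + bench$tn + bench$fp + bench$fn == 24))
  again <- run_benchmark(cohort_11, seed = 9, tune = FALSE)
  expect_equal(bench$accuracy, again$accuracy)
  g <- glance(bench)
  expect_equal(g$n_train, 56)
  expect_equal(g$n_test, 24)
})

test_that("noisier cohorts never help the threshold rule", {
  # Monte-Carlo estimate of the fixed-threshold accuracy as noise grows
  acc_at <- function(noise_sd) {
    big <- generate_cohort(cohort_spec(n_drivers = 4000, noise_sd = noise_sd,
                                       seed = 31))
    mean(predict_threshold(big$rpm) == big$label)
  }
  accs <- vapply(c(0, 1, 2, 4), acc_at, numeric(1))
  expect_true(all(diff(accs) < 0.02)) # non-increasing up to sampling error
  expect_equal(accs[1], 1)
})
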