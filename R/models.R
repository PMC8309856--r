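LABELS <- c("non-drowsy", "drowsy")

as_label <- function(x) factor(as.character(x), levels = LABELS)

check_cohort_frame <- function(data, arg = "data") {
  if (!is.data.frame(data) || !all(c("rpm", "age", "label") %in% names(data))) {
    abort_respirad(
      sprintf("`%s` must be a data frame with columns rpm, age, label.", arg),
      "respirad_invalid_input_error")
  }
  data$label <- as_label(data$label)
  if (anyNA(data$label)) {
    abort_respirad("`label` must be 'drowsy' or 'non-drowsy'.",
                   "respirad_invalid_input_error")
  }
  data
}

#' Classifier specification
#'
#' A model identifier plus its hyperparameters. The defaults for each model
#' are the published protocol's settings: SVM (linear kernel, C = 1, gamma
#' "scale", degree 3), DT (gini, best splitter, unlimited depth, min split 2,
#' min leaf 1), ETC (100 trees, entropy criterion), GBM (100 estimators,
#' max depth 5), LR (L2 penalty, liblinear-style solver, 100 iterations),
#' MLP (2 hidden layers of 100 neurons, relu, adam, 700 epochs) and a fixed
#' respiration-rate threshold rule at 18.5 breaths/min. Hyperparameters are
#' recorded verbatim in the spec; where the R backend cannot realize a
#' setting exactly (see the methods vignette) the closest faithful mapping is
#' used.
#'
#' @param model_id One of `"SVM"`, `"DT"`, `"ETC"`, `"GBM"`, `"LR"`, `"MLP"`,
#'   `"THRESHOLD"`.
#' @param ... Named hyperparameter overrides merged over the defaults.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("SVM")$params$cost
#' @export
model_spec <- function(model_id, ...) {
  model_id <- match.arg(toupper(model_id),
                        c("SVM", "DT", "ETC", "GBM", "LR", "MLP", "THRESHOLD"))
  defaults <- switch(model_id,
    SVM = list(kernel = "linear", cost = 1.0, gamma = "scale", degree = 3),
    DT = list(criterion = "gini", splitter = "best", max_depth = Inf,
              min_samples_split = 2, min_samples_leaf = 1, cp = 0),
    ETC = list(n_estimators = 100, criterion = "entropy",
               min_samples_split = 2, max_features = "auto"),
    GBM = list(loss = "deviance", n_estimators = 100,
               criterion = "friedman_mse", min_samples_split = 2,
               min_samples_leaf = 1, max_depth = 5, learning_rate = 0.1),
    LR = list(penalty = "l2", solver = "liblinear", max_iter = 100,
              lambda = "auto"),
    MLP = list(hidden_layers = 2, neurons = 100, epochs = 700,
               activation = "relu", solver = "adam", decay = 0),
    THRESHOLD = list(cut = 18.5))
  params <- utils::modifyList(defaults, list(...))
  structure(list(model_id = model_id, params = params), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %s\n", x$model_id,
              paste(names(x$params), vapply(x$params, function(p)
                paste(format(p), collapse = "/"), character(1)),
                sep = "=", collapse = ", ")))
  invisible(x)
}

#' The full published model suite
#'
#' @return Named list of [model_spec()]s: SVM, DT, ETC, GBM, LR, MLP,
#'   THRESHOLD, each at its default hyperparameters.
#' @export
default_model_set <- function() {
  ids <- c("SVM", "DT", "ETC", "GBM", "LR", "MLP", "THRESHOLD")
  stats::setNames(lapply(ids, model_spec), ids)
}

# small declared tuning grid per model; element 1 is always the default spec
default_tuning_grid <- function(spec) {
  alt <- switch(spec$model_id,
    SVM = list(list(cost = 0.1), list(cost = 10)),
    DT = list(list(cp = 0.01)),
    ETC = list(list(n_estimators = 200)),
    GBM = list(list(max_depth = 3)),
    LR = list(list(lambda = 0.01)),
    MLP = list(list(decay = 1e-4)),
    THRESHOLD = list())
  c(list(spec),
    lapply(alt, function(p) do.call(model_spec, c(list(spec$model_id), p))))
}

#' Stratified train/test split
#'
#' Splits a cohort into disjoint, exhaustive train and test sets, stratified
#' by label, with sizes within one record of the exact fractions.
#'
#' @param data Cohort data frame (`rpm`, `age`, `label`).
#' @param train_fraction Fraction of each class assigned to training.
#'   Default 0.70.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @examples
#' sp <- split_dataset(generate_cohort(cohort_spec(seed = 1)), seed = 1)
#' nrow(sp$train); nrow(sp$test) # 56 and 24
#' @export
split_dataset <- function(data, train_fraction = 0.70, seed = 1L) {
  data <- check_cohort_frame(data)
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort_respirad("`train_fraction` must lie strictly inside (0, 1).",
                   "respirad_config_error")
  }
  if (nrow(data) < 10) {
    abort_respirad("need at least 10 records to split.",
                   "respirad_invalid_input_error")
  }
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), data$label), function(i) {
      sample(i, round(train_fraction * length(i)))
    }), use.names = FALSE)
  })
  list(train = tibble::as_tibble(data[sort(idx), , drop = FALSE]),
       test = tibble::as_tibble(data[-idx, , drop = FALSE]))
}

# stratified fold assignment; errors if a class cannot cover every fold
stratified_folds <- function(labels, n_folds, seed) {
  tab <- table(labels)
  if (any(tab < n_folds)) {
    abort_respirad(
      sprintf("n_folds = %d exceeds the smaller class size (%d): every fold needs both classes.",
              n_folds, min(tab)),
      "respirad_fold_error")
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in levels(labels)) {
      i <- which(labels == lv)
      fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
  })
  fold
}

fit_backend <- function(spec, data, seed = 1L) {
  p <- spec$params
  x <- as.matrix(data[, c("rpm", "age")])
  y <- data$label
  fit <- switch(spec$model_id,
    SVM = e1071::svm(x, y, kernel = p$kernel, cost = p$cost,
                     degree = p$degree, scale = FALSE),
    DT = withr::with_seed(seed,
      rpart::rpart(label ~ rpm + age, data = data, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     minsplit = p$min_samples_split,
                     minbucket = p$min_samples_leaf,
                     cp = p$cp, xval = 0,
                     maxdepth = min(p$max_depth, 30)))),
    ETC = ranger::ranger(label ~ rpm + age, data = data,
                         num.trees = p$n_estimators,
                         splitrule = "extratrees",
                         replace = FALSE, sample.fraction = 1,
                         num.threads = 1, seed = seed),
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == "drowsy"),
                                     nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = p$max_depth, eta = p$learning_rate,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = p$n_estimators, verbose = 0)
    },
    LR = {
      lam <- if (identical(p$lambda, "auto")) 1 / nrow(data) else p$lambda
      glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lam)
    },
    MLP = withr::with_seed(seed,
      nnet::nnet(label ~ rpm + age, data = data, size = p$neurons,
                 maxit = p$epochs, decay = p$decay, trace = FALSE,
                 MaxNWts = 10000)),
    THRESHOLD = list(cut = p$cut))
  structure(list(spec = spec, fit = fit, seed = seed,
                 n_train = nrow(data)),
            class = "drowsy_model")
}

#' Predict drowsiness labels from a fitted model
#'
#' @param object A `drowsy_model` from [tune_and_train()].
#' @param newdata Data frame with columns `rpm` and `age`.
#' @param ... Unused.
#' @return Factor of predicted labels (levels `non-drowsy`, `drowsy`).
#' @export
predict.drowsy_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, c("rpm", "age")])
  p <- switch(object$spec$model_id,
    SVM = as.character(stats::predict(object$fit, x)),
    DT = {
      cls <- stats::predict(object$fit, newdata, type = "class")
      as.character(cls)
    },
    ETC = as.character(stats::predict(object$fit, data = newdata)$predictions),
    GBM = ifelse(stats::predict(object$fit,
                                xgboost::xgb.DMatrix(x, nthread = 1)) >= 0.5,
                 "drowsy", "non-drowsy"),
    LR = {
      pr <- stats::predict(object$fit, newx = x, type = "response")
      # glmnet's binomial response is P(second factor level) = P(drowsy)
      ifelse(pr[, 1] >= 0.5, "drowsy", "non-drowsy")
    },
    MLP = {
      pr <- stats::predict(object$fit, newdata, type = "raw")
      ifelse(pr[, 1] >= 0.5, "drowsy", "non-drowsy")
    },
    THRESHOLD = as.character(predict_threshold(newdata$rpm,
                                               cut = object$fit$cut)))
  as_label(p)
}

#' Fixed respiration-rate threshold rule
#'
#' Labels a record drowsy iff its respiration rate lies strictly below the
#' cut (drowsiness lowers respiration rate); a rate exactly at the cut is
#' non-drowsy.
#'
#' @param rpm Numeric vector of respiration rates, breaths/min.
#' @param cut Threshold, breaths/min. Default 18.5.
#' @return Factor of labels (levels `non-drowsy`, `drowsy`).
#' @examples
#' predict_threshold(c(12, 20, 18.5))
#' @export
predict_threshold <- function(rpm, cut = 18.5) {
  if (any(!is.finite(rpm))) {
    abort_respirad("`rpm` must be finite.", "respirad_invalid_input_error")
  }
  as_label(ifelse(rpm < cut, "drowsy", "non-drowsy"))
}

#' Cross-validated tuning and final fit
#'
#' Selects the winning hyperparameter configuration from a small declared
#' grid (the published defaults are always element 1 and win ties) by
#' stratified k-fold cross-validated accuracy, then refits on the full
#' training set. The THRESHOLD rule has nothing to tune and is returned
#' directly.
#'
#' @param train Training cohort (`rpm`, `age`, `label`).
#' @param spec A [model_spec()].
#' @param n_folds Number of CV folds. Default 15.
#' @param seed Integer seed (folds and any stochastic fit).
#' @param grid Optional list of [model_spec()]s to search; defaults to
#'   [model_spec()]'s published values plus one alternative per model.
#' @return A `drowsy_model`: the final fit plus the CV table (`cv` tibble
#'   with per-configuration accuracy), usable with [predict()][predict.drowsy_model].
#' @export
tune_and_train <- function(train, spec, n_folds = 15, seed = 1L,
                           grid = default_tuning_grid(spec)) {
  train <- check_cohort_frame(train, "train")
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model_id == "THRESHOLD" || length(grid) <= 1) {
    fit <- fit_backend(spec, train, seed = seed)
    fit$cv <- NULL
    return(fit)
  }
  fold <- stratified_folds(train$label, n_folds, seed)
  cv_acc <- vapply(grid, function(g) {
    correct <- vapply(seq_len(n_folds), function(k) {
      fit_k <- fit_backend(g, train[fold != k, , drop = FALSE], seed = seed)
      sum(predict(fit_k, train[fold == k, , drop = FALSE]) ==
            train$label[fold == k])
    }, numeric(1))
    sum(correct) / nrow(train)
  }, numeric(1))
  best <- grid[[which.max(cv_acc)]] # which.max: earliest wins ties
  out <- fit_backend(best, train, seed = seed)
  out$cv <- tibble::tibble(
    configuration = vapply(grid, function(g)
      paste(names(g$params), vapply(g$params, function(p)
        paste(format(p), collapse = "/"), character(1)),
        sep = "=", collapse = ", "), character(1)),
    cv_accuracy = cv_acc)
  out
}

#' @export
print.drowsy_model <- function(x, ...) {
  cat(sprintf("<drowsy_model> %s fitted on %d records\n",
              x$spec$model_id, x$n_train))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV-selected over %d configurations (best %.1f%%)\n",
                nrow(x$cv), 100 * max(x$cv$cv_accuracy)))
  }
  invisible(x)
}
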