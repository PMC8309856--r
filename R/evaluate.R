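#' Evaluate a fitted model on a held-out test set
#'
#' Computes the confusion counts with drowsy as the positive class, accuracy
#' as `(TP + TN) / (TP + TN + FP + FN) * 100`, and precision, recall and F1
#' both per class and macro-averaged (the unweighted mean over the two
#' classes). An undefined per-class ratio (empty denominator) is counted as 0.
#'
#' @param model A `drowsy_model` from [tune_and_train()].
#' @param test Test cohort (`rpm`, `age`, `label`), nonempty.
#' @return A `drowsy_eval` list: `model_id`, `tp`, `tn`, `fp`, `fn`,
#'   `accuracy` (percent), `precision`, `recall`, `f1` (macro), and
#'   `per_class` (tibble with the per-class values).
#' @examples
#' sp <- split_dataset(generate_cohort(cohort_spec(seed = 2)), seed = 2)
#' fit <- tune_and_train(sp$train, model_spec("THRESHOLD"))
#' evaluate_model(fit, sp$test)$accuracy
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "drowsy_model"))
  test <- check_cohort_frame(test, "test")
  if (nrow(test) == 0) {
    abort_respirad("`test` must be nonempty.", "respirad_invalid_input_error")
  }
  eval_predictions(predict(model, test), test$label, model$spec$model_id)
}

# metrics from predicted and true labels (drowsy = positive class)
eval_predictions <- function(pred, truth, model_id = NA_character_) {
  pred <- as_label(pred)
  truth <- as_label(truth)
  tp <- sum(pred == "drowsy" & truth == "drowsy")
  tn <- sum(pred == "non-drowsy" & truth == "non-drowsy")
  fp <- sum(pred == "drowsy" & truth == "non-drowsy")
  fn <- sum(pred == "non-drowsy" & truth == "drowsy")
  ratio <- function(num, den) if (den == 0) 0 else num / den
  per_class <- tibble::tibble(
    class = LABELS,
    precision = c(ratio(tn, tn + fn), ratio(tp, tp + fp)),
    recall = c(ratio(tn, tn + fp), ratio(tp, tp + fn)))
  per_class$f1 <- ifelse(per_class$precision + per_class$recall == 0, 0,
                         2 * per_class$precision * per_class$recall /
                           (per_class$precision + per_class$recall))
  structure(
    list(model_id = model_id, tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = (tp + tn) / (tp + tn + fp + fn) * 100,
         precision = mean(per_class$precision),
         recall = mean(per_class$recall),
         f1 = mean(per_class$f1),
         per_class = per_class),
    class = "drowsy_eval")
}

#' @export
print.drowsy_eval <- function(x, ...) {
  cat(sprintf("<drowsy_eval> %s: accuracy %.1f%% (TP %d, TN %d, FP %d, FN %d)\n",
              x$model_id, x$accuracy, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  macro precision %.2f, recall %.2f, F1 %.2f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `drowsy_eval`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `accuracy`, `precision`, `recall`, `f1`,
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
tidy.drowsy_eval <- function(x, ...) {
  tibble::tibble(model = x$model_id, accuracy = x$accuracy,
                 precision = x$precision, recall = x$recall, f1 = x$f1,
                 tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn)
}

#' Run the full classification benchmark
#'
#' Applies the published protocol to a cohort: one stratified 70/30 split,
#' cross-validated tuning (optional) and a final fit for every model, and
#' evaluation of each on the identical test set.
#'
#' @param data Cohort data frame (`rpm`, `age`, `label`).
#' @param models Named list of [model_spec()]s. Default [default_model_set()].
#' @param seed Integer seed driving the split, folds and stochastic fits.
#' @param train_fraction Train fraction. Default 0.70.
#' @param n_folds CV folds for tuning. Default 15.
#' @param tune If `FALSE`, skip cross-validation and fit each model's
#'   default configuration directly. Default `TRUE`.
#' @return A `drowsy_benchmark` tibble, one row per model with the metric
#'   columns of [tidy.drowsy_eval()].
#' @examples
#' \donttest{
#' bench <- run_benchmark(generate_cohort(cohort_spec(seed = 3)), seed = 3)
#' bench[, c("model", "accuracy")]
#' }
#' @export
run_benchmark <- function(data, models = default_model_set(), seed = 1L,
                          train_fraction = 0.70, n_folds = 15, tune = TRUE) {
  data <- check_cohort_frame(data)
  sp <- split_dataset(data, train_fraction = train_fraction, seed = seed)
  rows <- purrr::map(models, function(m) {
    fit <- if (tune) {
      tune_and_train(sp$train, m, n_folds = n_folds, seed = seed)
    } else {
      tune_and_train(sp$train, m, n_folds = n_folds, seed = seed,
                     grid = list(m))
    }
    tidy(evaluate_model(fit, sp$test))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "n_train") <- nrow(sp$train)
  attr(out, "n_test") <- nrow(sp$test)
  class(out) <- c("drowsy_benchmark", class(tibble::tibble()))
  out
}

#' Summarize a benchmark run
#'
#' @param x A `drowsy_benchmark`.
#' @param ... Unused.
#' @return One-row tibble: best model, its accuracy, split sizes and seed.
#' @importFrom generics glance
#' @export
glance.drowsy_benchmark <- function(x, ...) {
  best <- x[which.max(x$accuracy), ]
  tibble::tibble(best_model = best$model, best_accuracy = best$accuracy,
                 n_models = nrow(x),
                 n_train = attr(x, "n_train"), n_test = attr(x, "n_test"),
                 seed = attr(x, "seed"))
}
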