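#' Validation table
#'
#' Long-form per-compound, per-run prediction records from a (repeated)
#' validation: one row per (compound, run) with the predicted value and
#' optional probability and applicability-domain flag. Aggregation operators
#' collapse the runs of each compound into a single prediction, error,
#' probability and AD-inside-ratio -- the quantities highlighted in visual
#' validation.
#'
#' @param compound_index Integer compound indices (1-based).
#' @param run_id Run identifiers (integer or character).
#' @param predicted Predicted values (numeric or class labels).
#' @param probability Optional per-prediction probability/confidence.
#' @param ad_inside Optional logical AD flags.
#' @return `data.frame` of class `validation_table`.
#' @export
validation_table <- function(compound_index, run_id, predicted,
                             probability = NULL, ad_inside = NULL) {
  n <- length(compound_index)
  out <- data.frame(compound_index = as.integer(compound_index),
                    run_id = run_id,
                    predicted = predicted,
                    stringsAsFactors = FALSE)
  if (!is.null(probability)) out$probability <- as.numeric(probability)
  if (!is.null(ad_inside)) out$ad_inside <- as.logical(ad_inside)
  if (anyNA(out$compound_index)) stop("missing compound indices", call. = FALSE)
  if (n == 0) stop("empty validation table", call. = FALSE)
  class(out) <- c("validation_table", "data.frame")
  out
}

split_runs <- function(table, what) {
  stopifnot(inherits(table, "validation_table"))
  split(table[[what]], table$compound_index)
}

agg_frame <- function(table, actual) {
  idx <- sort(unique(table$compound_index))
  if (length(actual) < max(idx)) stop("actual endpoint shorter than compound indices",
                                      call. = FALSE)
  idx
}

#' Aggregate numeric (regression) predictions
#'
#' Prediction = mean over runs; error = per-compound RMSE of the runs against
#' the actual value (a single run gives the absolute residual).
#'
#' @param table A [validation_table] with numeric predictions.
#' @param actual Numeric endpoint vector (full dataset order).
#' @return `data.frame` with `compound_index`, `prediction`, `error`, `n_runs`,
#'   plus `probability` / `ad_ratio` when present in the table.
#' @export
aggregate_numeric <- function(table, actual) {
  if (!is.numeric(table$predicted))
    stop("numeric aggregation requires numeric predictions", call. = FALSE)
  idx <- agg_frame(table, actual)
  runs <- split_runs(table, "predicted")
  out <- data.frame(
    compound_index = idx,
    prediction = vapply(runs, mean, numeric(1)),
    error = mapply(function(p, a) sqrt(mean((p - a)^2)),
                   runs, actual[idx]),
    n_runs = lengths(runs)
  )
  add_optional_aggregates(out, table)
}

#' Aggregate binary classification predictions
#'
#' Prediction = fraction of runs predicting the positive class (a continuous
#' 0-1 value); error = fraction of runs predicting the wrong class. The
#' `always_wrong` flag marks compounds misclassified in every single run.
#'
#' @param table A [validation_table] with class-label predictions.
#' @param actual Class labels (full dataset order).
#' @param positive The positive ("active") class label.
#' @return `data.frame` with `compound_index`, `prediction` (positive-class
#'   ratio), `error`, `always_wrong`, `n_runs`, plus optional aggregates.
#' @export
aggregate_binary <- function(table, actual, positive) {
  idx <- agg_frame(table, actual)
  labels <- unique(c(as.character(table$predicted), as.character(actual[idx])))
  if (length(labels) > 2)
    stop("more than two labels in binary aggregation: ",
         paste(labels, collapse = ", "), call. = FALSE)
  if (length(labels) == 2 && !positive %in% labels)
    stop("unseen positive label '", positive, "'", call. = FALSE)
  runs <- split_runs(table, "predicted")
  out <- data.frame(
    compound_index = idx,
    prediction = vapply(runs, function(r) mean(as.character(r) == positive), numeric(1)),
    error = mapply(function(r, a) mean(as.character(r) != as.character(a)),
                   runs, actual[idx]),
    n_runs = lengths(runs)
  )
  out$always_wrong <- out$error == 1
  add_optional_aggregates(out, table)
}

#' Aggregate multi-class predictions
#'
#' Prediction = strict-majority class over the runs, or `"inconclusive"` when
#' no class wins a strict majority; error = misprediction ratio.
#'
#' @param table A [validation_table] with class-label predictions.
#' @param actual Class labels (full dataset order).
#' @return `data.frame` with `compound_index`, `prediction`, `error`,
#'   `n_runs`, plus optional aggregates.
#' @export
aggregate_multiclass <- function(table, actual) {
  idx <- agg_frame(table, actual)
  runs <- split_runs(table, "predicted")
  out <- data.frame(
    compound_index = idx,
    prediction = vapply(runs, function(r) {
      tab <- table(as.character(r))
      top <- tab[tab == max(tab)]
      if (length(top) == 1 && top[1] > length(r) / 2) names(top) else "inconclusive"
    }, character(1)),
    error = mapply(function(r, a) mean(as.character(r) != as.character(a)),
                   runs, actual[idx]),
    n_runs = lengths(runs),
    stringsAsFactors = FALSE
  )
  add_optional_aggregates(out, table)
}

#' Aggregate applicability-domain flags
#'
#' @param table A [validation_table] whose `ad_inside` column is set.
#' @return `data.frame` with `compound_index` and `ad_ratio` (fraction of runs
#'   with the compound inside the AD).
#' @export
aggregate_ad <- function(table) {
  if (is.null(table$ad_inside)) stop("no AD flags in validation table", call. = FALSE)
  runs <- split_runs(table, "ad_inside")
  data.frame(compound_index = sort(unique(table$compound_index)),
             ad_ratio = vapply(runs, mean, numeric(1)))
}

add_optional_aggregates <- function(out, table) {
  if (!is.null(table$probability))
    out$probability <- vapply(split_runs(table, "probability"), mean, numeric(1))
  if (!is.null(table$ad_inside))
    out$ad_ratio <- vapply(split_runs(table, "ad_inside"), mean, numeric(1))
  rownames(out) <- NULL
  out
}

#' Per-compound prediction-error difference of two models
#'
#' `difference = error_a - error_b`: positive entries mark compounds predicted
#' worse by model A -- a highlightable feature for comparing two modelling
#' approaches compound by compound.
#'
#' @param errors_a,errors_b Per-compound error vectors in the same compound
#'   order.
#' @return Numeric difference vector.
#' @export
error_difference <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("error vectors differ in length", call. = FALSE)
  as.numeric(errors_a) - as.numeric(errors_b)
}

#' Ordinary-least-squares learner adapter
#'
#' The built-in learner for cross-validation drivers: fits a linear model with
#' intercept by QR decomposition. External learners plug in as lists with the
#' same `fit(x, y)` / `predict(model, x)` interface.
#'
#' @return A learner adapter (list with `fit` and `predict` functions and a
#'   `name`).
#' @export
ols_learner <- function() {
  list(
    name = "ols",
    fit = function(x, y) {
      X <- cbind(1, as.matrix(x))
      stats::lm.fit(X, y)$coefficients
    },
    predict = function(model, x) {
      model[is.na(model)] <- 0
      as.numeric(cbind(1, as.matrix(x)) %*% model)
    }
  )
}

#' Leave-one-out / repeated k-fold cross-validation
#'
#' `loo_cross_validate` predicts each compound from a model trained on the
#' other n - 1 compounds. `kfold_cross_validate` runs `repeats` times `k`-fold
#' cross-validation with per-repetition fold shuffling derived from `seed`,
#' recording one run per repetition for every compound.
#'
#' @param dataset A [cs_dataset].
#' @param endpoint Endpoint column name (numeric or nominal).
#' @param learner A learner adapter (see [ols_learner()]).
#' @param columns Numeric feature columns used as model input; default all
#'   non-endpoint numeric columns.
#' @return A [validation_table].
#' @export
loo_cross_validate <- function(dataset, endpoint, learner = ols_learner(),
                               columns = NULL) {
  x <- feature_matrix(dataset, columns)
  y <- dataset$features[[endpoint]]
  if (is.null(y)) stop("unknown endpoint column: ", endpoint, call. = FALSE)
  n <- nrow(x)
  preds <- vector(mode = if (is.numeric(y)) "numeric" else "character", length = n)
  for (i in seq_len(n)) {
    model <- tryCatch(learner$fit(x[-i, , drop = FALSE], y[-i]),
                      error = function(e) stop("learner failed on fold ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
    preds[i] <- learner$predict(model, x[i, , drop = FALSE])
  }
  validation_table(seq_len(n), rep(1L, n), preds)
}

#' @rdname loo_cross_validate
#' @param k Number of folds.
#' @param repeats Number of repetitions (each with fresh fold shuffling).
#' @param seed Integer seed driving the fold shuffles.
#' @export
kfold_cross_validate <- function(dataset, endpoint, learner = ols_learner(),
                                 k = 10, repeats = 10, seed = 1L,
                                 columns = NULL) {
  x <- feature_matrix(dataset, columns)
  y <- dataset$features[[endpoint]]
  if (is.null(y)) stop("unknown endpoint column: ", endpoint, call. = FALSE)
  n <- nrow(x)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n", call. = FALSE)
  rows <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    folds <- with_seed(seed + rep_i - 1L,
                       sample(rep_len(seq_len(k), n)))
    preds <- vector(mode = if (is.numeric(y)) "numeric" else "character", length = n)
    for (f in seq_len(k)) {
      test <- which(folds == f)
      model <- tryCatch(learner$fit(x[-test, , drop = FALSE], y[-test]),
                        error = function(e) stop("learner failed on repetition ",
                                                 rep_i, " fold ", f, ": ",
                                                 conditionMessage(e), call. = FALSE))
      preds[test] <- learner$predict(model, x[test, , drop = FALSE])
    }
    rows[[rep_i]] <- data.frame(compound_index = seq_len(n), run_id = rep_i,
                                predicted = preds, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  validation_table(all$compound_index, all$run_id, all$predicted)
}

#' Regression / classification metrics
#'
#' `R^2 = 1 - SSE/SST` (SST about the mean of the actual values -- the scorer
#' convention, not squared correlation: predicting the mean scores exactly 0
#' and worse-than-mean models score negative), RMSE, and accuracy for class
#' labels.
#'
#' @param actual,predicted Same-length vectors (length >= 2).
#' @return For numeric input a list with `r2` and `rmse`; for labels a list
#'   with `accuracy`.
#' @export
metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2)
    stop("actual and predicted must have equal length >= 2", call. = FALSE)
  if (is.numeric(actual) && is.numeric(predicted)) {
    sst <- sum((actual - mean(actual))^2)
    if (sst == 0) stop("undefined R^2: actual values have zero variance", call. = FALSE)
    sse <- sum((actual - predicted)^2)
    list(r2 = 1 - sse / sst, rmse = sqrt(mean((actual - predicted)^2)))
  } else {
    list(accuracy = mean(as.character(actual) == as.character(predicted)))
  }
}
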