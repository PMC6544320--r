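#' Filter target predictions by the similarity-ensemble thresholds
#'
#' Keeps predicted drug-target pairs passing all three published confidence
#' thresholds, each strict: Z-score above 20, Tanimoto coefficient above 0.4,
#' P-value below 0.01.
#'
#' @param predictions data frame with columns `drug`, `target`, `z_score`,
#'   `tanimoto`, `p_value`.
#' @param z_min,tanimoto_min,p_max the thresholds.
#' @return data frame of accepted `(drug, target)` pairs.
#' @export
filter_sea <- function(predictions, z_min = 20, tanimoto_min = 0.4,
                       p_max = 0.01) {
  need <- c("drug", "target", "z_score", "tanimoto", "p_value")
  if (!all(need %in% names(predictions)))
    stop_combosens("predictions must have columns ",
                   paste(need, collapse = ", "),
                   class = "combosens_config_error")
  keep <- predictions$z_score > z_min &
    predictions$tanimoto > tanimoto_min &
    predictions$p_value < p_max
  predictions[keep, c("drug", "target"), drop = FALSE]
}

#' Combine two drug feature vectors
#'
#' A drug combination is featurised as the bitwise OR of its single drugs'
#' binary target/fingerprint profiles: a feature is on if either drug has it.
#'
#' @param f1,f2 binary vectors of equal length (and matching names, if
#'   named).
#' @return integer 0/1 vector.
#' @examples
#' combine_features(c(1, 0, 1), c(0, 0, 1))
#' @export
combine_features <- function(f1, f2) {
  if (length(f1) != length(f2))
    stop_combosens("feature vectors differ in length",
                   class = "combosens_value_error")
  if (!is.null(names(f1)) && !is.null(names(f2)) &&
      !identical(names(f1), names(f2)))
    stop_combosens("feature vectors differ in feature order",
                   class = "combosens_value_error")
  if (!all(f1 %in% c(0, 1)) || !all(f2 %in% c(0, 1)))
    stop_combosens("feature vectors must be binary",
                   class = "combosens_value_error")
  out <- as.integer(f1 | f2)
  names(out) <- names(f1)
  out
}

#' Feature matrix for a set of drug pairs
#'
#' @param features binary matrix, drugs in rows (rownames), features in
#'   columns.
#' @param pairs data frame with columns `drug1`, `drug2`.
#' @return binary matrix with one row per pair.
#' @export
combination_feature_matrix <- function(features, pairs) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  missing <- setdiff(unique(c(pairs$drug1, pairs$drug2)), rownames(features))
  if (length(missing))
    stop_combosens("drugs missing from feature table: ",
                   paste(missing, collapse = ", "),
                   class = "combosens_value_error")
  out <- t(mapply(function(d1, d2)
    combine_features(features[d1, ], features[d2, ]),
    pairs$drug1, pairs$drug2))
  rownames(out) <- paste(pairs$drug1, pairs$drug2, sep = "+")
  colnames(out) <- colnames(features)
  out
}

#' Bundled learners for the CV harness
#'
#' Learners are plain lists implementing the pluggable contract used by
#' [cv_harness()]: `fit(X, y, config)` returning a model, `predict(model, X)`
#' returning numeric predictions, and `grid`, a list of candidate
#' configurations scanned by the inner cross-validation.
#'
#' * `ridge_learner()`: closed-form ridge regression with an unpenalised
#'   intercept; `grid` is a ladder of penalty strengths.
#' * `mean_learner()`: predicts the training mean (baseline).
#' * `function_learner(f)`: ignores training and predicts `f(X)` - an oracle
#'   for testing the harness itself.
#'
#' @param lambdas ridge penalties to scan.
#' @return a learner list.
#' @export
ridge_learner <- function(lambdas = 10^seq(-3, 3, length.out = 7)) {
  list(
    name = "ridge",
    grid = as.list(lambdas),
    fit = function(X, y, config) {
      X <- as.matrix(X)
      Xm <- colMeans(X); ym <- mean(y)
      Xc <- sweep(X, 2, Xm)
      beta <- solve(crossprod(Xc) + config * diag(ncol(X)),
                    crossprod(Xc, y - ym))
      list(beta = beta, Xm = Xm, ym = ym)
    },
    predict = function(model, X) {
      drop(sweep(as.matrix(X), 2, model$Xm) %*% model$beta) + model$ym
    }
  )
}

#' @rdname ridge_learner
#' @export
mean_learner <- function() {
  list(name = "mean", grid = list(NA),
       fit = function(X, y, config) list(mu = mean(y)),
       predict = function(model, X) rep(model$mu, nrow(as.matrix(X))))
}

#' @rdname ridge_learner
#' @param f function mapping a feature matrix to predictions.
#' @export
function_learner <- function(f) {
  list(name = "oracle", grid = list(NA),
       fit = function(X, y, config) list(f = f),
       predict = function(model, X) model$f(X))
}

regression_metrics <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  cor <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) 0 else
    stats::cor(obs, pred)
  c(rmse = sqrt(mean((obs - pred)^2)), r2 = r2, cor = cor,
    mae = mean(abs(obs - pred)))
}

#' Repeated 70/30 cross-validated prediction harness
#'
#' The evaluation protocol used to test whether combination sensitivity can
#' be predicted from drug features, within one cell line: per repeat, a random
#' 70% of the combinations train and the held-out 30% test (test combinations
#' never appear in training); 10-fold cross-validation on the training split
#' selects the learner configuration with the lowest RMSE; the selected
#' configuration is refit on the full training split and scored on the test
#' split with RMSE, R2 (`1 - SS_res/SS_tot`, reported as 0 when `SS_tot = 0`),
#' Pearson correlation and MAE. Results are summarised as mean +/- sd over
#' repeats. Fully reproducible for a given `seed`.
#'
#' @param X feature matrix, one row per drug combination.
#' @param y response (e.g. CSS values), length `nrow(X)`; at least 20
#'   combinations.
#' @param learner a learner contract, e.g. [ridge_learner()].
#' @param train_frac training fraction; default 0.7.
#' @param folds inner CV folds; default 10.
#' @param repeats outer repetitions; default 20.
#' @param seed RNG seed.
#' @return list with `summary` (mean/sd per metric), `repeats` (per-repeat
#'   metrics and selected configuration) and `predictions` (per-repeat
#'   held-out predictions).
#' @export
cv_harness <- function(X, y, learner = ridge_learner(), train_frac = 0.7,
                       folds = 10, repeats = 20, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 20L)
    stop_combosens("cv_harness needs at least 20 combinations",
                   class = "combosens_value_error")
  metric_rows <- list(); pred_rows <- list(); configs <- list()
  for (r in seq_len(repeats)) {
    res <- tryCatch(
      cv_one_repeat(X, y, learner, train_frac, folds, seed + r - 1L),
      error = function(e) {
        warning("repeat ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    metric_rows[[length(metric_rows) + 1L]] <-
      data.frame(repeat_id = r, t(res$metrics))
    pred_rows[[length(pred_rows) + 1L]] <-
      data.frame(repeat_id = r, index = res$test_idx,
                 observed = y[res$test_idx], predicted = res$pred)
    configs[[length(configs) + 1L]] <- res$config
  }
  if (length(metric_rows) == 0L)
    stop_combosens("all cv_harness repeats failed",
                   class = "combosens_value_error")
  rep_df <- do.call(rbind, metric_rows)
  metrics <- c("rmse", "r2", "cor", "mae")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(rep_df[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(rep_df[[m]]), numeric(1)),
    row.names = NULL
  )
  list(summary = summary, repeats = rep_df,
       predictions = do.call(rbind, pred_rows), configs = configs)
}

cv_one_repeat <- function(X, y, learner, train_frac, folds, seed) {
  set.seed(seed)
  n <- nrow(X)
  train_idx <- sort(sample.int(n, floor(train_frac * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  fold_id <- sample(rep(seq_len(folds), length.out = length(train_idx)))
  cv_rmse <- vapply(learner$grid, function(config) {
    errs <- vapply(seq_len(folds), function(f) {
      hold <- fold_id == f
      if (!any(hold) || all(hold)) return(NA_real_)
      model <- learner$fit(Xtr[!hold, , drop = FALSE], ytr[!hold], config)
      pred <- learner$predict(model, Xtr[hold, , drop = FALSE])
      sqrt(mean((ytr[hold] - pred)^2))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- learner$grid[[which.min(cv_rmse)]]
  model <- learner$fit(Xtr, ytr, best)
  pred <- learner$predict(model, X[test_idx, , drop = FALSE])
  list(metrics = regression_metrics(y[test_idx], pred),
       test_idx = test_idx, pred = pred, config = best)
}
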