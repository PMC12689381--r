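# Binary distress classifier behind a pluggable algorithm tag. Gradient
# boosted trees (xgboost) are the primary model; logistic regression, naive
# Bayes and random forest run through the identical surface as comparison
# algorithms. All fitting is single-threaded and seed-deterministic.

with_seed <- function(seed, expr) {
  had <- .Random.seed_exists()
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(had, old), add = TRUE)
  set.seed(seed)
  expr
}

classifier_algorithms <- function() {
  c("gradient_boosted_trees", "logistic_regression", "naive_bayes",
    "random_forest")
}

#' Default gradient-boosting hyperparameters
#'
#' Moderate depth and shrinkage, no early stopping; every knob is exposed
#' through the `params` argument of [fit_classifier()].
#' @export
default_gbt_params <- function() {
  list(nrounds = 120, max_depth = 4, eta = 0.3, subsample = 1,
       colsample_bytree = 1, min_child_weight = 1)
}

#' Fit a binary distress classifier
#'
#' @param fm A [build_feature_matrix()] result.
#' @param algorithm One of `"gradient_boosted_trees"` (default),
#'   `"logistic_regression"`, `"naive_bayes"`, `"random_forest"`.
#' @param seed Integer training seed.
#' @param params Optional list of algorithm hyperparameters (see
#'   [default_gbt_params()]; for random forest, `num.trees`).
#' @return A `model_bundle`: the fitted model handle, the algorithm tag, the
#'   feature names and the seed. Probabilities come from
#'   [predict_distress_prob()].
#' @export
fit_classifier <- function(fm, algorithm = classifier_algorithms(), seed = 1L,
                           params = list()) {
  algorithm <- match.arg(algorithm)
  y <- fm$label
  if (length(unique(y)) < 2L) {
    stop("labels are single-class; cannot fit a classifier", call. = FALSE)
  }
  model <- with_seed(seed, switch(
    algorithm,
    gradient_boosted_trees = {
      p <- utils::modifyList(default_gbt_params(), params)
      dtrain <- xgboost::xgb.DMatrix(fm$x, label = as.numeric(y), nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = p$max_depth,
                      eta = p$eta, subsample = p$subsample,
                      colsample_bytree = p$colsample_bytree,
                      min_child_weight = p$min_child_weight,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = p$nrounds, verbose = 0
      )
    },
    logistic_regression = {
      df <- as.data.frame(fm$x)
      names(df) <- make.names(colnames(fm$x))
      df$.y <- as.numeric(y)
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
    },
    naive_bayes = {
      df <- as.data.frame(lapply(as.data.frame(fm$x), function(v) {
        factor(v, levels = c(0, 1))
      }))
      names(df) <- make.names(colnames(fm$x))
      e1071::naiveBayes(df, factor(y, levels = c(FALSE, TRUE)), laplace = 1)
    },
    random_forest = {
      nt <- if (is.null(params$num.trees)) 200 else params$num.trees
      df <- as.data.frame(fm$x)
      names(df) <- make.names(colnames(fm$x))
      df$.y <- factor(y, levels = c(FALSE, TRUE))
      ranger::ranger(.y ~ ., data = df, probability = TRUE, num.trees = nt,
                     seed = seed, num.threads = 1)
    }
  ))
  structure(list(model = model, algorithm = algorithm,
                 feature_names = fm$feature_names, seed = seed,
                 metrics = NULL),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("Distress classifier:", x$algorithm, "over",
      length(x$feature_names), "features (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Predicted probability of clinical distress
#'
#' @param bundle A `model_bundle`.
#' @param fm A feature matrix over the identical feature space.
#' @return Numeric vector of P(distressed).
#' @export
predict_distress_prob <- function(bundle, fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  if (!identical(colnames(x), bundle$feature_names)) {
    stop("feature names differ between training and scoring", call. = FALSE)
  }
  switch(bundle$algorithm,
    gradient_boosted_trees =
      predict(bundle$model, xgboost::xgb.DMatrix(x, nthread = 1)),
    logistic_regression = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      suppressWarnings(unname(predict(bundle$model, df, type = "response")))
    },
    naive_bayes = {
      df <- as.data.frame(lapply(as.data.frame(x), function(v) {
        factor(v, levels = c(0, 1))
      }))
      names(df) <- make.names(colnames(x))
      unname(predict(bundle$model, df, type = "raw")[, "TRUE"])
    },
    random_forest = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      unname(predict(bundle$model, df, num.threads = 1)$predictions[, "TRUE"])
    }
  )
}

confusion_counts <- function(labels, predicted) {
  c(tp = sum(predicted & labels), fp = sum(predicted & !labels),
    fn = sum(!predicted & labels), tn = sum(!predicted & !labels))
}

prf_from_counts <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

#' Evaluation metrics for probabilistic distress predictions
#'
#' AUC, accuracy, precision, recall and F1 at a 0.5 decision threshold.
#' `average = "macro"` (the default) computes precision/recall/F1 separately
#' for the distressed and the non-distressed prediction problem and averages
#' them — the "average across positive and negative prediction models";
#' `"pooled"` scores the distressed class alone from pooled confusion counts.
#'
#' @param labels Logical truth.
#' @param probs Predicted probabilities of distress.
#' @param threshold Decision threshold.
#' @param average `"macro"` or `"pooled"`.
#' @return A tibble with `auc`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(labels, probs, threshold = 0.5,
                            average = c("macro", "pooled")) {
  average <- match.arg(average)
  stopifnot(length(labels) == length(probs))
  pred <- probs > threshold
  cc <- confusion_counts(labels, pred)
  accuracy <- (cc["tp"] + cc["tn"]) / sum(cc)
  pos <- prf_from_counts(cc["tp"], cc["fp"], cc["fn"])
  auc <- if (length(unique(labels)) < 2L) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = probs,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }
  if (average == "macro") {
    neg <- prf_from_counts(cc["tn"], cc["fn"], cc["fp"])
    pos <- (pos + neg) / 2
  }
  tibble::tibble(auc = auc, accuracy = unname(accuracy),
                 precision = unname(pos["precision"]),
                 recall = unname(pos["recall"]), f1 = unname(pos["f1"]))
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

stratified_split <- function(labels, train_frac, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      train[sample(idx, round(train_frac * length(idx)))] <- TRUE
    }
    train
  })
}

#' Stratified k-fold cross-validation
#'
#' @param fm A feature matrix.
#' @param algorithm Classifier tag (see [fit_classifier()]).
#' @param k Number of folds (3, 5 or 10 in the standard benchmark; any
#'   `k >= 2` up to the minority-class size is accepted).
#' @param seed Seed controlling fold assignment and fitting.
#' @param params Hyperparameters forwarded to [fit_classifier()].
#' @param average Metric averaging mode, see [compute_metrics()].
#' @return A list: `metrics` (fold-averaged tibble) and `per_fold`.
#' @export
cross_validate <- function(fm, algorithm = "gradient_boosted_trees", k = 5L,
                           seed = 1L, params = list(), average = "macro") {
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (k > min(table(fm$label))) {
    stop("`k` exceeds the minority class size", call. = FALSE)
  }
  fold <- stratified_folds(fm$label, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    train <- subset_fm(fm, fold != f)
    test <- subset_fm(fm, fold == f)
    bundle <- fit_classifier(train, algorithm, seed = seed + f, params = params)
    m <- compute_metrics(test$label, predict_distress_prob(bundle, test),
                         average = average)
    m$fold <- f
    m
  })
  per_fold <- dplyr::bind_rows(per_fold)
  metrics <- dplyr::summarise(per_fold, dplyr::across(
    c("auc", "accuracy", "precision", "recall", "f1"), mean))
  list(metrics = metrics, per_fold = per_fold)
}

#' Repeated random train/test split evaluation
#'
#' Final-benchmark protocol: `n_repeats` independent stratified splits;
#' reported metrics are means over repeats of the per-class-averaged (macro)
#' test metrics.
#'
#' @inheritParams cross_validate
#' @param train_frac Fraction of each class assigned to training.
#' @param n_repeats Number of random splits.
#' @return A list: `metrics` (mean over repeats) and `per_repeat`.
#' @export
repeated_split_eval <- function(fm, algorithm = "gradient_boosted_trees",
                                train_frac = 0.65, n_repeats = 5L, seed = 1L,
                                params = list(), average = "macro") {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie strictly between 0 and 1", call. = FALSE)
  }
  per_repeat <- lapply(seq_len(n_repeats), function(r) {
    train <- stratified_split(fm$label, train_frac, seed + r)
    if (length(unique(fm$label[!train])) < 2L ||
        length(unique(fm$label[train])) < 2L) {
      stop("split leaves a class empty; adjust `train_frac`", call. = FALSE)
    }
    bundle <- fit_classifier(subset_fm(fm, train), algorithm,
                             seed = seed + r, params = params)
    test <- subset_fm(fm, !train)
    m <- compute_metrics(test$label, predict_distress_prob(bundle, test),
                         average = average)
    m$repeat_id <- r
    m$n_test <- sum(!train)
    m
  })
  per_repeat <- dplyr::bind_rows(per_repeat)
  metrics <- dplyr::summarise(per_repeat, dplyr::across(
    c("auc", "accuracy", "precision", "recall", "f1"), mean))
  list(metrics = metrics, per_repeat = per_repeat)
}

#' Sensitivity to correlated predictors
#'
#' Computes pairwise Pearson correlation over feature columns, greedily drops
#' the later-ordered member of every pair with `|r|` above the threshold,
#' refits on the identical train/test split, and returns the AUC change
#' (full minus reduced).
#'
#' @inheritParams cross_validate
#' @param r_threshold Absolute correlation above which the later column of a
#'   pair is dropped.
#' @param train_frac Fraction used to fit (remainder evaluates both models).
#' @return A list: `delta_auc`, `dropped` (feature names), `auc_full`,
#'   `auc_reduced`.
#' @export
drop_correlated_sensitivity <- function(fm, algorithm = "gradient_boosted_trees",
                                        r_threshold = 0.80, seed = 1L,
                                        train_frac = 0.7, params = list()) {
  if (ncol(fm$x) < 2L) stop("need at least 2 features", call. = FALSE)
  sds <- apply(fm$x, 2, sd)
  cm <- suppressWarnings(cor(fm$x))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  dropped <- character()
  for (j in seq_len(ncol(cm))) {
    if (colnames(cm)[j] %in% dropped) next
    hits <- which(abs(cm[, j]) > r_threshold)
    hits <- hits[hits > j & !colnames(cm)[hits] %in% dropped]
    dropped <- c(dropped, colnames(cm)[hits])
  }
  # constant columns carry no information; leave them (they never correlate)
  reduced <- drop_features_fm(fm, dropped)
  train <- stratified_split(fm$label, train_frac, seed)
  auc_of <- function(f) {
    b <- fit_classifier(subset_fm(f, train), algorithm, seed = seed,
                        params = params)
    te <- subset_fm(f, !train)
    compute_metrics(te$label, predict_distress_prob(b, te))$auc
  }
  auc_full <- auc_of(fm)
  auc_reduced <- if (length(dropped)) auc_of(reduced) else auc_full
  list(delta_auc = auc_full - auc_reduced, dropped = dropped,
       auc_full = auc_full, auc_reduced = auc_reduced)
}

#' Sensitivity to excluding the exposure features
#'
#' Refits without the exposure one-hot block and returns the AUC change
#' (full minus excluded) on a common test split: the exposure's unique
#' predictive contribution.
#'
#' @inheritParams drop_correlated_sensitivity
#' @param exposure_columns Feature names to exclude (default: the 5 exposure
#'   dummies).
#' @export
exclude_exposure_sensitivity <- function(fm,
                                         algorithm = "gradient_boosted_trees",
                                         exposure_columns = upf_feature_columns(),
                                         seed = 1L, train_frac = 0.7,
                                         params = list()) {
  absent <- setdiff(exposure_columns, fm$feature_names)
  if (length(absent)) {
    stop("exposure column(s) absent from the feature matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  reduced <- drop_features_fm(fm, exposure_columns)
  train <- stratified_split(fm$label, train_frac, seed)
  auc_of <- function(f) {
    b <- fit_classifier(subset_fm(f, train), algorithm, seed = seed,
                        params = params)
    te <- subset_fm(f, !train)
    compute_metrics(te$label, predict_distress_prob(b, te))$auc
  }
  list(delta_auc = auc_of(fm) - auc_of(reduced),
       excluded = exposure_columns)
}

#' Calibration curve of a fitted classifier
#'
#' Bins test predictions into `n_bins` equal-width probability bins and
#' reports the mean predicted probability against the observed distress rate.
#' Empty bins appear with `n = 0` and missing rates.
#'
#' @param bundle A `model_bundle`.
#' @param fm_test Test feature matrix (labels used as truth).
#' @param n_bins Number of equal-width bins on `[0, 1]`.
#' @return A tibble: `bin`, `mean_predicted`, `observed_rate`, `n`.
#' @export
calibration_curve <- function(bundle, fm_test, n_bins = 10L) {
  probs <- predict_distress_prob(bundle, fm_test)
  calibration_table(probs, fm_test$label, n_bins)
}

calibration_table <- function(probs, labels, n_bins = 10L) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    tibble::tibble(bin = b,
                   mean_predicted = if (any(sel)) mean(probs[sel]) else NA_real_,
                   observed_rate = if (any(sel)) mean(labels[sel]) else NA_real_,
                   n = sum(sel))
  })
  dplyr::bind_rows(out)
}
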