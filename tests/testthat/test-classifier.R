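small_fm <- function(n = 600) {
  fm <- fixture_fm()
  cached(paste0("small_fm_", n), {
    set.seed(2024)
    rows <- sort(sample(nrow(fm$x), n))
    f <- fm; f$x <- fm$x[rows, ]; f$label <- fm$label[rows]
    f$ids <- fm$ids[rows]; f
  })
}

test_that("the one-hot layout matches the dictionary and is order-stable", {
  fm <- fixture_fm()
  expect_identical(ncol(fm$x), 108L)
  expect_identical(colnames(fm$x), feature_dictionary()$feature_name)
  # one-hot groups sum to exactly 1 per categorical block
  dict <- fm$dictionary
  for (col in c("upf_freq", "age_group", "sex", "country", "income_band")) {
    block <- dict$feature_name[dict$column == col]
    expect_true(all(rowSums(fm$x[, block]) == 1))
  }
  # permuting records permutes rows only
  co <- fixture_cohort()[1:50, ]
  perm <- c(20:1, 21:50)
  a <- build_feature_matrix(co)
  b <- build_feature_matrix(co[perm, ])
  expect_identical(b$x, a$x[perm, ])
})

test_that("checklist selections map to exactly their columns", {
  co <- fixture_cohort()[1:20, ]
  co[, sprintf("trauma_%02d", 1:10)] <- 0L
  co$trauma_02 <- 1L
  co$trauma_07 <- 1L
  fm <- build_feature_matrix(co)
  tr_cols <- sprintf("trauma_%02d", 1:10)
  expect_true(all(fm$x[, "trauma_02"] == 1))
  expect_true(all(fm$x[, "trauma_07"] == 1))
  expect_true(all(fm$x[, setdiff(tr_cols, c("trauma_02", "trauma_07"))] == 0))
})

test_that("unseen category levels error naming the record and column", {
  co <- fixture_cohort()[1:5, ]
  co$sleep_quality[3] <- "Transcendent"
  expect_error(build_feature_matrix(co), "sleep_quality")
  expect_error(build_feature_matrix(co), co$id[3])
})

test_that("metrics agree with brute-force confusion counts and pairwise AUC", {
  set.seed(8)
  labels <- rbinom(60, 1, 0.4) == 1
  probs <- runif(60)
  m <- compute_metrics(labels, probs, average = "pooled")
  ref <- brute_confusion_metrics(labels, probs > 0.5)
  expect_equal(m$accuracy, ref$accuracy, tolerance = 1e-9)
  expect_equal(m$precision, ref$precision, tolerance = 1e-9)
  expect_equal(m$recall, ref$recall, tolerance = 1e-9)
  expect_equal(m$f1, ref$f1, tolerance = 1e-9)
  # F1 harmonic identity from pooled counts
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-9)
  expect_equal(m$auc, brute_auc(labels, probs), tolerance = 1e-9)
})

test_that("macro and pooled metrics differ on imbalanced predictions", {
  labels <- c(rep(TRUE, 8), rep(FALSE, 2))
  probs <- c(rep(0.9, 7), 0.1, 0.9, 0.1)
  macro <- compute_metrics(labels, probs, average = "macro")
  pooled <- compute_metrics(labels, probs, average = "pooled")
  expect_false(isTRUE(all.equal(macro$precision, pooled$precision)))
  # hand-computed: tp=7 fp=1 fn=1 tn=1
  expect_equal(pooled$precision, 7 / 8, tolerance = 1e-12)
  expect_equal(macro$precision, (7 / 8 + 1 / 2) / 2, tolerance = 1e-12)
})

test_that("a linearly separable problem is learned almost perfectly", {
  fm <- toy_fm()
  for (algo in c("gradient_boosted_trees", "logistic_regression",
                 "naive_bayes", "random_forest")) {
    b <- fit_classifier(fm, algo, seed = 3)
    m <- compute_metrics(fm$label, predict_distress_prob(b, fm))
    expect_gte(m$auc, 0.99)
  }
})

test_that("permuted labels give chance-level held-out AUC", {
  fm <- small_fm()
  set.seed(31)
  fm$label <- sample(fm$label)
  aucs <- vapply(1:3, function(s) {
    tr <- seq_len(nrow(fm$x)) %in% sample(nrow(fm$x), 400)
    f_tr <- fm; f_tr$x <- fm$x[tr, ]; f_tr$label <- fm$label[tr]
    f_te <- fm; f_te$x <- fm$x[!tr, ]; f_te$label <- fm$label[!tr]
    b <- fit_classifier(f_tr, "gradient_boosted_trees", seed = s,
                        params = list(nrounds = 40))
    compute_metrics(f_te$label, predict_distress_prob(b, f_te))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("single-class labels are rejected", {
  fm <- toy_fm()
  fm$label <- rep(TRUE, length(fm$label))
  expect_error(fit_classifier(fm), "single-class")
})

test_that("cross-validation is stratified, deterministic and fold-stable", {
  fm <- small_fm(3000)
  cv5a <- cross_validate(fm, "gradient_boosted_trees", k = 5, seed = 9,
                         params = list(nrounds = 60))
  cv5b <- cross_validate(fm, "gradient_boosted_trees", k = 5, seed = 9,
                         params = list(nrounds = 60))
  expect_identical(cv5a$metrics, cv5b$metrics)
  cv3 <- cross_validate(fm, "gradient_boosted_trees", k = 3, seed = 9,
                        params = list(nrounds = 60))
  cv10 <- cross_validate(fm, "gradient_boosted_trees", k = 10, seed = 9,
                         params = list(nrounds = 60))
  aucs <- c(cv3$metrics$auc, cv5a$metrics$auc, cv10$metrics$auc)
  expect_lt(max(aucs) - min(aucs), 0.03)
  expect_error(cross_validate(fm, k = 1), "at least 2")
  expect_error(cross_validate(fm, k = 5000), "minority")
})

test_that("a perfect predictor feature drives AUC to 1 for every k", {
  fm <- small_fm()
  fm$x <- cbind(fm$x, leak = as.numeric(fm$label))
  fm$feature_names <- colnames(fm$x)
  for (k in c(3, 5)) {
    cv <- cross_validate(fm, "gradient_boosted_trees", k = k, seed = 2,
                         params = list(nrounds = 30))
    expect_gte(cv$metrics$auc, 0.99)
  }
})

test_that("repeated splits hold out the requested fraction and average metrics", {
  fm <- small_fm(1000)
  rs <- repeated_split_eval(fm, "gradient_boosted_trees", train_frac = 0.65,
                            n_repeats = 3, seed = 5,
                            params = list(nrounds = 60))
  expect_identical(unique(rs$per_repeat$n_test),
                   as.integer(nrow(fm$x) - sum(round(0.65 * table(fm$label)))))
  expect_equal(rs$metrics$auc, mean(rs$per_repeat$auc), tolerance = 1e-12)
  expect_error(repeated_split_eval(fm, train_frac = 1.2), "strictly between")
  expect_gt(rs$metrics$accuracy, max(mean(fm$label), 1 - mean(fm$label)) - 0.02)
})

test_that("duplicated columns are detected and dropping them is harmless", {
  fm <- small_fm(1000)
  dup <- fm
  dup$x <- cbind(fm$x, dup_of_upf = fm$x[, "upf_freq=Rarely/Never"])
  dup$feature_names <- colnames(dup$x)
  res <- drop_correlated_sensitivity(dup, r_threshold = 0.8, seed = 3,
                                     params = list(nrounds = 60))
  expect_true("dup_of_upf" %in% res$dropped)
  expect_lt(abs(res$delta_auc), 0.03)
})

test_that("independent features trigger no drop and a zero delta", {
  fm <- toy_fm(500, seed = 9)
  res <- drop_correlated_sensitivity(fm, r_threshold = 0.8, seed = 1,
                                     params = list(nrounds = 20))
  expect_length(res$dropped, 0)
  expect_identical(res$delta_auc, 0)
})

test_that("excluding the exposure block costs AUC only when it carries signal", {
  fm <- small_fm(1500)
  eff <- exclude_exposure_sensitivity(fm, seed = 4,
                                      params = list(nrounds = 60))
  expect_gt(eff$delta_auc, 0)

  null_co <- cached("null_co_cls", {
    score_cohort(generate_cohort(null_config(n_respondents = 3000,
                                             seed = 70))$cohort)
  })
  fm0 <- build_feature_matrix(null_co)
  null_eff <- exclude_exposure_sensitivity(fm0, seed = 4,
                                           params = list(nrounds = 60))
  expect_lt(abs(null_eff$delta_auc), 0.05)  # split noise only at this n
  expect_error(exclude_exposure_sensitivity(fm, exposure_columns = "nope"),
               "absent")
})

test_that("calibration curves behave on canonical inputs", {
  set.seed(12)
  p <- runif(5000)
  y <- rbinom(5000, 1, p) == 1
  tab <- upfburden:::calibration_table(p, y, n_bins = 10)
  occ <- tab[tab$n > 0, ]
  expect_true(all(abs(occ$observed_rate - occ$mean_predicted) <
                    3 * sqrt(0.25 / occ$n) + 0.02))
  # constant predictor on balanced labels: single occupied bin at (0.5, 0.5)
  tab2 <- upfburden:::calibration_table(rep(0.5, 200),
                                        rep(c(TRUE, FALSE), 100), n_bins = 10)
  expect_identical(sum(tab2$n > 0), 1L)
  expect_equal(tab2$observed_rate[tab2$n > 0], 0.5)
  expect_identical(nrow(tab2), 10L)  # empty bins present with n = 0
})

test_that("the fitted model is broadly calibrated and monotone across bins", {
  fm <- fixture_fm()
  train <- seq_len(nrow(fm$x)) <= 4000
  f_tr <- fm; f_tr$x <- fm$x[train, ]; f_tr$label <- fm$label[train]
  f_te <- fm; f_te$x <- fm$x[!train, ]; f_te$label <- fm$label[!train]
  f_te$ids <- fm$ids[!train]
  b <- fit_classifier(f_tr, seed = 2, params = list(nrounds = 80))
  curve <- calibration_curve(b, f_te, n_bins = 8)
  occ <- curve[curve$n >= 30, ]
  expect_gte(nrow(occ), 4)
  # observed distress rate rises with predicted probability (small-n slack)
  expect_true(all(diff(occ$observed_rate) > -0.12))
  expect_gt(cor(occ$mean_predicted, occ$observed_rate), 0.9)
})

test_that("every algorithm runs through the identical evaluation surface", {
  fm <- small_fm()
  for (algo in c("logistic_regression", "naive_bayes", "random_forest")) {
    cv <- cross_validate(fm, algo, k = 3, seed = 1)
    expect_true(all(is.finite(unlist(cv$metrics))))
    expect_gt(cv$metrics$auc, 0.6)   # real signal present for every algorithm
  }
})
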