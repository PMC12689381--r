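shap_fixture <- function() {
  cached("shap", {
    fm <- fixture_fm()
    compute_attributions(fixture_gbt(), fm)
  })
}

test_that("attributions satisfy the additivity identity in margin space", {
  fm <- fixture_fm()
  shap <- shap_fixture()
  dm <- xgboost::xgb.DMatrix(fm$x, nthread = 1)
  margin_distress <- predict(fixture_gbt()$model, dm, outputmargin = TRUE)
  # positive-wellbeing orientation: base + sum(values) = -distress margin
  recon <- shap$base_value + rowSums(shap$values)
  expect_lt(max(abs(recon + margin_distress)), 1e-4)
})

test_that("constant features receive exactly zero attribution", {
  fm <- fixture_fm()
  shap <- shap_fixture()
  const_cols <- colnames(fm$x)[apply(fm$x, 2, function(v) length(unique(v)) == 1)]
  # age/sex/country blocks always vary; planted check with an explicit constant
  fm2 <- fm
  fm2$x <- cbind(fm$x[1:500, ], always_zero = 0)
  fm2$feature_names <- colnames(fm2$x)
  fm2$label <- fm$label[1:500]
  b <- fit_classifier(fm2, seed = 5, params = list(nrounds = 30))
  s2 <- compute_attributions(b, fm2)
  expect_true(all(s2$values[, "always_zero"] == 0))
  if (length(const_cols)) {
    expect_true(all(shap$values[, const_cols] == 0))
  }
})

test_that("a single-stump model attributes margin minus base to its one feature", {
  # one boosting round, depth 1: the model is a single split on the dominant
  # feature, so per record attribution = margin - base, all on that feature
  set.seed(41)
  n <- 500
  x <- cbind(strong = rbinom(n, 1, 0.5), weak = rbinom(n, 1, 0.5))
  label <- (x[, "strong"] + rbinom(n, 1, 0.05)) >= 1
  fm <- structure(list(x = x * 1.0, feature_names = colnames(x),
                       label = label, ids = as.character(1:n)),
                  class = "feature_matrix")
  b <- fit_classifier(fm, seed = 1,
                      params = list(nrounds = 1, max_depth = 1, eta = 1))
  s <- compute_attributions(b, fm, orientation = "distress")
  dm <- xgboost::xgb.DMatrix(fm$x, nthread = 1)
  margin <- predict(b$model, dm, outputmargin = TRUE)
  expect_equal(unname(s$values[, "strong"]), margin - s$base_value,
               tolerance = 1e-6)
  expect_true(all(s$values[, "weak"] == 0))
  # the stump's margin takes exactly two values, one per side of the split
  expect_identical(length(unique(round(margin, 8))), 2L)
})

test_that("flipping the orientation flips every attribution sign exactly", {
  fm <- fixture_fm()
  pos <- shap_fixture()
  neg <- compute_attributions(fixture_gbt(), fm, orientation = "distress")
  expect_identical(pos$values, -neg$values)
  expect_identical(pos$base_value, -neg$base_value)
})

test_that("non-tree models are rejected with a pointer to the fallback", {
  fm <- toy_fm(100)
  b <- fit_classifier(fm, "logistic_regression")
  expect_error(compute_attributions(b, fm), "tree")
})

test_that("daily exposure carries the most negative selected-record attribution", {
  fm <- fixture_fm()
  shap <- shap_fixture()
  lifestyle <- c(upf_feature_columns(),
                 paste0("exercise_freq=", exercise_levels()),
                 sprintf("trauma_%02d", 1:10))
  sel_mean <- vapply(lifestyle, function(f) {
    sel <- fm$x[, f] == 1
    if (!any(sel)) return(NA_real_)
    mean(shap$values[sel, f])
  }, numeric(1))
  expect_identical(names(which.min(sel_mean)), "upf_freq=Several times a day")
  # reference exposure and frequent exercise push toward positive wellbeing
  expect_gt(sel_mean[["upf_freq=Rarely/Never"]], 0)
  expect_gt(sel_mean[["exercise_freq=Everyday"]], 0)
})

test_that("rank stability is 1 for identical folds and equals its brute force", {
  fm <- fixture_fm()
  b <- fixture_gbt()
  same <- rank_stability(list(b, b, b), fm)
  expect_equal(as.numeric(same), 1, tolerance = 1e-12)

  b2 <- fit_classifier(fixture_fm(), seed = 99, params = list(nrounds = 40))
  rs <- rank_stability(list(b, b2), fm)
  imp1 <- colMeans(abs(compute_attributions(b, fm)$values))
  imp2 <- colMeans(abs(compute_attributions(b2, fm)$values))
  expect_equal(as.numeric(rs), cor(imp1, imp2, method = "spearman"),
               tolerance = 1e-12)
  expect_error(rank_stability(list(b), fm), "at least 2")
})

test_that("fold models rank features consistently when signal dominates", {
  fm <- fixture_fm()
  fold <- rep_len(1:5, nrow(fm$x))
  models <- lapply(1:5, function(f) {
    tr <- fm; tr$x <- fm$x[fold != f, ]; tr$label <- fm$label[fold != f]
    fit_classifier(tr, seed = f, params = list(nrounds = 60))
  })
  rho <- rank_stability(models, fm)
  # over all 108 features: the ~60 pure-noise columns shuffle freely at the
  # bottom of the ranking, capping the full-set correlation
  expect_gte(as.numeric(rho), 0.7)
  expect_length(attr(rho, "pairwise"), choose(5, 2))
  # where signal dominates (the jointly most important half), ranks are tight
  imp <- vapply(models, function(b) {
    colMeans(abs(compute_attributions(b, fm)$values))
  }, numeric(ncol(fm$x)))
  top <- order(rowMeans(imp), decreasing = TRUE)[1:30]
  pair_rho <- apply(utils::combn(5, 2), 2, function(pr) {
    cor(imp[top, pr[1]], imp[top, pr[2]], method = "spearman")
  })
  expect_gte(mean(pair_rho), 0.9)
})

test_that("beeswarm export carries one row per record and feature with flags", {
  fm <- fixture_fm()
  shap <- shap_fixture()
  feats <- c("upf_freq=Rarely/Never", "upf_freq=Several times a day",
             "exercise_freq=Everyday")
  tab <- beeswarm_export(shap, fm, feats)
  expect_identical(nrow(tab), nrow(fm$x) * length(feats))
  for (f in feats) {
    sub <- tab[tab$feature == f, ]
    expect_identical(sub$selected, unname(fm$x[, f]))
  }
  ref <- tab[tab$feature == "upf_freq=Rarely/Never", ]
  expect_gt(mean(ref$attribution[ref$selected == 1]),
            mean(ref$attribution[ref$selected == 0]))
  expect_error(beeswarm_export(shap, fm, "no_such"), "unknown")
})
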