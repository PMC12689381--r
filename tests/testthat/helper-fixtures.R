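# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A moderately sized study-like cohort, scored, with ground truth.
fixture_generated <- function() {
  cached("gen", generate_cohort(paper_like_config(n_respondents = 6000,
                                                  seed = 42)))
}

fixture_cohort <- function() {
  cached("cohort", score_cohort(fixture_generated()$cohort))
}

fixture_fm <- function() {
  cached("fm", build_feature_matrix(fixture_cohort()))
}

fixture_gbt <- function() {
  cached("gbt", fit_classifier(fixture_fm(), "gradient_boosted_trees",
                               seed = 7))
}

# tiny synthetic two-feature problem with a known decision boundary
toy_fm <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  label <- x[, "a"] == 1
  structure(list(x = x * 1.0, feature_names = colnames(x), label = label,
                 ids = as.character(seq_len(n))),
            class = "feature_matrix")
}

# Brute-force metric oracles, independent of the package implementation.
brute_confusion_metrics <- function(labels, pred) {
  tp <- sum(labels & pred); fp <- sum(!labels & pred)
  fn <- sum(labels & !pred); tn <- sum(!labels & !pred)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       precision = prec, recall = rec,
       f1 = 2 * prec * rec / (prec + rec))
}

# Pairwise-comparison AUC (Mann-Whitney), O(n^2), small vectors only.
brute_auc <- function(labels, probs) {
  pos <- probs[labels]; neg <- probs[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
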