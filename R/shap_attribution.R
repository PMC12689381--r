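# Additive per-feature attributions (SHAP) for the fitted tree model, exact
# via the tree-path algorithm in margin (log-odds) space. The sign is
# oriented so POSITIVE attributions push the classification toward positive
# wellbeing (the non-distressed class); the model internally predicts
# distress, so attributions are the negated distress contributions and the
# additivity identity reads base_value + sum(values) = -distress margin.

#' Per-record, per-feature additive attributions
#'
#' Exact tree-path attributions for the gradient-boosted model, in log-odds
#' units. Orientation: positive values move the record toward a positive
#' wellbeing classification.
#'
#' @param bundle A `model_bundle` with `algorithm = "gradient_boosted_trees"`.
#' @param fm A feature matrix over the model's feature space.
#' @param orientation `"positive_wellbeing"` (default) or `"distress"`;
#'   switching flips every attribution's (and the base value's) sign exactly.
#' @return A `shap_summary`: list with `values` (n x p matrix), `base_value`,
#'   `feature_names`, `feature_order` (by mean absolute attribution,
#'   descending) and `orientation`.
#' @export
compute_attributions <- function(bundle, fm,
                                 orientation = c("positive_wellbeing",
                                                 "distress")) {
  orientation <- match.arg(orientation)
  if (bundle$algorithm != "gradient_boosted_trees") {
    stop("exact attributions require the tree model; refit with ",
         "algorithm = 'gradient_boosted_trees' (a model-agnostic fallback ",
         "is out of scope)", call. = FALSE)
  }
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  if (!identical(colnames(x), bundle$feature_names)) {
    stop("feature space differs from the fitted model", call. = FALSE)
  }
  contrib <- predict(bundle$model, xgboost::xgb.DMatrix(x, nthread = 1),
                     predcontrib = TRUE)
  p <- ncol(contrib) - 1L
  values <- contrib[, seq_len(p), drop = FALSE]
  base <- contrib[1L, p + 1L]
  if (orientation == "positive_wellbeing") {
    values <- -values
    base <- -base
  }
  ord <- order(colMeans(abs(values)), decreasing = TRUE)
  structure(list(values = values, base_value = unname(base),
                 feature_names = colnames(values),
                 feature_order = colnames(values)[ord],
                 orientation = orientation),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat("SHAP attributions:", nrow(x$values), "records x", ncol(x$values),
      "features (", x$orientation, "orientation )\n")
  cat("top features:", paste(head(x$feature_order, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Mean absolute attribution per feature
#' @param shap A `shap_summary`.
#' @export
mean_abs_attribution <- function(shap) {
  sort(colMeans(abs(shap$values)), decreasing = TRUE)
}

#' Stability of attribution-based feature rankings across fold models
#'
#' Each fold model attributes the same evaluation matrix; features are ranked
#' by mean absolute attribution per fold and Spearman rank correlation is
#' computed over every pairwise fold combination. Returns the mean.
#'
#' @param fold_models List (length >= 2) of `model_bundle`s over an identical
#'   feature space.
#' @param fm Evaluation feature matrix.
#' @return Mean pairwise Spearman rho, with attribute `pairwise` (the full
#'   vector).
#' @export
rank_stability <- function(fold_models, fm) {
  if (length(fold_models) < 2L) {
    stop("need at least 2 fold models", call. = FALSE)
  }
  spaces <- lapply(fold_models, function(b) b$feature_names)
  if (!all(vapply(spaces, identical, logical(1), spaces[[1]]))) {
    stop("fold models span different feature spaces", call. = FALSE)
  }
  imp <- vapply(fold_models, function(b) {
    colMeans(abs(compute_attributions(b, fm)$values))
  }, numeric(length(spaces[[1]])))
  pairs <- utils::combn(length(fold_models), 2)
  rho <- apply(pairs, 2, function(pr) {
    cor(imp[, pr[1]], imp[, pr[2]], method = "spearman")
  })
  structure(mean(rho), pairwise = rho)
}

#' Export beeswarm-plot data for selected features
#'
#' One row per (record, feature): the attribution value plus a selected flag
#' (1 when the respondent chose that option — the red/blue encoding of the
#' summary plot). Data export only; no rendering.
#'
#' @param shap A `shap_summary`.
#' @param fm The feature matrix the attributions were computed on.
#' @param features_of_interest Feature names to export.
#' @return A tibble: `id`, `feature`, `attribution`, `selected`.
#' @export
beeswarm_export <- function(shap, fm, features_of_interest) {
  absent <- setdiff(features_of_interest, shap$feature_names)
  if (length(absent)) {
    stop("unknown feature(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  ids <- if (!is.null(fm$ids)) fm$ids else seq_len(nrow(fm$x))
  out <- lapply(features_of_interest, function(f) {
    tibble::tibble(id = ids, feature = f,
                   attribution = unname(shap$values[, f]),
                   selected = unname(fm$x[, f]))
  })
  dplyr::bind_rows(out)
}
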