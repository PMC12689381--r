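# The headline burden estimators.
#
# Data-based: linked percentage = overall distress prevalence minus the
# prevalence among Rarely/Never consumers; burden = linked / overall x 100.
#
# Simulation-based (g-computation / model-based standardization): on held-out
# test records, predict the percentage classified distressed, force the
# exposure one-hot block to Rarely/Never leaving every other feature
# untouched, re-predict, and take the drop as the linked percentage. The
# burden denominator is the MODEL-predicted distressed percentage on the
# unmanipulated test set (not the observed prevalence); an observed-baseline
# variant is available behind a flag. Repeated over randomly drawn test
# sets, refitting per iteration by default, and averaged.

#' Force the exposure to its reference category
#'
#' Sets every record's exposure one-hot block to (Rarely/Never = 1, others =
#' 0); all other columns are bit-identical.
#'
#' @param fm A feature matrix containing the exposure block.
#' @return The modified feature matrix.
#' @export
set_reference_exposure <- function(fm) {
  cols <- upf_feature_columns()
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  if (!all(cols %in% colnames(x))) {
    stop("exposure one-hot block missing from the feature matrix", call. = FALSE)
  }
  x[, cols] <- 0
  x[, cols[1]] <- 1
  if (inherits(fm, "feature_matrix")) { fm$x <- x; fm } else x
}

#' Data-based linked percentage
#'
#' Percentage points of the sample whose distress is linked to the exposure:
#' overall prevalence minus prevalence in the reference-exposure group. A
#' reference prevalence above the overall one (possible in small strata)
#' yields a signed result with a warning.
#'
#' @param overall_prev_pct,reference_prev_pct Prevalences in percent.
#' @export
linked_percentage_data <- function(overall_prev_pct, reference_prev_pct) {
  stopifnot(overall_prev_pct >= 0, overall_prev_pct <= 100,
            reference_prev_pct >= 0, reference_prev_pct <= 100)
  if (reference_prev_pct > overall_prev_pct) {
    warning("reference prevalence exceeds overall prevalence; ",
            "returning a signed (negative) linked percentage", call. = FALSE)
  }
  overall_prev_pct - reference_prev_pct
}

#' Burden ratio: linked percentage over baseline distressed percentage
#'
#' @param linked_pct Linked percentage (points of the sample).
#' @param baseline_pct Percentage classified distressed before any change.
#' @return The burden in percent (`linked / baseline * 100`).
#' @export
burden_ratio <- function(linked_pct, baseline_pct) {
  if (any(baseline_pct <= 0)) {
    stop("undefined burden: baseline distressed percentage is zero", call. = FALSE)
  }
  linked_pct / baseline_pct * 100
}

#' Broad age bands used in burden reporting
#'
#' Maps the survey age groups onto All/18-34/35-64/65+ reporting bands.
#' @param age_group Character vector of age-group labels.
#' @export
age_band <- function(age_group) {
  bands <- c("18-24" = "18-34", "25-34" = "18-34", "35-44" = "35-64",
             "45-54" = "35-64", "55-64" = "35-64", "65-74" = "65+",
             "75+" = "65+")
  out <- bands[age_group]
  if (anyNA(out)) stop("unknown age group label", call. = FALSE)
  unname(out)
}

#' Simulation-based (g-computation) burden estimates
#'
#' Per iteration: draw a stratified random test set from the cohort, fit the
#' classifier on the remainder (refit per iteration by default), predict the
#' percentage distressed on the untouched test set (baseline), force the
#' exposure to Rarely/Never via [set_reference_exposure()], re-predict
#' (counterfactual), and form linked = baseline - counterfactual and burden =
#' linked / baseline x 100. Estimates are computed globally and per requested
#' stratum, then averaged over iterations.
#'
#' @param cohort A scored cohort tibble.
#' @param strata `"global"` only, or also `"age_band"`, `"age_band_sex"`
#'   (every listed grouping is reported).
#' @param n_iterations Number of random test draws.
#' @param test_frac Fraction of each class held out per iteration.
#' @param algorithm,params Classifier settings, see [fit_classifier()].
#' @param seed Integer seed for splits and fits.
#' @param refit Refit the model on each iteration's training remainder
#'   (default) or fit once on the first split and reuse.
#' @param baseline `"model"` (denominator = model-predicted distressed
#'   percentage, default) or `"observed"` (observed test prevalence).
#' @param estimator `"threshold"` (classify at probability 0.5, default) or
#'   `"expectation"` (average predicted probabilities — the standard
#'   g-computation estimator).
#' @param dictionary Optional feature dictionary override.
#' @return A tibble of burden estimates, one row per stratum: `method`,
#'   `stratum`, `linked_pct`, `baseline_pct`, `burden_pct`, `n_iterations`,
#'   plus a list column `per_iteration`.
#' @export
simulation_burden <- function(cohort, strata = "global", n_iterations = 10L,
                              test_frac = 0.35,
                              algorithm = "gradient_boosted_trees",
                              params = list(), seed = 1L, refit = TRUE,
                              baseline = c("model", "observed"),
                              estimator = c("threshold", "expectation"),
                              dictionary = NULL) {
  baseline <- match.arg(baseline)
  estimator <- match.arg(estimator)
  fm <- build_feature_matrix(cohort, dictionary)
  strata_of <- function(rows) {
    out <- list(global = rep("global", sum(rows)))
    if ("age_band" %in% strata) {
      out$age_band <- age_band(cohort$age_group[rows])
    }
    if ("age_band_sex" %in% strata) {
      out$age_band_sex <- paste(age_band(cohort$age_group[rows]),
                                cohort$sex[rows])
    }
    out
  }
  pct_distressed <- function(probs) {
    if (estimator == "threshold") 100 * mean(probs > 0.5) else 100 * mean(probs)
  }

  bundle <- NULL
  iter_rows <- list()
  for (it in seq_len(n_iterations)) {
    train <- stratified_split(fm$label, 1 - test_frac, seed + it)
    if (refit || is.null(bundle)) {
      bundle <- fit_classifier(subset_fm(fm, train), algorithm,
                               seed = seed + it, params = params)
    }
    test <- subset_fm(fm, !train)
    p_obs <- predict_distress_prob(bundle, test)
    p_ref <- predict_distress_prob(bundle, set_reference_exposure(test))
    groups <- strata_of(!train)
    for (g in names(groups)) {
      for (lv in unique(groups[[g]])) {
        sel <- groups[[g]] == lv
        if (!any(sel)) next
        base_pct <- if (baseline == "model") pct_distressed(p_obs[sel]) else {
          100 * mean(test$label[sel])
        }
        linked <- pct_distressed(p_obs[sel]) - pct_distressed(p_ref[sel])
        iter_rows[[length(iter_rows) + 1L]] <- tibble::tibble(
          iteration = it, grouping = g, stratum = lv,
          baseline_pct = base_pct, linked_pct = linked,
          burden_pct = if (base_pct > 0) linked / base_pct * 100 else NA_real_,
          n_test = sum(sel)
        )
      }
    }
  }
  per_iter <- dplyr::bind_rows(iter_rows)
  out <- per_iter |>
    dplyr::group_by(.data$grouping, .data$stratum) |>
    dplyr::summarise(linked_pct = mean(.data$linked_pct),
                     baseline_pct = mean(.data$baseline_pct),
                     burden_pct = mean(.data$burden_pct, na.rm = TRUE),
                     n_iterations = dplyr::n(), .groups = "drop")
  out$method <- "simulation"
  out$per_iteration <- lapply(seq_len(nrow(out)), function(i) {
    per_iter[per_iter$grouping == out$grouping[i] &
               per_iter$stratum == out$stratum[i], ]
  })
  out[, c("method", "grouping", "stratum", "linked_pct", "baseline_pct",
          "burden_pct", "n_iterations", "per_iteration")]
}

#' Data-based burden estimates from a scored cohort
#'
#' Observed distress prevalence, prevalence among Rarely/Never consumers,
#' and the derived linked percentage and burden, globally and per stratum.
#'
#' @inheritParams simulation_burden
#' @param weights Optional per-record weights (e.g., post-stratification);
#'   unweighted by default.
#' @export
data_burden <- function(cohort, strata = "global", weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(cohort))
  groups <- list(global = rep("global", nrow(cohort)))
  if ("age_band" %in% strata) groups$age_band <- age_band(cohort$age_group)
  if ("age_band_sex" %in% strata) {
    groups$age_band_sex <- paste(age_band(cohort$age_group), cohort$sex)
  }
  rows <- list()
  ref_level <- upf_levels()[1]
  for (g in names(groups)) {
    for (lv in unique(groups[[g]])) {
      sel <- groups[[g]] == lv
      overall <- 100 * weighted_statistic(cohort$distressed[sel], weights[sel],
                                          "proportion")
      ref_sel <- sel & cohort$upf_freq == ref_level
      if (!any(ref_sel)) next
      ref <- 100 * weighted_statistic(cohort$distressed[ref_sel],
                                      weights[ref_sel], "proportion")
      linked <- suppressWarnings(linked_percentage_data(overall, ref))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = "data", grouping = g, stratum = lv, linked_pct = linked,
        baseline_pct = overall,
        burden_pct = if (overall > 0) burden_ratio(linked, overall) else NA_real_,
        n_iterations = 1L
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Combined burden report table
#'
#' Binds data-based and simulation-based estimates into one table shaped
#' like the headline report: one row per (stratum, method) with linked and
#' burden percentages side by side.
#'
#' @param data_estimates Tibble from [data_burden()] (or built from printed
#'   prevalences); may be `NULL`.
#' @param simulation_estimates Tibble from [simulation_burden()]; may be
#'   `NULL`.
#' @export
burden_report <- function(data_estimates = NULL, simulation_estimates = NULL) {
  keep <- c("method", "grouping", "stratum", "linked_pct", "baseline_pct",
            "burden_pct", "n_iterations")
  pieces <- list()
  if (!is.null(data_estimates) && nrow(data_estimates)) {
    pieces$data <- data_estimates[, intersect(keep, names(data_estimates))]
  }
  if (!is.null(simulation_estimates) && nrow(simulation_estimates)) {
    pieces$sim <- simulation_estimates[, intersect(keep,
                                                   names(simulation_estimates))]
  }
  if (!length(pieces)) {
    return(tibble::tibble(method = character(), grouping = character(),
                          stratum = character(), linked_pct = numeric(),
                          baseline_pct = numeric(), burden_pct = numeric(),
                          n_iterations = integer()))
  }
  out <- dplyr::bind_rows(pieces)
  out[order(out$grouping, out$stratum, out$method), ]
}
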