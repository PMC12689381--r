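# One-hot feature construction. Every multiple-choice answer becomes a block
# of 0/1 dummies over its full level set; checklist items (traumas, medical
# conditions, substances) are already binary and enter as single columns.
# With the default four-country dictionary the layout comes to exactly 108
# features, including country, age group and sex, so the classifier absorbs
# the hierarchical structure of the data without explicit random effects.

#' The one-hot feature dictionary
#'
#' Enumerates, in deterministic order, every feature the classifier sees:
#' one-hot blocks for each categorical answer (missing income is its own
#' level) and one binary column per checklist item.
#'
#' @param countries Country codes present in the data (one dummy each).
#' @return A tibble with columns `block`, `column`, `level`, `feature_name`;
#'   `level` is `NA` for binary checklist features.
#' @export
feature_dictionary <- function(countries = c("BRA", "GBR", "IND", "USA")) {
  cat_block <- function(column, levels) {
    tibble::tibble(block = column, column = column, level = levels,
                   feature_name = paste0(column, "=", levels))
  }
  bin_block <- function(block, cols) {
    tibble::tibble(block = block, column = cols, level = NA_character_,
                   feature_name = cols)
  }
  dplyr::bind_rows(
    cat_block("age_group", age_group_levels()),
    cat_block("sex", sex_levels()),
    cat_block("country", sort(countries)),
    cat_block("upf_freq", upf_levels()),
    cat_block("exercise_freq", exercise_levels()),
    cat_block("income_band", c(income_levels(), "Missing")),
    bin_block("trauma", sprintf("trauma_%02d", 1:10)),
    cat_block("sleep_quality", c("Very poor", "Poor", "Fair", "Good", "Very good")),
    cat_block("socializing_freq", c("Rarely/Never", "Few times a month",
                                    "Once a week", "Several times a week",
                                    "Everyday")),
    cat_block("education", c("Primary", "Secondary", "Vocational", "Bachelor",
                             "Master", "Doctoral")),
    cat_block("employment", c("Employed", "Self-employed", "Student",
                              "Homemaker", "Unemployed", "Retired")),
    cat_block("smoking", c("Never", "Former", "Occasional", "Daily")),
    cat_block("alcohol", c("Never", "Monthly", "Weekly",
                           "Several times a week", "Daily")),
    cat_block("diet_fresh_freq", c("Rarely/Never", "A few times a month",
                                   "A few times a week", "Once a day",
                                   "Several times a day")),
    cat_block("relationship_status", c("Single", "Partnered", "Married",
                                       "Divorced", "Widowed")),
    cat_block("urbanicity", c("Urban", "Suburban", "Rural")),
    cat_block("sleep_hours", c("<5", "5-6", "7-8", ">8")),
    cat_block("device_usage", c("<2h", "2-4h", "4-8h", ">8h")),
    bin_block("medical", sprintf("med_%02d", 1:12)),
    bin_block("substance", sprintf("sub_%02d", 1:6))
  )
}

#' The feature names of the exposure one-hot block
#' @export
upf_feature_columns <- function() paste0("upf_freq=", upf_levels())

#' Build the one-hot feature matrix and label vector
#'
#' @param cohort A scored cohort (the `distressed` column supplies labels;
#'   score with [score_cohort()] first).
#' @param dictionary A [feature_dictionary()] covering every level present.
#' @return A `feature_matrix`: list with `x` (numeric 0/1 matrix, one column
#'   per dictionary feature, deterministic order), `feature_names`, `label`
#'   (logical distressed) and `ids`.
#' @export
build_feature_matrix <- function(cohort, dictionary = NULL) {
  if (!"distressed" %in% names(cohort)) {
    stop("cohort must carry a `distressed` label; run score_cohort() first",
         call. = FALSE)
  }
  if (is.null(dictionary)) {
    dictionary <- feature_dictionary(countries = sort(unique(cohort$country)))
  }
  n <- nrow(cohort)
  x <- matrix(0, n, nrow(dictionary),
              dimnames = list(NULL, dictionary$feature_name))
  for (col in unique(dictionary$column)) {
    rows <- dictionary$column == col
    if (!col %in% names(cohort)) {
      stop("cohort is missing feature column `", col, "`", call. = FALSE)
    }
    if (all(is.na(dictionary$level[rows]))) {      # binary checklist column
      x[, dictionary$feature_name[rows]] <- as.numeric(cohort[[col]])
    } else {
      vals <- cohort[[col]]
      if (col == "income_band") vals[is.na(vals)] <- "Missing"
      bad <- !vals %in% dictionary$level[rows]
      if (any(bad)) {
        stop(sprintf("unseen level '%s' in column `%s` (record %s)",
                     vals[bad][1], col, cohort$id[bad][1]), call. = FALSE)
      }
      idx <- match(paste0(col, "=", vals), dictionary$feature_name)
      x[cbind(seq_len(n), idx)] <- 1
    }
  }
  structure(list(x = x, feature_names = dictionary$feature_name,
                 label = cohort$distressed, ids = cohort$id,
                 dictionary = dictionary),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "records x", ncol(x$x), "features;",
      sum(x$label), "distressed\n")
  invisible(x)
}

subset_fm <- function(fm, rows) {
  structure(list(x = fm$x[rows, , drop = FALSE],
                 feature_names = fm$feature_names,
                 label = fm$label[rows], ids = fm$ids[rows],
                 dictionary = fm$dictionary),
            class = "feature_matrix")
}

drop_features_fm <- function(fm, drop) {
  keep <- setdiff(fm$feature_names, drop)
  if (!length(keep)) stop("cannot drop every feature", call. = FALSE)
  structure(list(x = fm$x[, keep, drop = FALSE], feature_names = keep,
                 label = fm$label, ids = fm$ids, dictionary = fm$dictionary),
            class = "feature_matrix")
}
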