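# Cohort file I/O with a JSON schema sidecar, and the record- and
# country-level exclusion rules with an auditable log.

required_cohort_columns <- function() {
  c("id", "country", "age_group", "sex", item_columns(), "upf_freq",
    "exercise_freq", "income_band", "completion_minutes", "rating_sd",
    "comprehension_ok")
}

cohort_schema <- function(cohort) {
  list(
    columns = lapply(cohort, function(x) class(x)[1]),
    levels = list(
      upf_freq = upf_levels(), exercise_freq = exercise_levels(),
      age_group = age_group_levels(), sex = sex_levels(),
      income_band = income_levels()
    ),
    feature_dictionary = feature_dictionary(countries = sort(unique(cohort$country)))
  )
}

schema_path <- function(path) {
  paste0(sub("\\.(csv|parquet)$", "", path), ".schema.json")
}

#' Write / read a cohort with its JSON schema sidecar
#'
#' The format follows the file extension: `.csv` (via readr) or `.parquet`
#' (via arrow, if installed). A sidecar `<stem>.schema.json` records column
#' types, category level sets and the one-hot feature dictionary; reading
#' requires the sidecar and restores column types from it, so a write/read
#' round trip is the identity on values.
#'
#' @param cohort A cohort tibble.
#' @param path File path ending in `.csv` or `.parquet`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  fmt <- cohort_format(path)
  if (fmt == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("Parquet support needs the 'arrow' package", call. = FALSE)
    }
    arrow::write_parquet(cohort, path)
  } else {
    readr::write_csv(cohort, path, na = "")
  }
  jsonlite::write_json(cohort_schema(cohort), schema_path(path),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  sp <- schema_path(path)
  if (!file.exists(sp)) stop("schema sidecar not found: ", sp, call. = FALSE)
  schema <- jsonlite::read_json(sp)
  fmt <- cohort_format(path)
  if (fmt == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("Parquet support needs the 'arrow' package", call. = FALSE)
    }
    x <- tibble::as_tibble(arrow::read_parquet(path))
  } else {
    types <- vapply(schema$columns, identity, character(1))
    spec <- paste(vapply(types, function(tt) {
      switch(tt, character = "c", numeric = "d", integer = "i", logical = "l", "c")
    }, character(1)), collapse = "")
    x <- readr::read_csv(path, col_types = spec, na = "", progress = FALSE)
  }
  missing_cols <- setdiff(names(schema$columns), names(x))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check <- intersect(required_cohort_columns(), names(schema$columns))
  miss2 <- setdiff(check, names(x))
  if (length(miss2)) {
    stop("cohort file is missing required column(s): ",
         paste(miss2, collapse = ", "), call. = FALSE)
  }
  x
}

cohort_format <- function(path) {
  if (grepl("\\.parquet$", path)) "parquet"
  else if (grepl("\\.csv$", path)) "csv"
  else stop("unsupported cohort format (use .csv or .parquet): ", path,
            call. = FALSE)
}

new_exclusion_log <- function(input_count, kept_count, reasons) {
  counts <- table(factor(reasons$reason,
                         levels = c("SPEEDER", "FLATLINE", "NOT_UNDERSTOOD",
                                    "SMALL_COUNTRY")))
  structure(list(input_count = input_count, kept_count = kept_count,
                 excluded_count = input_count - kept_count,
                 reason_counts = as.list(counts), reasons = reasons),
            class = "exclusion_log")
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion log:", x$input_count, "in,", x$kept_count, "kept,",
      x$excluded_count, "excluded\n")
  for (r in names(x$reason_counts)) {
    if (x$reason_counts[[r]] > 0) cat("  ", r, ":", x$reason_counts[[r]], "\n")
  }
  invisible(x)
}

#' Record-level quality-control exclusions
#'
#' Removes speeders (time to completion under 7 minutes), flat responders
#' (population SD of the 47 ratings under 0.2, recomputed from the item
#' columns) and respondents who reported not understanding the assessment.
#' Boundaries are strict: equality survives. A record may carry several
#' reasons but is excluded once.
#'
#' @param cohort A cohort tibble with QC fields present.
#' @param min_minutes,min_sd Exclusion thresholds (records strictly below are
#'   dropped).
#' @return A list: `kept` (the filtered cohort) and `log` (an
#'   `exclusion_log` with per-record reason codes).
#' @export
apply_record_exclusions <- function(cohort, min_minutes = 7, min_sd = 0.2) {
  qc_fields <- c("completion_minutes", "comprehension_ok")
  miss <- setdiff(qc_fields, names(cohort))
  if (length(miss)) {
    stop("cohort is missing QC field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(item_columns() %in% names(cohort))) {
    stop("cohort is missing item rating columns needed to recompute rating_sd",
         call. = FALSE)
  }
  if (anyNA(cohort$completion_minutes) || anyNA(cohort$comprehension_ok)) {
    stop("QC fields contain missing values; refusing to silently keep records",
         call. = FALSE)
  }
  sd_val <- rating_sd(cohort)
  speeder <- cohort$completion_minutes < min_minutes
  flat <- sd_val < min_sd
  confused <- !cohort$comprehension_ok
  reasons <- rbind(
    data.frame(id = cohort$id[speeder],
               reason = rep("SPEEDER", sum(speeder))),
    data.frame(id = cohort$id[flat],
               reason = rep("FLATLINE", sum(flat))),
    data.frame(id = cohort$id[confused],
               reason = rep("NOT_UNDERSTOOD", sum(confused)))
  )
  keep <- !(speeder | flat | confused)
  list(kept = cohort[keep, , drop = FALSE],
       log = new_exclusion_log(nrow(cohort), sum(keep), reasons))
}

#' Country-level exclusion: drop countries with too few clean responses
#'
#' Applied after record-level QC; countries contributing strictly fewer than
#' `min_n` records are removed entirely (exactly `min_n` survives).
#'
#' @param cohort A (record-clean) cohort tibble.
#' @param min_n Minimum per-country respondent count.
#' @return A list: `kept` and `log`, as for [apply_record_exclusions()].
#' @export
apply_country_exclusions <- function(cohort, min_n = 1000) {
  tab <- table(cohort$country)
  small <- names(tab)[tab < min_n]
  drop <- cohort$country %in% small
  reasons <- data.frame(id = cohort$id[drop],
                        reason = rep("SMALL_COUNTRY", sum(drop)))
  list(kept = cohort[!drop, , drop = FALSE],
       log = new_exclusion_log(nrow(cohort), sum(!drop), reasons))
}
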