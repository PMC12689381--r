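# Dose-response and confound-stratified statistics: the 5 exposure
# categories are coded 1..5 (Rarely/Never = 1 ... Several times a day = 5)
# and treated as numeric for the linear trend; group contrasts use a Welch
# two-sided t-test with no multiple-testing correction (the 47 items measure
# one correlated construct, so independence-based corrections do not apply).

#' Ordinal coding of the exposure categories
#'
#' Rarely/Never = 1; A few times a month = 2; A few times a week = 3;
#' Once a day = 4; Several times a day = 5.
#' @param upf_freq Character vector of category labels.
#' @return Integer vector in 1..5.
#' @export
encode_upf_ordinal <- function(upf_freq) {
  code <- match(upf_freq, upf_levels())
  if (anyNA(code)) {
    bad <- unique(upf_freq[is.na(code)])
    stop("unknown UPF consumption category: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  code
}

#' Ordinary least-squares trend of score on exposure code
#'
#' @param scores Numeric composite scores.
#' @param upf_codes Integer exposure codes (1..5); at least 3 distinct codes
#'   must be present.
#' @return A tibble: `slope` (score points per exposure level), `intercept`,
#'   `p_value` (two-sided, slope = 0), `n`.
#' @export
fit_linear_trend <- function(scores, upf_codes) {
  if (length(scores) != length(upf_codes)) {
    stop("`scores` and `upf_codes` must have equal length", call. = FALSE)
  }
  if (length(unique(upf_codes)) < 3L) {
    stop("trend fit needs at least 3 distinct exposure codes", call. = FALSE)
  }
  fit <- lm(scores ~ upf_codes)
  sm <- summary(fit)$coefficients
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = unname(sm["upf_codes", "Pr(>|t|)"]),
                 n = length(scores))
}

#' Welch two-sided t-test contrast between two groups
#'
#' Degenerate input (zero variance in both groups) returns `p = 1`, `t = 0`
#' when the means are equal, and `p = 0` with infinite `t` otherwise.
#'
#' @param scores_a,scores_b Numeric vectors, each of length >= 2.
#' @return A tibble: `mean_a`, `mean_b`, `difference` (a - b), `t_stat`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
group_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ma <- mean(scores_a); mb <- mean(scores_b)
  if (var(scores_a) == 0 && var(scores_b) == 0) {
    eq <- isTRUE(all.equal(ma, mb))
    t_stat <- if (eq) 0 else sign(ma - mb) * Inf
    p <- if (eq) 1 else 0
  } else {
    ht <- t.test(scores_a, scores_b, var.equal = FALSE)
    t_stat <- unname(ht$statistic); p <- ht$p.value
  }
  tibble::tibble(mean_a = ma, mean_b = mb, difference = ma - mb,
                 t_stat = t_stat, p_value = p,
                 n_a = length(scores_a), n_b = length(scores_b))
}

#' Default high/low stratum definitions for the measured confounders
#'
#' Exercise: frequent = Everyday or Several times a week vs infrequent =
#' Less than once a week or Rarely/Never. Trauma: none vs three or more
#' listed events. Income: top band vs bottom band.
#' @export
default_strata_defs <- function() {
  list(
    exercise = list(
      high = c("Everyday", "Several times a week"),
      low = c("Less than once a week", "Rarely/Never")
    ),
    trauma_count = list(high = 0L, low = 3L),  # high wellbeing = no trauma
    income = list(high = ">100k", low = "<40k")
  )
}

#' Confound-stratified dose-response contrast
#'
#' Splits the scored cohort into a high and a low stratum of one confounder
#' (exercise frequency, trauma/adversity count, or income band), then
#' computes per-stratum mean scores by exposure category, the extreme-category
#' difference (Rarely/Never minus Several times a day), the linear trend, and
#' the per-category vertical offset between the strata (additivity readout).
#'
#' @param cohort A scored cohort (needs `mhq_score`, `upf_freq` and the
#'   stratifier column).
#' @param stratifier One of `"exercise"`, `"trauma_count"`, `"income"`.
#' @param strata_defs As [default_strata_defs()].
#' @return A list: `by_category` (stratum x exposure category means with n),
#'   `summary` (per-stratum trend + extreme-category difference),
#'   `offsets` (per-category high-minus-low mean offsets), and `warnings`
#'   (strata omitted for emptiness).
#' @export
stratified_contrast <- function(cohort, stratifier = c("exercise",
                                                       "trauma_count",
                                                       "income"),
                                strata_defs = default_strata_defs()) {
  stratifier <- match.arg(stratifier)
  if (!"mhq_score" %in% names(cohort)) {
    stop("cohort must be scored first (see score_cohort())", call. = FALSE)
  }
  def <- strata_defs[[stratifier]]
  member <- switch(stratifier,
    exercise = list(high = cohort$exercise_freq %in% def$high,
                    low = cohort$exercise_freq %in% def$low),
    trauma_count = {
      ntr <- rowSums(cohort[, grep("^trauma_\\d+$", names(cohort))])
      list(high = ntr == def$high, low = ntr >= def$low)
    },
    income = list(high = !is.na(cohort$income_band) & cohort$income_band == def$high,
                  low = !is.na(cohort$income_band) & cohort$income_band == def$low)
  )
  by_cat <- list(); summ <- list(); warns <- character()
  for (s in c("high", "low")) {
    sub <- cohort[member[[s]], ]
    if (nrow(sub) == 0) {
      warns <- c(warns, sprintf("stratum '%s' is empty and was omitted", s))
      warning(warns[length(warns)], call. = FALSE)
      next
    }
    code <- encode_upf_ordinal(sub$upf_freq)
    agg <- aggregate(sub$mhq_score, list(code = code),
                     function(v) c(mean = mean(v), n = length(v)))
    by_cat[[s]] <- tibble::tibble(
      stratum = s, upf_code = agg$code, upf_freq = upf_levels()[agg$code],
      mean_score = agg$x[, "mean"], n = agg$x[, "n"]
    )
    tr <- fit_linear_trend(sub$mhq_score, code)
    m1 <- by_cat[[s]]$mean_score[by_cat[[s]]$upf_code == 1L]
    m5 <- by_cat[[s]]$mean_score[by_cat[[s]]$upf_code == 5L]
    summ[[s]] <- tibble::tibble(
      stratum = s, slope = tr$slope, p_value = tr$p_value, n = tr$n,
      extreme_diff = if (length(m1) && length(m5)) m1 - m5 else NA_real_
    )
  }
  by_cat <- dplyr::bind_rows(by_cat)
  offsets <- NULL
  if (all(c("high", "low") %in% by_cat$stratum)) {
    hi <- by_cat[by_cat$stratum == "high", c("upf_code", "mean_score")]
    lo <- by_cat[by_cat$stratum == "low", c("upf_code", "mean_score")]
    both <- merge(hi, lo, by = "upf_code", suffixes = c("_high", "_low"))
    offsets <- tibble::tibble(upf_code = both$upf_code,
                              offset = both$mean_score_high - both$mean_score_low)
  }
  list(by_category = by_cat, summary = dplyr::bind_rows(summ),
       offsets = offsets, warnings = warns)
}
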