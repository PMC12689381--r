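# Two-step post-stratification: within each country, respondents are weighted
# so the age-sex composition matches national demographics (cell weight
# proportional to population share / sample share, calibrated to mean 1);
# between countries, estimates are combined with weights proportional to each
# country's internet-enabled population. Sparse cells are pooled with
# adjacent age bands (and, where a whole country-sex stratum is sparse and a
# region map is supplied, with regional partners) before weighting.

#' A synthetic population table matched to a generator configuration
#'
#' Builds per-(country, age group, sex) population counts from the config's
#' internet-population sizes with a mild systematic age skew relative to the
#' sampling distribution (older bands over-represented in the population), so
#' post-stratification weights are non-trivial. One flat tibble with columns
#' `country`, `age_group`, `sex`, `population`, `internet_population`.
#'
#' @param config A [generative_config()].
#' @export
synthetic_population_table <- function(config) {
  cfg <- validate_generative_config(config)
  skew <- seq(0.85, 1.25, length.out = length(cfg$age_groups))
  age_pop <- cfg$age_probs * skew
  age_pop <- age_pop / sum(age_pop)
  grid <- expand.grid(country = names(cfg$countries),
                      age_group = cfg$age_groups, sex = cfg$sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$population <- round(
    cfg$countries[grid$country] *
      age_pop[match(grid$age_group, cfg$age_groups)] *
      cfg$sex_probs[match(grid$sex, cfg$sexes)]
  )
  grid$internet_population <- unname(cfg$countries[grid$country])
  tibble::as_tibble(grid)
}

#' Per-cell sample counts of a cohort
#' @param cohort A cohort tibble.
#' @export
cell_counts <- function(cohort) {
  dplyr::count(cohort, .data$country, .data$age_group, .data$sex, name = "n")
}

# Greedy pooling of adjacent age bands within one country-sex stratum until
# every pooled group reaches min_cell_n (or a single group remains).
pool_age_bands <- function(n_by_age, min_cell_n) {
  groups <- as.list(seq_along(n_by_age))
  repeat {
    sizes <- vapply(groups, function(g) sum(n_by_age[g]), numeric(1))
    small <- which(sizes < min_cell_n)
    if (!length(small) || length(groups) == 1L) break
    i <- small[1]
    j <- if (i == length(groups)) i - 1L else i + 1L
    merged <- sort(c(groups[[i]], groups[[j]]))
    groups <- groups[-c(i, j)]
    groups <- append(groups, list(merged))
    groups <- groups[order(vapply(groups, min, numeric(1)))]
  }
  groups
}

#' Compute post-stratification cell and country weights
#'
#' Cell weight = (population share / sample share) within country, calibrated
#' so the sample-weighted mean weight is 1 in every country. Cells with fewer
#' than `min_cell_n` respondents are pooled with adjacent age bands of the
#' same country-sex stratum before weighting; if an entire country-sex
#' stratum stays sparse and `region_map` names a region for the country, the
#' stratum is pooled with its regional partners. Country weights are
#' internet-population shares over the countries present.
#'
#' @param sample_counts Tibble from [cell_counts()].
#' @param population_table Tibble from [synthetic_population_table()] (or the
#'   same shape read from CSV).
#' @param min_cell_n Minimum respondents per weighting cell before pooling.
#' @param region_map Optional named character vector country -> region.
#' @return A `weight_table`: list with `cells` (country, age_group, sex,
#'   weight, pool_id), `country_weights` (country, weight summing to 1) and
#'   `pooled_cells` (list of pooled cell groups).
#' @export
compute_cell_weights <- function(sample_counts, population_table,
                                 min_cell_n = 30, region_map = NULL) {
  pt <- population_table
  counts <- sample_counts
  missing_pop <- dplyr::anti_join(counts, pt, by = c("country", "age_group", "sex"))
  if (nrow(missing_pop)) {
    stop("population table lacks cells present in the sample: ",
         paste(missing_pop$country, missing_pop$age_group, missing_pop$sex,
               sep = "/", collapse = "; "), call. = FALSE)
  }
  zero_pop <- dplyr::semi_join(pt[pt$population <= 0, ], counts,
                               by = c("country", "age_group", "sex"))
  if (nrow(zero_pop)) {
    stop("zero population in a cell with sampled respondents", call. = FALSE)
  }
  countries <- sort(unique(counts$country))
  age_order <- intersect(age_group_levels(), unique(pt$age_group))
  if (!length(age_order)) age_order <- sort(unique(pt$age_group))

  cells <- list(); pooled <- list()
  for (co in countries) {
    n_co <- sum(counts$n[counts$country == co])
    if (n_co == 0) stop("empty country in sample counts: ", co, call. = FALSE)
    for (sx in unique(counts$sex[counts$country == co])) {
      n_age <- setNames(rep(0, length(age_order)), age_order)
      sub <- counts[counts$country == co & counts$sex == sx, ]
      n_age[sub$age_group] <- sub$n
      p_age <- setNames(rep(0, length(age_order)), age_order)
      psub <- pt[pt$country == co & pt$sex == sx, ]
      p_age[psub$age_group] <- psub$population

      groups <- pool_age_bands(n_age, min_cell_n)
      for (g in groups) {
        bands <- age_order[g]
        n_g <- sum(n_age[bands]); p_g <- sum(p_age[bands])
        if (n_g == 0) next
        if (length(bands) > 1L) {
          pooled[[length(pooled) + 1L]] <-
            list(country = co, sex = sx, age_groups = bands)
        }
        # raw (uncalibrated) weight: population share over sample share,
        # using within-country totals; calibration below restores mean 1
        w_raw <- (p_g / sum(pt$population[pt$country == co])) / (n_g / n_co)
        cells[[length(cells) + 1L]] <- tibble::tibble(
          country = co, age_group = bands, sex = sx,
          n = unname(n_age[bands]), weight = w_raw,
          pool_id = paste(co, sx, paste(bands, collapse = "+"), sep = ":")
        )
      }
    }
  }
  cells <- dplyr::bind_rows(cells)

  # regional pooling for entirely-sparse country-sex strata
  if (!is.null(region_map)) {
    strat_n <- aggregate(n ~ country + sex, cells, sum)
    sparse <- strat_n[strat_n$n < min_cell_n, ]
    for (k in seq_len(nrow(sparse))) {
      co <- sparse$country[k]; sx <- sparse$sex[k]
      if (is.na(region_map[co])) next
      partners <- names(region_map)[region_map == region_map[co]]
      sel_s <- counts$country %in% partners & counts$sex == sx
      sel_p <- pt$country %in% partners & pt$sex == sx
      n_g <- sum(counts$n[sel_s]); p_g <- sum(pt$population[sel_p])
      n_tot <- sum(counts$n[counts$country %in% partners])
      p_tot <- sum(pt$population[pt$country %in% partners])
      w_raw <- (p_g / p_tot) / (n_g / n_tot)
      cells$weight[cells$country == co & cells$sex == sx] <- w_raw
      cells$pool_id[cells$country == co & cells$sex == sx] <-
        paste("region", region_map[co], sx, sep = ":")
      pooled[[length(pooled) + 1L]] <-
        list(region = unname(region_map[co]), sex = sx, countries = partners)
    }
  }

  # calibrate to sample-weighted mean 1 within country
  for (co in countries) {
    sel <- cells$country == co
    denom <- sum(cells$weight[sel] * cells$n[sel]) / sum(cells$n[sel])
    cells$weight[sel] <- cells$weight[sel] / denom
  }

  ipop <- unique(pt[, c("country", "internet_population")])
  ipop <- ipop[ipop$country %in% countries, ]
  cw <- tibble::tibble(country = ipop$country,
                       weight = ipop$internet_population /
                         sum(ipop$internet_population))
  structure(list(cells = cells, country_weights = cw, pooled_cells = pooled),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Post-stratification weight table:", nrow(x$cells), "cells,",
      nrow(x$country_weights), "countries,", length(x$pooled_cells),
      "pooled group(s)\n")
  invisible(x)
}

#' Attach per-record post-stratification weights
#'
#' Adds a `ps_weight` column (the record's cell weight, mean 1 within
#' country) and a `country_weight` column.
#' @param cohort A cohort tibble.
#' @param weight_table From [compute_cell_weights()].
#' @export
attach_weights <- function(cohort, weight_table) {
  key <- paste(cohort$country, cohort$age_group, cohort$sex)
  ckey <- paste(weight_table$cells$country, weight_table$cells$age_group,
                weight_table$cells$sex)
  idx <- match(key, ckey)
  if (anyNA(idx)) stop("cohort contains cells absent from the weight table",
                       call. = FALSE)
  cohort$ps_weight <- weight_table$cells$weight[idx]
  cidx <- match(cohort$country, weight_table$country_weights$country)
  cohort$country_weight <- weight_table$country_weights$weight[cidx]
  cohort
}

#' Weighted mean or proportion
#'
#' @param values Numeric values, or a logical/0-1 indicator for
#'   `kind = "proportion"`.
#' @param weights Nonnegative weights, same length, positive sum.
#' @param kind `"mean"` or `"proportion"`.
#' @export
weighted_statistic <- function(values, weights, kind = c("mean", "proportion")) {
  kind <- match.arg(kind)
  if (length(values) != length(weights)) {
    stop("`values` and `weights` must have equal length", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  if (kind == "proportion") {
    values <- as.numeric(values)
    if (any(!values %in% c(0, 1))) {
      stop("proportion requires a 0/1 (or logical) indicator", call. = FALSE)
    }
  }
  sum(weights * values) / sum(weights)
}

#' Combine per-country estimates into a global estimate
#'
#' Second weighting step: countries are combined with weights proportional to
#' their internet-enabled population among the countries present in the
#' estimates.
#'
#' @param per_country_estimates Named numeric vector (names = country codes).
#' @param population_table Tibble with `country` and `internet_population`.
#' @export
two_step_aggregate <- function(per_country_estimates, population_table) {
  est <- per_country_estimates
  if (is.null(names(est)) || anyNA(names(est))) {
    stop("per-country estimates must be named by country code", call. = FALSE)
  }
  if (anyNA(est)) {
    stop("missing estimate for country: ",
         paste(names(est)[is.na(est)], collapse = ", "), call. = FALSE)
  }
  ipop <- unique(population_table[, c("country", "internet_population")])
  idx <- match(names(est), ipop$country)
  if (anyNA(idx)) {
    stop("missing estimate/population for country: ",
         paste(names(est)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  w <- ipop$internet_population[idx]
  sum(w * est) / sum(w)
}
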