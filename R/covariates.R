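#' Dietary source categories
#'
#' @return Character vector of the eight dietary source categories used in
#'   ethnographer diet estimates; the last two are the non-foraged sources.
#' @export
diet_sources <- function() {
  c("wild_plants", "large_game", "small_game", "fish_seafood", "insects",
    "honey", "domesticated", "traded_purchased")
}

#' Normalize ethnographer dietary estimates to proportions
#'
#' Ethnographers report per-source daily caloric contributions either as a
#' mean percentage or as a minimum and maximum; min/max pairs collapse to
#' their midpoint before the sources are renormalized to sum to 1.
#'
#' @param estimates Data frame with columns `source` and either `mean_pct` or
#'   both `min_pct` and `max_pct` per row (the unused columns may be `NA`).
#' @return Tibble `source`, `raw_pct`, `proportion`; proportions sum to 1.
#' @export
normalize_diet <- function(estimates) {
  stopifnot("source" %in% names(estimates))
  get <- function(col) {
    if (col %in% names(estimates)) estimates[[col]] else rep(NA_real_, nrow(estimates))
  }
  mean_pct <- get("mean_pct"); min_pct <- get("min_pct"); max_pct <- get("max_pct")
  has_mean <- !is.na(mean_pct)
  has_range <- !is.na(min_pct) & !is.na(max_pct)
  if (any(has_mean & has_range)) {
    stop("provide mean_pct or a min/max pair per source, not both")
  }
  if (any(!has_mean & !has_range)) {
    stop("sources without any intake estimate: ",
         paste(estimates$source[!has_mean & !has_range], collapse = ", "))
  }
  raw <- ifelse(has_mean, mean_pct, (min_pct + max_pct) / 2)
  if (any(raw < 0)) stop("negative dietary intake")
  if (sum(raw) <= 0) stop("all dietary intakes are zero")
  tibble::tibble(source = as.character(estimates$source), raw_pct = raw,
                 proportion = raw / sum(raw))
}

#' Proportion of non-foraged foods
#'
#' The summed dietary proportion of domesticated and traded/purchased foods,
#' the adjustment covariate shared by all models with fixed effects.
#'
#' @param diet Normalized diet table (see [normalize_diet()]).
#' @return A single number in \[0, 1\].
#' @export
prop_non_foraged <- function(diet) {
  stopifnot(abs(sum(diet$proportion) - 1) < 1e-8)
  sum(diet$proportion[diet$source %in% c("domesticated", "traded_purchased")])
}

#' Gendered division of food-production labour
#'
#' Each dietary source carries an ethnographer rating of who produces it, on a
#' 1-5 scale (1 = women only, 5 = men only). The society statistic is the
#' diet-proportion-weighted mean rating recentred to \[-2, 2\]:
#' D = sum_s p_s d_s - 3, so -2 means women do all food-production labour,
#' +2 means men do, and 0 means equal contribution.
#'
#' @param diet Normalized diet table with a `division_score` column (or
#'   supplied separately via `division_score`).
#' @param division_score Optional numeric vector of per-source scores aligned
#'   with `diet$source`.
#' @return A single number in \[-2, 2\].
#' @export
gendered_division <- function(diet, division_score = NULL) {
  d <- if (is.null(division_score)) diet$division_score else division_score
  stopifnot(length(d) == nrow(diet), abs(sum(diet$proportion) - 1) < 1e-8)
  if (any(d < 1 | d > 5)) stop("division scores must lie in [1, 5]")
  sum(diet$proportion * d) - 3
}

#' Classify dangerous-mammal density
#'
#' Site totals of dangerous-mammal population densities split naturally below
#' 1/km^2 (low) and above 10/km^2 (high); totals inside \[1, 10\] have no
#' principled cutpoint and require an explicit analyst decision.
#'
#' @param densities Numeric vector of per-species densities (n/km^2) from the
#'   ethnographer-curated species list.
#' @param manual_class Optional `"low"`/`"high"` override for totals in the
#'   unobserved middle band.
#' @return List with `total` and `class` (factor low/high, low reference).
#' @export
classify_mammal_density <- function(densities, manual_class = NULL) {
  if (length(densities) == 0) {
    warning("empty species list: total density 0, classified low")
    densities <- 0
  }
  if (any(densities < 0)) stop("densities must be non-negative")
  total <- sum(densities)
  cls <- if (total < 1) "low" else if (total > 10) "high" else manual_class
  if (is.null(cls)) {
    stop("total density ", format(total), " lies in [1, 10], outside the ",
         "naturally split bands; supply manual_class = 'low' or 'high'")
  }
  cls <- match.arg(cls, c("low", "high"))
  list(total = total, class = factor(cls, levels = c("low", "high")))
}

check_climate_series <- function(series, window_years) {
  stopifnot(all(c("year", "month", "tmax_c", "tmin_c", "precip_mm") %in%
                  names(series)))
  yrs <- sort(unique(series$year))
  if (!is.null(window_years) && length(yrs) != window_years) {
    stop("climate window has ", length(yrs), " years; expected ", window_years)
  }
  grid <- table(factor(series$month, levels = 1:12), series$year)
  if (any(grid != 1)) {
    gaps <- which(grid != 1, arr.ind = TRUE)
    stop("climate series is not a complete year x month grid; first gap: ",
         "month ", rownames(grid)[gaps[1, 1]], ", year ",
         colnames(grid)[gaps[1, 2]])
  }
  invisible(series)
}

#' Annual mean temperature (BIO1) from a monthly climate series
#'
#' Monthly maxima and minima are first averaged across the window years into
#' 12 climatological months; BIO1 is the mean over those months of
#' (tmax + tmin) / 2. The conventional window is the 30 years preceding and
#' including the most recent year of behavioural data collection.
#'
#' @param series Data frame with `year`, `month` (1-12), `tmax_c`, `tmin_c`,
#'   `precip_mm`; one row per year-month.
#' @param window_years Expected number of years (`NULL` to accept any
#'   complete grid).
#' @return Annual mean temperature in degrees C.
#' @export
bioclim_annual_mean_temp <- function(series, window_years = 30) {
  check_climate_series(series, window_years)
  monthly <- stats::aggregate(cbind(tmax_c, tmin_c) ~ month, series, mean)
  mean((monthly$tmax_c + monthly$tmin_c) / 2)
}

#' Annual precipitation (BIO12) from a monthly climate series
#'
#' Sum over the 12 climatological months of the window-mean monthly totals.
#'
#' @inheritParams bioclim_annual_mean_temp
#' @return Annual precipitation in mm.
#' @export
bioclim_annual_precip <- function(series, window_years = 30) {
  check_climate_series(series, window_years)
  monthly <- stats::aggregate(precip_mm ~ month, series, mean)
  sum(monthly$precip_mm)
}

#' Z-score a society-level covariate
#'
#' Standardizes over the set of society values (one value per society,
#' unweighted, sample standard deviation with n - 1 denominator). Children
#' inherit their society's standardized value downstream.
#'
#' @param x Numeric vector, one value per society.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("zscore needs at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zscore undefined for zero-variance input")
  (x - mean(x)) / s
}

#' Assemble society profiles from raw covariate tables
#'
#' Runs the full covariate construction for every society: diet normalization
#' and the two diet-derived statistics, dangerous-mammal classification,
#' bioclimatic summaries from monthly series (or precomputed values from
#' `static`), and z-scored versions of the continuous covariates.
#'
#' @param diet Long table: `society_id`, `source`, `min_pct`, `max_pct`,
#'   `mean_pct`, `division_score`.
#' @param mammals Long table: `society_id`, `species`, `density_n_per_km2`.
#'   Societies in the \[1, 10\] band need a `manual_class` column.
#' @param static Table: `society_id`, `npp_gc_m2_yr`, `water_rating`, and
#'   optionally precomputed `annual_mean_temp_c`, `annual_precip_mm`.
#' @param climate Optional long monthly series: `society_id`, `year`, `month`,
#'   `tmax_c`, `tmin_c`, `precip_mm`; used for societies without precomputed
#'   bioclim values.
#' @param window_years Climate window length (default 30).
#' @return Tibble, one row per society: `society_id`, `prop_non_foraged`,
#'   `gendered_division`, `npp`, `annual_mean_temp`, `annual_precip`,
#'   `mammal_density_class`, `water_rating`, plus `_z` columns for the four
#'   z-scored continuous covariates.
#' @export
build_society_profiles <- function(diet, mammals, static, climate = NULL,
                                   window_years = 30) {
  stopifnot(all(c("society_id", "npp_gc_m2_yr", "water_rating") %in% names(static)))
  if (!all(static$water_rating %in% 1:4)) stop("water_rating must be 1, 2, 3 or 4")

  per_soc <- lapply(split(diet, diet$society_id), function(d) {
    nd <- normalize_diet(d)
    tibble::tibble(society_id = d$society_id[1],
                   prop_non_foraged = prop_non_foraged(nd),
                   gendered_division = gendered_division(nd, d$division_score))
  })
  diet_tbl <- dplyr::bind_rows(per_soc)

  mam_tbl <- dplyr::bind_rows(lapply(split(mammals, mammals$society_id), function(m) {
    manual <- if ("manual_class" %in% names(m)) m$manual_class[1] else NULL
    cl <- classify_mammal_density(m$density_n_per_km2, manual_class = manual)
    tibble::tibble(society_id = m$society_id[1],
                   mammal_density_total = cl$total,
                   mammal_density_class = cl$class)
  }))

  clim_tbl <- tibble::tibble(society_id = static$society_id,
                             annual_mean_temp = NA_real_,
                             annual_precip = NA_real_)
  if ("annual_mean_temp_c" %in% names(static)) {
    clim_tbl$annual_mean_temp <- static$annual_mean_temp_c
  }
  if ("annual_precip_mm" %in% names(static)) {
    clim_tbl$annual_precip <- static$annual_precip_mm
  }
  if (!is.null(climate)) {
    for (soc in unique(climate$society_id)) {
      s <- climate[climate$society_id == soc, ]
      i <- match(soc, clim_tbl$society_id)
      clim_tbl$annual_mean_temp[i] <- bioclim_annual_mean_temp(s, window_years)
      clim_tbl$annual_precip[i] <- bioclim_annual_precip(s, window_years)
    }
  }
  if (anyNA(clim_tbl$annual_mean_temp) || anyNA(clim_tbl$annual_precip)) {
    stop("missing bioclim values for: ",
         paste(clim_tbl$society_id[is.na(clim_tbl$annual_mean_temp) |
                                     is.na(clim_tbl$annual_precip)],
               collapse = ", "))
  }

  out <- tibble::tibble(society_id = as.character(static$society_id),
                        npp = static$npp_gc_m2_yr,
                        water_rating = as.integer(static$water_rating)) |>
    dplyr::inner_join(diet_tbl, by = "society_id") |>
    dplyr::inner_join(mam_tbl, by = "society_id") |>
    dplyr::inner_join(clim_tbl, by = "society_id")
  add_zscores(out)
}

#' Add z-scored covariate columns to a society profile table
#'
#' @param profiles Society profile tibble with `prop_non_foraged`, `npp`,
#'   `annual_mean_temp`, `annual_precip`.
#' @return The same tibble with `prop_non_foraged_z`, `npp_z`,
#'   `annual_mean_temp_z`, `annual_precip_z` columns (re)computed.
#' @export
add_zscores <- function(profiles) {
  for (col in c("prop_non_foraged", "npp", "annual_mean_temp",
                "annual_precip")) {
    if (col %in% names(profiles)) {
      profiles[[paste0(col, "_z")]] <- zscore(profiles[[col]])
    }
  }
  profiles
}
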