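# shared fixtures, built in code

toy_code_map <- function() {
  activity_code_map(tibble::tibble(
    raw_code = c("P", "F", "D", "C", "O", "PF"),
    categories = c("play", "food_production", "domestic_work", "childcare",
                   "other", "play|food_production")))
}

toy_children <- function() {
  tibble::tibble(
    child_id = c("a1", "a2", "b1", "b2"),
    society_id = c("A", "A", "B", "B"),
    gender = c("girl", "boy", "girl", "boy"),
    age_years = c(5, 10.6, NA, 15),
    age_label = c(NA, NA, "late_juvenile", NA))
}

# monthly climate grid with a deterministic seasonal pattern
toy_climate <- function(years = 2001:2030) {
  grid <- expand.grid(year = years, month = 1:12)
  grid$tmax_c <- 20 + 10 * sin(2 * pi * grid$month / 12) + (grid$year - 2015) * 0.01
  grid$tmin_c <- grid$tmax_c - 8
  grid$precip_mm <- 50 + 30 * cos(2 * pi * grid$month / 12)
  grid
}

# truth for a small, quick model-4-style fit exercising society covariates
small_fit_truth <- function() {
  soc <- tibble::tibble(
    society_id = c("s1", "s2", "s3", "s4"),
    n_children = rep(10L, 4),
    prop_non_foraged = c(0.1, 0.4, 0.6, 0.9),
    mammal_density_class = factor(c("low", "low", "high", "high"),
                                  levels = c("low", "high")),
    water_rating = c(1L, 2L, 1L, 4L))
  spec <- mmbm_spec(4)
  beta <- default_beta(spec)
  beta[, "mammal_density_high"] <- c(-1.2, -0.2, -0.5, 0.2)
  beta[, "water_rating"] <- c(-0.8, 0.0, -0.3, -0.1)
  synthetic_truth(spec = spec, beta = beta,
                  sigma_individual = rep(0.8, 4), sigma_society = rep(0.3, 4),
                  corr_individual = diag(4), corr_society = diag(4),
                  societies = soc, obs_mean = 30, obs_sd = 0)
}

# one cached small fit shared across prediction/inference tests
small_fit_cache <- new.env(parent = emptyenv())
get_small_fit <- function() {
  if (is.null(small_fit_cache$fit)) {
    truth <- small_fit_truth()
    ds <- simulate_time_allocation(truth, seed = 99)
    records <- recode_observations(ds$observations, synthetic_code_map())
    roster <- prepare_children(ds$children)
    small_fit_cache$truth <- truth
    small_fit_cache$fit <- suppressWarnings(mmbm_fit(
      records = records, children = roster, societies = ds$societies,
      spec = truth$spec, chains = 2, iter = 500, warmup = 250, seed = 42))
  }
  small_fit_cache$fit
}
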