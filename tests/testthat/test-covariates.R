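test_that("diet normalization collapses min/max to midpoints and sums to 1", {
  est <- tibble::tibble(
    source = c("wild_plants", "domesticated"),
    mean_pct = c(NA, 85), min_pct = c(10, NA), max_pct = c(20, NA))
  nd <- normalize_diet(est)
  expect_equal(nd$raw_pct[1], 15)  # (10 + 20) / 2
  expect_equal(sum(nd$proportion), 1, tolerance = 1e-12)

  nd2 <- normalize_diet(tibble::tibble(source = c("a", "b"), mean_pct = c(50, 50)))
  expect_equal(nd2$proportion, c(0.5, 0.5))
  nd3 <- normalize_diet(tibble::tibble(source = c("a", "b", "c"),
                                       mean_pct = c(30, 30, 60)))
  expect_equal(nd3$proportion, c(0.25, 0.25, 0.5))

  expect_error(normalize_diet(tibble::tibble(source = "a", mean_pct = 0)), "zero")
  expect_error(normalize_diet(tibble::tibble(source = "a", mean_pct = -5)),
               "negative")
  # scale invariance
  set.seed(3)
  for (i in 1:5) {
    raw <- runif(4, 1, 50)
    a <- normalize_diet(tibble::tibble(source = letters[1:4], mean_pct = raw))
    b <- normalize_diet(tibble::tibble(source = letters[1:4], mean_pct = raw * 7.3))
    expect_equal(a$proportion, b$proportion, tolerance = 1e-12)
  }
})

test_that("proportion of non-foraged food sums domesticated and traded shares", {
  nd <- tibble::tibble(source = c("wild_plants", "domesticated", "traded_purchased"),
                       proportion = c(0.5, 0.3, 0.2))
  expect_equal(prop_non_foraged(nd), 0.5)
  expect_equal(prop_non_foraged(tibble::tibble(source = "wild_plants",
                                               proportion = 1)), 0)
  expect_equal(prop_non_foraged(tibble::tibble(source = "domesticated",
                                               proportion = 1)), 1)
})

test_that("gendered division hits its analytic endpoints and is monotone", {
  two <- function(p, d) {
    gendered_division(tibble::tibble(source = c("a", "b"), proportion = p),
                      division_score = d)
  }
  expect_equal(two(c(0.5, 0.5), c(5, 5)), 2)
  expect_equal(two(c(0.5, 0.5), c(1, 1)), -2)
  expect_equal(two(c(0.5, 0.5), c(1, 5)), 0)
  expect_equal(two(c(0.75, 0.25), c(5, 1)), 1.0)
  expect_error(two(c(0.5, 0.5), c(0.5, 5)), "\\[1, 5\\]")
  # monotone non-decreasing in every score, bounded in [-2, 2]
  set.seed(4)
  for (i in 1:10) {
    p <- runif(3); p <- p / sum(p)
    d <- runif(3, 1, 5)
    base <- gendered_division(tibble::tibble(source = letters[1:3],
                                             proportion = p), d)
    expect_gte(base, -2); expect_lte(base, 2)
    j <- sample(3, 1)
    d2 <- d; d2[j] <- min(5, d2[j] + 0.5)
    expect_gte(gendered_division(tibble::tibble(source = letters[1:3],
                                                proportion = p), d2), base)
  }
})

test_that("mammal density uses the natural low/high split and refuses the middle band", {
  expect_equal(as.character(classify_mammal_density(c(0.2, 0.3))$class), "low")
  hi <- classify_mammal_density(c(12, 4))
  expect_equal(as.character(hi$class), "high")
  expect_equal(hi$total, 16)
  expect_error(classify_mammal_density(3.0), "manual_class")
  expect_equal(as.character(classify_mammal_density(3.0, "high")$class), "high")
  expect_warning(lo <- classify_mammal_density(numeric(0)), "empty")
  expect_equal(as.character(lo$class), "low")
})

test_that("bioclim summaries average monthly climatology then combine", {
  const <- expand.grid(year = 2001:2030, month = 1:12)
  const$tmax_c <- 10; const$tmin_c <- 10; const$precip_mm <- 100
  expect_equal(bioclim_annual_mean_temp(const), 10)
  const$tmax_c <- 20
  expect_equal(bioclim_annual_mean_temp(const), 15)
  expect_equal(bioclim_annual_precip(const), 1200)
  const$precip_mm <- 0
  expect_equal(bioclim_annual_precip(const), 0)

  # hand computation on the seasonal toy series
  s <- toy_climate()
  monthly_mid <- sapply(1:12, function(m) {
    rows <- s[s$month == m, ]
    (mean(rows$tmax_c) + mean(rows$tmin_c)) / 2
  })
  expect_equal(bioclim_annual_mean_temp(s), mean(monthly_mid), tolerance = 1e-12)
  monthly_pr <- sapply(1:12, function(m) mean(s$precip_mm[s$month == m]))
  expect_equal(bioclim_annual_precip(s), sum(monthly_pr), tolerance = 1e-12)

  # gaps and wrong window length are rejected
  expect_error(bioclim_annual_mean_temp(s[-5, ]), "grid")
  expect_error(bioclim_annual_mean_temp(s, window_years = 10), "10")
})

test_that("z-scoring uses the sample SD and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(rep(2, 5)), "zero-variance")
  expect_error(zscore(3), "at least 2")
  set.seed(5)
  x <- rnorm(12, 10, 4)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_equal(zscore(z), z, tolerance = 1e-12)
})

test_that("society profiles assemble from raw tables with z-scored columns", {
  diet <- tibble::tibble(
    society_id = rep(c("A", "B", "C"), each = 2),
    source = rep(c("wild_plants", "domesticated"), 3),
    mean_pct = c(80, 20, 50, 50, 10, 90),
    min_pct = NA_real_, max_pct = NA_real_,
    division_score = rep(c(2, 4), 3))
  mam <- tibble::tibble(society_id = c("A", "A", "B", "C"),
                        species = c("x", "y", "x", "x"),
                        density_n_per_km2 = c(0.2, 0.1, 12, 0.4))
  static <- tibble::tibble(society_id = c("A", "B", "C"),
                           npp_gc_m2_yr = c(800, 1500, 600),
                           water_rating = c(1, 2, 4),
                           annual_mean_temp_c = c(20, 25, -5),
                           annual_precip_mm = c(900, 2000, 400))
  prof <- build_society_profiles(diet, mam, static)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$prop_non_foraged, c(0.2, 0.5, 0.9))
  expect_equal(as.character(prof$mammal_density_class), c("low", "high", "low"))
  expect_lt(abs(mean(prof$npp_z)), 1e-10)
  # monthly series path matches the precomputed path
  clim <- toy_climate()
  clim$society_id <- "A"
  static2 <- static
  static2$annual_mean_temp_c[1] <- NA
  prof2 <- build_society_profiles(diet, mam, static2, climate = clim)
  expect_equal(prof2$annual_mean_temp[prof2$society_id == "A"],
               bioclim_annual_mean_temp(toy_climate()))
})
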