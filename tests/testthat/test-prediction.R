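test_that("credible intervals follow the linear-interpolation percentile rule", {
  ci <- credible_interval(1:100, 0.90)
  expect_equal(unname(ci), c(5.95, 95.05))
  expect_equal(unname(credible_interval(rep(3, 30), 0.89)), c(3, 3))
  expect_error(credible_interval(1:100, 1.2), "level")
  expect_error(credible_interval(1:10, 0.9), "20 samples")
  set.seed(16)
  x <- rnorm(5e4)
  ci89 <- credible_interval(x, 0.89)
  expect_equal(unname(ci89), qnorm(c(0.055, 0.945)), tolerance = 0.03)
  # nesting: a wider level gives a containing interval
  for (i in 1:5) {
    s <- rnorm(200)
    a <- credible_interval(s, 0.89); b <- credible_interval(s, 0.95)
    expect_lte(b[["low"]], a[["low"]])
    expect_gte(b[["high"]], a[["high"]])
  }
})

test_that("median-unit predictions are draw-wise softmax probabilities summing to 1", {
  fit <- get_small_fit()
  prof <- new_profile(age_class = "middle")
  long <- predict_probability(fit, prof)
  sums <- long |>
    dplyr::group_by(.data$.draw) |>
    dplyr::summarise(s = sum(.data$prob))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # with an all-reference profile the draws are the softmax of the intercepts
  prof0 <- new_profile(water_rating = 0)
  long0 <- predict_probability(fit, prof0)
  th <- do.call(rbind, fit$draws)
  beta1 <- matrix(th[1, fit$layout$beta], nrow = 4)
  expect_equal(long0$prob[long0$.draw == 1],
               unname(category_probs(beta1[, 1])), tolerance = 1e-12)
  expect_error(predict_probability(fit, prof[, -1]), "missing inputs")
})

test_that("prediction tables reflect fitted covariate effects", {
  fit <- get_small_fit()
  profs <- dplyr::bind_rows(
    new_profile(age_class = "middle", mammal_density_class = "low"),
    new_profile(age_class = "middle", mammal_density_class = "high"))
  tab <- prediction_table(fit, profs, level = 0.89)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$mean >= 0 & tab$mean <= 1))
  expect_true(all(tab$low <= tab$mean & tab$mean <= tab$high))
  # the generating mammal-density effect on childcare is strongly negative;
  # the fitted prediction must shift the same way
  cc <- tab[tab$category == "childcare", ]
  expect_lt(cc$mean[cc$.profile == 2], cc$mean[cc$.profile == 1])
  # per-profile means sum to one in median-unit mode
  expect_equal(as.numeric(tapply(tab$mean, tab$.profile, sum)), c(1, 1),
               tolerance = 1e-9)
  p <- autoplot(tab, x_var = "mammal_density_class")
  expect_s3_class(p, "ggplot")
})

test_that("marginal predictions shrink the modal category by the Jensen effect", {
  fit <- get_small_fit()
  prof <- new_profile()   # early-childhood girls: play/other dominate
  set.seed(17)
  med <- predict_probability(fit, prof, re_mode = "median_unit")
  mar <- predict_probability(fit, prof, re_mode = "marginal", n_mc = 40)
  m_med <- tapply(med$prob, med$category, mean)
  m_mar <- tapply(mar$prob, mar$category, mean)
  expect_equal(sum(m_mar), 1, tolerance = 1e-6)
  # "other" is the modal category under this profile
  expect_equal(names(which.max(m_med)), "other")
  expect_lt(m_mar[["other"]], m_med[["other"]])
})
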