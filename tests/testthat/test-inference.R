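# brute-force WAIC written directly from its definition
oracle_waic <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  -2 * (lppd - p)
}

test_that("split R-hat distinguishes mixed from separated chains", {
  set.seed(14)
  same <- matrix(rnorm(2000), 1000, 2)
  expect_gt(rhat(same), 0.99)
  expect_lt(rhat(same), 1.02)
  apart <- cbind(rnorm(1000), rnorm(1000, 5))
  expect_gt(rhat(apart), 1.5)
  # a within-chain trend is caught by the split
  trend <- cbind(seq(0, 5, length.out = 500) + rnorm(500, 0, 0.1),
                 seq(0, 5, length.out = 500) + rnorm(500, 0, 0.1))
  expect_gt(rhat(trend), 1.5)
  expect_error(rhat(matrix(rnorm(10), 10, 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(4), 2, 2)), "4 draws")
  expect_equal(rhat(matrix(1, 100, 2)), 1)  # degenerate constant
})

test_that("WAIC follows its closed form and is additive over observations", {
  # one observation, zero-variance draws at log p = log(0.2)
  ll <- matrix(log(0.2), 50, 1)
  w <- waic(ll)
  expect_equal(w$waic, -2 * log(0.2), tolerance = 1e-12)
  expect_equal(w$p_waic, 0)
  # duplicating an observation exactly doubles WAIC
  set.seed(15)
  ll1 <- matrix(rnorm(200, -1.5, 0.2), 50, 4)
  expect_equal(waic(cbind(ll1, ll1))$waic, 2 * waic(ll1)$waic,
               tolerance = 1e-10)
  # matches the brute-force formula on a random matrix
  expect_equal(waic(ll1)$waic, oracle_waic(ll1), tolerance = 1e-10)
  expect_equal(waic(ll1)$p_waic, sum(apply(ll1, 2, var)), tolerance = 1e-12)
  expect_error(waic(matrix(-Inf, 10, 1)), "-Inf")
})

test_that("model weights reproduce the published five-model comparison", {
  waics <- c(176083.7, 176051.5, 176052.3, 176042.9, 176045.9)
  w <- model_weights(waics)
  expect_true(all(abs(w - c(0.00, 0.01, 0.01, 0.81, 0.18)) <= 0.01))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # invariances
  expect_equal(model_weights(waics + 1234.5), w, tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(model_weights(waics[perm]), w[perm], tolerance = 1e-12)
  expect_equal(model_weights(rep(100, 5)), rep(0.2, 5))
  w2 <- model_weights(c(0, 100))
  expect_gt(w2[1], 1 - 1e-10)
})

test_that("duplicate-seeded fits are identical and empty data errors", {
  truth <- small_fit_truth()
  ds <- simulate_time_allocation(truth, seed = 3)
  records <- recode_observations(ds$observations, synthetic_code_map())
  roster <- prepare_children(ds$children)
  f1 <- suppressWarnings(mmbm_fit(records = records, children = roster,
                                  societies = ds$societies, spec = truth$spec,
                                  chains = 2, iter = 200, seed = 77,
                                  save_loglik = FALSE))
  f2 <- suppressWarnings(mmbm_fit(records = records, children = roster,
                                  societies = ds$societies, spec = truth$spec,
                                  chains = 2, iter = 200, seed = 77,
                                  save_loglik = FALSE))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(mmbm_fit(records = records, children = roster,
                                  societies = ds$societies, spec = truth$spec,
                                  chains = 2, iter = 200, seed = 78,
                                  save_loglik = FALSE))
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
  expect_error(mmbm_fit(records = records[0, ], children = roster,
                        societies = ds$societies, spec = truth$spec),
               "no observation records")
})

test_that("a degenerate no-random-effects fit recovers the multinomial MLE logits", {
  # single society, sigma = 0 truth: the intercept-only model's posterior
  # concentrates on log(n_k / n_5)
  spec <- mmbm_spec(1)
  soc <- tibble::tibble(society_id = "only", n_children = 40L)
  truth <- synthetic_truth(spec, default_beta(spec),
                           sigma_individual = rep(0, 4),
                           sigma_society = rep(0, 4),
                           corr_individual = diag(4), corr_society = diag(4),
                           societies = soc, obs_mean = 50, obs_sd = 0)
  ds <- simulate_time_allocation(truth, seed = 21)
  records <- recode_observations(ds$observations, synthetic_code_map())
  roster <- prepare_children(ds$children)
  fit <- mmbm_fit(records = records, children = roster,
                  societies = ds$societies, spec = spec, chains = 2,
                  iter = 600, seed = 5, re = "none", save_loglik = FALSE)
  counts <- table(factor(records$category, levels = activity_categories()))
  mle <- log(counts[1:4] / counts[5])
  est <- summarize_fixed_effects(fit)
  expect_true(all(abs(est$mean - mle) < 3 * est$sd))
})

test_that("fixed-effect and random-effect summaries agree with direct computation", {
  fit <- get_small_fit()
  est <- summarize_fixed_effects(fit)
  th <- do.call(rbind, fit$draws)
  j <- 3  # beta[domestic_work, intercept]
  expect_equal(est$mean[j], mean(th[, j]))
  expect_equal(est$sd[j], sd(th[, j]))
  expect_equal(unname(c(est$ci_low[j], est$ci_high[j])),
               unname(quantile(th[, j], c(0.025, 0.975))))
  expect_equal(est$excludes_zero[j],
               unname(quantile(th[, j], 0.025) > 0 | quantile(th[, j], 0.975) < 0))
  re <- random_effect_summary(fit)
  expect_equal(nrow(re), 20)  # 4 sigmas + 6 correlations per level
  expect_true(all(re$mean[grepl("sigma", re$parameter)] > 0))
  rho_rows <- grepl("rho", re$parameter)
  expect_true(all(re$ci_low[rho_rows] >= -1 & re$ci_high[rho_rows] <= 1))
  # tidy/glance mirror the summaries
  expect_equal(tidy(fit), est)
  g <- glance(fit)
  expect_equal(g$n_children, 40)
  expect_true(is.finite(g$waic))
  # WAIC via weighted cells equals WAIC on the expanded observation matrix
  ll_cells <- fit$loglik_cells
  counts <- as.vector(ll_cells$counts)
  expanded <- ll_cells$logprob[, rep(seq_along(counts), counts), drop = FALSE]
  expect_equal(waic(fit)$waic, waic(expanded)$waic, tolerance = 1e-8)
  cmp <- compare_models(fits = list(model4 = fit))
  expect_equal(cmp$weight, 1)
})

test_that("a draws-table round trip preserves summaries bit for bit", {
  fit <- get_small_fit()
  dir <- withr::local_tempdir()
  write_draws(fit, dir)
  back <- read_draws(dir)
  fit2 <- fit
  fit2$draws <- lapply(back$draws, function(d) d[, colnames(fit$draws[[1]])])
  expect_identical(summarize_fixed_effects(fit2), summarize_fixed_effects(fit))
  expect_identical(random_effect_summary(fit2), random_effect_summary(fit))
  expect_equal(back$meta$diagnostics$divergences,
               fit$diagnostics$divergences)
})
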