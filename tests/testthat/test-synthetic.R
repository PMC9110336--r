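test_that("generation is deterministic given the seed", {
  truth <- recovery_default_truth()
  a <- simulate_time_allocation(truth, seed = 31)
  b <- simulate_time_allocation(truth, seed = 31)
  expect_identical(a$observations, b$observations)
  expect_identical(a$children, b$children)
  c <- simulate_time_allocation(truth, seed = 32)
  expect_false(identical(a$observations, c$observations))
  # files written are byte-identical across same-seed runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(a, d1); write_synthetic_dataset(b, d2)
  for (f in c("observations.csv", "children.csv", "society_profiles.csv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the study-scale design reproduces the sample structure", {
  truth <- default_study_design()
  ds <- simulate_time_allocation(truth, seed = 33)
  expect_equal(nrow(ds$children), 690)
  expect_equal(length(unique(ds$children$society_id)), 12)
  expect_true(all(table(ds$children$society_id) >= 1))
  # girl fraction: per-society expectation, binomial tolerance
  p_exp <- sum(truth$societies$n_children * truth$societies$pct_girls / 100) / 690
  se <- sqrt(p_exp * (1 - p_exp) / 690)
  expect_lt(abs(mean(ds$children$gender == "girl") - p_exp), 3 * se)
  # observation counts: heavy-tailed, mean near the study's 124
  counts <- table(ds$observations$child_id)
  expect_lt(abs(mean(counts) - 124.05), 3 * 160.88 / sqrt(690))
  expect_gt(sd(counts), 80)  # right-skewed spread, not a narrow bell
  # dual-coding rate ~ 2.6%
  dual <- grepl("|", ds$observations$raw_code, fixed = TRUE)
  expect_equal(mean(dual), 0.026, tolerance = 0.005)
  # records expand by exactly the number of dual codes
  rec <- recode_observations(ds$observations, synthetic_code_map())
  expect_equal(nrow(rec), nrow(ds$observations) + sum(dual))
})

test_that("category draws follow the per-child generating probabilities", {
  spec <- mmbm_spec(1)
  soc <- tibble::tibble(society_id = c("A", "B"), n_children = c(5L, 5L))
  truth <- synthetic_truth(spec, matrix(c(-3, -1.5, -1, 0.5), 4, 1),
                           sigma_individual = rep(0.7, 4),
                           sigma_society = rep(0.4, 4),
                           corr_individual = rlkj(4, 2),
                           corr_society = rlkj(4, 2),
                           societies = soc, obs_mean = 400, obs_sd = 0)
  set.seed(34)
  ds <- simulate_time_allocation(truth, seed = 34)
  rec <- recode_observations(ds$observations, synthetic_code_map())
  pr <- child_proportions(rec)
  for (i in seq_len(nrow(ds$children))) {
    cid <- ds$children$child_id[i]
    p_true <- ds$latent$probs[i, ]
    p_emp <- pr$proportion[pr$child_id == cid][
      match(activity_categories(), pr$category[pr$child_id == cid])]
    se <- sqrt(p_true * (1 - p_true) / 400)
    expect_true(all(abs(p_emp - p_true) < 4 * se + 1e-9))
  }
  # degenerate truths
  t0 <- synthetic_truth(spec, matrix(0, 4, 1), rep(0, 4), rep(0, 4),
                        diag(4), diag(4), soc, obs_mean = 500, obs_sd = 0)
  ds0 <- simulate_time_allocation(t0, seed = 35)
  rec0 <- recode_observations(ds0$observations, synthetic_code_map())
  freq <- table(rec0$category) / nrow(rec0)
  expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / nrow(rec0))))
  tneg <- synthetic_truth(spec, matrix(c(-20, 0, 0, 0), 4, 1), rep(0, 4),
                          rep(0, 4), diag(4), diag(4), soc,
                          obs_mean = 200, obs_sd = 0)
  dsn <- simulate_time_allocation(tneg, seed = 36)
  recn <- recode_observations(dsn$observations, synthetic_code_map())
  expect_equal(sum(recn$category == "childcare"), 0)
})

test_that("generated random effects converge to the target covariance", {
  set.seed(37)
  sigma <- c(0.5, 1, 1.5, 0.8)
  corr <- rlkj(4, 2)
  omega <- diag(sigma) %*% corr %*% diag(sigma)
  nu <- timealloc:::draw_random_effects(1e4, sigma, corr)
  emp <- crossprod(nu) / nrow(nu)
  expect_lt(norm(emp - omega, "F") / norm(omega, "F"), 0.10)
})

test_that("a small recovery run reports coverage and diagnostics per replicate", {
  soc <- tibble::tibble(society_id = c("p", "q", "r", "s"),
                        n_children = rep(6L, 4),
                        prop_non_foraged = c(0.2, 0.4, 0.6, 0.8))
  truth <- synthetic_truth(mmbm_spec(2), default_beta(mmbm_spec(2)),
                           sigma_individual = rep(0.8, 4),
                           sigma_society = rep(0.3, 4),
                           corr_individual = diag(4), corr_society = diag(4),
                           societies = soc, obs_mean = 20, obs_sd = 0)
  rep1 <- suppressWarnings(recovery_experiment(truth, n_replicates = 2,
                                               seed = 9, chains = 2,
                                               iter = 250, warmup = 125))
  expect_equal(nrow(rep1$per_replicate), 2)
  expect_true(all(rep1$per_replicate$coverage >= 0 &
                    rep1$per_replicate$coverage <= 1))
  expect_equal(nrow(rep1$per_parameter), 28)
  expect_true(rep1$aggregate$n_converged <= 2)
})
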