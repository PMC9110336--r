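# independent baseline-category softmax, written directly from its definition
oracle_softmax <- function(eta) {
  e <- exp(c(eta, 0))
  e / sum(e)
}

test_that("category probabilities match an independent softmax oracle", {
  expect_equal(unname(category_probs(rep(0, 4))), rep(0.2, 5))
  # reference category dominates when all log-odds are very negative
  p <- category_probs(rep(-30, 4))
  expect_gt(p[["other"]], 1 - 1e-10)
  # published intercept-only posterior means
  eta <- c(-4.12, -2.23, -2.07, -1.37)
  expect_equal(unname(category_probs(eta)), oracle_softmax(eta),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    eta <- runif(4, -30, 30)
    p <- category_probs(eta)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p), oracle_softmax(eta), tolerance = 1e-9)
    # logit/softmax round trip
    expect_equal(unname(log(p[1:4] / p[5])), eta, tolerance = 1e-10)
  }
  expect_error(category_probs(c(NA, 0, 0, 0)), "NaN")
  # matrix form agrees with row-wise evaluation
  m <- matrix(rnorm(12), 3, 4)
  pm <- category_probs(m)
  expect_equal(unname(pm[2, ]), unname(category_probs(m[2, ])))
})

test_that("the linear predictor is the term-by-term sum of its pieces", {
  spec <- mmbm_spec(2)
  M <- length(spec$terms)
  set.seed(9)
  params <- mmbm_params(
    beta = matrix(rnorm(4 * M), 4, M),
    sigma_individual = runif(4, 0.5, 2), sigma_society = runif(4, 0.1, 1),
    corr_individual = rlkj(4, 2), corr_society = rlkj(4, 2),
    z_individual = matrix(rnorm(12), 3, 4),
    z_society = matrix(rnorm(8), 2, 4))
  x <- c(1, rnorm(M - 1))
  eta <- linear_predictor(spec, params, x, child_index = 2, society_index = 1)
  nu_i <- noncentered_reconstruct(params$z_individual, params$sigma_individual,
                                  params$corr_individual)
  nu_s <- noncentered_reconstruct(params$z_society, params$sigma_society,
                                  params$corr_society)
  manual <- sapply(1:4, function(k) sum(params$beta[k, ] * x)) +
    nu_i[2, ] + nu_s[1, ]
  expect_equal(eta, manual, tolerance = 1e-12)
  # all-zero covariates and random effects give the intercepts
  p0 <- params
  p0$z_individual[] <- 0; p0$z_society[] <- 0
  expect_equal(linear_predictor(spec, p0, c(1, rep(0, M - 1)), 1, 1),
               unname(params$beta[, 1]))
  # linearity in beta
  p1 <- params
  p1$beta[3, 2] <- p1$beta[3, 2] + 0.7
  expect_equal(linear_predictor(spec, p1, x, 2, 1)[3] - eta[3], 0.7 * x[2])
  expect_error(linear_predictor(spec, params, x[-1], 2, 1), "mismatch")
  # pointwise log-likelihood is the log softmax entry
  ll <- pointwise_loglik(spec, params, x, 2, 1, "domestic_work")
  expect_equal(ll, log(oracle_softmax(eta)[3]), tolerance = 1e-10)
  expect_equal(pointwise_loglik(spec, p0, c(1, rep(0, M - 1)) * 0, 1, 1, "play"),
               log(0.2))
})

test_that("non-centered reconstruction reproduces the target covariance", {
  expect_equal(noncentered_reconstruct(matrix(0, 5, 4), rep(1, 4), diag(4)),
               matrix(0, 5, 4))
  z <- matrix(rnorm(40), 10, 4)
  expect_equal(noncentered_reconstruct(z, rep(1, 4), diag(4)), z)
  set.seed(10)
  sigma <- c(1, 2, 0.5, 1)
  corr <- rlkj(4, 2)
  omega <- diag(sigma) %*% corr %*% diag(sigma)
  nu <- noncentered_reconstruct(matrix(rnorm(4e5), 1e5, 4), sigma, corr)
  emp <- crossprod(nu) / nrow(nu)
  expect_lt(norm(emp - omega, "F") / norm(omega, "F"), 0.05)
  bad <- matrix(0.99, 4, 4); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(noncentered_reconstruct(z, sigma, bad), "positive semi-definite")
})

test_that("log-prior matches closed-form densities and flags out-of-support scales", {
  spec <- mmbm_spec(1)
  pr <- mmbm_priors()
  params <- mmbm_params(beta = matrix(0, 4, 1),
                        sigma_individual = rep(1, 4), sigma_society = rep(1, 4),
                        corr_individual = diag(4), corr_society = diag(4),
                        z_individual = matrix(0, 2, 4),
                        z_society = matrix(0, 2, 4))
  # at the all-zero mode each beta contributes the normal mode density
  expect_equal(log_prior(params, pr),
               4 * dnorm(0, 0, 2.5, log = TRUE) + 8 * dexp(1, 1, log = TRUE) +
                 16 * dnorm(0, log = TRUE))
  # doubling one sigma changes the log-prior by the analytic ratio
  p2 <- params; p2$sigma_individual[2] <- 2
  expect_equal(log_prior(p2, pr) - log_prior(params, pr),
               dexp(2, 1, log = TRUE) - dexp(1, 1, log = TRUE))
  # LKJ at the identity is the (unnormalized) zero point
  expect_equal(lkj_log_density(diag(4), 2), 0)
  R <- rlkj(4, 2)
  expect_equal(lkj_log_density(R, 2), log(det(R)))
  p3 <- params; p3$sigma_society[1] <- -1
  expect_equal(log_prior(p3, pr), -Inf)
})

test_that("the CPC parameterization samples the LKJ distribution", {
  # marginal of any correlation under LKJ(eta), K = 4: (r+1)/2 ~ Beta(3, 3)
  set.seed(12)
  rs <- replicate(4000, rlkj(4, 2)[2, 1])
  expect_lt(abs(mean(rs)), 0.02)
  expect_equal(var(rs), 1 / 7, tolerance = 0.05)
  ks <- suppressWarnings(ks.test((rs + 1) / 2, function(q) pbeta(q, 3, 3)))
  expect_gt(ks$p.value, 0.01)
  # transform round trip
  for (i in 1:10) {
    y <- rnorm(6)
    L <- timealloc:::cpc_to_cholesky(y)
    expect_equal(timealloc:::cholesky_to_cpc(L), y, tolerance = 1e-6)
    R <- tcrossprod(L)
    expect_equal(diag(R), rep(1, 4), tolerance = 1e-12)
    expect_true(min(eigen(R, symmetric = TRUE)$values) > 0)
  }
})

test_that("the compiled log-posterior gradient matches finite differences", {
  set.seed(13)
  n <- 7; J <- 3; M <- 2
  Y <- matrix(rpois(n * 5, 3), n, 5) * 1.0
  X <- cbind(1, rnorm(n))
  soc <- sample(1:J, n, replace = TRUE)
  for (re in c(1L, 0L)) {
    D <- if (re) 4 * M + 20 + 4 * n + 4 * J else 4 * M
    th <- rnorm(D, 0, 0.4)
    r <- timealloc:::mmbm_lp_grad(th, Y, X, soc, J, 2.5, 1, 2, re)
    h <- 1e-5
    num <- vapply(seq_len(D), function(t) {
      tp <- th; tm <- th
      tp[t] <- tp[t] + h; tm[t] <- tm[t] - h
      (timealloc:::mmbm_lp_grad(tp, Y, X, soc, J, 2.5, 1, 2, re)$lp -
         timealloc:::mmbm_lp_grad(tm, Y, X, soc, J, 2.5, 1, 2, re)$lp) / (2 * h)
    }, numeric(1))
    expect_equal(r$grad, num, tolerance = 1e-5)
  }
})
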