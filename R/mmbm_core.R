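#' Prior configuration
#'
#' Weakly informative defaults for a logit-scale hierarchical model: fixed
#' effects Normal(0, 2.5), random-effect scales Exponential(1), correlation
#' matrices LKJ(2).
#'
#' @param beta_sd SD of the zero-mean normal prior on fixed effects.
#' @param sigma_rate Rate of the exponential prior on random-effect SDs.
#' @param lkj_eta LKJ shape for the two 4x4 correlation matrices.
#' @return List of class `mmbm_priors`.
#' @export
mmbm_priors <- function(beta_sd = 2.5, sigma_rate = 1, lkj_eta = 2) {
  stopifnot(beta_sd > 0, sigma_rate > 0, lkj_eta > 0)
  structure(list(beta_sd = beta_sd, sigma_rate = sigma_rate,
                 lkj_eta = lkj_eta), class = "mmbm_priors")
}

#' Model parameters
#'
#' Container for one parameter state of the multilevel multinomial model:
#' fixed effects, random-effect scales and correlations at the individual and
#' society level, and the standardized (non-centered) random-effect draws.
#'
#' @param beta 4 x M matrix of fixed effects (rows: the four non-reference
#'   categories in [activity_categories()] order; columns: spec terms).
#' @param sigma_individual,sigma_society Positive length-4 vectors.
#' @param corr_individual,corr_society 4x4 correlation matrices.
#' @param z_individual n_children x 4 matrix of standardized effects.
#' @param z_society n_societies x 4 matrix of standardized effects.
#' @return List of class `mmbm_params`.
#' @export
mmbm_params <- function(beta, sigma_individual, sigma_society,
                        corr_individual, corr_society,
                        z_individual, z_society) {
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == 4, length(sigma_individual) == 4,
            length(sigma_society) == 4,
            all(sigma_individual > 0), all(sigma_society > 0))
  check_corr(corr_individual); check_corr(corr_society)
  stopifnot(ncol(z_individual) == 4, ncol(z_society) == 4)
  structure(list(beta = beta,
                 sigma_individual = as.numeric(sigma_individual),
                 sigma_society = as.numeric(sigma_society),
                 corr_individual = corr_individual,
                 corr_society = corr_society,
                 z_individual = as.matrix(z_individual),
                 z_society = as.matrix(z_society)),
            class = "mmbm_params")
}

check_corr <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == 4, ncol(R) == 4)
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("correlation matrix diagonal must be 1")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  invisible(R)
}

#' Reconstruct random effects from their non-centered form
#'
#' The sampler works with standardized draws z ~ Normal(0, I); actual random
#' effects are nu = z (diag(sigma) L)' with L the lower Cholesky factor of
#' the correlation matrix, so that rows of nu have covariance
#' Omega = diag(sigma) corr diag(sigma).
#'
#' @param z n x 4 matrix of standardized draws.
#' @param sigma Positive length-4 vector of scales.
#' @param corr 4x4 correlation matrix.
#' @return n x 4 matrix of random effects.
#' @export
noncentered_reconstruct <- function(z, sigma, corr) {
  check_corr(corr)
  L <- t(chol(corr))          # lower triangular, L %*% t(L) = corr
  z <- as.matrix(z)
  stopifnot(ncol(z) == 4, length(sigma) == 4)
  z %*% t(diag(as.numeric(sigma)) %*% L)
}

#' Linear predictor for one child
#'
#' Log-odds of each non-reference category against "other activities":
#' eta_k = beta_k' x + nu_individual\[i, k\] + nu_society\[j, k\]. The
#' reference category's log-odds are pinned at zero.
#'
#' @param spec An [mmbm_spec()].
#' @param params An [mmbm_params()].
#' @param x Named numeric vector of covariate values, ordered as `spec$terms`.
#' @param child_index Row of `z_individual` for this child.
#' @param society_index Row of `z_society` for this child's society.
#' @return Length-4 numeric vector of log-odds.
#' @export
linear_predictor <- function(spec, params, x, child_index, society_index) {
  if (length(x) != length(spec$terms) || ncol(params$beta) != length(spec$terms)) {
    stop("covariate/term length mismatch: spec has ", length(spec$terms),
         " terms, x has ", length(x), ", beta has ", ncol(params$beta))
  }
  nu_i <- noncentered_reconstruct(params$z_individual, params$sigma_individual,
                                  params$corr_individual)
  nu_s <- noncentered_reconstruct(params$z_society, params$sigma_society,
                                  params$corr_society)
  as.numeric(params$beta %*% x) + nu_i[child_index, ] + nu_s[society_index, ]
}

#' Category probabilities from log-odds
#'
#' Baseline-category softmax with the fifth (reference) logit pinned at 0,
#' stabilized by subtracting max(0, eta) before exponentiation.
#'
#' @param eta Length-4 vector, or an n x 4 matrix of log-odds.
#' @return Length-5 probability vector (or n x 5 matrix) summing to 1 per row,
#'   ordered as [activity_categories()].
#' @export
category_probs <- function(eta) {
  if (is.null(dim(eta))) {
    if (anyNA(eta)) stop("NaN/NA in log-odds")
    m <- max(0, eta)
    e <- exp(eta - m)
    denom <- exp(-m) + sum(e)
    return(stats::setNames(c(e, exp(-m)) / denom, activity_categories()))
  }
  eta <- as.matrix(eta)
  stopifnot(ncol(eta) == 4)
  if (anyNA(eta)) stop("NaN/NA in log-odds")
  m <- pmax(0, apply(eta, 1, max))
  e <- exp(eta - m)
  ref <- exp(-m)
  denom <- ref + rowSums(e)
  out <- cbind(e, ref) / denom
  colnames(out) <- activity_categories()
  out
}

#' Pointwise log-likelihood of one observation record
#'
#' Each coded observation follows a categorical (generalized Bernoulli)
#' distribution over the five activities with probabilities from
#' [category_probs()] applied to the child's [linear_predictor()].
#'
#' @inheritParams linear_predictor
#' @param category Observed category (one of [activity_categories()]).
#' @return Log probability of the observed category.
#' @export
pointwise_loglik <- function(spec, params, x, child_index, society_index,
                             category) {
  k <- match(category, activity_categories())
  if (is.na(k)) stop("invalid category: ", category)
  eta <- linear_predictor(spec, params, x, child_index, society_index)
  unname(log(category_probs(eta)[k]))
}

#' LKJ log-density of a correlation matrix (unnormalized)
#'
#' log p(R) = (eta - 1) log det R + const; the constant is omitted.
#'
#' @param corr Correlation matrix.
#' @param eta LKJ shape (> 0); eta = 1 is uniform over correlation matrices.
#' @return Unnormalized log density.
#' @export
lkj_log_density <- function(corr, eta) {
  check_corr(corr)
  (eta - 1) * determinant(corr, logarithm = TRUE)$modulus[[1]]
}

#' Joint log-prior of a parameter state
#'
#' Fixed effects are iid Normal(0, beta_sd); random-effect SDs iid
#' Exponential(sigma_rate); correlation matrices LKJ(lkj_eta) (unnormalized);
#' standardized random effects iid standard normal. Out-of-support sigma
#' returns -Inf.
#'
#' @param params An [mmbm_params()].
#' @param priors An [mmbm_priors()].
#' @return Log prior density (up to the LKJ normalizing constant).
#' @export
log_prior <- function(params, priors = mmbm_priors()) {
  if (any(params$sigma_individual <= 0) || any(params$sigma_society <= 0)) {
    return(-Inf)
  }
  sum(stats::dnorm(params$beta, 0, priors$beta_sd, log = TRUE)) +
    sum(stats::dexp(params$sigma_individual, priors$sigma_rate, log = TRUE)) +
    sum(stats::dexp(params$sigma_society, priors$sigma_rate, log = TRUE)) +
    lkj_log_density(params$corr_individual, priors$lkj_eta) +
    lkj_log_density(params$corr_society, priors$lkj_eta) +
    sum(stats::dnorm(params$z_individual, log = TRUE)) +
    sum(stats::dnorm(params$z_society, log = TRUE))
}

# --- canonical-partial-correlation (CPC) transform ------------------------
# The sampler parameterizes each correlation Cholesky factor by 6
# unconstrained numbers y; w = tanh(y) are canonical partial correlations and
# L is built row-wise: L[i,j] = w[i,j] * prod_{m<j} sqrt(1 - w[i,m]^2),
# L[i,i] = prod_{m<i} sqrt(1 - w[i,m]^2). Under LKJ(eta), the w in column j
# are independent 2*Beta(a_j, a_j) - 1 with a_j = eta + (K - 1 - j) / 2.

cpc_index <- function(K = 4) {
  idx <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

#' @keywords internal
cpc_to_cholesky <- function(y, K = 4) {
  idx <- cpc_index(K)
  w <- matrix(0, K, K)
  w[idx] <- tanh(y)
  L <- matrix(0, K, K)
  L[1, 1] <- 1
  for (i in 2:K) {
    prod_s <- 1
    for (j in seq_len(i - 1)) {
      L[i, j] <- w[i, j] * prod_s
      prod_s <- prod_s * sqrt(1 - w[i, j]^2)
    }
    L[i, i] <- prod_s
  }
  L
}

#' @keywords internal
cholesky_to_cpc <- function(L) {
  K <- nrow(L)
  idx <- cpc_index(K)
  w <- matrix(0, K, K)
  for (i in 2:K) {
    prod_s <- 1
    for (j in seq_len(i - 1)) {
      w[i, j] <- L[i, j] / prod_s
      prod_s <- prod_s * sqrt(max(1 - w[i, j]^2, 1e-12))
    }
  }
  atanh(pmin(pmax(w[idx], -1 + 1e-9), 1 - 1e-9))
}

#' Sample a correlation matrix from the LKJ distribution
#'
#' Draws via independent scaled-Beta canonical partial correlations, the
#' construction the sampler's unconstrained parameterization is based on.
#'
#' @param K Dimension.
#' @param eta LKJ shape.
#' @return A K x K correlation matrix.
#' @export
rlkj <- function(K = 4, eta = 2) {
  idx <- cpc_index(K)
  a <- eta + (K - 1 - idx[, "col"]) / 2
  w <- 2 * stats::rbeta(nrow(idx), a, a) - 1
  L <- cpc_to_cholesky(atanh(w), K)
  R <- L %*% t(L)
  (R + t(R)) / 2
}
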