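param_layout <- function(M, n, J, re_mode, terms = NULL) {
  cats <- activity_categories()[1:4]
  if (is.null(terms)) terms <- paste0("x", seq_len(M))
  beta_names <- as.vector(outer(cats, terms, function(k, m)
    paste0("beta[", k, ",", m, "]")))
  if (re_mode == 0L) {
    return(list(D = 4L * M, beta = seq_len(4L * M), names = beta_names))
  }
  o <- 4L * M
  pairs <- cpc_index(4)
  idx <- list(
    beta = seq_len(o),
    lam_i = o + 1:4, lam_s = o + 5:8,
    y_i = o + 9:14, y_s = o + 15:20,
    z_i = o + 20L + seq_len(4L * n),
    z_s = o + 20L + 4L * n + seq_len(4L * J))
  idx$D <- o + 20L + 4L * n + 4L * J
  idx$names <- c(
    beta_names,
    paste0("sigma_individual[", cats, "]"),
    paste0("sigma_society[", cats, "]"),
    paste0("y_corr_individual[", pairs[, 1], ",", pairs[, 2], "]"),
    paste0("y_corr_society[", pairs[, 1], ",", pairs[, 2], "]"),
    paste0("z_individual[", rep(seq_len(n), 4), ",", rep(1:4, each = n), "]"),
    paste0("z_society[", rep(seq_len(J), 4), ",", rep(1:4, each = J), "]"))
  idx
}

#' Fit a multilevel multinomial behavioural model
#'
#' Samples the joint posterior by Hamiltonian Monte Carlo with a non-centered
#' parameterization of the correlated random effects (standard-normal draws
#' scaled through the Cholesky factor of each covariance matrix). The default
#' sampling plan is 3 chains of 2000 iterations with the first half discarded
#' as warmup; convergence requires all split R-hat below 1.01 and zero
#' post-warmup divergences, and fits failing either are flagged with a
#' warning.
#'
#' @param data An [mmbm_data()] object (or pass `records`, `children`,
#'   `societies` to build one).
#' @param spec An [mmbm_spec()]; ignored when `data` is given.
#' @param records,children,societies Raw tables, used when `data` is `NULL`.
#' @param chains,iter,warmup Sampling plan (defaults 3 x 2000, half warmup).
#' @param seed Master seed; per-chain randomness is derived deterministically.
#' @param priors An [mmbm_priors()].
#' @param re `"both"` for individual + society random effects (the model), or
#'   `"none"` for a fixed-effects-only fit (used for degenerate oracle
#'   checks).
#' @param max_treedepth Maximum doubling depth of a NUTS trajectory
#'   (up to 2^depth leapfrog steps).
#' @param cond_sweeps Number of conditional-move sweeps (latent-field slice
#'   updates and interweaving) composed with each NUTS update.
#' @param updates_per_iter Number of NUTS-plus-conditional-move updates
#'   composing one recorded iteration of the transition kernel.
#' @param interweave_period Apply the centered re-draw of the scales and
#'   correlations every this many iterations (0 disables it).
#' @param target_accept Dual-averaging acceptance target.
#' @param save_loglik Keep the pointwise log-likelihood draws needed for
#'   WAIC (per child x category cell, expanded on demand).
#' @return Object of class `mmbm_fit`.
#' @export
mmbm_fit <- function(data = NULL, spec = NULL, records = NULL, children = NULL,
                     societies = NULL, chains = 3, iter = 2000,
                     warmup = floor(iter / 2), seed = 1,
                     priors = mmbm_priors(), re = c("both", "none"),
                     max_treedepth = 10, target_accept = 0.95,
                     cond_sweeps = 3, interweave_period = 1, updates_per_iter = 3,
                     save_loglik = TRUE) {
  re <- match.arg(re)
  re_mode <- if (re == "both") 1L else 0L
  if (is.null(data)) {
    if (is.null(records) || is.null(children) || is.null(societies)) {
      stop("supply either `data` or all of records/children/societies")
    }
    data <- mmbm_data(records, children, societies, spec)
  }
  if (nrow(data$Y) == 0) stop("empty dataset")
  n <- nrow(data$Y); J <- length(data$society_id); M <- ncol(data$X)
  lay <- param_layout(M, n, J, re_mode, terms = data$spec$terms)

  set.seed(seed)
  # start intercepts near the pooled empirical logits; everything else near 0
  pooled <- colSums(data$Y) + 0.5
  logit0 <- log(pooled[1:4] / pooled[5])
  int_pos <- match("intercept", data$spec$terms)
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- stats::rnorm(lay$D, 0, 0.1)
    init[4L * (int_pos - 1L) + 1:4] <- logit0 + stats::rnorm(4, 0, 0.2)
    runs[[ch]] <- mmbm_hmc_chain(
      Y = data$Y * 1.0, X = data$X, society = data$society, n_society = J,
      beta_sd = priors$beta_sd, sigma_rate = priors$sigma_rate,
      lkj_eta = priors$lkj_eta, re_mode = re_mode, init = init,
      iter = as.integer(iter), warmup = as.integer(warmup),
      max_treedepth = as.integer(max_treedepth), target_accept = target_accept,
      cond_sweeps = as.integer(cond_sweeps),
      interweave_period = as.integer(interweave_period),
      updates_per_iter = as.integer(updates_per_iter))
  }
  draws <- lapply(runs, `[[`, "draws")
  for (ch in seq_len(chains)) colnames(draws[[ch]]) <- lay$names
  divergences <- sum(vapply(runs, `[[`, numeric(1), "divergences"))

  rh <- rhat_all(draws)
  # the convergence rule is applied to the reported parameters on their
  # natural scale (fixed effects, random-effect SDs, correlations); the
  # standardized latent effects are monitored but enter the summaries only
  # through those
  rh_rep <- rhat_reported(draws, lay, re_mode)
  max_rhat <- max(rh_rep)
  converged <- is.finite(max_rhat) && max_rhat < 1.01 && divergences == 0

  fit <- structure(list(
    draws = draws, layout = lay, data = data, spec = data$spec, priors = priors,
    meta = list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                re = re, max_treedepth = max_treedepth,
                target_accept = target_accept,
                step_size = vapply(runs, `[[`, numeric(1), "step_size"),
                accept_rate = vapply(runs, `[[`, numeric(1), "accept_rate")),
    diagnostics = list(rhat = rh, rhat_reported = rh_rep,
                       max_rhat = max_rhat, max_rhat_all = max(rh),
                       divergences = divergences, converged = converged)
  ), class = "mmbm_fit")
  if (save_loglik) fit$loglik_cells <- cell_logprob_draws(fit)
  if (!converged) {
    warning("fit did not meet the convergence rule (max split R-hat ",
            format(round(max_rhat, 4)), ", ", divergences,
            " divergent iterations); interpret summaries with caution",
            call. = FALSE)
  }
  fit
}

#' @export
print.mmbm_fit <- function(x, ...) {
  cat("<mmbm_fit> model", x$spec$model_id, "|", nrow(x$data$Y), "children,",
      length(x$data$society_id), "societies,", x$data$n_obs, "observations\n")
  cat("  ", x$meta$chains, "chains x", x$meta$iter, "iterations (warmup ",
      x$meta$warmup, "), random effects:", x$meta$re, "\n")
  cat("   max split R-hat", format(round(x$diagnostics$max_rhat, 4)),
      "|", x$diagnostics$divergences, "divergences |",
      if (x$diagnostics$converged) "converged" else "NOT CONVERGED", "\n")
  invisible(x)
}

# stacked post-warmup draws with chain/iteration bookkeeping
stacked_draws <- function(fit) {
  do.call(rbind, fit$draws)
}

#' Split R-hat for a single parameter
#'
#' Each chain is split in half and the classic potential-scale-reduction
#' statistic is computed over the resulting half-chains.
#'
#' @param x Matrix of draws, iterations x chains (at least 2 chains or a
#'   single chain is an error; at least 4 draws per chain).
#' @return R-hat value; `Inf` when within-chain variance is zero (treated as
#'   failing).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("rhat needs at least 2 chains")
  if (nrow(x) < 4) stop("rhat needs at least 4 draws per chain")
  half <- floor(nrow(x) / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  m <- ncol(splits); n_it <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- n_it * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n_it - 1) / n_it * W + B / n_it) / W)
}

# split R-hat of the reported parameters on their natural scale
rhat_reported <- function(draws_list, lay, re_mode) {
  nat <- lapply(draws_list, function(d) {
    if (re_mode == 0L) return(d[, lay$beta, drop = FALSE])
    pairs <- cpc_index(4)
    rho <- function(cols) {
      t(apply(d[, cols, drop = FALSE], 1,
              function(y) tcrossprod(cpc_to_cholesky(y))[pairs]))
    }
    cbind(d[, lay$beta, drop = FALSE],
          exp(d[, c(lay$lam_i, lay$lam_s), drop = FALSE]),
          rho(lay$y_i), rho(lay$y_s))
  })
  out <- vapply(seq_len(ncol(nat[[1]])), function(j) {
    rhat(vapply(nat, function(d) d[, j], numeric(nrow(nat[[1]]))))
  }, numeric(1))
  cats <- activity_categories()[1:4]
  pairs <- cpc_index(4)
  nm <- lay$names[lay$beta]
  if (re_mode == 1L) {
    nm <- c(nm,
            paste0("sigma_individual[", cats, "]"),
            paste0("sigma_society[", cats, "]"),
            paste0("rho_individual[", pairs[, 1], ",", pairs[, 2], "]"),
            paste0("rho_society[", pairs[, 1], ",", pairs[, 2], "]"))
  }
  stats::setNames(out, nm)
}

rhat_all <- function(draws_list) {
  D <- ncol(draws_list[[1]])
  out <- vapply(seq_len(D), function(j) {
    rhat(vapply(draws_list, function(d) d[, j], numeric(nrow(draws_list[[1]]))))
  }, numeric(1))
  names(out) <- colnames(draws_list[[1]])
  out
}

# per-draw, per-child log-probabilities of all 5 categories
# returns list(logprob = draws x (n*5) matrix, counts = n x 5)
cell_logprob_draws <- function(fit) {
  d <- fit$data
  n <- nrow(d$Y); M <- ncol(d$X); J <- length(d$society_id)
  lay <- fit$layout
  th <- stacked_draws(fit)
  S <- nrow(th)
  out <- matrix(NA_real_, S, n * 5L)
  re_on <- fit$meta$re == "both"
  for (s in seq_len(S)) {
    beta <- matrix(th[s, lay$beta], nrow = 4)
    eta <- d$X %*% t(beta)
    if (re_on) {
      sig_i <- exp(th[s, lay$lam_i]); sig_s <- exp(th[s, lay$lam_s])
      L_i <- cpc_to_cholesky(th[s, lay$y_i]); L_s <- cpc_to_cholesky(th[s, lay$y_s])
      z_i <- matrix(th[s, lay$z_i], nrow = n)
      z_s <- matrix(th[s, lay$z_s], nrow = J)
      nu_i <- z_i %*% t(diag(sig_i) %*% L_i)
      nu_s <- z_s %*% t(diag(sig_s) %*% L_s)
      eta <- eta + nu_i + nu_s[d$society, , drop = FALSE]
    }
    mx <- pmax(0, apply(eta, 1, max))
    lse <- mx + log(exp(-mx) + rowSums(exp(eta - mx)))
    out[s, ] <- as.vector(cbind(eta, 0) - lse)
  }
  list(logprob = out, counts = d$Y)
}

#' Widely applicable information criterion
#'
#' WAIC on the deviance scale: waic = -2 (lppd - p_waic), with
#' lppd = sum_i log mean_s exp(loglik\[s, i\]) and p_waic the summed
#' across-draw variances of the pointwise log-likelihood. The standard error
#' comes from the pointwise waic contributions.
#'
#' @param x Either a draws x observations matrix of pointwise log-likelihoods,
#'   or an `mmbm_fit` (which must have been fit with `save_loglik = TRUE`).
#' @param ... Unused.
#' @return List with `waic`, `p_waic`, `se`, `lppd`, and `pointwise` (the
#'   per-observation waic contributions).
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.default <- function(x, ...) {
  ll <- as.matrix(x)
  if (!all(is.finite(apply(ll, 2, max)))) {
    stop("some observations have -Inf log-likelihood in every draw")
  }
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, stats::var)
  pointwise <- -2 * (lppd_i - p_i)
  waic <- sum(pointwise)
  se <- sqrt(length(lppd_i) * stats::var(pointwise))
  list(waic = waic, p_waic = sum(p_i), se = se, lppd = sum(lppd_i),
       pointwise = pointwise)
}

#' @rdname waic
#' @export
waic.mmbm_fit <- function(x, ...) {
  if (is.null(x$loglik_cells)) {
    stop("fit was run with save_loglik = FALSE; refit to compute WAIC")
  }
  ll <- x$loglik_cells$logprob
  counts <- as.vector(x$loglik_cells$counts)
  keep <- counts > 0
  # every observation in a (child, category) cell has an identical pointwise
  # log-likelihood; weight cell contributions by their observation counts
  ll <- ll[, keep, drop = FALSE]
  w <- counts[keep]
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_c <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_c <- apply(ll, 2, stats::var)
  pw_c <- -2 * (lppd_c - p_c)
  n_obs <- sum(w)
  mean_pw <- sum(w * pw_c) / n_obs
  var_pw <- sum(w * (pw_c - mean_pw)^2) / (n_obs - 1)
  list(waic = sum(w * pw_c), p_waic = sum(w * p_c), se = sqrt(n_obs * var_pw),
       lppd = sum(w * lppd_c), pointwise = NULL)
}

#' Akaike-style model weights from WAIC values
#'
#' w_i = exp(-0.5 (waic_i - min)) / sum_j exp(-0.5 (waic_j - min));
#' invariant to adding a constant to all WAICs.
#'
#' @param waics Numeric vector of WAIC values (deviance scale).
#' @return Numeric weights summing to 1.
#' @export
model_weights <- function(waics) {
  stopifnot(length(waics) >= 1, any(is.finite(waics)))
  d <- waics - min(waics, na.rm = TRUE)
  w <- exp(-0.5 * d)
  w / sum(w)
}

#' Compare fitted models by WAIC
#'
#' @param ... Named or unnamed `mmbm_fit` objects.
#' @param fits Alternatively, a list of fits.
#' @return Tibble with `model`, `waic`, `se`, `p_waic`, `weight`, sorted as
#'   given.
#' @export
compare_models <- function(..., fits = NULL) {
  if (is.null(fits)) fits <- list(...)
  stopifnot(length(fits) >= 1)
  nm <- names(fits)
  if (is.null(nm) || any(nm == "")) {
    nm <- vapply(fits, function(f) paste0("model", f$spec$model_id), character(1))
  }
  ws <- lapply(fits, waic)
  tibble::tibble(
    model = nm,
    waic = vapply(ws, `[[`, numeric(1), "waic"),
    se = vapply(ws, `[[`, numeric(1), "se"),
    p_waic = vapply(ws, `[[`, numeric(1), "p_waic"),
    weight = unname(model_weights(vapply(ws, `[[`, numeric(1), "waic"))))
}

#' Posterior summaries of fixed effects
#'
#' One row per (category, term): posterior mean, SD, equal-tailed credible
#' interval, and a flag for intervals excluding zero (the bolding rule of the
#' coefficient tables).
#'
#' @param fit An `mmbm_fit`.
#' @param prob Interval probability (default 0.95).
#' @return Tibble `category`, `term`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `excludes_zero`.
#' @export
summarize_fixed_effects <- function(fit, prob = 0.95) {
  th <- stacked_draws(fit)[, fit$layout$beta, drop = FALSE]
  cats <- activity_categories()[1:4]
  terms <- fit$spec$terms
  a <- (1 - prob) / 2
  grid <- expand.grid(category = cats, term = terms, stringsAsFactors = FALSE)
  qs <- apply(th, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  tibble::tibble(
    category = factor(grid$category, levels = cats),
    term = factor(grid$term, levels = terms),
    mean = unname(colMeans(th)),
    sd = unname(apply(th, 2, stats::sd)),
    ci_low = unname(qs[1, ]),
    ci_high = unname(qs[2, ]),
    excludes_zero = unname(qs[1, ] > 0 | qs[2, ] < 0))
}

#' Posterior summaries of random-effect scales and correlations
#'
#' @param fit An `mmbm_fit` with random effects.
#' @param prob Interval probability.
#' @return Tibble `level` (individual/society), `parameter` (`sigma[k]` or
#'   `rho[k,l]`), `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
random_effect_summary <- function(fit, prob = 0.95) {
  if (fit$meta$re != "both") stop("fit has no random effects")
  th <- stacked_draws(fit)
  lay <- fit$layout
  cats <- activity_categories()[1:4]
  pairs <- cpc_index(4)
  a <- (1 - prob) / 2
  one_level <- function(level, lam_idx, y_idx) {
    sig <- exp(th[, lam_idx, drop = FALSE])
    rho <- t(apply(th[, y_idx, drop = FALSE], 1, function(y) {
      R <- tcrossprod(cpc_to_cholesky(y))
      R[pairs]
    }))
    vals <- cbind(sig, rho)
    nm <- c(paste0("sigma[", cats, "]"),
            paste0("rho[", cats[pairs[, 1]], ",", cats[pairs[, 2]], "]"))
    qs <- apply(vals, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    tibble::tibble(level = level, parameter = nm, mean = colMeans(vals),
                   sd = apply(vals, 2, stats::sd),
                   ci_low = qs[1, ], ci_high = qs[2, ])
  }
  dplyr::bind_rows(one_level("individual", lay$lam_i, lay$y_i),
                   one_level("society", lay$lam_s, lay$y_s))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy method for fitted models
#'
#' @param x An `mmbm_fit`.
#' @param prob Credible-interval probability.
#' @param ... Unused.
#' @return The [summarize_fixed_effects()] tibble.
#' @export
tidy.mmbm_fit <- function(x, prob = 0.95, ...) {
  summarize_fixed_effects(x, prob = prob)
}

#' Glance method for fitted models
#'
#' @param x An `mmbm_fit`.
#' @param ... Unused.
#' @return One-row tibble with sizes, WAIC (if available) and diagnostics.
#' @export
glance.mmbm_fit <- function(x, ...) {
  w <- if (!is.null(x$loglik_cells)) waic(x) else list(waic = NA_real_, p_waic = NA_real_)
  tibble::tibble(
    model = x$spec$model_id, n_obs = x$data$n_obs,
    n_children = nrow(x$data$Y), n_societies = length(x$data$society_id),
    waic = w$waic, p_waic = w$p_waic,
    max_rhat = x$diagnostics$max_rhat,
    divergences = x$diagnostics$divergences,
    converged = x$diagnostics$converged)
}

#' Extract posterior draws on the natural scale
#'
#' @param fit An `mmbm_fit`.
#' @return Tibble with `.chain`, `.iteration`, fixed effects
#'   (`beta[category,term]`), and for random-effect fits `sigma_*` and
#'   `rho_*` columns.
#' @export
as_draws_df <- function(fit) {
  lay <- fit$layout
  th <- stacked_draws(fit)
  keep <- nrow(fit$draws[[1]])
  out <- tibble::as_tibble(as.data.frame(th[, lay$beta, drop = FALSE]),
                           .name_repair = "minimal")
  names(out) <- lay$names[lay$beta]
  if (fit$meta$re == "both") {
    cats <- activity_categories()[1:4]
    pairs <- cpc_index(4)
    for (lv in c("individual", "society")) {
      lam <- if (lv == "individual") lay$lam_i else lay$lam_s
      yy <- if (lv == "individual") lay$y_i else lay$y_s
      sig <- exp(th[, lam, drop = FALSE])
      colnames(sig) <- paste0("sigma_", lv, "[", cats, "]")
      rho <- t(apply(th[, yy, drop = FALSE], 1, function(y) {
        tcrossprod(cpc_to_cholesky(y))[pairs]
      }))
      colnames(rho) <- paste0("rho_", lv, "[", cats[pairs[, 1]], ",",
                              cats[pairs[, 2]], "]")
      out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(sig)),
                              tibble::as_tibble(as.data.frame(rho)))
    }
  }
  dplyr::bind_cols(
    tibble::tibble(.chain = rep(seq_along(fit$draws), each = keep),
                   .iteration = rep(seq_len(keep), length(fit$draws))),
    out)
}

#' Write posterior draws to disk
#'
#' Serializes the unconstrained draws as a long-format CSV (`chain`,
#' `iteration`, `parameter`, `value`) plus a JSON sidecar with the sampling
#' configuration and diagnostics, enough to reproduce or re-summarize the
#' fit.
#'
#' @param fit An `mmbm_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keep <- nrow(fit$draws[[1]])
  long <- purrr::imap_dfr(fit$draws, function(d, ch) {
    tibble::tibble(
      chain = as.integer(ch),
      iteration = rep(seq_len(keep), ncol(d)),
      parameter = rep(colnames(d), each = keep),
      # 17 significant digits: doubles survive the text round trip exactly
      value = sprintf("%.17g", as.vector(d)))
  })
  readr::write_csv(long, file.path(dir, "draws_long.csv"))
  jsonlite::write_json(list(
    spec_terms = fit$spec$terms, model_id = fit$spec$model_id,
    meta = fit$meta,
    priors = unclass(fit$priors),
    diagnostics = list(max_rhat = fit$diagnostics$max_rhat,
                       divergences = fit$diagnostics$divergences,
                       converged = fit$diagnostics$converged)),
    file.path(dir, "fit_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param dir Directory containing `draws_long.csv` and `fit_meta.json`.
#' @return List with `draws` (per-chain matrices, as in an `mmbm_fit`) and
#'   `meta` (the JSON sidecar).
#' @export
read_draws <- function(dir) {
  # base R's strtod parsing is correctly rounded, keeping the text round
  # trip exact to the bit
  long <- utils::read.csv(file.path(dir, "draws_long.csv"),
                          colClasses = c(chain = "integer",
                                         iteration = "integer",
                                         parameter = "character",
                                         value = "numeric"))
  params <- unique(long$parameter)
  draws <- lapply(split(long, long$chain), function(ch) {
    m <- matrix(ch$value, ncol = length(params))
    colnames(m) <- params
    m
  })
  names(draws) <- NULL
  list(draws = draws,
       meta = jsonlite::read_json(file.path(dir, "fit_meta.json")))
}
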