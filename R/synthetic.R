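#' Society covariates of the twelve-society study design
#'
#' The default synthetic design mirrors the structure of the cross-cultural
#' study sample: twelve foraging societies with their published child counts,
#' percent girls, net primary productivity, bioclimatic values, ecological
#' risk ratings, diet composition and gendered division of labour.
#'
#' @return Tibble, one row per society.
#' @export
default_society_covariates <- function() {
  tibble::tibble(
    society_id = c("Agta", "Aka", "Baka", "BaYaka", "Dukha", "Hadza",
                   "Matsigenka", "Maya", "Mayangna", "Mikea", "Pume",
                   "Tsimane"),
    n_children = c(15L, 50L, 14L, 53L, 15L, 18L, 119L, 49L, 114L, 31L, 31L, 181L),
    pct_girls = c(33, 52, 50, 42, 53, 78, 61, 59, 46, 48, 52, 52),
    npp = c(1389.7, 886.7, 1120, 969.6, 142.4, 601, 2438.6, 540, 1220.5,
            1191.6, 524.7, 1952.5),
    annual_mean_temp = c(25.23, 24.76, 24.16, 24.81, -6.71, 21.44, 17.71,
                         26.20, 25.89, 23.73, 27.77, 26.11),
    annual_precip = c(2653.69, 1551.03, 1570.26, 1616.51, 411.20, 673.74,
                      834.53, 1058.72, 2715.84, 516.36, 2069.46, 1829.21),
    mammal_density_class = factor(
      c("low", "high", "high", "high", "low", "high", "low", "low", "low",
        "low", "low", "low"), levels = c("low", "high")),
    water_rating = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L, 4L, 1L, 2L),
    prop_non_foraged = c(0.50, 0.49, 0.30, 0.30, 0.86, 0.05, 0.97, 0.94,
                         0.77, 0.45, 0.07, 0.77),
    gendered_division = c(0.02, -0.08, -0.15, 0.20, -0.19, 0.18, 0.99, 1.02,
                          0.99, -0.02, -0.64, 0.43))
}

#' Default generating truth for the study-scale design
#'
#' Generating parameters for synthetic datasets that emulate the study:
#' twelve societies, 690 children (52% girls overall, per-society counts from
#' the study sample), age classes roughly 30/45/25% across early/middle/
#' adolescent, heavily unbalanced observation counts (lognormal matched by
#' moments to mean 124, SD 161, truncated at 1), and a small dual-coding rate
#' (2.6% of observations carry two concurrent categories). Fixed effects
#' default to the individual-level model's published posterior means; scales
#' and correlations are field-realistic choices (individual SD 1, society SD
#' 0.5, exchangeable correlation 0.2).
#'
#' @param spec An [mmbm_spec()] naming the generating fixed effects.
#' @return Object of class `synthetic_truth`.
#' @export
default_study_design <- function(spec = mmbm_spec(2)) {
  soc <- default_society_covariates()
  truth <- synthetic_truth(
    spec = spec,
    beta = default_beta(spec),
    sigma_individual = rep(1, 4), sigma_society = rep(0.5, 4),
    corr_individual = exchangeable_corr(0.2),
    corr_society = exchangeable_corr(0.2),
    societies = soc,
    age_probs = c(early = 0.30, middle = 0.45, adolescent = 0.25),
    obs_mean = 124.05, obs_sd = 160.88, dual_rate = 0.026)
  truth
}

#' Published individual-level fixed effects as generating values
#'
#' Posterior-mean coefficients of the individual-level model (gender, age
#' class, their interaction and the shared diet adjustment), used as default
#' generating truth so synthetic data resemble the field data in scale.
#'
#' @param spec An [mmbm_spec()]; terms outside the individual-level model get
#'   zero coefficients.
#' @return 4 x M matrix (categories x terms).
#' @export
default_beta <- function(spec = mmbm_spec(2)) {
  vals <- rbind(
    # intercept   boy  middle   ado  boy:mid boy:ado  pnf_z
    c(-4.11, -1.18, 1.33, 1.80, -0.39, -1.19, 0.09),   # childcare
    c(-3.03,  0.05, 0.92, 1.26,  0.27,  0.55, -0.45),  # food production
    c(-2.83, -0.12, 1.49, 2.10, -0.66, -0.92, 0.09),   # domestic work
    c(-1.08,  0.67, -0.33, -2.18, -0.22, 0.82, -0.13)) # play
  base_terms <- c("intercept", "boy", "middle", "adolescent", "boy:middle",
                  "boy:adolescent", "prop_non_foraged_z")
  colnames(vals) <- base_terms
  out <- matrix(0, 4, length(spec$terms),
                dimnames = list(activity_categories()[1:4], spec$terms))
  shared <- intersect(spec$terms, base_terms)
  out[, shared] <- vals[, shared]
  out
}

#' @keywords internal
exchangeable_corr <- function(rho, K = 4) {
  R <- matrix(rho, K, K); diag(R) <- 1; R
}

#' Construct a synthetic generating truth
#'
#' @param spec An [mmbm_spec()].
#' @param beta 4 x M matrix of generating fixed effects (columns follow
#'   `spec$terms`).
#' @param sigma_individual,sigma_society Length-4 non-negative scales.
#' @param corr_individual,corr_society 4x4 correlation matrices.
#' @param societies Tibble with `society_id`, `n_children`, and every
#'   covariate column the spec's terms need (natural scale; z-scores are
#'   computed at generation time). An optional `pct_girls` column overrides
#'   `p_girl` per society.
#' @param p_girl Overall probability a child is a girl (used when
#'   `societies$pct_girls` is absent).
#' @param age_probs Named length-3 probability vector over age classes.
#' @param obs_mean,obs_sd Moments of the lognormal observations-per-child
#'   distribution (truncated at 1). Set `obs_sd = 0` for a fixed count.
#' @param dual_rate Fraction of observations carrying a second concurrent
#'   category.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(spec, beta, sigma_individual, sigma_society,
                            corr_individual, corr_society, societies,
                            p_girl = 0.52,
                            age_probs = c(early = 0.30, middle = 0.45,
                                          adolescent = 0.25),
                            obs_mean = 124.05, obs_sd = 160.88,
                            dual_rate = 0) {
  stopifnot(inherits(spec, "mmbm_spec"),
            nrow(beta) == 4, ncol(beta) == length(spec$terms),
            length(sigma_individual) == 4, all(sigma_individual >= 0),
            length(sigma_society) == 4, all(sigma_society >= 0),
            all(c("society_id", "n_children") %in% names(societies)),
            all(societies$n_children >= 1),
            abs(sum(age_probs) - 1) < 1e-8, obs_mean >= 1,
            dual_rate >= 0, dual_rate < 1)
  check_corr(corr_individual); check_corr(corr_society)
  structure(list(spec = spec, beta = beta,
                 sigma_individual = as.numeric(sigma_individual),
                 sigma_society = as.numeric(sigma_society),
                 corr_individual = corr_individual,
                 corr_society = corr_society,
                 societies = tibble::as_tibble(societies),
                 p_girl = p_girl, age_probs = age_probs,
                 obs_mean = obs_mean, obs_sd = obs_sd, dual_rate = dual_rate),
            class = "synthetic_truth")
}

# lognormal parameters matched by moments, truncated at >= 1 by rounding up
draw_obs_counts <- function(n, mean, sd) {
  if (sd <= 0) return(rep(as.integer(round(mean)), n))
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

# multivariate normal via the same non-centered construction the model uses
draw_random_effects <- function(n, sigma, corr) {
  noncentered_reconstruct(matrix(stats::rnorm(4 * n), n, 4), sigma, corr)
}

#' The synthetic activity code map
#'
#' Maps single-category codes to themselves and pipe-joined dual codes to
#' their two categories, matching the raw codes the generator emits.
#'
#' @return An [activity_code_map()].
#' @export
synthetic_code_map <- function() {
  singles <- activity_categories()
  # dual codes are emitted with their two categories alphabetically sorted
  duals <- utils::combn(singles, 2, function(x) paste(sort(x), collapse = "|"))
  activity_code_map(tibble::tibble(raw_code = c(singles, duals),
                                   categories = c(singles, duals)))
}

#' Generate a synthetic time-allocation dataset
#'
#' Runs the model's generative process forward with known parameters: society
#' random effects, a child roster with gender/age structure and unbalanced
#' observation counts, child random effects, linear predictors, and
#' categorical draws; a configurable fraction of observations receives a
#' second concurrent category (emitted as a pipe-joined dual raw code).
#'
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List of class `synthetic_dataset`: `observations` (society_id,
#'   child_id, obs_index, raw_code), `children` (roster), `societies`
#'   (profile table with z-scored covariates), `truth`, and `latent`
#'   (`nu_individual`, `nu_society`, `probs` - the per-child generating
#'   category probabilities).
#' @export
simulate_time_allocation <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  soc <- truth$societies
  J <- nrow(soc)
  # z-score continuous covariates over the design's societies, if present
  for (col in c("prop_non_foraged", "npp", "annual_mean_temp", "annual_precip")) {
    zc <- paste0(col, "_z")
    if (col %in% names(soc) && !(zc %in% names(soc))) soc[[zc]] <- zscore(soc[[col]])
  }

  n_children <- sum(soc$n_children)
  society_id <- rep(soc$society_id, soc$n_children)
  child_id <- sprintf("%s_c%03d", society_id,
                      unlist(lapply(soc$n_children, seq_len)))
  p_girl <- if ("pct_girls" %in% names(soc)) {
    rep(soc$pct_girls / 100, soc$n_children)
  } else rep(truth$p_girl, n_children)
  gender <- ifelse(stats::runif(n_children) < p_girl, "girl", "boy")
  age_class <- sample(names(truth$age_probs), n_children, replace = TRUE,
                      prob = truth$age_probs)
  bounds <- list(early = c(3, 6), middle = c(7, 12), adolescent = c(13, 18))
  age_years <- vapply(age_class, function(a) {
    b <- bounds[[a]]; b[1] + floor(stats::runif(1) * (b[2] - b[1] + 1))
  }, numeric(1))

  children <- tibble::tibble(child_id = child_id, society_id = society_id,
                             gender = gender, age_years = age_years,
                             age_label = NA_character_)
  roster <- prepare_children(children)
  d <- dplyr::inner_join(roster, soc, by = "society_id")
  X <- vapply(truth$spec$terms, term_column, numeric(n_children), d = d)
  X <- matrix(X, nrow = n_children)

  nu_s <- draw_random_effects(J, truth$sigma_society, truth$corr_society)
  nu_i <- draw_random_effects(n_children, truth$sigma_individual,
                              truth$corr_individual)
  soc_idx <- match(society_id, soc$society_id)
  eta <- X %*% t(truth$beta) + nu_i + nu_s[soc_idx, , drop = FALSE]
  probs <- category_probs(eta)

  n_obs <- draw_obs_counts(n_children, truth$obs_mean, truth$obs_sd)
  cats <- activity_categories()
  obs <- vector("list", n_children)
  for (i in seq_len(n_children)) {
    k <- sample.int(5, n_obs[i], replace = TRUE, prob = probs[i, ])
    raw <- cats[k]
    if (truth$dual_rate > 0) {
      dual <- stats::runif(n_obs[i]) < truth$dual_rate
      if (any(dual)) {
        raw[dual] <- vapply(k[dual], function(k1) {
          p2 <- probs[i, ]; p2[k1] <- 0
          k2 <- sample.int(5, 1, prob = p2 / sum(p2))
          paste(sort(cats[c(k1, k2)]), collapse = "|")
        }, character(1))
      }
    }
    obs[[i]] <- tibble::tibble(society_id = society_id[i],
                               child_id = child_id[i],
                               obs_index = seq_len(n_obs[i]), raw_code = raw)
  }
  # dual codes were sorted alphabetically; align map keys the same way
  structure(list(
    observations = dplyr::bind_rows(obs),
    children = children,
    societies = soc,
    truth = truth,
    latent = list(nu_individual = nu_i, nu_society = nu_s, probs = probs)
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to CSV + JSON
#'
#' Emits `observations.csv`, `children.csv`, `society_profiles.csv` in the
#' ingestion schemas plus `truth.json` with the generating parameters.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$observations, file.path(dir, "observations.csv"))
  readr::write_csv(dataset$children, file.path(dir, "children.csv"))
  readr::write_csv(dataset$societies, file.path(dir, "society_profiles.csv"))
  tr <- dataset$truth
  jsonlite::write_json(list(
    terms = tr$spec$terms, beta = tr$beta,
    sigma_individual = tr$sigma_individual, sigma_society = tr$sigma_society,
    corr_individual = tr$corr_individual, corr_society = tr$corr_society,
    p_girl = tr$p_girl, age_probs = as.list(tr$age_probs),
    obs_mean = tr$obs_mean, obs_sd = tr$obs_sd, dual_rate = tr$dual_rate),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Reduced-scale truth for parameter-recovery runs
#'
#' Eight societies of 15 children with a fixed 40 observations per child:
#' small enough to refit many times, large enough to identify the
#' individual-level fixed effects. Society diet covariates span the unit
#' interval; other parameters follow [default_study_design()] except that
#' dual coding is off, so the generative process coincides exactly with the
#' likelihood being recovered.
#'
#' @return A [synthetic_truth()].
#' @export
recovery_default_truth <- function() {
  soc <- tibble::tibble(
    society_id = sprintf("soc%02d", 1:8),
    n_children = rep(15L, 8),
    prop_non_foraged = seq(0.05, 0.95, length.out = 8))
  synthetic_truth(
    spec = mmbm_spec(2), beta = default_beta(mmbm_spec(2)),
    sigma_individual = rep(1, 4), sigma_society = rep(0.5, 4),
    corr_individual = exchangeable_corr(0.2),
    corr_society = exchangeable_corr(0.2),
    societies = soc, obs_mean = 40, obs_sd = 0, dual_rate = 0)
}

#' Generate-fit-check parameter recovery experiment
#'
#' For each replicate, generates a dataset from `truth`, refits the model,
#' and records whether each generating fixed effect lies inside its 95%
#' credible interval. Non-convergent replicates are recorded and excluded
#' from the coverage denominator with a warning.
#'
#' @param truth A [synthetic_truth()] (default: the reduced-scale design).
#' @param n_replicates Number of generate-fit cycles.
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @param chains,iter,warmup Sampling plan per replicate fit.
#' @param ... Passed to [mmbm_fit()].
#' @return List of class `recovery_report`: `per_replicate` tibble (replicate,
#'   coverage, bias, max_rhat, divergences, converged), `per_parameter`
#'   coverage tibble, and `aggregate` (overall coverage across converged
#'   replicates, mean absolute bias, number converged).
#' @export
recovery_experiment <- function(truth = recovery_default_truth(),
                                n_replicates = 20, seed = 1, chains = 2,
                                iter = 800, warmup = floor(0.375 * iter), ...) {
  stopifnot(n_replicates >= 1)
  beta_true <- as.vector(truth$beta)
  per_rep <- vector("list", n_replicates)
  cover_mat <- matrix(NA, n_replicates, length(beta_true))
  bias_mat <- matrix(NA_real_, n_replicates, length(beta_true))
  for (r in seq_len(n_replicates)) {
    ds <- simulate_time_allocation(truth, seed = seed * 1000L + r)
    records <- recode_observations(ds$observations, synthetic_code_map())
    roster <- prepare_children(ds$children)
    fit <- suppressWarnings(mmbm_fit(
      records = records, children = roster, societies = ds$societies,
      spec = truth$spec, chains = chains, iter = iter, warmup = warmup,
      seed = seed * 1000L + 500L + r, save_loglik = FALSE, ...))
    est <- summarize_fixed_effects(fit)
    est_vec <- est$mean                              # category-major order
    cover <- beta_true >= est$ci_low & beta_true <= est$ci_high
    cover_mat[r, ] <- cover
    bias_mat[r, ] <- est_vec - beta_true
    per_rep[[r]] <- tibble::tibble(
      replicate = r, coverage = mean(cover),
      mean_abs_bias = mean(abs(est_vec - beta_true)),
      max_rhat = fit$diagnostics$max_rhat,
      divergences = fit$diagnostics$divergences,
      converged = fit$diagnostics$converged)
  }
  per_rep <- dplyr::bind_rows(per_rep)
  ok <- per_rep$converged
  if (!all(ok)) {
    warning(sum(!ok), " replicate(s) failed the convergence rule and were ",
            "excluded from the coverage denominator")
  }
  cats <- activity_categories()[1:4]
  grid <- expand.grid(category = cats, term = truth$spec$terms,
                      stringsAsFactors = FALSE)
  per_param <- tibble::tibble(
    category = grid$category, term = grid$term, truth = beta_true,
    coverage = colMeans(cover_mat[ok, , drop = FALSE]),
    bias = colMeans(bias_mat[ok, , drop = FALSE]))
  structure(list(
    per_replicate = per_rep, per_parameter = per_param,
    aggregate = list(
      coverage = mean(cover_mat[ok, , drop = FALSE]),
      mean_abs_bias = mean(abs(bias_mat[ok, , drop = FALSE])),
      n_converged = sum(ok), n_replicates = n_replicates)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$aggregate$n_replicates, "replicates,",
      x$aggregate$n_converged, "converged\n")
  cat("  aggregate 95% CI coverage of generating fixed effects:",
      format(round(x$aggregate$coverage, 3)), "\n")
  cat("  mean absolute bias (logit scale):",
      format(round(x$aggregate$mean_abs_bias, 3)), "\n")
  invisible(x)
}
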