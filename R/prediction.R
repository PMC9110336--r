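#' Equal-tailed credible interval
#'
#' Percentile interval with linear interpolation between order statistics
#' (quantile type 7). On finite samples an 89% interval depends on the
#' interpolation rule, so it is fixed and documented here.
#'
#' @param samples Numeric vector of at least 20 posterior samples.
#' @param level Interval probability in (0, 1); prediction plots use 0.89,
#'   coefficient tables 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
credible_interval <- function(samples, level = 0.89) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (length(samples) < 20) stop("need at least 20 samples")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, probs = c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

term_requirements <- function(terms) {
  req <- list(
    "intercept" = character(0),
    "boy" = "gender", "middle" = "age_class", "adolescent" = "age_class",
    "boy:middle" = c("gender", "age_class"),
    "boy:adolescent" = c("gender", "age_class"),
    "prop_non_foraged_z" = "prop_non_foraged_z", "npp_z" = "npp_z",
    "annual_mean_temp_z" = "annual_mean_temp_z",
    "annual_precip_z" = "annual_precip_z",
    "mammal_density_high" = "mammal_density_class",
    "water_rating" = "water_rating", "division" = "gendered_division",
    "division:boy" = c("gendered_division", "gender"))
  unique(unlist(req[terms]))
}

#' Build a covariate profile for prediction
#'
#' A profile fixes every fixed-effect input at an interpretable value.
#' Defaults are the reference levels: girls, early childhood, z-scored
#' covariates at the sample mean (0), low mammal density, best water rating,
#' gender-equal division of labour.
#'
#' @param gender `"girl"` or `"boy"`.
#' @param age_class `"early"`, `"middle"` or `"adolescent"`.
#' @param prop_non_foraged_z,npp_z,annual_mean_temp_z,annual_precip_z
#'   Z-scored society covariates.
#' @param mammal_density_class `"low"` or `"high"`.
#' @param water_rating Integer 1-4.
#' @param gendered_division Division-of-labour statistic in \[-2, 2\].
#' @return One-row tibble usable in [predict_probability()].
#' @export
new_profile <- function(gender = "girl", age_class = "early",
                        prop_non_foraged_z = 0, npp_z = 0,
                        annual_mean_temp_z = 0, annual_precip_z = 0,
                        mammal_density_class = "low", water_rating = 1,
                        gendered_division = 0) {
  tibble::tibble(
    gender = factor(gender, levels = c("girl", "boy")),
    age_class = factor(age_class, levels = c("early", "middle", "adolescent")),
    prop_non_foraged_z = prop_non_foraged_z, npp_z = npp_z,
    annual_mean_temp_z = annual_mean_temp_z, annual_precip_z = annual_precip_z,
    mammal_density_class = factor(mammal_density_class, levels = c("low", "high")),
    water_rating = water_rating, gendered_division = gendered_division)
}

profile_design <- function(profile, spec) {
  need <- term_requirements(spec$terms)
  missing <- setdiff(need, names(profile))
  if (length(missing)) {
    stop("profile is missing inputs for the model's terms: ",
         paste(missing, collapse = ", "))
  }
  X <- vapply(spec$terms, term_column, numeric(nrow(profile)), d = profile)
  matrix(X, nrow = nrow(profile), dimnames = list(NULL, spec$terms))
}

#' Posterior predicted activity probabilities
#'
#' For each retained posterior draw, computes the five category probabilities
#' for a covariate profile. Random effects are either set to zero
#' (`"median_unit"`: a typical child in a typical society, the convention of
#' the prediction figures) or freshly drawn from the fitted covariance
#' matrices and averaged (`"marginal"`: a randomly sampled child/society).
#'
#' @param fit An `mmbm_fit`.
#' @param profile Profile table (see [new_profile()]); may have several rows.
#' @param re_mode `"median_unit"` or `"marginal"`.
#' @param n_mc Monte-Carlo draws of random effects per posterior draw in
#'   marginal mode.
#' @return Tibble with `.draw`, `.profile` (row number), `category`, `prob`.
#' @export
predict_probability <- function(fit, profile, re_mode = c("median_unit",
                                                          "marginal"),
                                n_mc = 30) {
  re_mode <- match.arg(re_mode)
  Xp <- profile_design(profile, fit$spec)
  th <- stacked_draws(fit)
  lay <- fit$layout
  S <- nrow(th)
  cats <- activity_categories()
  out <- vector("list", nrow(Xp))
  re_on <- fit$meta$re == "both"
  for (p in seq_len(nrow(Xp))) {
    probs <- matrix(NA_real_, S, 5)
    for (s in seq_len(S)) {
      beta <- matrix(th[s, lay$beta], nrow = 4)
      eta <- as.numeric(beta %*% Xp[p, ])
      if (re_mode == "median_unit" || !re_on) {
        probs[s, ] <- category_probs(eta)
      } else {
        sig_i <- exp(th[s, lay$lam_i]); sig_s <- exp(th[s, lay$lam_s])
        Mi <- diag(sig_i) %*% cpc_to_cholesky(th[s, lay$y_i])
        Ms <- diag(sig_s) %*% cpc_to_cholesky(th[s, lay$y_s])
        zi <- matrix(stats::rnorm(4 * n_mc), n_mc)
        zs <- matrix(stats::rnorm(4 * n_mc), n_mc)
        nu <- zi %*% t(Mi) + zs %*% t(Ms)
        pm <- category_probs(sweep(nu, 2, eta, `+`))
        probs[s, ] <- colMeans(pm)
      }
    }
    out[[p]] <- tibble::tibble(
      .draw = rep(seq_len(S), 5), .profile = p,
      category = factor(rep(cats, each = S), levels = cats),
      prob = as.vector(probs))
  }
  dplyr::bind_rows(out)
}

#' Prediction table with credible intervals
#'
#' One row per profile x category: posterior mean probability and an
#' equal-tailed credible interval (default 89%, the plotting convention).
#'
#' @inheritParams predict_probability
#' @param profiles Profile table; one prediction per row.
#' @param level Credible-interval probability.
#' @return Tibble of class `mmbm_prediction`: `.profile`, `category`, `mean`,
#'   `low`, `high`, plus the profile columns.
#' @export
prediction_table <- function(fit, profiles, level = 0.89,
                             re_mode = "median_unit", n_mc = 30) {
  long <- predict_probability(fit, profiles, re_mode = re_mode, n_mc = n_mc)
  out <- long |>
    dplyr::group_by(.data$.profile, .data$category) |>
    dplyr::summarise(
      mean = mean(.data$prob),
      low = credible_interval(.data$prob, level)[["low"]],
      high = credible_interval(.data$prob, level)[["high"]],
      .groups = "drop") |>
    dplyr::left_join(dplyr::mutate(tibble::as_tibble(profiles),
                                   .profile = dplyr::row_number()),
                     by = ".profile")
  class(out) <- c("mmbm_prediction", class(out))
  out
}

#' Plot predicted activity probabilities
#'
#' @param object An `mmbm_prediction` table.
#' @param x_var Optional name of a profile column to map to the x axis;
#'   defaults to the profile index.
#' @param ... Unused.
#' @return A ggplot object: point + interval per category.
#' @export
autoplot.mmbm_prediction <- function(object, x_var = NULL, ...) {
  xv <- if (is.null(x_var)) ".profile" else x_var
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data[[xv]]), y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$low, ymax = .data$high)) +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = xv, y = "predicted probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot group time-allocation summaries
#'
#' Stacked-bar view of mean individual proportions by group, in the style of
#' descriptive time-allocation figures.
#'
#' @param summary Output of [summarize_time_allocation()].
#' @return A ggplot object.
#' @export
plot_time_allocation <- function(summary) {
  x <- if ("society_id" %in% names(summary)) "society_id" else
    setdiff(names(summary), c("category", "mean_proportion", "n_children"))[1]
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data[[x]], y = .data$mean_proportion,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean individual proportion of observed time") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  extra <- intersect(c("gender", "age_class"), names(summary))
  if (length(extra) == 2) p <- p + ggplot2::facet_grid(gender ~ age_class)
  else if (length(extra) == 1) p <- p + ggplot2::facet_wrap(extra)
  p
}
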