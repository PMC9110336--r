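#' Descriptive sample report
#'
#' Per-society sample characteristics (children, percent girls, mean age with
#' midpoint imputation for label-coded children, observations per child) and
#' group-level time-allocation proportions.
#'
#' @param records Observation records (see [recode_observations()]).
#' @param children Prepared roster (see [prepare_children()]).
#' @return List with `sample` (per-society characteristics incl. a `Total`
#'   row) and `time_allocation` (society x gender x age-class mean individual
#'   proportions).
#' @export
descriptive_report <- function(records, children) {
  opc <- dplyr::count(records, .data$child_id, name = "n_obs") |>
    dplyr::inner_join(children, by = "child_id")
  per_soc <- opc |>
    dplyr::group_by(.data$society_id) |>
    dplyr::summarise(
      n_children = dplyr::n(),
      pct_girls = 100 * mean(.data$gender == "girl"),
      mean_age = mean(.data$age_descriptive),
      sd_age = stats::sd(.data$age_descriptive),
      mean_obs = mean(.data$n_obs), sd_obs = stats::sd(.data$n_obs),
      .groups = "drop")
  total <- opc |>
    dplyr::summarise(
      society_id = "Total", n_children = dplyr::n(),
      pct_girls = 100 * mean(.data$gender == "girl"),
      mean_age = mean(.data$age_descriptive),
      sd_age = stats::sd(.data$age_descriptive),
      mean_obs = mean(.data$n_obs), sd_obs = stats::sd(.data$n_obs))
  list(sample = dplyr::bind_rows(per_soc, total),
       time_allocation = summarize_time_allocation(records, children))
}

read_pipeline_inputs <- function(config) {
  obs <- readr::read_csv(config$observations, col_types = readr::cols(
    society_id = readr::col_character(), child_id = readr::col_character(),
    obs_index = readr::col_integer(), raw_code = readr::col_character()))
  kids <- readr::read_csv(config$children, show_col_types = FALSE)
  socs <- readr::read_csv(config$societies, show_col_types = FALSE)
  map <- if (!is.null(config$code_map)) {
    read_activity_code_map(config$code_map)
  } else synthetic_code_map()
  list(observations = obs, children = kids, societies = socs, map = map)
}

#' Run the end-to-end analysis pipeline
#'
#' Ingest -> recode -> subset -> (re)standardize covariates -> fit the
#' requested models -> compare by WAIC -> write coefficient tables, all under
#' one config and one master seed. Re-running with the same config and seed
#' reproduces every output.
#'
#' @param config Named list (or path to a YAML file) with keys:
#'   `observations`, `children`, `societies` (CSV paths), optional
#'   `code_map` (CSV path; defaults to the identity map of
#'   [synthetic_code_map()]), `models` (subset of 1:5), `chains`, `iter`,
#'   `warmup`, `seed`, `out_dir`, and optional subset filters
#'   `exclude_societies`, `exclude_age_classes` plus `restandardize`
#'   (default `TRUE`: z-scores recomputed within the subset). Optional
#'   outputs: `predictions` (default `TRUE`) writes an 89% prediction table
#'   over the gender-by-age-class grid per model; `save_draws` (default
#'   `FALSE`) writes each fit's draws to `out_dir/modelN/` via
#'   [write_draws()].
#' @return List of class `pipeline_result`: `fits` (named list), `comparison`
#'   tibble, `descriptives`, and `manifest` (also written as JSON to
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(models = 1:2, chains = 3, iter = 2000, warmup = NULL,
                   seed = 1, restandardize = TRUE,
                   exclude_societies = character(0),
                   exclude_age_classes = character(0),
                   predictions = TRUE, save_draws = FALSE)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$warmup)) config$warmup <- floor(config$iter / 2)
  stopifnot(all(config$models %in% 1:5), !is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  inp <- read_pipeline_inputs(config)
  records <- recode_observations(inp$observations, inp$map)
  roster <- prepare_children(inp$children)
  societies <- tibble::as_tibble(inp$societies)
  if (is.character(societies$mammal_density_class)) {
    societies$mammal_density_class <- factor(societies$mammal_density_class,
                                             levels = c("low", "high"))
  }

  # subset filters (robustness refits: drop societies or age classes)
  if (length(config$exclude_societies)) {
    societies <- societies[!societies$society_id %in% config$exclude_societies, ]
    roster <- roster[!roster$society_id %in% config$exclude_societies, ]
    records <- records[records$child_id %in% roster$child_id, ]
  }
  if (length(config$exclude_age_classes)) {
    roster <- roster[!(as.character(roster$age_class) %in%
                         config$exclude_age_classes), ]
    records <- records[records$child_id %in% roster$child_id, ]
  }
  if (isTRUE(config$restandardize)) societies <- add_zscores(societies)

  desc <- descriptive_report(records, roster)
  readr::write_csv(desc$sample, file.path(config$out_dir, "sample_summary.csv"))
  readr::write_csv(desc$time_allocation,
                   file.path(config$out_dir, "time_allocation.csv"))
  readr::write_csv(societies, file.path(config$out_dir, "society_profiles.csv"))

  fits <- list()
  for (m in config$models) {
    fit <- mmbm_fit(records = records, children = roster,
                    societies = societies, spec = mmbm_spec(m),
                    chains = config$chains, iter = config$iter,
                    warmup = config$warmup,
                    seed = config$seed + 100L * m)
    coef_path <- file.path(config$out_dir, sprintf("coefficients_model%d.csv", m))
    readr::write_csv(summarize_fixed_effects(fit), coef_path)
    if (isTRUE(config$save_draws)) {
      write_draws(fit, file.path(config$out_dir, sprintf("model%d", m)))
    }
    if (isTRUE(config$predictions)) {
      grid <- expand.grid(gender = c("girl", "boy"),
                          age_class = c("early", "middle", "adolescent"),
                          stringsAsFactors = FALSE)
      profiles <- dplyr::bind_rows(purrr::pmap(grid, function(gender, age_class) {
        new_profile(gender = gender, age_class = age_class)
      }))
      readr::write_csv(
        prediction_table(fit, profiles, level = 0.89),
        file.path(config$out_dir, sprintf("predictions_model%d.csv", m)))
    }
    fits[[paste0("model", m)]] <- fit
  }
  comparison <- compare_models(fits = fits)
  readr::write_csv(comparison, file.path(config$out_dir, "comparison.csv"))

  out_files <- list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("timealloc")),
    seed = config$seed, models = config$models,
    chains = config$chains, iter = config$iter, warmup = config$warmup,
    exclude_societies = config$exclude_societies,
    exclude_age_classes = config$exclude_age_classes,
    restandardize = isTRUE(config$restandardize),
    n_children = nrow(roster), n_records = nrow(records),
    n_societies = nrow(societies),
    diagnostics = lapply(fits, function(f) list(
      max_rhat = f$diagnostics$max_rhat,
      divergences = f$diagnostics$divergences,
      converged = f$diagnostics$converged)),
    hashes = as.list(tools::md5sum(out_files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(fits = fits, comparison = comparison, descriptives = desc,
                 manifest = manifest), class = "pipeline_result")
}
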