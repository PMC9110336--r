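#' The five activity categories
#'
#' All models use a five-category outcome. The first four categories contrast
#' against `"other"`, the designated reference category (socialising, eating,
#' resting, schooling and any remaining activity).
#'
#' @return Character vector of length 5, in fixed model order; `"other"` last.
#' @export
activity_categories <- function() {
  c("childcare", "food_production", "domestic_work", "play", "other")
}

#' Build an activity code map
#'
#' Field teams code behaviour with site-specific vocabularies; each raw code
#' maps to one or two of the five activity categories (some coding schemes
#' allow two concurrent activities, e.g. play while foraging).
#'
#' @param df Data frame with columns `raw_code` and `categories`, the latter
#'   either a character column with pipe-joined categories
#'   (`"play|food_production"`) or a list column of character vectors.
#' @return A tibble of class `activity_code_map` with columns `raw_code`
#'   (character) and `categories` (list of character vectors, length 1 or 2).
#' @export
activity_code_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("raw_code", "categories") %in% names(df)))
  cats <- df$categories
  if (!is.list(cats)) cats <- strsplit(as.character(cats), "|", fixed = TRUE)
  ok_len <- lengths(cats) >= 1L & lengths(cats) <= 2L
  if (any(!ok_len)) {
    stop("each raw code must map to 1 or 2 categories; offending codes: ",
         paste(df$raw_code[!ok_len], collapse = ", "))
  }
  bad <- !vapply(cats, function(x) all(x %in% activity_categories()), logical(1))
  if (any(bad)) {
    stop("unknown activity categories for codes: ",
         paste(df$raw_code[bad], collapse = ", "))
  }
  if (anyDuplicated(df$raw_code)) stop("duplicated raw codes in code map")
  out <- tibble::tibble(raw_code = as.character(df$raw_code), categories = cats)
  class(out) <- c("activity_code_map", class(out))
  out
}

#' Read an activity code map from CSV
#'
#' @param path CSV with columns `raw_code`, `categories` (pipe-joined for
#'   dual codes).
#' @return An [activity_code_map()].
#' @export
read_activity_code_map <- function(path) {
  activity_code_map(readr::read_csv(path, col_types = readr::cols(
    raw_code = readr::col_character(), categories = readr::col_character()
  )))
}

#' Recode one raw activity code
#'
#' @param raw_code Single raw code string.
#' @param map An [activity_code_map()].
#' @param society Optional society id, used only to make error messages
#'   actionable during ingestion.
#' @return Character vector of 1 or 2 categories.
#' @export
recode_observation <- function(raw_code, map, society = NULL) {
  i <- match(raw_code, map$raw_code)
  if (is.na(i)) {
    stop("unknown raw activity code '", raw_code, "'",
         if (!is.null(society)) paste0(" in society '", society, "'"),
         call. = FALSE)
  }
  map$categories[[i]]
}

#' Recode and expand a table of raw observations
#'
#' Dual-coded observations (a raw code mapping to two categories) are expanded
#' into two records with equal weight, each counted as a unique observation.
#'
#' @param observations Data frame with columns `society_id`, `child_id`,
#'   `obs_index`, `raw_code`.
#' @param map An [activity_code_map()].
#' @return Tibble of observation records: `society_id`, `child_id`,
#'   `obs_index`, `category`. Row count equals the raw count plus the number
#'   of dual-coded observations.
#' @export
recode_observations <- function(observations, map) {
  stopifnot(all(c("society_id", "child_id", "obs_index", "raw_code") %in%
                  names(observations)))
  idx <- match(observations$raw_code, map$raw_code)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("unknown raw activity code '", observations$raw_code[bad],
         "' in society '", observations$society_id[bad], "'", call. = FALSE)
  }
  cats <- map$categories[idx]
  n_each <- lengths(cats)
  out <- observations[rep(seq_len(nrow(observations)), n_each),
                      c("society_id", "child_id", "obs_index")]
  out$category <- factor(unlist(cats), levels = activity_categories())
  tibble::as_tibble(out)
}

#' Assign developmental age classes
#'
#' Children are grouped into early childhood (3-6 y), middle childhood
#' (7-12 y) and adolescence (13-18 y). One contributing dataset (Mikea) lacks
#' ages in years and uses labels instead: early juveniles map to early
#' childhood, late juveniles to middle childhood and young adults (up to 25 y)
#' to adolescence. Non-integer ages are floored to whole years before
#' classification, since the class bounds are stated in whole years.
#'
#' @param age_years Numeric vector of ages (may contain `NA` where a label is
#'   supplied instead).
#' @param label Character vector of `"early_juvenile"`, `"late_juvenile"`,
#'   `"young_adult"` (or `NA` where `age_years` is supplied).
#' @param allow_out_of_range If `TRUE`, numeric ages outside 3-18 are clamped
#'   into the nearest class instead of erroring.
#' @return Factor with levels `early`, `middle`, `adolescent`.
#' @export
assign_age_class <- function(age_years = NULL, label = NULL,
                             allow_out_of_range = FALSE) {
  n <- max(length(age_years), length(label))
  if (is.null(age_years)) age_years <- rep(NA_real_, n)
  if (is.null(label)) label <- rep(NA_character_, n)
  stopifnot(length(age_years) == n, length(label) == n)
  out <- rep(NA_character_, n)

  lab_map <- c(early_juvenile = "early", late_juvenile = "middle",
               young_adult = "adolescent")
  has_lab <- !is.na(label) & label != ""
  if (any(has_lab & !(label %in% names(lab_map)))) {
    stop("unknown age label(s): ",
         paste(unique(label[has_lab & !(label %in% names(lab_map))]),
               collapse = ", "))
  }
  out[has_lab] <- lab_map[label[has_lab]]

  num <- !has_lab & !is.na(age_years)
  yrs <- floor(age_years[num])
  if (!allow_out_of_range && any(yrs < 3 | yrs > 18)) {
    stop("numeric ages outside 3-18 require allow_out_of_range = TRUE ",
         "(label-coded young adults may reach 25)")
  }
  yrs <- pmin(pmax(yrs, 3), 18)
  out[num] <- ifelse(yrs <= 6, "early", ifelse(yrs <= 12, "middle", "adolescent"))

  if (anyNA(out)) stop("age class could not be assigned for ", sum(is.na(out)),
                       " child(ren): need age_years or label")
  factor(out, levels = c("early", "middle", "adolescent"))
}

#' Impute descriptive ages for label-coded children
#'
#' For descriptive statistics only (never for modelling), label-coded children
#' are given the midpoint age of their label: early juveniles 6.5 y, late
#' juveniles 12 y, young adults 20.5 y.
#'
#' @param age_years Numeric vector (NA where labelled).
#' @param label Character vector of age labels (NA where numeric).
#' @return Numeric vector with labels replaced by midpoint ages.
#' @export
impute_descriptive_age <- function(age_years, label) {
  mid <- c(early_juvenile = 6.5, late_juvenile = 12, young_adult = 20.5)
  has_lab <- !is.na(label) & label != ""
  out <- age_years
  out[has_lab] <- mid[label[has_lab]]
  out
}

#' Prepare a child roster
#'
#' Validates the roster, assigns age classes (numeric or label path) and an
#' imputed descriptive age, and sets reference levels: girls and early
#' childhood.
#'
#' @param children Data frame with columns `child_id`, `society_id`, `gender`
#'   (`"girl"`/`"boy"`), and `age_years` and/or `age_label`.
#' @param allow_out_of_range Passed to [assign_age_class()].
#' @return Tibble with `child_id`, `society_id`, `gender` (factor, girl
#'   reference), `age_class` (factor, early reference), `age_descriptive`.
#' @export
prepare_children <- function(children, allow_out_of_range = FALSE) {
  stopifnot(all(c("child_id", "society_id", "gender") %in% names(children)))
  if (anyDuplicated(children$child_id)) {
    stop("duplicated child_id in roster; children observed in multiple years ",
         "must be collapsed to a single row (age = mean across years)")
  }
  if (!all(children$gender %in% c("girl", "boy"))) {
    stop("gender must be 'girl' or 'boy'")
  }
  age_years <- if ("age_years" %in% names(children)) children$age_years else NULL
  label <- if ("age_label" %in% names(children)) children$age_label else NULL
  tibble::tibble(
    child_id = as.character(children$child_id),
    society_id = as.character(children$society_id),
    gender = factor(children$gender, levels = c("girl", "boy")),
    age_class = assign_age_class(age_years, label, allow_out_of_range),
    age_descriptive = impute_descriptive_age(
      if (is.null(age_years)) rep(NA_real_, nrow(children)) else age_years,
      if (is.null(label)) rep(NA_character_, nrow(children)) else label
    )
  )
}

#' Summarize individual time allocation
#'
#' Computes, per child, the proportion of observed records in each of the five
#' activity categories, then averages those individual proportions within
#' groups (unweighted mean over children, so heavily observed children do not
#' dominate group values).
#'
#' @param records Observation records (see [recode_observations()]).
#' @param children Prepared roster (see [prepare_children()]).
#' @param grouping Character vector of grouping columns among `"society_id"`,
#'   `"gender"`, `"age_class"`.
#' @return Tibble with the grouping columns, `category`, `mean_proportion`,
#'   and `n_children`.
#' @export
summarize_time_allocation <- function(records, children,
                                      grouping = c("society_id", "gender",
                                                   "age_class")) {
  stopifnot(all(grouping %in% c("society_id", "gender", "age_class")))
  missing_children <- setdiff(unique(records$child_id), children$child_id)
  if (length(missing_children)) {
    stop("records reference children absent from roster: ",
         paste(utils::head(missing_children, 5), collapse = ", "))
  }
  zero_obs <- setdiff(children$child_id, unique(records$child_id))
  if (length(zero_obs)) {
    warning(length(zero_obs), " child(ren) with zero records excluded from ",
            "time-allocation summaries")
  }
  props <- child_proportions(records)
  props |>
    dplyr::inner_join(children, by = "child_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "category")))) |>
    dplyr::summarise(mean_proportion = mean(.data$proportion),
                     n_children = dplyr::n(), .groups = "drop")
}

#' Per-child category proportions
#'
#' @param records Observation records with `child_id` and `category`.
#' @return Tibble `child_id`, `category`, `n`, `proportion`; proportions sum
#'   to 1 within each child (all five categories present, zeros included).
#' @export
child_proportions <- function(records) {
  records |>
    dplyr::count(.data$child_id, .data$category, name = "n") |>
    tidyr::complete(.data$child_id,
                    category = factor(activity_categories(),
                                      levels = activity_categories()),
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$child_id) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Observations-per-child summary
#'
#' @param records Observation records.
#' @param children Optional roster; if given, the summary is per society.
#' @return Tibble with `n_children`, `mean_obs`, `sd_obs` (overall or by
#'   society).
#' @export
obs_per_child <- function(records, children = NULL) {
  counts <- dplyr::count(records, .data$child_id, name = "n_obs")
  if (is.null(children)) {
    return(tibble::tibble(n_children = nrow(counts),
                          mean_obs = mean(counts$n_obs),
                          sd_obs = stats::sd(counts$n_obs)))
  }
  counts |>
    dplyr::inner_join(children, by = "child_id") |>
    dplyr::group_by(.data$society_id) |>
    dplyr::summarise(n_children = dplyr::n(), mean_obs = mean(.data$n_obs),
                     sd_obs = stats::sd(.data$n_obs), .groups = "drop")
}
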