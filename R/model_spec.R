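#' Fixed-effect term pool
#'
#' @return Character vector of all fixed-effect terms the five model
#'   definitions draw from, in canonical order.
#' @export
mmbm_terms <- function() {
  c("intercept", "boy", "middle", "adolescent", "boy:middle",
    "boy:adolescent", "prop_non_foraged_z", "npp_z", "annual_mean_temp_z",
    "annual_precip_z", "mammal_density_high", "water_rating", "division",
    "division:boy")
}

#' Define a multilevel multinomial behavioural model
#'
#' The five standard models share correlated individual- and society-level
#' random effects and differ only in fixed effects:
#' \describe{
#'   \item{1}{intercept only}
#'   \item{2}{+ age, gender, age x gender, proportion non-foraged food (z)}
#'   \item{3}{Model 2 + NPP, annual precipitation, annual mean temperature
#'     (all z)}
#'   \item{4}{Model 2 + dangerous mammal density (high vs low), water
#'     quality/quantity rating}
#'   \item{5}{Model 2 + gendered division of food-production labour and its
#'     interaction with gender}
#' }
#'
#' @param model Integer 1-5, or `NULL` when `terms` is given explicitly.
#' @param terms Optional explicit ordered subset of [mmbm_terms()]; must
#'   include `"intercept"`.
#' @return Object of class `mmbm_spec`: list with `model_id`, `terms`,
#'   `n_categories = 5`, `reference_index = 5`.
#' @export
mmbm_spec <- function(model = NULL, terms = NULL) {
  base2 <- c("intercept", "boy", "middle", "adolescent", "boy:middle",
             "boy:adolescent", "prop_non_foraged_z")
  if (is.null(terms)) {
    stopifnot(length(model) == 1, model %in% 1:5)
    terms <- switch(model,
      `1` = "intercept",
      `2` = base2,
      `3` = c(base2, "npp_z", "annual_precip_z", "annual_mean_temp_z"),
      `4` = c(base2, "mammal_density_high", "water_rating"),
      `5` = c(base2, "division", "division:boy"))
  } else {
    if (!"intercept" %in% terms) stop("terms must include 'intercept'")
    unknown <- setdiff(terms, mmbm_terms())
    if (length(unknown)) stop("unknown terms: ", paste(unknown, collapse = ", "))
  }
  structure(list(model_id = if (is.null(model)) NA_integer_ else as.integer(model),
                 terms = terms, n_categories = 5L, reference_index = 5L),
            class = "mmbm_spec")
}

#' @export
print.mmbm_spec <- function(x, ...) {
  cat("<mmbm_spec> model", x$model_id, "-", length(x$terms), "fixed effects:\n ",
      paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

term_column <- function(term, d) {
  boy <- as.numeric(d$gender == "boy")
  switch(term,
    "intercept" = rep(1, nrow(d)),
    "boy" = boy,
    "middle" = as.numeric(d$age_class == "middle"),
    "adolescent" = as.numeric(d$age_class == "adolescent"),
    "boy:middle" = boy * as.numeric(d$age_class == "middle"),
    "boy:adolescent" = boy * as.numeric(d$age_class == "adolescent"),
    "prop_non_foraged_z" = d$prop_non_foraged_z,
    "npp_z" = d$npp_z,
    "annual_mean_temp_z" = d$annual_mean_temp_z,
    "annual_precip_z" = d$annual_precip_z,
    "mammal_density_high" = as.numeric(d$mammal_density_class == "high"),
    "water_rating" = as.numeric(d$water_rating),
    "division" = d$gendered_division,
    "division:boy" = d$gendered_division * boy,
    stop("unknown term: ", term))
}

#' Build the per-child design for model fitting
#'
#' The likelihood depends on observations only through per-child category
#' counts, because every fixed effect is constant within a child. This builder
#' collapses records to a children x 5 count matrix, assembles the fixed-effect
#' design matrix for a [mmbm_spec()], and indexes children into societies.
#'
#' @param records Observation records (`child_id`, `category`).
#' @param children Prepared roster (see [prepare_children()]).
#' @param societies Society profile table (needs the covariate columns the
#'   spec's terms use).
#' @param spec An [mmbm_spec()].
#' @return List of class `mmbm_data`: `Y` (n_children x 5 integer counts),
#'   `X` (n_children x M design), `society` (1-based index per child),
#'   `child_id`, `society_id`, `spec`, `n_obs`.
#' @export
mmbm_data <- function(records, children, societies, spec) {
  stopifnot(inherits(spec, "mmbm_spec"))
  d <- dplyr::inner_join(children, societies, by = "society_id")
  if (nrow(d) != nrow(children)) {
    stop("children reference societies absent from the profile table: ",
         paste(setdiff(children$society_id, societies$society_id), collapse = ", "))
  }
  counts <- table(factor(records$child_id, levels = d$child_id),
                  factor(records$category, levels = activity_categories()))
  if (sum(counts) == 0) stop("no observation records for any rostered child")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning(sum(zero), " child(ren) without records dropped from the design")
    d <- d[!zero, , drop = FALSE]
    counts <- counts[!zero, , drop = FALSE]
  }
  X <- vapply(spec$terms, term_column, numeric(nrow(d)), d = d)
  X <- matrix(X, nrow = nrow(d), dimnames = list(NULL, spec$terms))
  soc_levels <- sort(unique(d$society_id))
  structure(list(
    Y = matrix(as.integer(counts), nrow = nrow(d),
               dimnames = list(d$child_id, activity_categories())),
    X = X,
    society = match(d$society_id, soc_levels),
    child_id = d$child_id,
    society_id = soc_levels,
    spec = spec,
    n_obs = sum(counts)
  ), class = "mmbm_data")
}
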