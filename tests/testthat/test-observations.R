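test_that("raw codes recode to one or two categories and unknown codes error", {
  map <- toy_code_map()
  expect_equal(recode_observation("P", map), "play")
  expect_equal(recode_observation("PF", map), c("play", "food_production"))
  expect_error(recode_observation("ZZ", map, society = "A"), "ZZ")
  expect_error(activity_code_map(tibble::tibble(raw_code = "X",
                                                categories = "play|other|childcare")),
               "1 or 2")
  expect_error(activity_code_map(tibble::tibble(raw_code = "X",
                                                categories = "swimming")),
               "unknown")
})

test_that("dual-coded observations expand to extra rows, exactly one per dual code", {
  map <- toy_code_map()
  obs <- tibble::tibble(society_id = "A", child_id = "a1",
                        obs_index = 1:6,
                        raw_code = c("P", "F", "PF", "O", "PF", "C"))
  rec <- recode_observations(obs, map)
  expect_equal(nrow(rec), 6 + 2)
  expect_s3_class(rec$category, "factor")
  expect_setequal(levels(rec$category), activity_categories())
  # property: expansion count equals dual-code count for random mixes
  set.seed(7)
  for (i in 1:5) {
    codes <- sample(map$raw_code, 50, replace = TRUE)
    o <- tibble::tibble(society_id = "A", child_id = "a1",
                        obs_index = seq_along(codes), raw_code = codes)
    expect_equal(nrow(recode_observations(o, map)),
                 length(codes) + sum(codes == "PF"))
  }
})

test_that("age classes follow the whole-year bounds and the Mikea label map", {
  expect_equal(as.character(assign_age_class(c(5, 12, 13))),
               c("early", "middle", "adolescent"))
  # floor-to-integer rule at boundaries
  expect_equal(as.character(assign_age_class(c(6.4, 6.9, 12.9))),
               c("early", "early", "middle"))
  expect_equal(as.character(assign_age_class(label = c("early_juvenile",
                                                       "late_juvenile",
                                                       "young_adult"))),
               c("early", "middle", "adolescent"))
  expect_error(assign_age_class(2), "allow_out_of_range")
  expect_error(assign_age_class(20), "allow_out_of_range")
  expect_equal(as.character(assign_age_class(20, allow_out_of_range = TRUE)),
               "adolescent")
  expect_error(assign_age_class(label = "toddler"), "unknown")
  # descriptive midpoint imputation
  expect_equal(impute_descriptive_age(c(7, NA, NA, NA),
                                      c(NA, "early_juvenile", "late_juvenile",
                                        "young_adult")),
               c(7, 6.5, 12, 20.5))
})

test_that("per-child proportions are normalized and group means average children", {
  map <- toy_code_map()
  obs <- tibble::tibble(
    society_id = rep("A", 10), child_id = rep("a1", 10), obs_index = 1:10,
    raw_code = c(rep("P", 4), rep("F", 3), rep("O", 3)))
  rec <- recode_observations(obs, map)
  pr <- child_proportions(rec)
  expect_equal(nrow(pr), 5)
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-12)
  expect_equal(pr$proportion[pr$category == "play"], 0.4)
  # group mean is the unweighted mean of individual proportions
  obs2 <- dplyr::bind_rows(
    obs,
    tibble::tibble(society_id = "A", child_id = "a2", obs_index = 1:2,
                   raw_code = c("P", "P")))
  kids <- prepare_children(toy_children()[1:2, ])
  summ <- summarize_time_allocation(recode_observations(obs2, map), kids,
                                    grouping = "society_id")
  play <- summ$mean_proportion[summ$category == "play"]
  expect_equal(play, mean(c(0.4, 1)))  # not the pooled 6/12
})

test_that("children without records are excluded with a warning, never divided by zero", {
  map <- toy_code_map()
  obs <- tibble::tibble(society_id = "A", child_id = "a1", obs_index = 1:2,
                        raw_code = c("P", "O"))
  kids <- prepare_children(toy_children()[1:2, ])
  expect_warning(s <- summarize_time_allocation(recode_observations(obs, map),
                                                kids, grouping = "society_id"),
                 "zero records")
  expect_true(all(is.finite(s$mean_proportion)))
})

test_that("group means recover the generating probabilities on synthetic data", {
  # sigma = 0 makes every child in a gender/age cell share the same
  # generating probabilities, so group means estimate them directly
  spec <- mmbm_spec(2)
  soc <- tibble::tibble(society_id = c("A", "B"), n_children = c(60L, 60L),
                        prop_non_foraged = c(0.2, 0.8))
  truth <- synthetic_truth(spec, default_beta(spec),
                           sigma_individual = rep(0, 4),
                           sigma_society = rep(0, 4),
                           corr_individual = diag(4), corr_society = diag(4),
                           societies = soc, obs_mean = 60, obs_sd = 0)
  ds <- simulate_time_allocation(truth, seed = 11)
  rec <- recode_observations(ds$observations, synthetic_code_map())
  roster <- prepare_children(ds$children)
  summ <- summarize_time_allocation(rec, roster,
                                    grouping = c("gender", "age_class"))
  # generating probabilities for one cell: boys, adolescent, society A/B mix
  d <- dplyr::inner_join(roster, ds$societies, by = "society_id")
  for (g in c("girl", "boy")) {
    cell <- summ[summ$gender == g & summ$age_class == "middle", ]
    kids <- d[d$gender == g & d$age_class == "middle", ]
    X <- vapply(spec$terms, timealloc:::term_column, numeric(nrow(kids)), d = kids)
    p_true <- colMeans(category_probs(X %*% t(truth$beta)))
    expect_equal(cell$mean_proportion[match(activity_categories(),
                                            cell$category)],
                 unname(p_true), tolerance = 0.06)
  }
})
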