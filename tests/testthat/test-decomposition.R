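test_that("the early/late split partitions at the cutoff with overrides", {
  sim <- sim_annotated(n = 80, seed = 301)
  halves <- split_at_threshold(sim$records, 18)
  expect_true(all(halves$early$age <= 18))
  expect_true(all(halves$late$age > 18))
  expect_equal(nrow(halves$early) + nrow(halves$late), nrow(sim$records))
  # the override map wins over the scan's cutoff for the flagged group
  r <- sim$records
  r$species <- "WA"; r$sex <- "F"
  ov <- split_at_threshold(r, 14, overrides = c(WA.F = 18))
  expect_true(all(ov$early$age <= 18))
  expect_error(split_at_threshold(sim$records, max(sim$records$age)  + 1),
               "empty")
})

test_that("within-group centring is invariant to a common age shift", {
  sim <- sim_annotated(n = 120, seed = 311)
  halves <- split_at_threshold(sim$records, sim$cfg$threshold_age)
  f1 <- fit_early_model(halves$early, importance = FALSE)
  shifted <- as.data.frame(sim$records)
  shifted$age <- shifted$age + 5
  shifted <- annotate_records(as_breeding_records(
    shifted[, c("individual_id", "species", "sex", "season", "age", "outcome",
                "partner_id", "known_recruit")]
  ), study_end = sim$cfg$n_years)
  halves2 <- split_at_threshold(shifted, sim$cfg$threshold_age + 5)
  f2 <- fit_early_model(halves2$early, importance = FALSE)
  expect_equal(f1$table$estimate, f2$table$estimate, tolerance = 1e-3)
})

test_that("estimates are invariant to the order of input rows", {
  sim <- sim_annotated(n = 260, seed = 321)
  raw <- as.data.frame(sim$records)[, c("individual_id", "species", "sex",
                                        "season", "age", "outcome",
                                        "partner_id", "known_recruit")]
  set.seed(1)
  shuffled <- annotate_records(as_breeding_records(raw[sample(nrow(raw)), ]),
                               study_end = sim$cfg$n_years)
  h1 <- split_at_threshold(sim$records, 24)
  h2 <- split_at_threshold(shuffled, 24)
  f1 <- fit_late_model(h1$late, importance = FALSE)
  f2 <- fit_late_model(h2$late, importance = FALSE)
  expect_equal(f1$table$estimate, f2$table$estimate, tolerance = 1e-10)
})

test_that("the decomposition recovers the simulated effect structure", {
  sim <- sim_annotated(n = 350, seed = 331)   # GHA-like: terminal +0.9, cost -0.5
  halves <- split_at_threshold(sim$records, sim$cfg$threshold_age)
  early <- fit_early_model(halves$early, importance = FALSE)
  late <- fit_late_model(halves$late)
  est <- function(res, tm) res$table$estimate[match(tm, res$table$term)]
  expect_gt(est(early, "years_since_first"), 0)
  expect_lt(est(early, "is_first_attempt"), 0)
  expect_gt(est(late, "years_before_death"), 0)   # success falls approaching death
  expect_gt(est(late, "is_last_attempt"), 0)      # terminal improvement
  expect_lt(est(late, "age_last"), 0)             # good breeders die younger
  # strong terminal effect carries model-selection weight
  daic <- late$table$delta_aic[match("is_last_attempt", late$table$term)]
  expect_gt(daic, 2)
  rep <- truth_recovery_report(sim$cfg, early = early, late = late)
  expect_true(all(rep$sign_ok))
  expect_true(rep$covered[rep$term == "years_since_first"])
})

test_that("a null robustness term carries no model-selection weight", {
  sim <- sim_annotated(n = 250, seed = 341)
  halves <- split_at_threshold(sim$records, sim$cfg$threshold_age)
  late <- fit_late_model(halves$late, robustness = "partner_change")
  tab <- late$table
  expect_true("partner_change" %in% tab$term)
  # partner change does not enter the generative model: removal costs <= ~0
  expect_lt(tab$delta_aic[tab$term == "partner_change"], 2)
  # headline terms are unaffected by its presence
  expect_true(all(c("years_before_death", "age_last", "is_last_attempt") %in% tab$term))
})

test_that("the sex comparison identifies the influential parent", {
  pairs <- simulate_pair_records(n_pairs = 250, n_years = 12, seed = 351,
                                 male_weight = 0, female_weight = 1,
                                 age_corr = 0.7)
  cmp <- compare_sex_ages(pairs, male_threshold = 20, female_threshold = 20)
  expect_equal(cmp$more_variation, "F")
  expect_gt(cmp$delta_aic_female, 2)
  expect_lt(cmp$delta_aic_male, 2)   # two uninformative parameters cost AIC
})

test_that("species interactions flag heterogeneous improvement rates", {
  sim_species <- function(profile, label, slope, seed, n = 300) {
    cfg <- simulation_config(n, profile, n_years = 35, seed = seed,
                             species_label = label, threshold_age = 20,
                             early_slope = slope, late_slope = -0.08,
                             cost_coefficient = 0)
    annotate_records(simulate_population(cfg)$records, study_end = 35)
  }
  mk_early <- function(slopes, seeds, n = 260) {
    parts <- Map(sim_species,
                 list("annual", "biennial_short", "biennial_yearlong"),
                 list("BBA", "GHA", "WA"), slopes, seeds, list(n, n, n))
    do.call(rbind, lapply(parts, function(p) {
      as.data.frame(split_at_threshold(p, 20)$early)
    }))
  }
  hetero <- mk_early(list(0.24, 0.12, 0.12), list(361, 362, 363), n = 420)
  res_h <- species_interaction_model(hetero, phase = "early")
  expect_gt(res_h$block_delta_aic[["years_since_first"]], 2)
  homo <- mk_early(list(0.12, 0.12, 0.12), list(364, 365, 366))
  res_0 <- species_interaction_model(homo, phase = "early")
  expect_lt(res_0$block_delta_aic[["years_since_first"]], 2)
  expect_error(species_interaction_model(hetero, phase = "early",
                                         reference = "XX"), "reference")
})
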