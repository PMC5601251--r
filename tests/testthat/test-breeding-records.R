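test_that("reading a records CSV derives the attempt structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tiny_raw_records(), path, row.names = FALSE, na = "")
  r <- read_records(path)
  expect_s3_class(r, "breeding_records")
  expect_equal(r$attempt_index, 1:3)
  expect_equal(r$years_since_last, c(NA, 1L, 2L))
  expect_equal(r$previous_outcome, c(NA, 0L, 1L))
  expect_equal(r$partner_change, c(0L, 0L, 1L))
})

test_that("invalid tables are rejected with informative errors", {
  raw <- tiny_raw_records()
  expect_error(as_breeding_records(raw[, setdiff(names(raw), "outcome")]),
               "missing required column")
  dup <- rbind(raw, raw[2, ])
  expect_error(as_breeding_records(dup), "duplicate")
  bad_age <- raw
  bad_age$age <- c(10, 9, 13)
  expect_error(as_breeding_records(bad_age), "non-monotone")
  bad_out <- raw
  bad_out$outcome[1] <- 2
  expect_error(as_breeding_records(bad_out), "binary")
})

test_that("records round-trip through CSV field-for-field", {
  sim <- simulate_population(simulation_config(40, "annual", n_years = 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(sim$records, path)
  back <- read_records(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$records),
               ignore_attr = TRUE)
})

test_that("the death proxy follows the species gap rule and is monotone in study end", {
  mk <- function(sp, last_season) {
    as_breeding_records(data.frame(
      individual_id = "b1", species = sp, sex = "M",
      season = last_season, age = 12, outcome = 1, stringsAsFactors = FALSE
    ))
  }
  expect_true(build_histories(mk("WA", 2007), 2013)$presumed_dead)
  expect_false(build_histories(mk("BBA", 2010), 2013)$presumed_dead)
  expect_true(build_histories(mk("BBA", 2009), 2013)$presumed_dead)
  expect_error(build_histories(mk("WA", 2015), 2013), "earlier")
  # once presumed dead, extending the study never resurrects the bird
  for (sp in c("BBA", "GHA", "WA")) {
    r <- mk(sp, 2000)
    flags <- vapply(2000:2015, function(e) build_histories(r, e)$presumed_dead,
                    logical(1))
    expect_true(all(diff(flags) >= 0))
  }
})

test_that("the age-support filter drops sparse ages once and only once", {
  raw <- do.call(rbind, lapply(1:34, function(i) {
    data.frame(individual_id = paste0("b", i), species = "GHA", sex = "F",
               season = 1990 + i, age = if (i <= 30) 10 else 11,
               outcome = i %% 2, stringsAsFactors = FALSE)
  }))
  r <- as_breeding_records(raw)
  f <- filter_age_support(r, min_count = 5)
  expect_equal(nrow(f), 30)
  expect_false(11 %in% f$age)
  # identity when all ages are well supported
  expect_equal(nrow(filter_age_support(f, min_count = 5)), 30)
  # property: no surviving age has support below the threshold
  sim <- simulate_population(simulation_config(120, "annual", n_years = 25, seed = 8))
  for (mc in c(3, 5, 10)) {
    ff <- filter_age_support(sim$records, min_count = mc)
    expect_true(all(table(ff$age) >= mc))
    expect_lte(nrow(ff), nrow(sim$records))
  }
  expect_error(filter_age_support(r, min_count = 1e6), "no records remain")
})

test_that("derived covariates partition each bird's reproductive span", {
  raw <- data.frame(
    individual_id = "b1", species = "GHA", sex = "M",
    season = c(2000, 2002, 2005), age = c(10, 12, 15),
    outcome = c(0, 1, 1), stringsAsFactors = FALSE
  )
  r <- derive_covariates(as_breeding_records(raw))
  expect_equal(r$years_since_first, c(0, 2, 5))
  expect_equal(r$years_before_death, c(5, 3, 0))
  expect_equal(r$is_first_attempt, c(1, 0, 0))
  expect_equal(r$is_last_attempt, c(0, 0, 1))
  single <- derive_covariates(as_breeding_records(raw[1, ]))
  expect_equal(single$is_first_attempt, 1L)
  expect_equal(single$is_last_attempt, 1L)
  expect_equal(single$years_since_first + single$years_before_death, 0)
  # invariant on simulated data
  sim <- simulate_population(simulation_config(80, "biennial_short", n_years = 30, seed = 5))
  d <- derive_covariates(sim$records)
  expect_equal(d$years_since_first + d$years_before_death, d$age_last - d$age_first)
})

test_that("the life-history summary is a difference of cohort means", {
  raw <- data.frame(
    individual_id = c("a", "b", "c", "c", "d", "d"),
    species = "BBA", sex = "M",
    season = c(2010, 2010, 2000, 2005, 2001, 2007),
    age = c(9, 11, 12, 17, 16, 22),
    outcome = 1,
    known_recruit = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  h <- build_histories(as_breeding_records(raw), study_end = 2013)
  # a, b are recent known recruits (censored); c, d disappeared long ago
  tab <- summarize_life_history(h)
  expect_equal(tab$age_first_mean, 10)      # mean(9, 11), known recruits only
  expect_equal(tab$age_last_mean, 19.5)     # mean(17, 22), presumed dead only
  expect_equal(tab$repro_lifespan, 9.5)
  expect_equal(tab$age_first_se, sd(c(9, 11)) / sqrt(2))
})
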