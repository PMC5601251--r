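test_that("age bases implement the hinge arithmetic and stay continuous", {
  s1 <- age_function_spec("threshold1", 18)
  B <- make_age_basis(s1, ages = c(10, 18, 25), center = 0)
  expect_equal(B[, "age_post"], c(0, 0, 7))
  expect_equal(B[, "age_pre"], c(10, 18, 18))
  s2 <- age_function_spec("threshold2", c(15, 25))
  B2 <- make_age_basis(s2, ages = c(10, 20, 30), center = 0)
  expect_equal(B2[2, ], c(age_pre = 15, age_mid = 5, age_post = 0))
  expect_equal(B2[3, ], c(age_pre = 15, age_mid = 10, age_post = 5))
  # linear predictor is continuous in age at every breakpoint
  for (spec in list(s1, s2)) {
    grid <- seq(5, 30, by = 1e-3)
    Bg <- make_age_basis(spec, grid, center = mean(grid))
    lp <- drop(Bg %*% rep(1, ncol(Bg)))
    expect_lt(max(abs(diff(lp))), 3e-3)  # bounded increments, no jumps
  }
  expect_error(make_age_basis(s1, ages = 19:30), "outside")
  expect_error(age_function_spec("threshold1"), "1 threshold")
  expect_error(age_function_spec("threshold2", c(20, 18)), "increasing")
  expect_equal(ncol(make_age_basis(age_function_spec("null"), 1:10)), 0)
})

test_that("the linear basis supports exact slope recovery", {
  ages <- 1:30
  y <- 2 + 0.3 * ages
  B <- make_age_basis(age_function_spec("linear"), ages)
  slope <- cov(B[, "age"], y) / var(B[, "age"])  # closed-form OLS
  expect_equal(slope, 0.3, tolerance = 1e-12)
})

test_that("a threshold scan is exactly a set of independent fits", {
  sim <- sim_annotated(n = 120, seed = 201)
  filt <- filter_age_support(sim$records, 5)
  grid <- c(18, 20, 22)
  scan <- scan_thresholds(filt, "threshold1", grid = grid)
  indep <- vapply(grid, function(t) {
    fit_age_model(filt, age_function_spec("threshold1", t),
                  center = scan$center)$aic
  }, numeric(1))
  expect_equal(scan$aic_profile, indep)
  expect_equal(scan$best$thresholds, grid[which.min(indep)])
  expect_true(scan$ci_low <= scan$best$thresholds &&
              scan$best$thresholds <= scan$ci_high)
  expect_error(scan_thresholds(filt, "threshold1", grid = integer(0)), "empty")
})

test_that("the profile CI follows the deviance rule", {
  mk_scan <- function(grid, dev) {
    ll <- -dev / 2
    structure(list(kind = "threshold1", grid = grid, aic_profile = dev,
                   loglik = ll, best_index = which.min(dev)),
              class = "threshold_scan")
  }
  scan <- mk_scan(10:14, c(5, 1, 0, 2, 6.2))
  expect_equal(threshold_ci(scan), c(11, 13))
  expect_equal(threshold_ci(mk_scan(20, 0)), c(20, 20))
  # a non-contiguous dip outside the run around the best is not included
  scan2 <- mk_scan(10:15, c(1, 6, 0, 2, 6.2, 1))
  expect_equal(threshold_ci(scan2), c(12, 13))
})

test_that("Akaike weights follow the closed form over the top set", {
  expect_equal(akaike_weights(c(0, 2)), c(1, 0))
  w <- akaike_weights(c(0, 1))
  expect_equal(w, c(1, exp(-0.5)) / (1 + exp(-0.5)))
  expect_equal(round(w, 3), c(0.622, 0.378))
  expect_equal(sum(akaike_weights(c(0, 0.5, 1.2, 1.9, 4))), 1)
  # invariant to a constant shift of every AIC (delta is unchanged)
  aics <- c(310.2, 311.1, 314.9)
  expect_equal(akaike_weights(aics - min(aics)),
               akaike_weights((aics + 57) - min(aics + 57)))
})

test_that("model averaging interpolates the member curves", {
  sim <- sim_annotated(n = 150, seed = 211)
  filt <- filter_age_support(sim$records, 5)
  center <- mean(filt$age)
  fits <- list(
    null = fit_age_model(filt, age_function_spec("null"), center),
    linear = fit_age_model(filt, age_function_spec("linear"), center),
    quadratic = fit_age_model(filt, age_function_spec("quadratic"), center)
  )
  ages <- seq(min(filt$age), max(filt$age))
  ms <- select_and_average(fits, ages)
  expect_equal(sum(ms$members$weight), 1)
  member_preds <- vapply(fits, function(f) {
    B <- make_age_basis(f$age_spec, ages, center = f$age_center)
    predict_fixed(f, cbind(`(Intercept)` = 1, B))$fit
  }, numeric(length(ages)))
  top <- member_preds[, ms$members$in_top, drop = FALSE]
  expect_true(all(ms$curve$averaged_fit >= apply(top, 1, min) - 1e-12))
  expect_true(all(ms$curve$averaged_fit <= apply(top, 1, max) + 1e-12))
  # a single-model top set reproduces that model's curve exactly
  solo <- select_and_average(fits["linear"], ages)
  expect_equal(solo$curve$averaged_fit, solo$curve$best_fit)
  # equal-AIC twins share the weight equally
  twins <- select_and_average(list(a = fits$linear, b = fits$linear), ages)
  expect_equal(twins$members$weight, c(0.5, 0.5))
})

test_that("flat data prefer the null age model", {
  wins <- 0
  competitive <- 0
  for (r in 1:4) {
    sim <- sim_annotated(n = 130, seed = 220 + r, profile = "annual",
                         early_slope = 0, late_slope = 0,
                         first_attempt_effect = 0, terminal_effect = 0,
                         cost_coefficient = 0)
    filt <- filter_age_support(sim$records, 5)
    center <- mean(filt$age)
    null_fit <- fit_age_model(filt, age_function_spec("null"), center)
    scan <- scan_thresholds(filt, "threshold1",
                            grid = candidate_thresholds(filt$age, min_side = 25))
    if (null_fit$aic < min(scan$aic_profile)) wins <- wins + 1
    if (null_fit$aic < min(scan$aic_profile) + 2) competitive <- competitive + 1
  }
  expect_gte(wins, 2)
  expect_gte(competitive, 3)
})
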