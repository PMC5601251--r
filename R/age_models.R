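#' Specify a candidate age function
#'
#' @param kind One of `"null"` (no age term), `"linear"`, `"quadratic"`,
#'   `"threshold1"` (single breakpoint) or `"threshold2"` (two breakpoints
#'   with independently varying slopes between them).
#' @param thresholds Integer breakpoint age(s): none, one, or two strictly
#'   increasing values depending on `kind`.
#' @return Object of class `age_function_spec`.
#' @export
age_function_spec <- function(kind = c("null", "linear", "quadratic",
                                       "threshold1", "threshold2"),
                              thresholds = integer(0)) {
  kind <- match.arg(kind)
  thresholds <- as.numeric(thresholds)
  need <- switch(kind, null = 0L, linear = 0L, quadratic = 0L,
                 threshold1 = 1L, threshold2 = 2L)
  if (length(thresholds) != need) {
    stop(kind, " age function needs ", need, " threshold(s)")
  }
  if (need == 2L && diff(thresholds) <= 0) stop("thresholds must be strictly increasing")
  structure(list(kind = kind, thresholds = thresholds), class = "age_function_spec")
}

#' @export
print.age_function_spec <- function(x, ...) {
  cat("age function:", x$kind)
  if (length(x$thresholds) > 0) cat(" @", paste(x$thresholds, collapse = ", "), "yr")
  cat("\n")
  invisible(x)
}

age_spec_label <- function(spec) {
  if (length(spec$thresholds) == 0) spec$kind
  else paste0(spec$kind, "(", paste(spec$thresholds, collapse = ","), ")")
}

#' Design columns for an age function
#'
#' Ages are centred on `center` (their mean by default) before the basis is
#' constructed, which stabilises the mixed-model fits without changing the
#' model space; thresholds are always given on the original age scale. The
#' piecewise bases are hinge functions, continuous at the breakpoints by
#' construction: for a single threshold `t`, columns `(min(age, t),
#' max(age - t, 0))`; for a double threshold `(t1, t2)`, `(min(age, t1),
#' clamp(age - t1, 0, t2 - t1), max(age - t2, 0))` (all on the centred
#' scale).
#'
#' @param spec An [age_function_spec()].
#' @param ages Integer ages.
#' @param center Centring constant; defaults to `mean(ages)` and is recorded
#'   as an attribute so prediction grids can reuse it.
#' @return Numeric matrix (possibly zero columns) with attributes `center`
#'   and `spec`.
#' @export
make_age_basis <- function(spec, ages, center = NULL) {
  stopifnot(inherits(spec, "age_function_spec"))
  if (is.null(center)) center <- mean(ages)
  if (length(spec$thresholds) > 0 &&
      (min(spec$thresholds) < min(ages) || max(spec$thresholds) > max(ages))) {
    stop("threshold(s) outside the observed age range")
  }
  a <- ages - center
  th <- spec$thresholds - center
  B <- switch(spec$kind,
    null = matrix(numeric(0), nrow = length(ages), ncol = 0),
    linear = cbind(age = a),
    quadratic = cbind(age = a, age2 = a^2),
    threshold1 = cbind(age_pre = pmin(a, th[1]),
                       age_post = pmax(a - th[1], 0)),
    threshold2 = cbind(age_pre = pmin(a, th[1]),
                       age_mid = pmin(pmax(a - th[1], 0), th[2] - th[1]),
                       age_post = pmax(a - th[2], 0))
  )
  attr(B, "center") <- center
  attr(B, "spec") <- spec
  B
}

#' Fit one candidate age model
#'
#' Breeding success against the age basis of `spec`, with crossed individual
#' and year (season) random intercepts.
#'
#' @param records One species x sex `breeding_records` table (age-support
#'   filtered upstream).
#' @param spec An [age_function_spec()].
#' @param center Optional centring constant shared across candidates.
#' @return A `glmm_fit` carrying `age_spec` and `age_center`.
#' @export
fit_age_model <- function(records, spec, center = NULL) {
  B <- make_age_basis(spec, records$age, center)
  X <- cbind(`(Intercept)` = 1, B)
  fit <- fit_glmm(records$outcome, X,
                  list(individual = records$individual_id, year = records$season))
  fit$age_spec <- spec
  fit$age_center <- attr(B, "center")
  fit
}

#' Candidate breakpoint grid
#'
#' Integer ages from (min observed + `margin`) to (max observed - `margin`)
#' with at least `min_side` observations strictly on each side of the split,
#' preventing degenerate hinge columns.
#'
#' @param ages Observed ages.
#' @param min_side Minimum observations on each side (default 25).
#' @param margin Years trimmed off each end of the range (default 2).
#' @return Integer vector (possibly empty).
#' @export
candidate_thresholds <- function(ages, min_side = 25, margin = 2) {
  lo <- min(ages) + margin
  hi <- max(ages) - margin
  if (hi < lo) return(integer(0))
  cand <- seq.int(lo, hi)
  ok <- vapply(cand, function(t) sum(ages < t) >= min_side && sum(ages > t) >= min_side,
               logical(1))
  cand[ok]
}

#' Scan breakpoint candidates for a threshold age model
#'
#' Refits the GLMM for every candidate breakpoint (or pair of breakpoints at
#' least 3 years apart for `kind = "threshold2"`) and profiles the AIC over
#' the grid. The best candidate minimises AIC (ties broken toward the earlier
#' threshold), and a 95% profile-deviance confidence interval is attached for
#' single-threshold scans via [threshold_ci()].
#'
#' @param records One species x sex `breeding_records` table.
#' @param kind `"threshold1"` or `"threshold2"`.
#' @param grid Candidate threshold ages; defaults to
#'   [candidate_thresholds()].
#' @param min_side Passed to [candidate_thresholds()] when `grid` is `NULL`.
#' @param min_gap Minimum separation of double thresholds (default 3).
#' @return Object of class `threshold_scan`: `kind`, `grid` (vector, or
#'   2-column matrix for double thresholds), `aic_profile`, `loglik`,
#'   `best` (an [age_function_spec()]), `best_fit` (its `glmm_fit`),
#'   `ci_low`/`ci_high` (single-threshold scans), `center`.
#' @export
scan_thresholds <- function(records, kind = c("threshold1", "threshold2"),
                            grid = NULL, min_side = 25, min_gap = 3) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- candidate_thresholds(records$age, min_side = min_side)
  if (length(grid) == 0) stop("empty candidate threshold grid")
  center <- mean(records$age)
  if (kind == "threshold1") {
    cands <- lapply(grid, function(t) age_function_spec("threshold1", t))
    grid_out <- as.numeric(grid)
  } else {
    pairs <- expand.grid(t1 = grid, t2 = grid)
    pairs <- pairs[pairs$t2 - pairs$t1 >= min_gap, , drop = FALSE]
    if (nrow(pairs) == 0) stop("empty candidate threshold grid (after min_gap)")
    cands <- lapply(seq_len(nrow(pairs)), function(i) {
      age_function_spec("threshold2", c(pairs$t1[i], pairs$t2[i]))
    })
    grid_out <- as.matrix(pairs)
  }
  fits <- lapply(cands, function(sp) fit_age_model(records, sp, center = center))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  best_i <- which(aics == min(aics))[1]    # earliest threshold wins exact ties
  scan <- structure(list(
    kind = kind, grid = grid_out, aic_profile = aics, loglik = lls,
    best = cands[[best_i]], best_index = best_i, best_fit = fits[[best_i]],
    center = center, n_obs = nrow(records)
  ), class = "threshold_scan")
  if (kind == "threshold1") {
    ci <- threshold_ci(scan)
    scan$ci_low <- ci[1]
    scan$ci_high <- ci[2]
  }
  scan
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("threshold scan (", x$kind, "), ", length(x$aic_profile), " candidates, n = ",
      x$n_obs, "\n", sep = "")
  cat("best:", age_spec_label(x$best), " AIC =", round(min(x$aic_profile), 2), "\n")
  if (!is.null(x$ci_low)) cat("95% profile CI: [", x$ci_low, ",", x$ci_high, "]\n")
  invisible(x)
}

#' Profile-deviance confidence interval for a breakpoint
#'
#' The interval is the contiguous run of candidate thresholds around the best
#' one whose deviance (-2 logLik) lies within the chi-square(1) quantile of
#' the minimum (3.841 at 95%); endpoints are the extreme grid ages in that
#' run. With a single candidate the interval is that candidate. The deviance
#' profile uses the Laplace log-likelihood, so the interval inherits that
#' approximation.
#'
#' @param scan A single-threshold [scan_thresholds()] result.
#' @param level Coverage level (default 0.95).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
threshold_ci <- function(scan, level = 0.95) {
  stopifnot(inherits(scan, "threshold_scan"))
  if (scan$kind != "threshold1") {
    stop("profile CI is defined for single-threshold scans")
  }
  dev <- -2 * scan$loglik
  within <- (dev - min(dev)) <= stats::qchisq(level, df = 1)
  i <- scan$best_index
  lo <- i
  while (lo > 1 && within[lo - 1]) lo <- lo - 1
  hi <- i
  while (hi < length(within) && within[hi + 1]) hi <- hi + 1
  c(scan$grid[lo], scan$grid[hi])
}

#' AIC model set, Akaike weights and averaged age curve
#'
#' Given candidate age-model fits on identical data, computes Delta AIC
#' relative to the best model, forms the top model set (`Delta < 2`,
#' strictly), assigns Akaike weights `w_i = exp(-Delta_i / 2) /
#' sum(exp(-Delta_j / 2))` over that set, and averages the fixed-effect
#' predicted age curves on the response (probability) scale. Averaging
#' operates on predictions rather than coefficients because coefficient
#' averaging across different bases is ill-defined.
#'
#' @param fits List of `glmm_fit` objects from [fit_age_model()] (identical
#'   response, shared centring).
#' @param prediction_ages Ages at which to evaluate the curves.
#' @return Object of class `model_set`: `members` (data frame with model,
#'   k, aic, delta, in_top, weight), `curve` (data frame with age, best
#'   model's fit and se, and `averaged_fit`), `best_index`.
#' @export
select_and_average <- function(fits, prediction_ages) {
  if (length(fits) == 0) stop("empty fit list")
  for (f in fits) {
    if (length(f$y) != length(fits[[1]]$y) || !all(f$y == fits[[1]]$y)) {
      stop("all candidate fits must share the same response data")
    }
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  delta <- aics - min(aics)
  # best: lowest AIC; exact ties broken by fewer parameters, then first listed
  ord <- order(aics, ks)
  best_i <- ord[1]
  in_top <- delta < 2
  w <- ifelse(in_top, exp(-delta / 2), 0)
  w <- w / sum(w)
  preds <- lapply(fits, function(f) {
    B <- make_age_basis(f$age_spec, prediction_ages, center = f$age_center)
    predict_fixed(f, cbind(`(Intercept)` = 1, B))
  })
  averaged <- Reduce(`+`, Map(function(p, wi) p$fit * wi, preds, w))
  members <- data.frame(
    model = vapply(fits, function(f) age_spec_label(f$age_spec), character(1)),
    k = ks, aic = aics, delta = delta, in_top = in_top, weight = w,
    stringsAsFactors = FALSE
  )
  structure(list(
    members = members,
    curve = data.frame(age = prediction_ages,
                       best_fit = preds[[best_i]]$fit,
                       best_se = preds[[best_i]]$se,
                       averaged_fit = averaged),
    best_index = best_i,
    fits = fits
  ), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  m <- x$members
  m[c("aic", "delta", "weight")] <- round(m[c("aic", "delta", "weight")], 3)
  print(m)
  cat("best:", x$members$model[x$best_index], "\n")
  invisible(x)
}

#' Akaike weights from AIC differences
#'
#' Closed form over the top model set (`delta < 2` strictly); members outside
#' the top set get weight 0.
#'
#' @param delta Vector of AIC differences relative to the best model.
#' @return Weights summing to 1 over the top set.
#' @export
akaike_weights <- function(delta) {
  in_top <- delta < 2
  w <- ifelse(in_top, exp(-delta / 2), 0)
  w / sum(w)
}
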