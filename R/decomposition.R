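#' Split records into early and late adulthood
#'
#' Early adulthood is `age <= cutoff`, late is `age > cutoff`. The cutoff is
#' normally the best single-threshold breakpoint from the population-level
#' scan for that species x sex; `overrides` (named by `"SPECIES.SEX"`, e.g.
#' `c(WA.F = 18)`) replace it where a different split is required to ensure
#' all birds have started breeding during early adulthood.
#'
#' @param records A `breeding_records` table (typically one species x sex).
#' @param cutoff Cutoff age in years.
#' @param overrides Optional named numeric vector of per-species-sex cutoffs.
#' @return List with elements `early` and `late`.
#' @export
split_at_threshold <- function(records, cutoff, overrides = NULL) {
  stopifnot(is.data.frame(records))
  cut_row <- rep(cutoff, nrow(records))
  if (!is.null(overrides)) {
    key <- paste(records$species, records$sex, sep = ".")
    hit <- key %in% names(overrides)
    cut_row[hit] <- overrides[key[hit]]
  }
  early <- records[records$age <= cut_row, , drop = FALSE]
  late <- records[records$age > cut_row, , drop = FALSE]
  if (nrow(early) == 0) stop("early-adulthood subset is empty at cutoff ", cutoff)
  if (nrow(late) == 0) stop("late-adulthood subset is empty at cutoff ", cutoff)
  cls <- class(records)
  early <- structure(early, class = cls)
  late <- structure(late, class = cls)
  list(early = early, late = late)
}

drop_degenerate <- function(X, protect = "(Intercept)") {
  dropped <- character(0)
  repeat {
    const <- apply(X, 2, function(col) stats::var(col) == 0)
    const[colnames(X) %in% protect] <- FALSE
    if (any(const)) {
      dropped <- c(dropped, colnames(X)[const])
      X <- X[, !const, drop = FALSE]
      next
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      dropped <- c(dropped, bad)
      X <- X[, !(colnames(X) %in% bad), drop = FALSE]
      next
    }
    break
  }
  list(X = X, dropped = dropped)
}

fit_decomposition <- function(records, terms, phase, importance = TRUE) {
  y <- records$outcome
  X <- cbind(`(Intercept)` = 1, as.matrix(records[, terms, drop = FALSE]))
  rep_ok <- stats::complete.cases(X)
  if (!all(rep_ok)) {
    records <- records[rep_ok, , drop = FALSE]
    X <- X[rep_ok, , drop = FALSE]
    y <- y[rep_ok]
  }
  # centre the among-individual age covariates for numerical stability only
  for (cc in intersect(c("age_first", "age_last"), colnames(X))) {
    X[, cc] <- X[, cc] - mean(X[, cc])
  }
  dd <- drop_degenerate(X)
  if (length(dd$dropped) > 0) {
    warning(phase, " model: dropped degenerate column(s): ",
            paste(dd$dropped, collapse = ", "))
  }
  fit <- fit_glmm(y, dd$X,
                  list(individual = records$individual_id, year = records$season))
  kept <- setdiff(colnames(dd$X), "(Intercept)")
  tab <- data.frame(
    term = kept,
    estimate = fit$beta[kept],
    se = fit$se[kept],
    delta_aic = if (importance) {
      vapply(kept, function(tm) term_importance(fit, tm), numeric(1))
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(
    phase = phase,
    species = paste(sort(unique(records$species)), collapse = "+"),
    sex = paste(sort(unique(records$sex)), collapse = "+"),
    table = tab, n_obs = fit$n_obs, dropped = dd$dropped, fit = fit
  ), class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("%s-adulthood decomposition: %s %s, n = %d\n",
              x$phase, x$species, x$sex, x$n_obs))
  tab <- x$table
  tab[c("estimate", "se", "delta_aic")] <- round(tab[c("estimate", "se", "delta_aic")], 3)
  print(tab)
  if (length(x$dropped) > 0) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Early-adulthood within-group-centring model
#'
#' Breeding success against `years_since_first` (within-individual
#' improvement), `age_first` (selective appearance of phenotypically
#' different recruits) and `is_first_attempt` (first-time-breeder penalty),
#' with individual and year random intercepts. Restricted to known recruits,
#' so age at first measurement reflects age at first reproduction. Each
#' headline term is reported with its Delta AIC on removal (positive = the
#' term improves fit).
#'
#' @param records Early-adulthood subset of [annotate_records()] output.
#' @param importance Compute Delta AIC on removal for each term (default
#'   `TRUE`; involves one refit per term).
#' @return A `decomposition_result`.
#' @export
fit_early_model <- function(records, importance = TRUE) {
  stopifnot(all(c("years_since_first", "age_first", "is_first_attempt",
                  "known_recruit") %in% names(records)))
  records <- records[records$known_recruit, , drop = FALSE]
  if (nrow(records) == 0) stop("no known recruits in early subset")
  fit_decomposition(records,
                    c("years_since_first", "age_first", "is_first_attempt"),
                    phase = "early", importance = importance)
}

#' Late-adulthood within-group-centring model
#'
#' Breeding success against `years_before_death` (within-individual change
#' approaching death; a positive coefficient means success declines toward
#' death), `age_last` (selective disappearance; negative = good breeders die
#' younger) and `is_last_attempt` (terminal effect), with individual and year
#' random intercepts. Restricted to presumed-dead birds, so age at last
#' measurement reflects age at last reproduction. Optional robustness terms
#' can be added without altering the headline terms.
#'
#' @param records Late-adulthood subset of [annotate_records()] output.
#' @param robustness Character subset of `c("partner_change",
#'   "years_since_last", "previous_outcome", "gap_x_previous")`; the last adds
#'   the years-since-last x previous-outcome interaction.
#' @param importance Compute Delta AIC on removal for each term (default
#'   `TRUE`).
#' @return A `decomposition_result`.
#' @export
fit_late_model <- function(records, robustness = character(0), importance = TRUE) {
  stopifnot(all(c("years_before_death", "age_last", "is_last_attempt",
                  "presumed_dead") %in% names(records)))
  allowed <- c("partner_change", "years_since_last", "previous_outcome",
               "gap_x_previous")
  bad <- setdiff(robustness, allowed)
  if (length(bad) > 0) stop("unknown robustness term(s): ", paste(bad, collapse = ", "))
  records <- records[records$presumed_dead, , drop = FALSE]
  if (nrow(records) == 0) stop("no presumed-dead birds in late subset")
  terms <- c("years_before_death", "age_last", "is_last_attempt")
  if ("gap_x_previous" %in% robustness) {
    robustness <- union(robustness, c("years_since_last", "previous_outcome"))
    records$gap_x_previous <- records$years_since_last * records$previous_outcome
  }
  terms <- c(terms, intersect(allowed, robustness))
  fit_decomposition(records, terms, phase = "late", importance = importance)
}

#' Delta AIC on removal of a term
#'
#' Refits the model without the named column(s), on identical data and with
#' the identical random-effect structure, and returns
#' `AIC(without) - AIC(with)`: positive values mean the term improves fit
#' (the sign convention of the decomposition tables).
#'
#' @param fit A `glmm_fit`.
#' @param term Column name(s) in the fitted design (a block may be removed at
#'   once); the intercept is not removable.
#' @return Scalar Delta AIC.
#' @export
term_importance <- function(fit, term) {
  stopifnot(inherits(fit, "glmm_fit"))
  if ("(Intercept)" %in% term) stop("the intercept is not removable")
  if (!all(term %in% colnames(fit$X))) {
    stop("term(s) not in the fitted design: ",
         paste(setdiff(term, colnames(fit$X)), collapse = ", "))
  }
  X0 <- fit$X[, setdiff(colnames(fit$X), term), drop = FALSE]
  if (ncol(X0) == 0) stop("removal would empty the fixed design")
  fit0 <- fit_glmm(fit$y, X0, fit$groups)
  fit0$aic - fit$aic
}

#' Which parent's age explains more variation?
#'
#' For nests where both parents' ages are known, fits the nest outcome
#' against the best single-threshold age basis of each sex simultaneously,
#' then drops each sex's pair of age columns in turn and reports the AIC
#' change (positive = that sex's age terms improve fit). The sex whose
#' removal increases AIC more explains more variation.
#'
#' @param pairs Data frame with `pair_id`, `season`, `male_age`,
#'   `female_age`, `outcome` (one row per nest x season).
#' @param male_threshold,female_threshold Best single-threshold breakpoints
#'   for each sex.
#' @param random Random-intercept structure: `"pair_year"` (default; nest
#'   pair identity plus season) or `"year"` only.
#' @return List: `delta_aic_male`, `delta_aic_female`, `more_variation`
#'   (`"M"`/`"F"`), `fit`.
#' @export
compare_sex_ages <- function(pairs, male_threshold, female_threshold,
                             random = c("pair_year", "year")) {
  random <- match.arg(random)
  need <- c("pair_id", "season", "male_age", "female_age", "outcome")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs) == 0) stop("no overlapping known-age pairs")
  Bm <- make_age_basis(age_function_spec("threshold1", male_threshold), pairs$male_age)
  Bf <- make_age_basis(age_function_spec("threshold1", female_threshold), pairs$female_age)
  colnames(Bm) <- paste0("male_", colnames(Bm))
  colnames(Bf) <- paste0("female_", colnames(Bf))
  X <- cbind(`(Intercept)` = 1, Bm, Bf)
  groups <- if (random == "pair_year") {
    list(pair = pairs$pair_id, year = pairs$season)
  } else {
    list(year = pairs$season)
  }
  fit <- fit_glmm(pairs$outcome, X, groups)
  d_m <- term_importance(fit, colnames(Bm))
  d_f <- term_importance(fit, colnames(Bf))
  list(delta_aic_male = d_m, delta_aic_female = d_f,
       more_variation = if (d_m >= d_f) "M" else "F", fit = fit)
}

#' Cross-species interaction models
#'
#' Fits the early- or late-adulthood decomposition model on all species
#' combined, with a species main effect (treatment contrasts against
#' `reference`) and species x term interactions for each of the three
#' phase-specific terms. Reports each interaction coefficient with its SE and
#' the Delta AIC on removing the whole interaction block for a term.
#'
#' @param records [annotate_records()] output covering all three species,
#'   already restricted to the phase subset (and implicitly filtered to known
#'   recruits / presumed-dead birds as in the single-species models).
#' @param phase `"early"` or `"late"`.
#' @param reference Reference species for the contrasts (default `"BBA"`).
#' @return List: `coefficients` (interaction terms with estimate/SE),
#'   `block_delta_aic` (named per term), `fit`.
#' @export
species_interaction_model <- function(records, phase = c("early", "late"),
                                      reference = "BBA") {
  phase <- match.arg(phase)
  terms <- if (phase == "early") {
    c("years_since_first", "age_first", "is_first_attempt")
  } else {
    c("years_before_death", "age_last", "is_last_attempt")
  }
  keepflag <- if (phase == "early") "known_recruit" else "presumed_dead"
  records <- records[records[[keepflag]], , drop = FALSE]
  sp <- unique(records$species)
  if (length(sp) < 2) stop("need records from at least two species")
  if (!reference %in% sp) stop("reference species absent from the data")
  records$species_f <- stats::relevel(factor(records$species), ref = reference)
  fml <- stats::as.formula(paste("~ species_f *", paste("(", paste(terms, collapse = " + "), ")")))
  X <- stats::model.matrix(fml, data = records)
  colnames(X)[1] <- "(Intercept)"
  dd <- drop_degenerate(X)
  fit <- fit_glmm(records$outcome, dd$X,
                  list(individual = records$individual_id, year = records$season))
  inter <- grep(":", colnames(dd$X), value = TRUE)
  block_delta <- vapply(terms, function(tm) {
    cols <- inter[grepl(paste0(":", tm, "$"), inter) | grepl(paste0("^", tm, ":"), inter)]
    if (length(cols) == 0) return(NA_real_)
    term_importance(fit, cols)
  }, numeric(1))
  coefs <- data.frame(term = inter, estimate = fit$beta[inter], se = fit$se[inter],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  list(coefficients = coefs, block_delta_aic = block_delta, fit = fit,
       n_obs = fit$n_obs)
}
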