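#' @keywords internal
"_PACKAGE"

SPECIES_LEVELS <- c("BBA", "GHA", "WA")
SEX_LEVELS <- c("M", "F")

REQUIRED_COLS <- c("individual_id", "species", "sex", "season", "age", "outcome")

#' Species-specific disappearance gap rule
#'
#' Number of consecutive years a bird must be unseen at the colony before it
#' is presumed dead: 4 years for the annual breeder (BBA), 5 for the two
#' biennial breeders (GHA, WA), reflecting how rarely established breeders
#' take longer gaps between attempts.
#'
#' @return Named integer vector keyed by species code.
#' @export
default_gap_rule <- function() c(BBA = 4L, GHA = 5L, WA = 5L)

#' Validate and derive a breeding-records table
#'
#' Takes a raw long-format table (one row per individual x breeding season)
#' and returns a validated, sorted `breeding_records` data frame with the
#' derived columns `attempt_index`, `years_since_last`, `previous_outcome`
#' and `partner_change`.
#'
#' @param df Data frame with columns `individual_id`, `species` (one of
#'   `"BBA"`, `"GHA"`, `"WA"`), `sex` (`"M"`/`"F"`), `season` (integer year
#'   in which the chick would fledge), `age` (integer years, >= 1) and
#'   `outcome` (0/1, 1 = chick fledged). `partner_id` and any extra columns
#'   (e.g. `known_recruit`, `failure_stage`) are carried through.
#' @return A data frame of class `breeding_records`, sorted by
#'   (`individual_id`, `season`). `years_since_last` and `previous_outcome`
#'   are `NA` on each bird's first recorded attempt; `partner_change` is 1 on
#'   the first attempt with a new partner (0 on the first attempt overall,
#'   `NA` where partner identity is unknown).
#' @export
as_breeding_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$individual_id <- as.character(df$individual_id)
  df$species <- as.character(df$species)
  df$sex <- as.character(df$sex)
  if (!all(df$species %in% SPECIES_LEVELS)) {
    stop("species must be one of ", paste(SPECIES_LEVELS, collapse = ", "))
  }
  if (!all(df$sex %in% SEX_LEVELS)) {
    stop("sex must be 'M' or 'F'")
  }
  if (!all(df$outcome %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (any(is.na(df$season)) || any(is.na(df$age))) stop("season/age must not be missing")
  if (any(df$age < 1)) stop("age must be >= 1")

  df <- df[order(df$individual_id, df$season), , drop = FALSE]
  key <- paste(df$individual_id, df$season)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, season) rows: ", key[duplicated(key)][1])
  }

  # per-individual derived covariates; seasons are strictly increasing after
  # the duplicate check, ages must be too
  idx <- split(seq_len(nrow(df)), df$individual_id)
  n <- nrow(df)
  attempt_index <- integer(n)
  years_since_last <- rep(NA_integer_, n)
  previous_outcome <- rep(NA_integer_, n)
  partner_change <- rep(NA_integer_, n)
  has_partner <- "partner_id" %in% names(df)
  for (rows in idx) {
    ages <- df$age[rows]
    if (length(rows) > 1 && any(diff(ages) <= 0)) {
      stop("non-monotone ages within individual ", df$individual_id[rows[1]])
    }
    attempt_index[rows] <- seq_along(rows)
    if (length(rows) > 1) {
      years_since_last[rows[-1]] <- diff(df$season[rows])
      previous_outcome[rows[-1]] <- df$outcome[rows[-length(rows)]]
    }
    if (has_partner) {
      p <- as.character(df$partner_id[rows])
      pc <- integer(length(rows))
      pc[1] <- 0L
      if (length(rows) > 1) {
        same <- p[-1] == p[-length(p)]
        pc[-1] <- ifelse(is.na(same), NA_integer_, as.integer(!same))
      }
      pc[is.na(p)] <- NA_integer_
      partner_change[rows] <- pc
    }
  }
  df$attempt_index <- attempt_index
  df$years_since_last <- years_since_last
  df$previous_outcome <- previous_outcome
  df$partner_change <- partner_change
  rownames(df) <- NULL
  class(df) <- c("breeding_records", "data.frame")
  df
}

#' Read breeding records from CSV
#'
#' @param path Path to a comma-separated file with a header row; missing
#'   values are empty strings. Required columns as in [as_breeding_records()].
#' @return A `breeding_records` data frame.
#' @export
read_records <- function(path) {
  # read everything as character first: "F" in the sex column must not be
  # auto-converted to logical FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  for (cc in intersect(c("season", "age", "outcome", "attempt_index",
                         "years_since_last", "previous_outcome",
                         "partner_change"), names(df))) {
    df[[cc]] <- as.integer(df[[cc]])
  }
  for (cc in intersect(c("known_recruit", "presumed_dead"), names(df))) {
    df[[cc]] <- as.logical(df[[cc]])
  }
  as_breeding_records(df)
}

#' Write breeding records to CSV
#'
#' @param records A `breeding_records` data frame.
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build per-individual breeding histories
#'
#' Summarises records into one row per bird with ages at first and last
#' observed reproduction and the disappearance-based death proxy: a bird is
#' presumed dead when the gap between its last breeding season and the end of
#' the study reaches the species-specific rule (see [default_gap_rule()]).
#' Birds failing the rule are treated as censored, not imputed.
#'
#' @param records A `breeding_records` data frame.
#' @param study_end Final monitored season (integer year).
#' @param gap_rule Named integer vector, years unseen before presumed death.
#' @return Data frame with one row per individual: `individual_id`, `species`,
#'   `sex`, `n_attempts`, `first_season`, `last_season`, `age_first`,
#'   `age_last`, `known_recruit` (taken from the records when present, else
#'   `TRUE`), `presumed_dead`.
#' @export
build_histories <- function(records, study_end, gap_rule = default_gap_rule()) {
  stopifnot(inherits(records, "breeding_records"))
  if (any(records$season > study_end)) {
    stop("study_end (", study_end, ") earlier than some breeding seasons")
  }
  idx <- split(seq_len(nrow(records)), records$individual_id)
  out <- lapply(idx, function(rows) {
    r <- records[rows, , drop = FALSE]
    kr <- if ("known_recruit" %in% names(r)) as.logical(r$known_recruit[1]) else TRUE
    data.frame(
      individual_id = r$individual_id[1],
      species = r$species[1],
      sex = r$sex[1],
      n_attempts = nrow(r),
      first_season = min(r$season),
      last_season = max(r$season),
      age_first = r$age[1],
      age_last = r$age[nrow(r)],
      known_recruit = kr,
      stringsAsFactors = FALSE
    )
  })
  h <- do.call(rbind, out)
  rownames(h) <- NULL
  gap <- gap_rule[h$species]
  if (any(is.na(gap))) stop("gap_rule missing a species present in the data")
  h$presumed_dead <- (study_end - h$last_season) >= gap
  h
}

#' Filter out poorly supported ages
#'
#' Removes observations at ages represented by fewer than `min_count` records
#' within each species x sex dataset, so that sparse extremes of the age range
#' do not unduly influence the population-level age curves. Applied once, not
#' iterated. The alternative `mode = "pool"` instead recodes sparse tail ages
#' to the nearest adequately supported age (useful with `min_count = 10`); the
#' default is to drop.
#'
#' @param records A `breeding_records` data frame (typically one species x
#'   sex).
#' @param min_count Minimum records per age value (default 5).
#' @param mode `"drop"` (default) or `"pool"`.
#' @return Filtered `breeding_records`.
#' @export
filter_age_support <- function(records, min_count = 5, mode = c("drop", "pool")) {
  mode <- match.arg(mode)
  stopifnot(inherits(records, "breeding_records"))
  grp <- interaction(records$species, records$sex, drop = TRUE)
  keep <- logical(nrow(records))
  age <- records$age
  for (g in levels(grp)) {
    sel <- which(grp == g)
    tab <- table(age[sel])
    good_ages <- as.integer(names(tab)[tab >= min_count])
    if (mode == "drop") {
      keep[sel] <- age[sel] %in% good_ages
    } else {
      keep[sel] <- TRUE
      if (length(good_ages) == 0) stop("no age has support >= ", min_count)
      # pool sparse extremes onto the nearest supported age
      bad <- sel[!(age[sel] %in% good_ages)]
      for (i in bad) {
        records$age[i] <- good_ages[which.min(abs(good_ages - age[i]))]
      }
    }
  }
  out <- if (mode == "drop") records[keep, , drop = FALSE] else records
  if (nrow(out) == 0) stop("no records remain after age-support filter")
  rownames(out) <- NULL
  class(out) <- c("breeding_records", "data.frame")
  out
}

#' Annotate records with within-individual age covariates
#'
#' Adds the covariates used by the early/late adulthood decomposition models:
#' `age_first`, `age_last`, `years_since_first` (= age - age at first
#' reproduction), `years_before_death` (= age at last reproduction - age),
#' and the binary `is_first_attempt` / `is_last_attempt` flags. Counters are
#' measured in calendar years, so skipped (deferred) seasons still advance
#' them.
#'
#' @param records A `breeding_records` data frame.
#' @return The records with derived columns appended.
#' @export
derive_covariates <- function(records) {
  stopifnot(inherits(records, "breeding_records"))
  if (nrow(records) == 0) stop("no records")
  idx <- split(seq_len(nrow(records)), records$individual_id)
  n <- nrow(records)
  age_first <- integer(n); age_last <- integer(n)
  for (rows in idx) {
    age_first[rows] <- records$age[rows[1]]
    age_last[rows] <- records$age[rows[length(rows)]]
  }
  records$age_first <- age_first
  records$age_last <- age_last
  records$years_since_first <- records$age - age_first
  records$years_before_death <- age_last - records$age
  records$is_first_attempt <- as.integer(records$attempt_index == 1)
  records$is_last_attempt <- as.integer(records$age == age_last)
  records
}

#' Merge history flags onto records
#'
#' Convenience wrapper: derives the within-individual covariates and joins the
#' `known_recruit` / `presumed_dead` flags from [build_histories()], giving an
#' analysis-ready table for the decomposition models.
#'
#' @inheritParams build_histories
#' @return Annotated `breeding_records`.
#' @export
annotate_records <- function(records, study_end, gap_rule = default_gap_rule()) {
  h <- build_histories(records, study_end, gap_rule)
  r <- derive_covariates(records)
  m <- match(r$individual_id, h$individual_id)
  r$known_recruit <- h$known_recruit[m]
  r$presumed_dead <- h$presumed_dead[m]
  r
}

#' Reproductive lifespan from mean ages
#'
#' Mean reproductive lifespan defined as the difference between the mean age
#' at last and the mean age at first reproduction (a difference of cohort
#' means, not a mean of within-bird differences, so the two cohorts need not
#' contain the same birds).
#'
#' @param mean_age_first,mean_age_last Mean ages in years.
#' @return Lifespan in years.
#' @export
repro_lifespan <- function(mean_age_first, mean_age_last) {
  mean_age_last - mean_age_first
}

#' Life-history summary per species and sex
#'
#' Mean +/- SE age at first reproduction (among known recruits), mean +/- SE
#' age at last reproduction (among presumed-dead birds, so that last observed
#' age reflects last reproduction) and the implied mean reproductive lifespan.
#'
#' @param histories Output of [build_histories()].
#' @return Data frame with one row per species x sex.
#' @export
summarize_life_history <- function(histories) {
  se <- function(x) stats::sd(x) / sqrt(length(x))
  groups <- split(histories, list(histories$species, histories$sex), drop = TRUE)
  rows <- lapply(groups, function(h) {
    first <- h$age_first[h$known_recruit]
    last <- h$age_last[h$presumed_dead]
    if (length(first) == 0) stop("no known recruits for ", h$species[1], " ", h$sex[1])
    if (length(last) == 0) stop("no presumed-dead birds for ", h$species[1], " ", h$sex[1])
    data.frame(
      species = h$species[1], sex = h$sex[1],
      n_first = length(first),
      age_first_mean = mean(first), age_first_se = se(first),
      n_last = length(last),
      age_last_mean = mean(last), age_last_se = se(last),
      repro_lifespan = repro_lifespan(mean(first), mean(last)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species, out$sex), , drop = FALSE]
}

#' Published life-history reference values
#'
#' Reference summaries of age at first and last reproduction for the three
#' Bird Island albatross study populations (black-browed, grey-headed and
#' wandering albatross), as printed in the published colony-monitoring
#' literature: sample sizes, mean +/- SE ages, and the derived mean
#' reproductive lifespan. Useful as plausibility anchors for simulations and
#' as a worked example for [repro_lifespan()].
#'
#' @return Data frame with one row per species x sex.
#' @export
albatross_life_history <- function() {
  ref <- data.frame(
    species = c("BBA", "BBA", "GHA", "GHA", "WA", "WA"),
    sex = c("M", "F", "M", "F", "M", "F"),
    n_first = c(170L, 90L, 157L, 125L, 331L, 339L),
    age_first_mean = c(9.40, 11.78, 13.47, 13.33, 10.21, 9.73),
    age_first_se = c(0.13, 0.30, 0.20, 0.19, 0.13, 0.13),
    n_last = c(155L, 82L, 180L, 161L, 279L, 276L),
    age_last_mean = c(17.89, 20.87, 27.54, 28.63, 21.33, 18.99),
    age_last_se = c(0.61, 0.86, 0.67, 0.67, 0.55, 0.58),
    stringsAsFactors = FALSE
  )
  ref$repro_lifespan <- repro_lifespan(ref$age_first_mean, ref$age_last_mean)
  ref
}
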