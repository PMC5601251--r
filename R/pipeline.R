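#' Descriptive population summary
#'
#' Per species: mean annual breeding success with its among-year standard
#' error (mean and SD/sqrt(n) of the yearly means, reflecting among-year
#' variability rather than among-nest variability), failure-stage proportions
#' when a `failure_stage` column (`"incubation"`/`"chick_rearing"`) is
#' present, and pairwise Pearson correlations of annual success between
#' species over their shared years.
#'
#' @param records A `breeding_records` table (one or more species).
#' @param min_shared_years Minimum overlapping years for a between-species
#'   correlation (default 3; fewer raises an error).
#' @return List with `species` (data frame), `correlations` (data frame,
#'   possibly empty), and `yearly` (species x year success means).
#' @export
summarize_population <- function(records, min_shared_years = 3) {
  stopifnot(inherits(records, "breeding_records"))
  sp_list <- sort(unique(records$species))
  yearly <- lapply(sp_list, function(sp) {
    r <- records[records$species == sp, ]
    agg <- stats::aggregate(outcome ~ season, data = r, FUN = mean)
    names(agg) <- c("season", "success")
    agg$species <- sp
    agg
  })
  names(yearly) <- sp_list
  sp_rows <- lapply(sp_list, function(sp) {
    ym <- yearly[[sp]]$success
    r <- records[records$species == sp, ]
    row <- data.frame(
      species = sp, n_obs = nrow(r), n_years = length(ym),
      mean_success = mean(ym), se_success = stats::sd(ym) / sqrt(length(ym)),
      stringsAsFactors = FALSE
    )
    if ("failure_stage" %in% names(r)) {
      fails <- r[r$outcome == 0 & !is.na(r$failure_stage), ]
      row$prop_fail_incubation <- if (nrow(fails) > 0) {
        mean(fails$failure_stage == "incubation")
      } else NA_real_
    }
    row
  })
  cors <- list()
  if (length(sp_list) >= 2) {
    cmb <- utils::combn(sp_list, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- yearly[[cmb[1, j]]]; b <- yearly[[cmb[2, j]]]
      shared <- intersect(a$season, b$season)
      if (length(shared) < min_shared_years) {
        stop("fewer than ", min_shared_years, " shared years for ",
             cmb[1, j], " vs ", cmb[2, j])
      }
      ct <- stats::cor.test(a$success[match(shared, a$season)],
                            b$success[match(shared, b$season)])
      cors[[j]] <- data.frame(species_a = cmb[1, j], species_b = cmb[2, j],
                              n_years = length(shared),
                              r = unname(ct$estimate), p = ct$p.value,
                              stringsAsFactors = FALSE)
    }
  }
  list(
    species = do.call(rbind, sp_rows),
    correlations = if (length(cors) > 0) do.call(rbind, cors) else
      data.frame(species_a = character(0), species_b = character(0),
                 n_years = integer(0), r = numeric(0), p = numeric(0)),
    yearly = do.call(rbind, yearly)
  )
}

#' Build an analysis configuration
#'
#' Exactly one of `input` (a records CSV path) or `simulation` (a
#' [simulation_config()], or a list of them for a multi-species run) must be
#' given.
#'
#' @param input Path to a breeding-records CSV, or `NULL`.
#' @param simulation A `simulation_config` or list thereof, or `NULL`.
#' @param study_end Final season; defaults to the maximum season in the data.
#' @param species,sex Optional subsets.
#' @param min_age_count Age-support filter threshold (default 5).
#' @param threshold_grid Optional explicit breakpoint grid.
#' @param min_side Minimum observations per side of a candidate breakpoint.
#' @param cutoff_overrides Named vector of early/late split overrides (e.g.
#'   `c(WA.F = 18)`).
#' @param robustness Robustness terms for the late model (see
#'   [fit_late_model()]).
#' @param out_dir Output directory for CSVs and the run log, or `NULL` to
#'   skip writing.
#' @param seed Seed applied before any simulation.
#' @param gap_rule Death-proxy rule, see [default_gap_rule()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, simulation = NULL, study_end = NULL,
                            species = NULL, sex = NULL, min_age_count = 5,
                            threshold_grid = NULL, min_side = 25,
                            cutoff_overrides = c(WA.F = 18),
                            robustness = character(0),
                            out_dir = NULL, seed = NULL,
                            gap_rule = default_gap_rule()) {
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of 'input' and 'simulation' must be given")
  }
  if (!is.null(simulation) && inherits(simulation, "simulation_config")) {
    simulation <- list(simulation)
  }
  structure(list(
    input = input, simulation = simulation, study_end = study_end,
    species = species, sex = sex, min_age_count = min_age_count,
    threshold_grid = threshold_grid, min_side = min_side,
    cutoff_overrides = cutoff_overrides, robustness = robustness,
    out_dir = out_dir, seed = seed, gap_rule = gap_rule
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys mirror [analysis_config()]; a `simulation` key holds one
#' simulation block or a list of blocks whose keys mirror
#' [simulation_config()].
#'
#' @param path YAML file.
#' @param seed Optional seed override.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (!is.null(seed)) vals$seed <- seed
  if (!is.null(vals$simulation)) {
    sims <- vals$simulation
    if (!is.null(names(sims)) && any(names(sims) != "")) sims <- list(sims)
    vals$simulation <- lapply(sims, function(s) do.call(simulation_config, s))
  }
  if (!is.null(vals$cutoff_overrides)) {
    vals$cutoff_overrides <- unlist(vals$cutoff_overrides)
  }
  do.call(analysis_config, vals)
}

stage <- function(name, expr, log) {
  log(paste0("stage: ", name))
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full reproductive-ageing analysis
#'
#' Pipeline per species x sex: age-support filter; candidate age models
#' (null, linear, quadratic, single-threshold scan); AIC model set with
#' averaged curve and breakpoint profile CI; early/late split at the selected
#' breakpoint (with overrides); early- and late-adulthood decomposition
#' models. Also produces a life-history summary table, a descriptive
#' population summary, and (when `out_dir` is set) CSV outputs plus a plain
#' text run log recording record counts at every stage.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list: `records`, `histories`, `life_history`,
#'   `population`, and per species-x-sex `groups` each holding `scan`,
#'   `model_set`, `cutoff`, `early`, `late`, and record counts.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character(0)
  logf <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  records <- stage("load", {
    if (!is.null(config$input)) {
      read_records(config$input)
    } else {
      parts <- lapply(config$simulation, function(sc) simulate_population(sc)$records)
      out <- do.call(rbind, lapply(parts, as.data.frame))
      as_breeding_records(out)
    }
  }, logf)
  logf(paste("records loaded:", nrow(records)))

  if (!is.null(config$species)) records <- records[records$species %in% config$species, ]
  if (!is.null(config$sex)) records <- records[records$sex %in% config$sex, ]
  if (nrow(records) == 0) stop("no records after species/sex subset")
  class(records) <- c("breeding_records", "data.frame")

  study_end <- if (is.null(config$study_end)) max(records$season) else config$study_end
  histories <- stage("histories", build_histories(records, study_end, config$gap_rule), logf)
  life <- stage("life_history", summarize_life_history(histories), logf)
  pop <- stage("population_summary", summarize_population(records), logf)
  annotated <- stage("annotate", annotate_records(records, study_end, config$gap_rule), logf)

  groups <- list()
  group_errors <- character(0)
  for (sp in sort(unique(records$species))) for (sx in sort(unique(records$sex))) {
    sel <- annotated$species == sp & annotated$sex == sx
    if (!any(sel)) next
    gname <- paste(sp, sx, sep = ".")
    grp <- annotated[sel, , drop = FALSE]
    class(grp) <- c("breeding_records", "data.frame")
    logf(paste0(gname, ": ", nrow(grp), " records"))
    res <- tryCatch({
      filtered <- stage(paste0(gname, "/age_support"),
                        filter_age_support(grp, min_count = config$min_age_count), logf)
      logf(paste0(gname, ": ", nrow(filtered), " after age-support filter"))
      center <- mean(filtered$age)
      cand <- list(
        null = fit_age_model(filtered, age_function_spec("null"), center),
        linear = fit_age_model(filtered, age_function_spec("linear"), center),
        quadratic = fit_age_model(filtered, age_function_spec("quadratic"), center)
      )
      scan <- stage(paste0(gname, "/threshold_scan"),
                    scan_thresholds(filtered, "threshold1",
                                    grid = config$threshold_grid,
                                    min_side = config$min_side), logf)
      cand$threshold1 <- scan$best_fit
      ages <- seq(min(filtered$age), max(filtered$age))
      mset <- stage(paste0(gname, "/model_set"), select_and_average(cand, ages), logf)
      cutoff <- scan$best$thresholds[1]
      halves <- stage(paste0(gname, "/split"),
                      split_at_threshold(grp, cutoff, config$cutoff_overrides), logf)
      early <- stage(paste0(gname, "/early_model"), fit_early_model(halves$early), logf)
      late <- stage(paste0(gname, "/late_model"),
                    fit_late_model(halves$late, robustness = config$robustness), logf)
      logf(paste0(gname, ": threshold ", cutoff, " [", scan$ci_low, ", ",
                  scan$ci_high, "], early n=", early$n_obs, ", late n=", late$n_obs))
      list(scan = scan, model_set = mset, cutoff = cutoff, early = early,
           late = late, n_records = nrow(grp), n_filtered = nrow(filtered))
    }, error = function(e) {
      logf(paste0(gname, ": skipped (", conditionMessage(e), ")"))
      group_errors <<- c(group_errors, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) groups[[gname]] <- res
  }
  if (length(groups) == 0 && length(group_errors) > 0) {
    stop("no species-sex group could be analysed; first error: ", group_errors[1],
         call. = FALSE)
  }

  bundle <- list(records = records, histories = histories, life_history = life,
                 population = pop, groups = groups, log = log_lines,
                 study_end = study_end)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE, na = "")
    }
    wr(life, "life_history.csv")
    wr(pop$species, "population_summary.csv")
    wr(pop$correlations, "annual_success_correlations.csv")
    decomp <- do.call(rbind, lapply(names(groups), function(g) {
      do.call(rbind, lapply(c("early", "late"), function(ph) {
        r <- groups[[g]][[ph]]
        cbind(phase = ph, species = r$species, sex = r$sex, r$table,
              n = r$n_obs, stringsAsFactors = FALSE)
      }))
    }))
    if (!is.null(decomp)) wr(decomp, "decomposition.csv")
    for (g in names(groups)) {
      tag <- gsub("\\.", "_", g)
      wr(groups[[g]]$model_set$curve, paste0("curve_", tag, ".csv"))
      scan <- groups[[g]]$scan
      wr(data.frame(threshold = scan$grid, aic = scan$aic_profile,
                    loglik = scan$loglik), paste0("scan_", tag, ".csv"))
      wr(groups[[g]]$model_set$members, paste0("model_set_", tag, ".csv"))
    }
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(bundle)
}
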