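#' Read a pipeline run configuration
#'
#' Run configurations are plain lists (or YAML files) with these fields,
#' all optional unless noted: `simulate` (a list of [sim_config()]
#' overrides; if absent, `readings` and `patients` CSV paths must be
#' given), `cutoff` (calendar cutoff, default 2015-09-01),
#' `observation_end`, `white_coat_delta` (default 5), `bootstrap` (list
#' with `n_resamples`, `telemon_threshold`, `comparator_threshold`),
#' `stages` (subset of `"standardise"`, `"end_digits"`, `"stratified"`,
#' `"matched"`, `"propensity"`, `"rcm"`; default all), `seed` (required
#' when any stochastic stage is enabled), and `out_dir` (required).
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: simulate (or read) a cohort, clean it,
#' build the standardised dataset, and execute the enabled analysis stages,
#' writing every table as CSV plus a machine-readable run manifest
#' (package version, seed, config hash, row counts) to `config$out_dir`.
#' Reruns with the same configuration and seed are identical.
#'
#' @param config A configuration list (see [read_run_config()]) or a YAML
#'   path.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `standardised`, and one element per stage) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) abort("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||%
    c("standardise", "end_digits", "stratified", "matched", "propensity",
      "rcm")
  cutoff <- as.Date(config$cutoff %||% "2015-09-01")
  delta <- config$white_coat_delta %||% 5
  seed <- config$seed
  results <- list()

  emit <- function(df, name) {
    write.csv(df, file.path(out_dir, paste0(name, ".csv")),
              row.names = FALSE)
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  if (!is.null(config$simulate)) {
    if (is.null(seed)) abort("config$seed is required when simulating")
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    sim <- run_stage("simulate",
                     simulate_cohort(do.call(sim_config, sim_args)))
    cohort_raw <- sim$cohort
    emit(sim$truth, "truth")
    write_cohort(cohort_raw,
                 file.path(out_dir, "readings.csv"),
                 file.path(out_dir, "patients.csv"))
  } else {
    cohort_raw <- run_stage("read",
                            read_cohort(config$readings, config$patients,
                                        telemonitoring_start = cutoff))
  }

  cleaned <- run_stage("clean", clean_cohort(cohort_raw))
  cohort <- cleaned$cohort
  results$cohort <- cohort
  if (nrow(cleaned$exclusions$excluded) > 0) {
    emit(cleaned$exclusions$excluded, "excluded_readings")
  }

  if ("end_digits" %in% stages) {
    results$end_digits <- run_stage("end_digits", {
      surgery <- filter(cohort$readings, .data$source == "surgery")
      tab <- end_digit_table(surgery)
      emit(tidy(tab), "end_digit_crosstab")
      emit(bind_rows(end_digit_frequencies(surgery, "systolic"),
                     end_digit_frequencies(surgery, "diastolic")),
           "end_digit_frequencies")
      tab
    })
  }

  needs_std <- any(c("standardise", "stratified", "matched", "propensity")
                   %in% stages)
  if (needs_std) {
    records <- run_stage("standardise", {
      r <- build_standardised_dataset(
        cohort, observation_end = config$observation_end)
      emit(flow_report(r), "flow_report")
      emit(r, "standardised")
      r
    })
    results$standardised <- records

    if ("stratified" %in% stages) {
      results$stratified <- run_stage("stratified", {
        emit(raised_bp_table(records), "raised_bp")
        emit(strata_summary(records, "systolic"), "strata_summary_sbp")
        emit(strata_summary(records, "diastolic"), "strata_summary_dbp")
        strata <- c("overall", "<135", "135+", "140+", "145+", "150+")
        models <- purrr::map_dfr(strata, function(s) {
          tryCatch(tidy(stratified_lmm(records, s, white_coat_delta = delta)),
                   error = function(e) tibble(stratum = s,
                                              error = conditionMessage(e)))
        })
        emit(models, "stratified_models")
        boot_cfg <- config$bootstrap %||% list()
        boot <- bootstrap_rrr_ratio(
          records,
          telemon_threshold = boot_cfg$telemon_threshold %||% 145,
          comparator_threshold = boot_cfg$comparator_threshold %||% 145,
          n_resamples = boot_cfg$n_resamples %||% 9999,
          seed = seed)
        emit(glance(boot), "rrr_ratio_bootstrap")
        list(models = models, bootstrap = boot)
      })
    }
    if ("matched" %in% stages) {
      results$matched <- run_stage("matched", {
        m <- find_matches(records,
                          criteria = list(sbp_matching = "nearest_0_or_5",
                                          white_coat_delta = delta))
        emit(m$pairs, "matched_pairs")
        grid <- sensitivity_grid(records)
        emit(grid, "matched_sensitivity_grid")
        list(matched = m, grid = grid,
             effect = if (nrow(m$pairs) >= 2) paired_t_test(m) else NULL)
      })
    }
    if ("propensity" %in% stages) {
      results$propensity <- run_stage("propensity", {
        adj <- adjust_white_coat(records, delta)
        ps <- fit_propensity(adj)
        emit(ps$scores, "propensity_scores")
        eff <- ps_adjusted_lmm(records, scores = ps$scores,
                               white_coat_delta = delta)
        emit(tidy(eff), "propensity_effect")
        list(scores = ps, effect = eff)
      })
    }
  }

  if ("rcm" %in% stages) {
    results$rcm <- run_stage("rcm", {
      rows <- prepare_longitudinal(cohort_raw, cutoff = cutoff)
      fits <- fit_all_practices(rows)
      pooled <- pool_practices(fits)
      forest <- forest_data(pooled)
      emit(forest, "rcm_forest")
      per_practice <- purrr::map_dfr(fits, function(f) {
        mutate(f$estimates, practice_id = f$practice_id,
               annualised = annualise(.data$estimate))
      })
      emit(per_practice, "rcm_per_practice")
      overall <- fit_overall_rcm(rows)
      emit(tidy(overall), "rcm_overall")
      list(rows = rows, fits = fits, pooled = pooled, overall = overall)
    })
  }

  manifest <- list(
    package = "telebp",
    version = as.character(utils::packageVersion("telebp")),
    seed = seed,
    stages = stages,
    config_hash = rlang::hash(config),
    n_patients = nrow(cohort$patients),
    n_readings = nrow(cohort$readings),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
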