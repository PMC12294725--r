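#' Assessment configuration
#'
#' Bundles the tunables of the acute exposure assessment: the acute
#' reference dose, the Monte Carlo size, bootstrap replication count, master
#' seed, reported percentile levels, and the suppression threshold for
#' percentile statistics.
#'
#' @param arfd acute reference dose in mg/d (default 50, the temporary
#'   histamine ARfD for healthy adults).
#' @param iterations Monte Carlo iterations (default 100000).
#' @param bootstrap_reps bootstrap resamples for the P97.5 CI (default 100).
#' @param seed integer master seed (default 1).
#' @param report_percentiles strictly increasing percent levels in (0, 100)
#'   (default 25, 50, 75, 90, 95, 97.5, 99, 99.9).
#' @param min_detects_for_p95 suppression threshold for percentile
#'   statistics (default 10 detects).
#' @return a list of class `ba_config`.
#' @export
assessment_config <- function(arfd = 50, iterations = 100000L,
                              bootstrap_reps = 100L, seed = 1L,
                              report_percentiles = c(25, 50, 75, 90, 95,
                                                     97.5, 99, 99.9),
                              min_detects_for_p95 = 10L) {
  cfg <- structure(
    list(arfd = arfd, iterations = as.integer(iterations),
         bootstrap_reps = as.integer(bootstrap_reps),
         seed = as.integer(seed),
         report_percentiles = as.numeric(report_percentiles),
         min_detects_for_p95 = as.integer(min_detects_for_p95)),
    class = "ba_config"
  )
  validate_config(cfg)
}

#' Validate an assessment configuration
#'
#' Checks every range constraint without running anything; violations are
#' collected and reported together, each naming the offending key.
#'
#' @param config a `ba_config` (or a plain list with the same keys, e.g.
#'   parsed from a YAML/JSON config file).
#' @return the configuration, invisibly, when valid; otherwise an error
#'   listing every violation.
#' @export
validate_config <- function(config) {
  errors <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(config$arfd) && config$arfd > 0, "arfd: must be > 0")
  chk(is.numeric(config$iterations) && config$iterations >= 1,
      "iterations: must be >= 1")
  chk(is.numeric(config$bootstrap_reps) && config$bootstrap_reps >= 2,
      "bootstrap_reps: must be >= 2")
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed: must be a single integer")
  p <- config$report_percentiles
  chk(is.numeric(p) && length(p) >= 1L && all(p > 0) && all(p < 100) &&
        !is.unsorted(p, strictly = TRUE),
      "report_percentiles: must be strictly increasing within (0, 100)")
  chk(is.numeric(config$min_detects_for_p95) &&
        config$min_detects_for_p95 >= 1,
      "min_detects_for_p95: must be >= 1")
  if (length(errors) > 0L) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  }
  invisible(config)
}

#' Read an assessment configuration from a YAML or JSON file
#'
#' Missing keys fall back to the [assessment_config()] defaults; the merged
#' configuration is validated before being returned.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a validated `ba_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- formals(assessment_config)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(raw, unlist)
  do.call(assessment_config, args)
}

#' Run the full assessment pipeline
#'
#' Chains the stages end to end on a monitoring + consumption dataset:
#' censored descriptive summaries; worst-case point assessment against the
#' ARfD; lognormal/mixture model fitting for the strata with enough
#' detects; Monte Carlo exposure simulation with bootstrap CI and
#' exceedance probability; and level-of-concern back-calculation with a
#' count of samples above it. Every output table is written under
#' `out_dir` and listed in the returned manifest.
#'
#' @param concentrations concentration record data.frame, or a CSV path.
#' @param consumption consumption record data.frame, or a CSV path.
#' @param config an [assessment_config()].
#' @param out_dir output directory for the result tables.
#' @param simulate_categories food categories to run the probabilistic
#'   stage for (default: those with at least 30 detected histamine
#'   samples and consumption data).
#' @param analyte analyte for the probabilistic stage (default `"HIS"`,
#'   the only amine with an established acute reference dose).
#' @return a manifest list: `config`, `outputs` (named file paths),
#'   `summaries`, `point`, `models`, `simulations`, `loc`.
#' @export
run_full_pipeline <- function(concentrations, consumption,
                              config = assessment_config(),
                              out_dir = tempfile("ba_run_"),
                              simulate_categories = NULL,
                              analyte = "HIS") {
  validate_config(config)
  if (is.character(concentrations)) {
    concentrations <- read_concentration_table(concentrations)
  } else {
    concentrations <- validate_concentration_records(concentrations)
  }
  if (is.character(consumption)) {
    consumption <- read_consumption_table(consumption)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()

  ## 1. censored descriptive summaries (per subcategory and per category)
  summaries <- summarize_concentrations(concentrations,
                                        min_n = config$min_detects_for_p95)
  cat_records <- concentrations
  cat_records$subcategory <- cat_records$food_category
  cat_summaries <- summarize_concentrations(cat_records,
                                            min_n = config$min_detects_for_p95)
  outputs["summary"] <- file.path(out_dir, "summary.csv")
  write_summary_table(summaries, outputs[["summary"]])

  ## 2. empirical P99 consumption per category, then point assessment
  com_p99 <- tapply(consumption$amount, consumption$food_category,
                    function(a) unname(stats::quantile(a, 0.99, type = 7)))
  com_p99 <- stats::setNames(as.numeric(com_p99), names(com_p99))
  point <- point_assessment(cat_summaries, com_p99, arfd = config$arfd)
  outputs["point"] <- file.path(out_dir, "point_assessment.csv")
  utils::write.csv(point, outputs[["point"]], row.names = FALSE)

  ## 3. fit + simulate for the probabilistic categories
  conc_by_cat <- split(concentrations,
                       concentrations$food_category)
  if (is.null(simulate_categories)) {
    simulate_categories <- names(Filter(function(g) {
      sum(g$detected & g$analyte == analyte) >= 30L
    }, conc_by_cat))
    simulate_categories <- intersect(simulate_categories, names(com_p99))
  }
  models <- list()
  sims <- list()
  loc_rows <- list()
  for (cat in simulate_categories) {
    g <- conc_by_cat[[cat]]
    g <- g[g$analyte == analyte, , drop = FALSE]
    cons_amounts <- consumption$amount[consumption$food_category == cat]
    if (sum(g$detected) < 2L || length(cons_amounts) < 2L) next
    conc_model <- fit_mixture(g)
    cons_model <- fit_consumption(cons_amounts)
    models[[cat]] <- list(conc = conc_model, cons = cons_model)
    params_path <- file.path(out_dir, paste0("params_", gsub("\\W+", "_", cat),
                                             ".json"))
    write_model_params(models_to_params(conc_model, cons_model), params_path)
    outputs[paste0("params_", cat)] <- params_path
    sims[[cat]] <- simulate_exposure(conc_model, cons_model, config)
    loc <- level_of_concern(config$arfd, com_p99[[cat]])
    loc_rows[[cat]] <- data.frame(
      food_category = cat, loc = loc,
      n_samples_above = count_above_loc(g, loc),
      stringsAsFactors = FALSE
    )
  }
  if (length(sims) > 0L) {
    report <- exposure_report(sims)
    outputs["exposure"] <- file.path(out_dir, "exposure_report.csv")
    write_exposure_report(report, outputs[["exposure"]])
  }
  loc_table <- if (length(loc_rows) > 0L) {
    do.call(rbind, loc_rows)
  } else {
    data.frame(food_category = character(), loc = numeric(),
               n_samples_above = integer(), stringsAsFactors = FALSE)
  }
  rownames(loc_table) <- NULL
  outputs["loc"] <- file.path(out_dir, "level_of_concern.csv")
  utils::write.csv(loc_table, outputs[["loc"]], row.names = FALSE)

  list(config = config, outputs = outputs, summaries = summaries,
       point = point, models = models, simulations = sims, loc = loc_table)
}
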