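#' @keywords internal
#' @importFrom stats quantile simulate coef
#' @importFrom graphics plot hist abline
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

## Five-analyte vocabulary used throughout: histamine, tyramine, putrescine,
## cadaverine, tryptamine.
BA_ANALYTES <- c("HIS", "TYR", "PUT", "CAD", "TRY")

#' Default limit of detection (mg/kg)
#'
#' The monitoring assay's effective limit of detection. Non-detects are
#' left-censored at this concentration; the mixture model places a
#' Uniform(0, LOD) distribution below it.
#' @export
DEFAULT_LOD <- 0.2

#' Construct a table of concentration records
#'
#' Builds and validates the sample-level concentration table: one row per
#' analytical measurement of one analyte in one food sample, possibly
#' left-censored at the limit of detection (a non-detect).
#'
#' @param sample_id character sample identifiers.
#' @param food_category character food category (e.g. "fermented bean products").
#' @param subcategory character subcategory (e.g. "fermented bean curd").
#' @param analyte analyte code, one of `"HIS"`, `"TYR"`, `"PUT"`, `"CAD"`,
#'   `"TRY"` (case-insensitive).
#' @param value measured concentration in mg/kg; `NA` for non-detects.
#' @param detected logical; `TRUE` when the analyte was quantified. Defaults
#'   to `!is.na(value)`.
#' @param lod limit of detection in mg/kg applicable to each measurement.
#'
#' @return A `data.frame` with columns `sample_id`, `food_category`,
#'   `subcategory`, `analyte`, `value`, `detected`, `lod`, validated for
#'   censoring consistency: `value` is present iff `detected`, positive, and
#'   never below `lod`.
#' @export
concentration_records <- function(sample_id, food_category, subcategory,
                                  analyte, value, detected = !is.na(value),
                                  lod = DEFAULT_LOD) {
  n <- length(value)
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    food_category = rep_len(as.character(food_category), n),
    subcategory = rep_len(as.character(subcategory), n),
    analyte = rep_len(toupper(as.character(analyte)), n),
    value = rep_len(as.numeric(value), n),
    detected = rep_len(as.logical(detected), n),
    lod = rep_len(as.numeric(lod), n),
    stringsAsFactors = FALSE
  )
  validate_concentration_records(df)
}

#' Validate a concentration record table
#'
#' Enforces the censoring-consistency invariants: a value is present iff the
#' row is a detect, detected values are positive and not below their limit of
#' detection, and analyte codes belong to the five-analyte vocabulary.
#'
#' @param df a data.frame shaped as [concentration_records()].
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_concentration_records <- function(df) {
  required <- c("sample_id", "food_category", "subcategory", "analyte",
                "value", "detected", "lod")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("concentration table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_analyte <- !(df$analyte %in% BA_ANALYTES)
  if (any(bad_analyte)) {
    stop("unknown analyte code in row(s) ",
         paste(utils::head(which(bad_analyte), 5L), collapse = ", "),
         ": ", paste(unique(df$analyte[bad_analyte]), collapse = ", "))
  }
  if (any(df$lod <= 0 | is.na(df$lod))) {
    stop("lod must be positive for every row")
  }
  mismatch <- df$detected != !is.na(df$value)
  if (any(mismatch)) {
    stop("value present iff detected violated in row(s) ",
         paste(utils::head(which(mismatch), 5L), collapse = ", "))
  }
  det <- which(df$detected)
  if (any(df$value[det] <= 0)) {
    stop("detected concentrations must be positive")
  }
  below <- det[df$value[det] < df$lod[det]]
  if (length(below) > 0L) {
    stop("detected value below its LOD (censoring inconsistency) in row(s) ",
         paste(utils::head(below, 5L), collapse = ", "))
  }
  df
}

#' Read a concentration monitoring table from CSV
#'
#' Expects header columns `sample_id`, `food_category`, `subcategory`,
#' `analyte`, `value`, `lod`. An empty `value` cell or the sentinel `"ND"`
#' marks a non-detect. Rows failing censoring consistency (a detected value
#' below its LOD) or carrying an unknown analyte code are rejected with an
#' error naming the row.
#'
#' @param path path to a CSV file.
#' @return a validated concentration record data.frame
#'   (see [concentration_records()]).
#' @export
read_concentration_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("sample_id", "food_category", "subcategory", "analyte",
                "value", "lod")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("concentration CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  vraw <- trimws(raw$value)
  nd <- vraw == "" | toupper(vraw) == "ND" | is.na(raw$value)
  value <- rep(NA_real_, nrow(raw))
  if (any(!nd)) {
    parsed <- suppressWarnings(as.numeric(vraw[!nd]))
    if (any(is.na(parsed))) {
      stop("non-numeric concentration in row(s) ",
           paste(utils::head(which(!nd)[is.na(parsed)], 5L), collapse = ", "))
    }
    value[!nd] <- parsed
  }
  lod <- suppressWarnings(as.numeric(raw$lod))
  if (any(is.na(lod))) {
    stop("non-numeric lod in row(s) ",
         paste(utils::head(which(is.na(lod)), 5L), collapse = ", "))
  }
  concentration_records(
    sample_id = raw$sample_id,
    food_category = raw$food_category,
    subcategory = raw$subcategory,
    analyte = raw$analyte,
    value = value,
    detected = !nd,
    lod = lod
  )
}

#' Write a concentration record table to CSV
#'
#' Inverse of [read_concentration_table()]: non-detects are serialized with
#' the `"ND"` sentinel in the value column.
#'
#' @param records a validated concentration record data.frame.
#' @param path output CSV path.
#' @export
write_concentration_table <- function(records, path) {
  records <- validate_concentration_records(records)
  out <- records[, c("sample_id", "food_category", "subcategory", "analyte",
                     "value", "lod")]
  out$value <- ifelse(records$detected, sprintf("%.17g", records$value), "ND")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-person-day food consumption table from CSV
#'
#' Expects header columns `person_day_id`, `food_category`, `amount`
#' (grams per day). Only consumers are recorded, so non-positive or
#' non-numeric amounts are rejected.
#'
#' @param path path to a CSV file.
#' @return a data.frame with columns `person_day_id`, `food_category`,
#'   `amount`.
#' @export
read_consumption_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("person_day_id", "food_category", "amount")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("consumption CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  amount <- suppressWarnings(as.numeric(raw$amount))
  if (any(is.na(amount))) {
    stop("non-numeric amount in row(s) ",
         paste(utils::head(which(is.na(amount)), 5L), collapse = ", "))
  }
  if (any(amount <= 0)) {
    stop("consumption amounts must be positive (consumer-only table); row(s) ",
         paste(utils::head(which(amount <= 0), 5L), collapse = ", "))
  }
  data.frame(
    person_day_id = raw$person_day_id,
    food_category = raw$food_category,
    amount = amount,
    stringsAsFactors = FALSE
  )
}

#' Write consumption records to CSV
#' @param records data.frame with `person_day_id`, `food_category`, `amount`.
#' @param path output CSV path.
#' @export
write_consumption_table <- function(records, path) {
  utils::write.csv(records[, c("person_day_id", "food_category", "amount")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Sentinel used to render a suppressed percentile in report tables, matching
## the monitoring-report convention for cells that cannot be reliably
## estimated from a small number of detects.
SUPPRESSED_SENTINEL <- "\\"

#' Write a category-by-analyte summary table to CSV
#'
#' Renders detection rates as percent and concentrations in mg/kg, both to
#' one decimal; a suppressed 95th percentile (too few detects) is rendered
#' with the `"\\"` sentinel. Full precision is retained in the in-memory
#' summary; rounding happens only at serialization.
#'
#' @param summaries data.frame from [summarize_concentrations()].
#' @param path output CSV path.
#' @export
write_summary_table <- function(summaries, path) {
  out <- data.frame(
    food_category = summaries$food_category,
    subcategory = summaries$subcategory,
    analyte = summaries$analyte,
    n = summaries$n,
    n_detect = summaries$n_detect,
    detection_rate_pct = sprintf("%.1f", 100 * summaries$detection_rate),
    mean_detect = ifelse(is.na(summaries$mean_detect), SUPPRESSED_SENTINEL,
                         sprintf("%.1f", summaries$mean_detect)),
    p95_detect = ifelse(is.na(summaries$p95_detect), SUPPRESSED_SENTINEL,
                        sprintf("%.1f", summaries$p95_detect)),
    max_detect = ifelse(is.na(summaries$max_detect), SUPPRESSED_SENTINEL,
                        sprintf("%.1f", summaries$max_detect)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a summary table written by [write_summary_table()]
#'
#' Suppressed cells (the `"\\"` sentinel) come back as `NA`.
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored (1-decimal precision).
#' @export
read_summary_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  num <- function(x) suppressWarnings(
    ifelse(trimws(x) == SUPPRESSED_SENTINEL, NA_real_, as.numeric(x)))
  data.frame(
    food_category = raw$food_category,
    subcategory = raw$subcategory,
    analyte = raw$analyte,
    n = as.integer(raw$n),
    n_detect = as.integer(raw$n_detect),
    detection_rate = num(raw$detection_rate_pct) / 100,
    mean_detect = num(raw$mean_detect),
    p95_detect = num(raw$p95_detect),
    max_detect = num(raw$max_detect),
    stringsAsFactors = FALSE
  )
}

#' Write fitted model parameters to a YAML or JSON file
#'
#' Round-trips the quantities of the mixture exposure model: lognormal
#' parameters for detected concentrations and for consumption, the detection
#' probability, and the LOD. The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param params named list with elements `con_ds_meanlog`, `con_ds_sdlog`,
#'   `lod`, `p_detect`, `com_meanlog`, `com_sdlog`.
#' @param path output path.
#' @export
write_model_params <- function(params, path) {
  required <- c("con_ds_meanlog", "con_ds_sdlog", "lod", "p_detect",
                "com_meanlog", "com_sdlog")
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop("model parameter file lacks key(s): ", paste(missing, collapse = ", "))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(params[required], path)
  } else {
    jsonlite::write_json(params[required], path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read fitted model parameters from a YAML or JSON file
#' @param path path written by [write_model_params()].
#' @return named list of the six model parameters.
#' @export
read_model_params <- function(path) {
  params <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  required <- c("con_ds_meanlog", "con_ds_sdlog", "lod", "p_detect",
                "com_meanlog", "com_sdlog")
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop("model parameter file lacks key(s): ", paste(missing, collapse = ", "))
  }
  lapply(params[required], as.numeric)
}
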