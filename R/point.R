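#' Deterministic worst-case acute exposure
#'
#' Point (deterministic) assessment of acute dietary exposure: the product
#' of a high-percentile daily consumption (P99, g/d) and a high-percentile
#' concentration (P95, mg/kg), divided by 1000 to express the result in
#' mg/d. This is the worst-case screening estimate compared against an
#' acute reference dose.
#'
#' @param com_p99 99th percentile of daily consumption, g/d (>= 0).
#' @param con_stat concentration statistic, mg/kg (>= 0); the P95 of the
#'   detected concentrations, or the maximum when the P95 is suppressed.
#' @return acute exposure in mg/d. Vectorized over both arguments.
#' @export
point_exposure <- function(com_p99, con_stat) {
  if (any(com_p99 < 0) || any(con_stat < 0)) {
    stop("consumption and concentration must be non-negative")
  }
  com_p99 * con_stat / 1000
}

#' Concentration statistic for the point assessment
#'
#' Selects the 95th percentile of detected concentrations when available;
#' when the P95 is suppressed (too few detects) it falls back to the maximum
#' detected concentration, flagged so reports can mark the cell with an
#' asterisk. A stratum with zero detects yields no statistic and is excluded
#' with a warning.
#'
#' @param summary one row of [summarize_concentrations()] output.
#' @return list with elements `value` (mg/kg) and `is_max` (logical), or
#'   `NULL` (with a warning) when the stratum has no detects.
#' @export
select_concentration_statistic <- function(summary) {
  if (summary$n_detect == 0L || is.na(summary$max_detect)) {
    warning("no detected samples for ", summary$food_category, " / ",
            summary$analyte, "; stratum excluded from point assessment")
    return(NULL)
  }
  if (!is.na(summary$p95_detect)) {
    list(value = summary$p95_detect, is_max = FALSE)
  } else {
    list(value = summary$max_detect, is_max = TRUE)
  }
}

#' Worst-case substitution of non-detects at the LOD
#'
#' Conservative treatment of left-censored observations for screening:
#' every non-detect is assigned its limit of detection as the value and
#' marked as imputed; detected values are untouched. Substituting at the
#' LOD can only raise summary statistics, never lower them.
#'
#' @param records concentration record data.frame.
#' @return a copy of `records` with non-detect `value` set to `lod`,
#'   `detected` unchanged, and a logical `imputed` column added.
#' @export
worst_case_substitute <- function(records) {
  out <- records
  out$imputed <- !records$detected
  out$value[!records$detected] <- records$lod[!records$detected]
  out
}

#' Screen point-assessment exposures against an acute reference dose
#'
#' Flags each result whose exposure strictly exceeds the ARfD ("more than"
#' the reference dose indicates a possible acute health risk; boundary
#' equality does not flag). Comparison is on unrounded values.
#'
#' @param results data.frame with an `exp` column in mg/d.
#' @param arfd acute reference dose in mg/d (> 0); default 50 (the
#'   temporary histamine ARfD for healthy adults).
#' @return `results` with a logical `exceeds_arfd` column set; row order
#'   preserved.
#' @export
arfd_screen <- function(results, arfd = 50) {
  if (arfd <= 0) stop("arfd must be positive")
  results$exceeds_arfd <- results$exp > arfd
  results
}

#' Level of concern for a food category
#'
#' Back-calculates the concentration at which a high consumer (P99 daily
#' consumption) exactly reaches the acute reference dose:
#' LOC = ARfD / Com_P99 x 1000 (mg/kg). A food sample above the LOC can, on
#' its own, push a high consumer past the ARfD.
#'
#' @param arfd acute reference dose in mg/d.
#' @param com_p99 99th percentile of daily consumption in g/d (> 0).
#' @return level of concern in mg/kg.
#' @export
level_of_concern <- function(arfd, com_p99) {
  if (any(com_p99 <= 0)) stop("com_p99 must be positive")
  arfd / com_p99 * 1000
}

#' Count samples above a level of concern
#'
#' Number of detected records whose measured concentration strictly exceeds
#' the level of concern. Non-detects (below the LOD, hence far below any
#' meaningful LOC) never count.
#'
#' @param records concentration record data.frame.
#' @param loc level of concern in mg/kg (> 0).
#' @return integer count.
#' @export
count_above_loc <- function(records, loc) {
  if (loc <= 0) stop("loc must be positive")
  if (nrow(records) == 0L) return(0L)
  sum(records$detected & records$value > loc)
}

#' Point assessment table over categories and analytes
#'
#' Builds the full deterministic screening table: for every food category x
#' analyte stratum of `summaries`, applies the P95-or-maximum concentration
#' rule, computes exposure = P99 consumption x concentration / 1000, and
#' flags exceedance of the ARfD.
#'
#' @param summaries output of [summarize_concentrations()] aggregated at the
#'   level matching `consumption_p99` (typically food_category).
#' @param consumption_p99 named numeric vector: P99 daily consumption (g/d)
#'   per food_category. Categories without consumption data are skipped.
#' @param arfd acute reference dose in mg/d (default 50).
#' @return data.frame with columns `food_category`, `analyte`, `com_p99`,
#'   `con_stat`, `con_stat_is_max`, `exp`, `exceeds_arfd`.
#' @export
point_assessment <- function(summaries, consumption_p99, arfd = 50) {
  rows <- vector("list", nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, , drop = FALSE]
    if (!(s$food_category %in% names(consumption_p99))) next
    stat <- select_concentration_statistic(s)
    if (is.null(stat)) next
    com <- unname(consumption_p99[[s$food_category]])
    rows[[i]] <- data.frame(
      food_category = s$food_category,
      analyte = s$analyte,
      com_p99 = com,
      con_stat = stat$value,
      con_stat_is_max = stat$is_max,
      exp = point_exposure(com, stat$value),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(food_category = character(), analyte = character(),
                      com_p99 = numeric(), con_stat = numeric(),
                      con_stat_is_max = logical(), exp = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  arfd_screen(out, arfd)
}
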