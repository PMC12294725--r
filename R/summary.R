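#' Detection rate of a censored sample
#'
#' Fraction of monitoring samples with a measurable (>= LOD) concentration:
#' number of positive samples over total samples. This is also the mixture
#' weight placed on the detected-concentration branch of the probabilistic
#' model.
#'
#' @param records concentration record data.frame (one category x analyte).
#' @return fraction in `[0, 1]`.
#' @export
detection_rate <- function(records) {
  if (nrow(records) == 0L) stop("detection rate undefined on an empty sample")
  mean(records$detected)
}

#' Mean concentration over detected samples
#'
#' Arithmetic mean of the quantified values only; non-detects are excluded,
#' not substituted. With zero detects the statistic is suppressed (`NA`),
#' never reported as 0.
#'
#' @param records concentration record data.frame.
#' @return mean in mg/kg, or `NA` when there are no detects.
#' @export
mean_of_detects <- function(records) {
  v <- records$value[records$detected]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Empirical percentile of detected concentrations
#'
#' Sorted-sample linear interpolation (the type-7 convention,
#' index h = (n - 1) p / 100 + 1) over detected values only. When fewer than
#' `min_n` detects are available the percentile cannot be reliably estimated
#' and is suppressed (`NA`).
#'
#' @param records concentration record data.frame.
#' @param p percent level in (0, 100]; p = 100 returns the maximum.
#' @param min_n minimum number of detects below which the estimate is
#'   suppressed (default 10).
#' @return percentile in mg/kg, or `NA` when suppressed or no detects.
#' @export
percentile_of_detects <- function(records, p = 95, min_n = 10L) {
  if (p <= 0 || p > 100) stop("percent level must lie in (0, 100]")
  v <- records$value[records$detected]
  if (length(v) == 0L || length(v) < min_n) return(NA_real_)
  unname(stats::quantile(v, probs = p / 100, type = 7))
}

#' Maximum detected concentration
#' @param records concentration record data.frame.
#' @return maximum in mg/kg, or `NA` when there are no detects.
#' @export
max_of_detects <- function(records) {
  v <- records$value[records$detected]
  if (length(v) == 0L) return(NA_real_)
  max(v)
}

#' Category-by-analyte summary of a censored monitoring table
#'
#' Computes, for every `food_category` x `subcategory` x `analyte` stratum:
#' sample count, detect count, detection rate, mean and 95th percentile of
#' the detected concentrations, and the maximum detect. The percentile is
#' suppressed (`NA`) below `min_n` detects.
#'
#' @param records concentration record data.frame.
#' @param min_n suppression threshold for the percentile (default 10).
#' @param p percent level for the reported upper percentile (default 95).
#' @return data.frame with one row per stratum, columns `food_category`,
#'   `subcategory`, `analyte`, `n`, `n_detect`, `detection_rate`,
#'   `mean_detect`, `p95_detect`, `max_detect`.
#' @export
summarize_concentrations <- function(records, min_n = 10L, p = 95) {
  records <- validate_concentration_records(records)
  key <- interaction(records$food_category, records$subcategory,
                     records$analyte, drop = TRUE, sep = "\r")
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    data.frame(
      food_category = g$food_category[1L],
      subcategory = g$subcategory[1L],
      analyte = g$analyte[1L],
      n = nrow(g),
      n_detect = sum(g$detected),
      detection_rate = detection_rate(g),
      mean_detect = mean_of_detects(g),
      p95_detect = percentile_of_detects(g, p = p, min_n = min_n),
      max_detect = max_of_detects(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$food_category, out$subcategory,
            match(out$analyte, BA_ANALYTES)), , drop = FALSE]
}

#' Detection-weighted total biogenic amine concentration
#'
#' The total average burden of the five amines in one food subcategory:
#' the sum over analytes of detection_rate x mean-of-detects. This equals
#' the mean over all samples of the per-sample analyte sum with non-detects
#' scored as zero, which is how the total burden of a food is ranked across
#' categories.
#'
#' @param summaries summary rows (one per analyte) of a single subcategory,
#'   as produced by [summarize_concentrations()]. Missing analytes
#'   contribute zero.
#' @return total average concentration in mg/kg.
#' @export
total_average_bas <- function(summaries) {
  if (nrow(summaries) == 0L) return(0)
  contrib <- summaries$detection_rate * summaries$mean_detect
  contrib[is.na(contrib)] <- 0  # zero detects: no burden contribution
  sum(contrib)
}

#' Per-sample total burden computed directly from records
#'
#' Independent route to [total_average_bas()]: for each sample, sum the
#' concentrations of its analytes with non-detects scored zero, then average
#' over samples. Used to check the weighted-sum identity. Assumes every
#' sample was assayed for the same set of analytes (a complete design).
#'
#' @param records concentration record data.frame of one subcategory.
#' @return mean per-sample total in mg/kg.
#' @export
total_average_bas_from_records <- function(records) {
  if (nrow(records) == 0L) return(0)
  scored <- ifelse(records$detected, records$value, 0)
  per_sample <- tapply(scored, records$sample_id, sum)
  mean(per_sample)
}
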