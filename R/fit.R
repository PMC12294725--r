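#' Maximum-likelihood lognormal fit
#'
#' Fits a lognormal distribution to positive data by maximum likelihood:
#' `meanlog` is the mean of the log values and `sdlog` their standard
#' deviation with divisor n (the true MLE; at survey sample sizes the n
#' versus n-1 choice is immaterial, but it is fixed here and documented).
#' Used both for detected concentrations (mg/kg) and for daily consumption
#' amounts (g/d).
#'
#' @param x positive numeric values, length >= 2.
#' @param what label for the fitted quantity carried into print output.
#' @return an object of class `ba_lognormal` with elements `meanlog`,
#'   `sdlog`, `n`, `what`, and `gof` (a Shapiro-Wilk statistic on the log
#'   values when 3 <= n <= 5000; reported, never gating).
#' @export
fit_lognormal <- function(x, what = "values") {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("lognormal fit requires finite positive values")
  }
  n <- length(x)
  if (n < 2L) stop("at least 2 values required (sdlog undefined)")
  lx <- log(x)
  meanlog <- mean(lx)
  sdlog <- sqrt(sum((lx - meanlog)^2) / n)
  if (sdlog == 0) stop("degenerate sample: all values identical")
  gof <- if (n >= 3L && n <= 5000L) {
    unname(stats::shapiro.test(lx)$statistic)
  } else NA_real_
  structure(
    list(meanlog = meanlog, sdlog = sdlog, n = n, what = what, gof = gof),
    class = "ba_lognormal"
  )
}

#' Construct a lognormal parameter object directly
#'
#' For models specified from published parameters rather than fitted from
#' data (e.g. a reported consumption distribution).
#'
#' @param meanlog mean of the natural-log values.
#' @param sdlog standard deviation of the natural-log values (> 0).
#' @param what label for print output.
#' @return a `ba_lognormal` object.
#' @export
lognormal_params <- function(meanlog, sdlog, what = "values") {
  if (sdlog <= 0) stop("sdlog must be positive")
  structure(
    list(meanlog = meanlog, sdlog = sdlog, n = NA_integer_, what = what,
         gof = NA_real_),
    class = "ba_lognormal"
  )
}

#' Fit the consumption distribution
#'
#' Lognormal MLE on per-person-day consumption amounts (g/d); a thin wrapper
#' over [fit_lognormal()] that takes a consumption record table.
#'
#' @param records consumption data.frame with an `amount` column, or a bare
#'   numeric vector of amounts.
#' @return a `ba_lognormal` object.
#' @export
fit_consumption <- function(records) {
  amounts <- if (is.data.frame(records)) records$amount else records
  fit_lognormal(amounts, what = "consumption (g/d)")
}

#' @export
print.ba_lognormal <- function(x, ...) {
  cat("Lognormal model for", x$what, "\n")
  cat(sprintf("  meanlog = %.4f, sdlog = %.4f", x$meanlog, x$sdlog))
  if (!is.na(x$n)) cat(sprintf("  (MLE, n = %d)", x$n))
  cat("\n")
  cat(sprintf("  implied mean %.4g, P99 %.4g\n",
              exp(x$meanlog + x$sdlog^2 / 2),
              stats::qlnorm(0.99, x$meanlog, x$sdlog)))
  if (!is.na(x$gof)) {
    cat(sprintf("  Shapiro-Wilk W on log values: %.4f (descriptive only)\n",
                x$gof))
  }
  invisible(x)
}

#' @export
coef.ba_lognormal <- function(object, ...) {
  c(meanlog = object$meanlog, sdlog = object$sdlog)
}

#' Quantiles of a fitted lognormal
#' @param x a `ba_lognormal` object.
#' @param probs probabilities.
#' @param ... unused.
#' @return quantile vector (same units as the fitted data).
#' @export
quantile.ba_lognormal <- function(x, probs = seq(0, 1, 0.25), ...) {
  stats::qlnorm(probs, meanlog = x$meanlog, sdlog = x$sdlog)
}

#' Mean of a fitted lognormal
#' @param x a `ba_lognormal` object.
#' @param ... unused.
#' @return `exp(meanlog + sdlog^2 / 2)`.
#' @export
mean.ba_lognormal <- function(x, ...) {
  exp(x$meanlog + x$sdlog^2 / 2)
}

#' Draw random variates from a fitted lognormal
#' @param object a `ba_lognormal` object.
#' @param nsim number of draws.
#' @param seed optional integer seed (set before drawing when given).
#' @param ... unused.
#' @return numeric vector of draws.
#' @export
simulate.ba_lognormal <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::rlnorm(nsim, meanlog = object$meanlog, sdlog = object$sdlog)
}

#' Fit the detect/non-detect mixture concentration model
#'
#' The concentration of an analyte in a food category is modelled as a
#' two-branch discrete mixture: with probability `p_detect` (the detection
#' rate) a lognormal variate fitted to the detected concentrations, and
#' with probability `1 - p_detect` a Uniform(0, LOD) variate standing in
#' for the unknown concentration of a non-detect.
#'
#' @param records concentration record data.frame of a single food category
#'   x analyte stratum. All rows must share one LOD; mixed LODs require
#'   stratifying the data first.
#' @param fitted optional pre-fitted `ba_lognormal` for the detected branch;
#'   fitted from the detects by MLE when omitted.
#' @param food_category,analyte labels (taken from `records` when omitted).
#' @return an object of class `ba_mixture` with elements `p_detect`,
#'   `p_nondetect`, `detect_dist` (`ba_lognormal`), `nondetect_upper` (the
#'   LOD, mg/kg), `food_category`, `analyte`, `n`.
#' @export
fit_mixture <- function(records, fitted = NULL, food_category = NULL,
                        analyte = NULL) {
  records <- validate_concentration_records(records)
  lods <- unique(records$lod)
  if (length(lods) != 1L) {
    stop("records carry ", length(lods), " distinct LODs; stratify the data ",
         "so each mixture model has a single LOD")
  }
  p <- detection_rate(records)
  if (is.null(fitted)) {
    if (sum(records$detected) < 2L) {
      stop("need at least 2 detected values to fit the lognormal branch")
    }
    fitted <- fit_lognormal(records$value[records$detected],
                            what = "detected concentrations (mg/kg)")
  }
  mixture_model(
    p_detect = p, detect_dist = fitted, lod = lods,
    food_category = if (is.null(food_category)) records$food_category[1L]
                    else food_category,
    analyte = if (is.null(analyte)) records$analyte[1L] else analyte,
    n = nrow(records)
  )
}

#' Construct a mixture concentration model from parameters
#'
#' Assembles the detect/non-detect mixture directly from published or
#' externally fitted parameters.
#'
#' @param p_detect detection probability in `[0, 1]`.
#' @param detect_dist a `ba_lognormal` for the detected branch, or a
#'   numeric vector `c(meanlog, sdlog)`.
#' @param lod upper bound (mg/kg) of the Uniform(0, LOD) non-detect branch.
#' @param food_category,analyte labels.
#' @param n optional sample size behind the model.
#' @return a `ba_mixture` object.
#' @export
mixture_model <- function(p_detect, detect_dist, lod = DEFAULT_LOD,
                          food_category = NA_character_,
                          analyte = "HIS", n = NA_integer_) {
  if (p_detect < 0 || p_detect > 1) stop("p_detect must lie in [0, 1]")
  if (lod <= 0) stop("lod must be positive")
  if (is.numeric(detect_dist)) {
    detect_dist <- lognormal_params(detect_dist[[1L]], detect_dist[[2L]],
                                    what = "detected concentrations (mg/kg)")
  }
  stopifnot(inherits(detect_dist, "ba_lognormal"))
  structure(
    list(p_detect = p_detect, p_nondetect = 1 - p_detect,
         detect_dist = detect_dist, nondetect_upper = lod,
         food_category = food_category, analyte = analyte, n = n),
    class = "ba_mixture"
  )
}

#' @export
print.ba_mixture <- function(x, ...) {
  cat("Mixture concentration model")
  if (!is.na(x$food_category)) cat(" for", x$analyte, "in", x$food_category)
  cat("\n")
  cat(sprintf("  detect branch (weight %.4f): Lognormal(%.4f, %.4f)\n",
              x$p_detect, x$detect_dist$meanlog, x$detect_dist$sdlog))
  cat(sprintf("  non-detect branch (weight %.4f): Uniform(0, %.3g)\n",
              x$p_nondetect, x$nondetect_upper))
  m <- model_moments(x)
  cat(sprintf("  model mean %.4g mg/kg, sd %.4g mg/kg\n", m[["mean"]],
              sqrt(m[["variance"]])))
  invisible(x)
}

#' @export
coef.ba_mixture <- function(object, ...) {
  c(p_detect = object$p_detect,
    meanlog = object$detect_dist$meanlog,
    sdlog = object$detect_dist$sdlog,
    lod = object$nondetect_upper)
}

#' Analytic mean and variance of a mixture concentration model
#'
#' Closed-form moments of the detect/non-detect mixture, used as an oracle
#' against the sampler: the mean is
#' `p_detect * exp(meanlog + sdlog^2/2) + p_nondetect * LOD/2`, and the
#' variance follows the standard mixture decomposition (mean of the branch
#' variances plus the variance of the branch means).
#'
#' @param model a `ba_mixture` object.
#' @return named numeric vector `c(mean =, variance =)` in mg/kg (squared
#'   for the variance).
#' @export
model_moments <- function(model) {
  mu <- model$detect_dist$meanlog
  sg <- model$detect_dist$sdlog
  u <- model$nondetect_upper
  m_ln <- exp(mu + sg^2 / 2)
  v_ln <- (exp(sg^2) - 1) * exp(2 * mu + sg^2)
  m_un <- u / 2
  v_un <- u^2 / 12
  p <- model$p_detect
  q <- model$p_nondetect
  m <- p * m_ln + q * m_un
  v <- p * v_ln + q * v_un + p * (m_ln - m)^2 + q * (m_un - m)^2
  c(mean = m, variance = v)
}

#' @rdname model_moments
#' @param x a `ba_mixture` object.
#' @param ... unused.
#' @export
mean.ba_mixture <- function(x, ...) {
  unname(model_moments(x)[["mean"]])
}

#' Convert fitted models to a flat parameter list
#'
#' Packs a mixture concentration model and a consumption lognormal into the
#' six-key parameter list round-tripped by [write_model_params()].
#'
#' @param conc_model a `ba_mixture`.
#' @param cons a `ba_lognormal` for consumption.
#' @return named list of six numeric parameters.
#' @export
models_to_params <- function(conc_model, cons) {
  list(
    con_ds_meanlog = conc_model$detect_dist$meanlog,
    con_ds_sdlog = conc_model$detect_dist$sdlog,
    lod = conc_model$nondetect_upper,
    p_detect = conc_model$p_detect,
    com_meanlog = cons$meanlog,
    com_sdlog = cons$sdlog
  )
}

#' Rebuild model objects from a flat parameter list
#' @param params list as returned by [read_model_params()].
#' @param food_category,analyte labels for the concentration model.
#' @return list with elements `conc` (`ba_mixture`) and `cons`
#'   (`ba_lognormal`).
#' @export
params_to_models <- function(params, food_category = NA_character_,
                             analyte = "HIS") {
  list(
    conc = mixture_model(
      p_detect = params$p_detect,
      detect_dist = c(params$con_ds_meanlog, params$con_ds_sdlog),
      lod = params$lod, food_category = food_category, analyte = analyte
    ),
    cons = lognormal_params(params$com_meanlog, params$com_sdlog,
                            what = "consumption (g/d)")
  )
}
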