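test_that("concentration sampling follows the detect/non-detect mixture", {
  # degenerate detect-only model collapses to exp(meanlog)
  m <- mixture_model(1, c(2, 1e-9), lod = 0.2)
  draws <- simulate(m, 100, seed = TEST_SEED)
  expect_equal(as.numeric(draws), rep(exp(2), 100), tolerance = 1e-6)

  # pure non-detect model: Uniform(0, 0.2)
  m0 <- mixture_model(0, c(2, 1), lod = 0.2)
  draws0 <- simulate(m0, 5e4, seed = TEST_SEED)
  expect_true(all(draws0 > 0 & draws0 < 0.2))
  expect_lt(abs(mean(draws0) - 0.1), 3 * (0.2 / sqrt(12)) / sqrt(5e4))

  # branch frequency converges to the mixture weight
  n <- 1e5
  fb <- fb_mixture()
  draws_fb <- simulate(fb, n, seed = TEST_SEED)
  f_unif <- mean(!attr(draws_fb, "branch_detect"))
  se <- sqrt(0.2123 * 0.7877 / n)
  expect_lt(abs(f_unif - 0.2123), 3 * se)
})

test_that("exposure simulation is reproducible and seed-sensitive", {
  cfg <- assessment_config(iterations = 2e4, seed = TEST_SEED)
  a <- simulate_exposure(fb_mixture(), fb_consumption(), cfg)
  b <- simulate_exposure(fb_mixture(), fb_consumption(), cfg)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$percentile_table, b$percentile_table)
  expect_identical(a$ci_p975, b$ci_p975)
  cfg2 <- assessment_config(iterations = 2e4, seed = TEST_SEED + 1L)
  c <- simulate_exposure(fb_mixture(), fb_consumption(), cfg2)
  expect_false(identical(a$exposures, c$exposures))
})

test_that("point-mass models reproduce the level-of-concern duality", {
  conc <- mixture_model(1, c(log(416 + 2 / 3), 1e-12), lod = 0.2)
  cons <- lognormal_params(log(120), 1e-12)
  cfg <- assessment_config(iterations = 1000, seed = TEST_SEED)
  sim <- simulate_exposure(conc, cons, cfg)
  expect_equal(sim$exposures, rep(50, 1000), tolerance = 1e-6)
  expect_equal(unname(diff(sim$ci_p975)), 0, tolerance = 1e-6)
})

test_that("the simulated mean factorizes into the analytic model means", {
  cfg <- assessment_config(iterations = 1e5, seed = TEST_SEED)
  for (models in list(list(fb_mixture(), fb_consumption()),
                      list(ch_mixture(), ch_consumption()))) {
    sim <- simulate_exposure(models[[1]], models[[2]], cfg)
    expected <- mean(models[[1]]) * mean(models[[2]]) / 1000
    se <- sd(sim$exposures) / sqrt(cfg$iterations)
    expect_lt(abs(sim$mean_exposure - expected), 3 * se)
  }
})

test_that("exceedance probability uses the strict threshold convention", {
  expect_equal(exceedance_probability(c(1, 2, 3), arfd = 50), 0)
  expect_equal(exceedance_probability(c(1, 2, 3), arfd = 0), 1)
  expect_equal(exceedance_probability(c(49, 50, 51), arfd = 50), 1 / 3)
  expect_error(exceedance_probability(numeric(), 50), "empty")
})

test_that("the closed-form tail oracle matches its frozen value and refuses misuse", {
  p <- analytic_tail_oracle(fb_mixture(), fb_consumption(), 50)
  expect_equal(p, 0.00401229, tolerance = 1e-5)
  expect_lt(analytic_tail_oracle(fb_mixture(), fb_consumption(), 1e9), 1e-12)
  none <- mixture_model(0, c(2.52, 2.01), lod = 0.2)
  expect_equal(analytic_tail_oracle(none, fb_consumption(), 50), 0)
  # a threshold within the non-detect branch's reach invalidates the oracle
  expect_error(analytic_tail_oracle(fb_mixture(), fb_consumption(), 0.001),
               "oracle invalid")
})

test_that("simulated tails agree with the oracle on randomized parameter sets", {
  set.seed(TEST_SEED)
  n <- 4e4
  for (k in 1:5) {
    conc <- mixture_model(runif(1, 0.3, 0.95),
                          c(runif(1, 0.5, 3), runif(1, 1.2, 2.2)), lod = 0.2)
    cons <- lognormal_params(runif(1, 2, 3.5), runif(1, 0.5, 1))
    # threshold near the upper tail of the detect branch
    thr <- qlnorm(0.995, conc$detect_dist$meanlog + cons$meanlog - log(1000),
                  sqrt(conc$detect_dist$sdlog^2 + cons$sdlog^2))
    p_true <- analytic_tail_oracle(conc, cons, thr)
    cfg <- assessment_config(iterations = n, seed = TEST_SEED + k,
                             bootstrap_reps = 2L)
    sim <- simulate_exposure(conc, cons, cfg)
    p_hat <- exceedance_probability(sim, thr)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
})

test_that("bootstrap interval brackets the percentile and tightens with n", {
  cfg <- assessment_config(iterations = 2e4, seed = TEST_SEED)
  sim <- simulate_exposure(fb_mixture(), fb_consumption(), cfg)
  p975 <- unname(quantile(sim, 0.975))
  width <- unname(diff(sim$ci_p975))
  expect_lt(sim$ci_p975[["low"]], p975 * 1.05)
  expect_gt(sim$ci_p975[["high"]], p975 * 0.95)
  expect_lt(width, 0.25 * p975)

  widths <- sapply(1:5, function(k) {
    x_small <- simulate_exposure(
      fb_mixture(), fb_consumption(),
      assessment_config(iterations = 5e3, seed = TEST_SEED + 10L + k))
    x_big <- simulate_exposure(
      fb_mixture(), fb_consumption(),
      assessment_config(iterations = 2e4, seed = TEST_SEED + 10L + k))
    c(small = unname(diff(x_small$ci_p975)),
      big = unname(diff(x_big$ci_p975)))
  })
  expect_lt(median(widths["big", ]), median(widths["small", ]))
})

test_that("exposure reports are tabular, ordered and round-trippable", {
  cfg <- assessment_config(iterations = 5e3, seed = TEST_SEED)
  sims <- list(simulate_exposure(fb_mixture(), fb_consumption(), cfg),
               simulate_exposure(ch_mixture(), ch_consumption(), cfg))
  rep_tab <- exposure_report(sims)
  expect_equal(nrow(rep_tab), 2L)
  pct_cols <- grep("^P[0-9]", names(rep_tab), value = TRUE)
  expect_equal(pct_cols, c("P25", "P50", "P75", "P90", "P95", "P97.5",
                           "P99", "P99.9"))
  for (i in 1:2) {
    expect_false(is.unsorted(as.numeric(rep_tab[i, pct_cols])))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_exposure_report(rep_tab, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(as.numeric(back[1, pct_cols]),
               as.numeric(rep_tab[1, pct_cols]), tolerance = 1e-10)
})

test_that("reported percentiles are monotone for every seed", {
  for (k in 1:4) {
    cfg <- assessment_config(iterations = 2e3, seed = 100L + k,
                             bootstrap_reps = 2L)
    sim <- simulate_exposure(fb_mixture(), fb_consumption(), cfg)
    expect_false(is.unsorted(sim$percentile_table))
  }
})
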