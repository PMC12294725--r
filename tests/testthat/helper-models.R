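# Canonical model objects and record builders shared across tests.
# TEST_SEED is the suite's master seed, fixed once for all stochastic checks.
TEST_SEED <- 42L

# Published mixture model for histamine in fermented bean products:
# 78.77% detects ~ Lognormal(2.52, 2.01), else Uniform(0, 0.2).
fb_mixture <- function() {
  mixture_model(0.7877, c(2.52, 2.01), lod = 0.2,
                food_category = "fermented bean products", analyte = "HIS")
}
fb_consumption <- function() lognormal_params(2.62, 0.92, "consumption (g/d)")

# Cheese: 27.16% detects ~ Lognormal(0.84, 1.96), else Uniform(0, 0.2).
ch_mixture <- function() {
  mixture_model(0.2716, c(0.84, 1.96), lod = 0.2,
                food_category = "cheese", analyte = "HIS")
}
ch_consumption <- function() lognormal_params(3.02, 0.62, "consumption (g/d)")

# Quick record builder: values with NA marking non-detects.
make_records <- function(values, lod = 0.2, category = "test",
                         subcategory = category, analyte = "HIS",
                         id_prefix = "s") {
  concentration_records(
    sample_id = paste0(id_prefix, seq_along(values)),
    food_category = category, subcategory = subcategory,
    analyte = analyte, value = values, lod = lod
  )
}

# A mixed multi-analyte dataset with a complete design (every sample
# measured for all five analytes), for total-burden equivalence checks.
make_multianalyte_records <- function(n = 40, seed = TEST_SEED) {
  set.seed(seed)
  parts <- lapply(seq_along(c("HIS", "TYR", "PUT", "CAD", "TRY")), function(j) {
    analyte <- c("HIS", "TYR", "PUT", "CAD", "TRY")[j]
    v <- rlnorm(n, meanlog = j * 0.4, sdlog = 1.1)
    v[v < 0.2] <- NA  # left-censor at the LOD
    concentration_records(
      sample_id = paste0("m", seq_len(n)),
      food_category = "mixed", subcategory = "mixed",
      analyte = analyte, value = v, lod = 0.2
    )
  })
  do.call(rbind, parts)
}
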