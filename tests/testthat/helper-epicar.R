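# Shared helpers: Monte-Carlo standard errors, scaled-down chain settings and
# small window builders used across the suite.

# batch-means Monte-Carlo standard error of a (possibly autocorrelated) chain
mcse <- function(x, n_batch = 25) {
  n <- length(x)
  b <- n %/% n_batch
  bm <- colMeans(matrix(x[seq_len(b * n_batch)], nrow = b))
  stats::sd(bm) / sqrt(n_batch)
}

# desk-scale chain profile used throughout the tests
test_control <- function(...) {
  mcmc_control(burn_in = 1000, iterations = 20000, thin = 10, ...)
}

# uniform-births window with given per-pixel case counts
flat_window <- function(width, height, births_per_pixel, cases, rate) {
  b <- matrix(births_per_pixel, height, width)
  compute_expected(study_window(b, cases), rate)
}

# the three hierarchical priors compared in the sensitivity analysis
three_priors <- function() {
  list(prior_gamma_variance(0.5, 0.0005),
       prior_gamma_variance(0.01, 0.01),
       prior_uniform_sd(0, 100))
}
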