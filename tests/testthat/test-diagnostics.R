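# Convergence diagnostics and sensitivity analyses.

test_that("R-hat is 1 for identical chains and large for separated chains", {
  set.seed(2)
  x <- rnorm(500)
  expect_equal(gelman_rubin(cbind(x, x))$rhat, 1, tolerance = 1e-9)
  # chains with disjoint supports
  sep <- cbind(rnorm(100, 0, 1e-4), rnorm(100, 10, 1e-4))
  gr <- gelman_rubin(sep)
  expect_gt(gr$rhat, 10)
  expect_false(gr$converged)
})

test_that("R-hat of i.i.d. chains is near 1", {
  set.seed(3)
  for (r in 1:5) {
    m <- matrix(rnorm(2000), 1000, 2)
    gr <- gelman_rubin(m)
    expect_lt(gr$rhat, 1.05)
    expect_true(gr$converged)
  }
})

test_that("R-hat matches an independent recomputation of its formula", {
  set.seed(4)
  draws <- matrix(rnorm(120, rep(c(0, 0.4, 1), each = 40)), 40, 3)
  got <- gelman_rubin(draws)$rhat
  # reference: sqrt((W + B/n)/W), W = mean within-chain variance,
  # B/n = variance of the chain means
  W <- mean(c(var(draws[, 1]), var(draws[, 2]), var(draws[, 3])))
  Bn <- var(colMeans(draws))
  expect_equal(got, sqrt((W + Bn) / W), tolerance = 1e-6)
})

test_that("R-hat validates its inputs and addresses fit parameters", {
  expect_error(gelman_rubin(matrix(rnorm(100), 100, 1)), "two chains")
  expect_error(gelman_rubin(matrix(rnorm(8), 4, 2)), "ten draws")
  set.seed(5)
  w <- compute_expected(study_window(matrix(30, 3, 3),
                                     matrix(rbinom(9, 30, 0.1), 3, 3)), 0.1)
  fit <- zip_icar(w, control = mcmc_control(burn_in = 200, iterations = 2000,
                                            thin = 5, seed = 2))
  for (p in c("alpha", "sigma", "S[5]")) {
    gr <- gelman_rubin(fit, p)
    expect_true(is.finite(gr$rhat) && gr$rhat >= 1 - 1e-9)
  }
  expect_error(gelman_rubin(fit, "S[99]"), "out of range")
})

test_that("listing the same prior twice with one seed reproduces the report exactly", {
  set.seed(6)
  w <- compute_expected(study_window(matrix(50, 4, 4),
                                     matrix(rbinom(16, 50, 0.15), 4, 4)), 0.1)
  rep <- run_prior_sensitivity(w, list(prior_uniform_sd(0, 100),
                                       prior_uniform_sd(0, 100)),
                               control = mcmc_control(burn_in = 200,
                                                      iterations = 2000,
                                                      thin = 5, seed = 44))
  expect_identical(rep$runs[[1]]$ep$ep, rep$runs[[2]]$ep$ep)
  expect_identical(rep$runs[[1]]$sigma, rep$runs[[2]]$sigma)
  expect_equal(rep$pairwise$max_abs_ep_diff, 0)
  expect_equal(rep$pairwise$status_agreement, 1)
})

test_that("on null data the neighbourhood SD posterior shrinks for every prior", {
  scn <- scenario(n_births = 100000, rr0 = 1, seed = 23)
  pts <- simulate_dataset(scn)
  w <- compute_expected(extract_window(bin_to_pixels(pts), scenario_site(scn)),
                        overall_rate(pts))
  rep <- run_prior_sensitivity(w, three_priors(),
                               control = test_control(seed = 3, n_chains = 1))
  meds <- vapply(rep$runs, function(r) unname(r$sigma["median"]), 0)
  expect_true(all(meds < 0.5))
  # ...and is smaller than under a strong spatial signal
  scn2 <- scenario(n_births = 100000, rr0 = 5, seed = 23)
  pts2 <- simulate_dataset(scn2)
  w2 <- compute_expected(extract_window(bin_to_pixels(pts2), scenario_site(scn2)),
                         overall_rate(pts2))
  fit2 <- zip_icar(w2, control = test_control(seed = 3, n_chains = 1))
  expect_gt(median(fit2$samples$sigma), min(meds))
})

test_that("outcome sensitivity runs the full pipeline per outcome and matches clusters", {
  scn <- scenario(n_births = 150000, rr0 = 5, decay_range = 2,
                  outcomes = c(VLBW = 1, LBW = 10), seed = 31)
  pts <- simulate_dataset(scn)
  rep <- run_outcome_sensitivity(pts, c("VLBW", "LBW"), scenario_site(scn),
                                 control = test_control(seed = 7, n_chains = 1))
  expect_equal(rep$labels, c("VLBW", "LBW"))
  expect_true(all(vapply(rep$runs, function(r) nrow(r$clusters$clusters), 0L) >= 1))
  # the two outcomes share the risk surface: top clusters nearly coincide
  expect_lt(rep$pairwise$centroid_distance_km, 2)

  # a single outcome degenerates to one run without pairwise entries
  rep1 <- run_outcome_sensitivity(pts, "VLBW", scenario_site(scn),
                                  control = test_control(seed = 7, n_chains = 1))
  expect_equal(length(rep1$runs), 1L)
  expect_null(rep1$pairwise)
})

test_that("outcome sensitivity validates outcomes", {
  pts <- data.frame(x = runif(50, 0, 5), y = runif(50, 0, 5), VLBW = 0L)
  expect_error(run_outcome_sensitivity(pts, "PTD", list(x = 2, y = 2)),
               "not found")
  expect_error(run_outcome_sensitivity(pts, "VLBW", list(x = 2, y = 2)),
               "zero cases")
})
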