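# Likelihood, ICAR prior density and the MCMC sampler.

test_that("zero-inflated Poisson log-likelihood matches closed forms", {
  # one occupied pixel with E = 1, Y = 2 at alpha = S = 0: log pmf = -1 - log 2
  w <- compute_expected(study_window(matrix(c(2, 0, 0, 0), 2, 2),
                                     matrix(c(1, 0, 0, 0), 2, 2)), 0.5)
  expect_equal(zip_loglik(w, 0, rep(0, 4)),
               dpois(1, 1, log = TRUE))
  w2 <- compute_expected(study_window(matrix(c(10, 0, 0, 0), 2, 2),
                                      matrix(c(2, 0, 0, 0), 2, 2)), 0.1)
  expect_equal(zip_loglik(w2, 0, rep(0, 4)), -1 - log(2))
  # structural zeros contribute exactly nothing
  w0 <- compute_expected(study_window(matrix(0, 2, 2)), 0.5)
  expect_equal(zip_loglik(w0, 1.3, rnorm(4)), 0)
})

test_that("log-likelihood is additive over disjoint duplicated windows", {
  b <- matrix(c(5, 8, 0, 12), 2, 2)
  y <- matrix(c(1, 0, 0, 3), 2, 2)
  one <- compute_expected(study_window(b, y), 0.1)
  two <- compute_expected(study_window(cbind(b, b), cbind(y, y)), 0.1)
  a <- 0.3
  expect_equal(zip_loglik(two, a, rep(0, 8)), 2 * zip_loglik(one, a, rep(0, 4)))
})

test_that("windows with cases at empty pixels or occupied pixels without expectation are rejected", {
  expect_error(study_window(matrix(c(0, 5, 3, 2), 2, 2),
                            matrix(c(1, 0, 0, 0), 2, 2)),
               "cases exceed births")
  expect_error(study_window(matrix(c(1, 5, 3, 2), 2, 2),
                            expected = matrix(0, 2, 2)),
               "occupied pixel with zero expected")
})

test_that("ICAR log-density matches hand computations and is translation invariant", {
  a <- build_adjacency(3, 3)
  tau <- 1.7
  # constant field: pairwise sum 0, density = ((n - c)/2) log tau
  expect_equal(icar_logdensity(rep(4.2, 9), tau, a), (8 / 2) * log(tau))
  # 2-pixel path graph, S = (0, 1), tau = 2: pairwise term = -1
  a2 <- epicar:::.grid_adjacency(2, 1)
  expect_equal(icar_logdensity(c(0, 1), 2, a2) - 0.5 * log(2), -1)
  # improper prior: invariant to adding any constant
  S <- rnorm(9)
  expect_equal(icar_logdensity(S, tau, a), icar_logdensity(S + 3.14, tau, a))
})

test_that("initial values follow the zero and dispersed strategies", {
  w <- study_window(matrix(1, 3, 3))
  expect_equal(initial_values(w, "zero"),
               list(alpha = 0, S = rep(0, 9), sigma = 1))
  d1 <- initial_values(w, "dispersed", seed = 9)
  d2 <- initial_values(w, "dispersed", seed = 9)
  expect_identical(d1, d2)
  expect_equal(sum(d1$S), 0, tolerance = 1e-12)
  expect_true(abs(d1$alpha) <= 3 && d1$sigma >= 0.1 && d1$sigma <= 10)
})

test_that("a fixed seed reproduces the posterior draws bitwise", {
  w <- compute_expected(study_window(matrix(5, 3, 3),
                                     matrix(rbinom(9, 5, 0.2), 3, 3)), 0.2)
  ctl <- mcmc_control(burn_in = 100, iterations = 500, thin = 5, seed = 77)
  f1 <- zip_icar(w, control = ctl)
  f2 <- zip_icar(w, control = ctl)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$log_post, f2$log_post)
})

test_that("field draws honour the sum-to-zero constraint and SD prior bounds", {
  set.seed(8)
  w <- compute_expected(study_window(matrix(20, 4, 4),
                                     matrix(rbinom(16, 20, 0.1), 4, 4)), 0.1)
  fit <- zip_icar(w, prior = prior_uniform_sd(0.05, 2),
                  control = mcmc_control(burn_in = 200, iterations = 2000,
                                         thin = 5, seed = 3))
  expect_lt(max(abs(rowSums(fit$samples$S))), 1e-8)
  expect_true(all(fit$samples$sigma > 0.05 & fit$samples$sigma < 2))
  expect_true(all(is.finite(fit$samples$alpha)))
})

test_that("single-pixel model reduces to the conjugate Poisson-gamma posterior", {
  # one pixel, S constrained to 0: flat prior on alpha makes exp(alpha)
  # posterior Gamma(Y, E) with mean Y/E
  w <- compute_expected(study_window(matrix(50), matrix(2)), 0.014)
  expect_equal(w$expected[1, 1], 0.7)
  fit <- zip_icar(w, prior = prior_fixed_sd(1),
                  control = mcmc_control(burn_in = 2000, iterations = 40000,
                                         thin = 10, seed = 21, n_chains = 1))
  expect_true(all(fit$samples$S == 0))
  lam <- exp(fit$samples$alpha)
  expect_lt(abs(mean(lam) - 2 / 0.7), 3 * mcse(lam) + 0.01)
  expect_equal(sd(lam), sqrt(2) / 0.7, tolerance = 0.1)
})

test_that("posterior means on a 2x2 fixed-sigma window match the dense-quadrature oracle", {
  # frozen oracle values from dense quadrature over (alpha, S) on the
  # sum-to-zero subspace (complete-graph adjacency, sigma = 0.5):
  # grids alpha in [-3, 3] x 121, S_i in [-2.5, 2.5] x 81
  oracle <- list(alpha = 0.311885,
                 S = c(0.011881, -0.073893, 0.000001, 0.062011))
  w <- compute_expected(study_window(matrix(c(5, 8, 0, 12), 2, 2),
                                     matrix(c(1, 0, 0, 3), 2, 2)), 0.1)
  fit <- zip_icar(w, prior = prior_fixed_sd(0.5),
                  control = mcmc_control(burn_in = 2000, iterations = 40000,
                                         thin = 10, seed = 3))
  expect_lt(abs(mean(fit$samples$alpha) - oracle$alpha),
            3 * mcse(fit$samples$alpha) + 0.003)
  for (k in 1:4) {
    expect_lt(abs(mean(fit$samples$S[, k]) - oracle$S[k]),
              3 * mcse(fit$samples$S[, k]) + 0.003)
  }
})

test_that("the precision Gibbs step draws from its closed-form Gamma conditional", {
  set.seed(5)
  a <- build_adjacency(3, 3)
  S <- as.vector(ricar(1, 4, a))
  ss <- epicar:::icar_pair_ss(S, a)
  w <- compute_expected(study_window(matrix(10, 3, 3),
                                     matrix(rbinom(9, 10, 0.2), 3, 3)), 0.2)
  fit <- zip_icar(w, prior = prior_gamma_variance(2, 1),
                  control = mcmc_control(burn_in = 0, iterations = 4000,
                                         thin = 1, seed = 13, n_chains = 1,
                                         fixed = list(alpha = 0, S = S)))
  tau <- 1 / fit$samples$sigma^2
  ks <- suppressWarnings(
    stats::ks.test(tau, stats::pgamma, shape = 2 + (9 - 1) / 2,
                   rate = 1 + ss / 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("with the likelihood switched off the sampler reproduces the ICAR prior", {
  # all-unoccupied window: the likelihood contributes nothing, so with sigma
  # fixed the chain targets the sum-to-zero ICAR prior, under which
  # E[sum over pairs (S_i - S_j)^2] = (n - c)/tau
  h <- 4; wd <- 4; tau <- 1
  w0 <- compute_expected(study_window(matrix(0, h, wd)), 0.5)
  adj <- build_adjacency(wd, h)
  fit <- zip_icar(w0, prior = prior_fixed_sd(1 / sqrt(tau)),
                  control = mcmc_control(burn_in = 1000, iterations = 30000,
                                         thin = 10, seed = 31, n_chains = 1,
                                         fixed = list(alpha = 0)))
  ss_mc <- apply(fit$samples$S, 1, epicar:::icar_pair_ss, adjacency = adj)
  expect_lt(abs(mean(ss_mc) - 15 / tau), 4 * mcse(ss_mc))
  # the direct constrained-Gaussian sampler agrees with the same closed form
  set.seed(6)
  ss_direct <- apply(ricar(4000, tau, adj), 1, epicar:::icar_pair_ss,
                     adjacency = adj)
  expect_lt(abs(mean(ss_direct) - 15 / tau),
            4 * sd(ss_direct) / sqrt(length(ss_direct)))
})

test_that("adding cases to a pixel does not decrease its posterior log relative risk", {
  set.seed(14)
  y <- matrix(2L, 5, 5)
  base <- compute_expected(study_window(matrix(100L, 5, 5), y), 0.02)
  y2 <- y; y2[3, 3] <- 12L
  more <- compute_expected(study_window(matrix(100L, 5, 5), y2), 0.02)
  ctl <- mcmc_control(burn_in = 500, iterations = 10000, thin = 10, seed = 9,
                      n_chains = 1)
  k <- (3 - 1) * 5 + 3  # centre pixel, column-major
  f1 <- zip_icar(base, control = ctl)
  f2 <- zip_icar(more, control = ctl)
  lrr1 <- mean(f1$samples$alpha + f1$samples$S[, k])
  lrr2 <- mean(f2$samples$alpha + f2$samples$S[, k])
  expect_gt(lrr2, lrr1)
})
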