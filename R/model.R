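# Zero-inflated Poisson / ICAR model: likelihood, priors and the MCMC fit.
#
# Model, per pixel i of a study window:
#   Y_i ~ Poisson(group_i * mu_i),   log(mu_i) = log(E_i) + alpha + S_i
#   group_i ~ Bernoulli(p_i) with p_i = 1 iff the pixel holds any births —
#     deterministic given the data, so it enters as a likelihood mask:
#     unoccupied pixels force Y_i = 0 with probability one (structural zeros)
#     and contribute nothing to the likelihood.
#   S ~ ICAR(tau): improper Gaussian Markov random field on the pixel grid,
#     identified by a sum-to-zero constraint (recentred every sweep, with the
#     mean absorbed into alpha).
#   alpha: improper flat prior.
#   tau (or sigma = 1/sqrt(tau)): one of the hierarchical priors below.

#' Hierarchical priors for the spatial precision / neighbourhood SD
#'
#' Three conventional disease-mapping priors for the smoothness parameter of
#' the ICAR field: `prior_gamma_variance(a, b)` places a Gamma(a, b)
#' (shape/rate) prior on the precision `tau`, sampled by conjugate Gibbs;
#' `prior_uniform_sd(lo, hi)` places a bounded uniform prior on the
#' neighbourhood standard deviation `sigma = 1/sqrt(tau)`, sampled by
#' log-scale random-walk Metropolis; `prior_fixed_sd(value)` holds `sigma`
#' fixed (mainly for validation against closed-form oracles).
#'
#' Common choices are Gamma(0.5, 0.0005), Gamma(0.01, 0.01) and
#' Uniform(0, 100); the uniform SD prior is the default in [zip_icar()].
#'
#' @param a,b Gamma shape and rate, both positive.
#' @param lo,hi uniform bounds, `0 <= lo < hi`.
#' @param value fixed positive SD.
#' @return a `zip_icar_prior` object.
#' @export
prior_gamma_variance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0)
  structure(list(kind = "gamma_variance", a = a, b = b),
            class = "zip_icar_prior")
}

#' @rdname prior_gamma_variance
#' @export
prior_uniform_sd <- function(lo = 0, hi = 100) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo >= 0, lo < hi)
  structure(list(kind = "uniform_sd", lo = lo, hi = hi),
            class = "zip_icar_prior")
}

#' @rdname prior_gamma_variance
#' @export
prior_fixed_sd <- function(value) {
  stopifnot(is.numeric(value), value > 0)
  structure(list(kind = "fixed_sd", value = value), class = "zip_icar_prior")
}

#' @export
print.zip_icar_prior <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.zip_icar_prior <- function(x, ...) {
  switch(x$kind,
    gamma_variance = sprintf("Gamma(%g, %g) on the ICAR precision", x$a, x$b),
    uniform_sd = sprintf("Uniform(%g, %g) on the neighbourhood SD", x$lo, x$hi),
    fixed_sd = sprintf("neighbourhood SD fixed at %g", x$value))
}

#' MCMC settings
#'
#' Chain-length defaults follow long production runs (5,000 burn-in sweeps
#' discarded, then every 100th of 500,000 sweeps retained, two chains with
#' widely different initial values).  Tests and simulation studies use a
#' scaled-down profile such as `mcmc_control(burn_in = 1000,
#' iterations = 20000, thin = 10)`.
#'
#' @param n_chains number of chains; chain 1 starts at the `"zero"` state and
#'   later chains at `"dispersed"` states unless `init` says otherwise.
#' @param burn_in sweeps discarded (with proposal adaptation) before sampling.
#' @param iterations post-burn-in sweeps; must be divisible by `thin`.
#' @param thin keep every `thin`-th sweep.
#' @param seed master seed; per-chain streams are derived from it.
#' @param adapt_interval batch length for proposal-scale adaptation during
#'   burn-in (target acceptance 0.44; adaptation frozen afterwards).
#' @param init character vector of initial-value strategies recycled over
#'   chains (`"zero"` or `"dispersed"`).
#' @param fixed optional list fixing components for validation runs: any of
#'   `alpha` (scalar), `S` (full field), `sigma` (scalar).
#' @return an `mcmc_control` list.
#' @export
mcmc_control <- function(n_chains = 2, burn_in = 5000, iterations = 500000,
                         thin = 100, seed = 1L, adapt_interval = 50,
                         init = NULL, fixed = list()) {
  stopifnot(n_chains >= 1, burn_in >= 0, thin >= 1, iterations >= thin)
  if (iterations %% thin != 0)
    stop("iterations must be divisible by thin")
  if (is.null(init))
    init <- c("zero", rep("dispersed", max(0L, n_chains - 1L)))
  init <- rep_len(match.arg(init, c("zero", "dispersed"), several.ok = TRUE),
                  n_chains)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 init = init, fixed = fixed),
            class = "mcmc_control")
}

#' Initial values for a chain
#'
#' `"zero"` starts at `alpha = 0`, a flat field and `sigma = 1`;
#' `"dispersed"` draws `alpha` uniformly in `[-3, 3]`, each `S_i` uniformly
#' in `[-2, 2]` (then recentres the field to sum zero) and `sigma` uniformly
#' in `[0.1, 10]` — the "widely different" starting points used to check
#' convergence across chains.
#'
#' @param window a `study_window` (sets the field dimension).
#' @param strategy `"zero"` or `"dispersed"`.
#' @param seed optional seed for reproducible dispersed draws.
#' @return list with `alpha`, `S` (vector of length `width * height`) and
#'   `sigma`.
#' @export
initial_values <- function(window, strategy = c("zero", "dispersed"),
                           seed = NULL) {
  strategy <- match.arg(strategy)
  n <- window$width * window$height
  if (!is.null(seed)) set.seed(seed)
  if (strategy == "zero")
    return(list(alpha = 0, S = rep(0, n), sigma = 1))
  S <- runif(n, -2, 2)
  S <- S - mean(S)
  list(alpha = runif(1, -3, 3), S = S, sigma = runif(1, 0.1, 10))
}

#' Zero-inflated Poisson log-likelihood of a study window
#'
#' Sum over occupied pixels of the Poisson log-pmf of the case count with
#' mean `E_i * exp(alpha + S_i)`.  Unoccupied pixels are structural zeros
#' (their case count is 0 with probability one) and contribute exactly 0.
#'
#' @param window a `study_window` with expected counts.
#' @param alpha intercept (log relative risk shared by all pixels).
#' @param S spatial field, one value per pixel (vector in column-major pixel
#'   order, or a matrix of the window's dimensions).
#' @return the log-likelihood.
#' @export
zip_loglik <- function(window, alpha, S) {
  validate_window(window)
  if (is.null(window$expected))
    stop("window has no expected counts; call compute_expected() first")
  S <- as.vector(S)
  n <- window$width * window$height
  if (length(S) != n) stop("S must have one value per pixel")
  occ <- as.vector(window$occupied) == 1L
  if (any(occ & as.vector(window$expected) <= 0))
    stop("occupied pixel with non-positive expected count")
  if (!any(occ)) return(0)
  Y <- as.vector(window$cases)[occ]
  mu <- as.vector(window$expected)[occ] * exp(alpha + S[occ])
  sum(dpois(Y, mu, log = TRUE))
}

#' ICAR log-density of a spatial field (up to an additive constant)
#'
#' The intrinsic conditional autoregressive (pairwise-difference) prior:
#' `((n - c)/2) log(tau) - (tau/2) * sum over neighbour pairs (S_i - S_j)^2`,
#' where `n` is the number of pixels and `c` the number of connected
#' components of the adjacency graph.  The density is improper: it is
#' invariant to adding a constant to the whole field.
#'
#' @param S field (vector or matrix), one value per pixel.
#' @param tau positive precision.
#' @param adjacency a `grid_adjacency` from [build_adjacency()].
#' @return the log-density up to a constant.
#' @export
icar_logdensity <- function(S, tau, adjacency) {
  stopifnot(tau > 0, inherits(adjacency, "grid_adjacency"))
  S <- as.vector(S)
  n <- length(adjacency$neighbors)
  if (length(S) != n) stop("S must match the adjacency size")
  ss <- icar_pair_ss(S, adjacency)
  cc <- n_components(adjacency)
  ((n - cc) / 2) * log(tau) - (tau / 2) * ss
}

# sum over unordered neighbour pairs of squared field differences
icar_pair_ss <- function(S, adjacency) {
  ss <- 0
  for (i in seq_along(adjacency$neighbors)) {
    js <- adjacency$neighbors[[i]]
    js <- js[js > i]
    if (length(js)) ss <- ss + sum((S[i] - S[js])^2)
  }
  ss
}

#' Draw sum-to-zero ICAR fields directly
#'
#' Exact sampler for the intrinsic Gaussian Markov random field under the
#' sum-to-zero constraint, via the eigendecomposition of the graph Laplacian:
#' the field is a linear combination of the non-null eigenvectors with
#' independent `N(0, 1/(tau * lambda_k))` coefficients.  Used as an
#' independent oracle for the MCMC and to simulate fields with known
#' smoothness in recovery studies.
#'
#' @param n number of fields to draw.
#' @param tau precision of the pairwise-difference form.
#' @param adjacency a `grid_adjacency`.
#' @return an `n` x `n_pixels` matrix; each row sums to (numerically) zero.
#' @export
ricar <- function(n, tau, adjacency) {
  stopifnot(n >= 1, tau > 0, inherits(adjacency, "grid_adjacency"))
  np <- length(adjacency$neighbors)
  L <- matrix(0, np, np)
  for (i in seq_len(np)) {
    js <- adjacency$neighbors[[i]]
    L[i, js] <- -1
    L[i, i] <- length(js)
  }
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  z <- matrix(rnorm(n * length(lam)), n) %*%
    (t(V) * (1 / sqrt(tau * lam)))
  z - rowMeans(z)  # remove numerical drift off the constraint
}

#' Fit the zero-inflated Poisson ICAR model by MCMC
#'
#' Samples the posterior of the intercept `alpha`, the ICAR spatial field
#' `S` and the neighbourhood SD `sigma` for a study window of observed and
#' expected case counts.  The sampler is single-site adaptive random-walk
#' Metropolis for the field and intercept, with conjugate Gibbs (gamma
#' precision priors) or log-scale Metropolis (bounded uniform SD prior) for
#' the smoothness parameter; the field is recentred to sum zero after every
#' sweep with the mean absorbed into the intercept.  Structural-zero pixels
#' (no births) are masked out of the likelihood and influence the posterior
#' only through the neighbourhood graph.
#'
#' @param window a `study_window` with expected counts
#'   ([compute_expected()]).
#' @param prior a [prior_gamma_variance()], [prior_uniform_sd()] (default
#'   `Uniform(0, 100)`) or [prior_fixed_sd()] object.
#' @param control an [mcmc_control()] object.
#' @param adjacency optional `grid_adjacency`; built from the window
#'   dimensions (queen rule) when omitted.
#' @return a `zip_icar` object with components `samples` (list of `alpha`,
#'   `sigma` vectors and a draws-by-pixels matrix `S`, all chains pooled),
#'   `chain` (chain id per draw), `log_post`, `accept`, `window`,
#'   `adjacency`, `prior`, `control` and `inits`.  Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `simulate`, `plot`, and
#'   [exceedance()].
#' @examples
#' \donttest{
#' scn <- scenario(n_births = 20000, rr0 = 4, seed = 7)
#' pts <- simulate_dataset(scn)
#' win <- extract_window(bin_to_pixels(pts), scenario_site(scn))
#' win <- compute_expected(win, overall_rate(pts))
#' fit <- zip_icar(win, control = mcmc_control(burn_in = 500,
#'                 iterations = 5000, thin = 10, seed = 1))
#' summary(fit)
#' }
#' @export
zip_icar <- function(window, prior = prior_uniform_sd(0, 100),
                     control = mcmc_control(), adjacency = NULL) {
  validate_window(window)
  if (is.null(window$expected))
    stop("window has no expected counts; call compute_expected() first")
  stopifnot(inherits(prior, "zip_icar_prior"), inherits(control, "mcmc_control"))
  n <- window$width * window$height
  if (is.null(adjacency)) {
    adjacency <- if (n == 1L) .grid_adjacency(1L, 1L)
      else build_adjacency(window$width, window$height)
  }
  if (length(adjacency$neighbors) != n)
    stop("adjacency does not match the window")
  occ <- as.integer(as.vector(window$occupied))
  E <- as.vector(window$expected)
  if (any(occ == 1L & E <= 0))
    stop("occupied pixel with zero expected count")
  Y <- as.integer(as.vector(window$cases))
  fa <- flatten_adjacency(adjacency)
  cc <- n_components(adjacency)

  fixed <- control$fixed
  fix_alpha <- !is.null(fixed$alpha)
  fix_S <- !is.null(fixed$S)
  fix_sigma <- !is.null(fixed$sigma) || prior$kind == "fixed_sd"
  pk <- switch(prior$kind, gamma_variance = 0L, uniform_sd = 1L, fixed_sd = 1L)
  pa <- switch(prior$kind, gamma_variance = prior$a, uniform_sd = prior$lo,
               fixed_sd = 0)
  pb <- switch(prior$kind, gamma_variance = prior$b, uniform_sd = prior$hi,
               fixed_sd = Inf)

  chains <- vector("list", control$n_chains)
  inits <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    chain_seed <- (control$seed + 1000003L * (ch - 1L)) %% .Machine$integer.max
    set.seed(chain_seed)
    iv <- initial_values(window, control$init[ch])
    if (fix_alpha) iv$alpha <- fixed$alpha
    if (fix_S) iv$S <- as.vector(fixed$S)
    if (fix_sigma)
      iv$sigma <- if (prior$kind == "fixed_sd") prior$value else fixed$sigma
    if (prior$kind == "uniform_sd") {
      # keep the starting SD inside the prior's support
      eps <- 0.01 * (prior$hi - prior$lo)
      iv$sigma <- min(max(iv$sigma, prior$lo + eps), prior$hi - eps)
    }
    inits[[ch]] <- iv
    chains[[ch]] <- .zip_icar_chain(
      Y, E, occ, fa$idx, fa$ptr, cc,
      iv$alpha, iv$S, iv$sigma,
      control$burn_in, control$iterations, control$thin,
      pk, pa, pb, fix_alpha, fix_S, fix_sigma, control$adapt_interval)
  }
  n_store <- control$iterations %/% control$thin
  fit <- structure(list(
    samples = list(
      alpha = unlist(lapply(chains, `[[`, "alpha")),
      sigma = unlist(lapply(chains, `[[`, "sigma")),
      S = do.call(rbind, lapply(chains, `[[`, "S"))),
    chain = rep(seq_len(control$n_chains), each = n_store),
    log_post = unlist(lapply(chains, `[[`, "log_post")),
    accept = lapply(chains, `[[`, "accept"),
    window = window, adjacency = adjacency, prior = prior,
    control = control, inits = inits, n_components = cc,
    call = match.call()), class = "zip_icar")
  fit
}

# draws of a named parameter as a draws x chains matrix
param_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "zip_icar"))
  m <- fit$control$n_chains
  v <- if (parameter == "alpha") fit$samples$alpha
    else if (parameter == "sigma") fit$samples$sigma
    else {
      k <- if (grepl("^S\\[[0-9]+\\]$", parameter))
        as.integer(sub("^S\\[([0-9]+)\\]$", "\\1", parameter))
      else if (is.numeric(parameter)) as.integer(parameter)
      else stop("unknown parameter: ", parameter)
      if (k < 1 || k > ncol(fit$samples$S)) stop("S index out of range")
      fit$samples$S[, k]
    }
  matrix(v, ncol = m)
}
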