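# Convergence diagnostics and prior/outcome sensitivity analyses.

#' Gelman-Rubin potential scale reduction (R-hat)
#'
#' Compares between-chain and within-chain variance for one monitored
#' parameter.  With `m` chains of `n` draws, `W` the mean within-chain
#' variance and `B/n` the variance of the chain means, the statistic is
#' `R-hat = sqrt((W + B/n) / W)`, which is exactly 1 for chains that agree
#' perfectly and grows without bound as the chains separate.  With
#' `split = TRUE` each chain is first split in half (sensitive to
#' within-chain drift).  A fit is flagged converged when `R-hat < 1.1`.
#'
#' @param fit a `zip_icar` fit with at least two chains and ten draws per
#'   chain (or a draws-by-chains numeric matrix).
#' @param parameter `"alpha"`, `"sigma"`, `"S[k]"`, or a pixel index.
#' @param split split each chain in half first.
#' @return list with `rhat` and logical `converged` (`rhat < 1.1`).
#' @export
gelman_rubin <- function(fit, parameter = "alpha", split = FALSE) {
  draws <- if (is.matrix(fit)) fit else param_draws(fit, parameter)
  if (ncol(draws) < 2L)
    stop("at least two chains are required for R-hat")
  if (nrow(draws) < 10L)
    stop("at least ten draws per chain are required")
  if (split) {
    half <- nrow(draws) %/% 2L
    draws <- cbind(draws[seq_len(half), , drop = FALSE],
                   draws[half + seq_len(half), , drop = FALSE])
  }
  n <- nrow(draws)
  means <- colMeans(draws)
  W <- mean(apply(draws, 2, var))
  B_over_n <- var(means)
  rhat <- if (W == 0) {
    if (B_over_n == 0) 1 else Inf
  } else {
    sqrt((W + B_over_n) / W)
  }
  list(rhat = rhat, converged = is.finite(rhat) && rhat < 1.1)
}

# parameters monitored in sensitivity reports: intercept, SD and ten evenly
# spaced field pixels
monitored_parameters <- function(n_pixels) {
  ks <- unique(round(seq(1, n_pixels, length.out = min(10, n_pixels))))
  c("alpha", "sigma", paste0("S[", ks, "]"))
}

# deterministic seed offset from a prior's content, so that identical priors
# re-use identical seeds (bit-identical reports) while distinct priors get
# distinct streams
prior_seed_offset <- function(prior) {
  key <- paste(prior$kind,
               paste(format(unlist(prior[-1]), digits = 12), collapse = ","))
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 100003L
}

#' Prior sensitivity analysis
#'
#' Refits the model once per prior on the same window and summarises, per
#' prior, the posterior of the neighbourhood SD (median and central 95%
#' interval), R-hat for the monitored parameters, and the EP surface; and,
#' per pair of priors, the maximum absolute EP difference and the fraction
#' of pixels whose high-exceedance status (EP > 0.99) agrees.
#'
#' Each run's seed is derived deterministically from the master seed and the
#' prior's content, so listing the same prior twice reproduces the same
#' report while distinct priors use distinct streams.
#'
#' @param window a `study_window` with expected counts.
#' @param priors list of two or more `zip_icar_prior` objects.
#' @param control an [mcmc_control()].
#' @param adjacency optional `grid_adjacency`.
#' @return a `sensitivity_report` (kind `"prior"`).
#' @export
run_prior_sensitivity <- function(window, priors, control = mcmc_control(),
                                  adjacency = NULL) {
  stopifnot(is.list(priors), length(priors) >= 2)
  labels <- vapply(priors, format, "")
  runs <- vector("list", length(priors))
  for (i in seq_along(priors)) {
    ctl <- control
    ctl$seed <- as.integer((control$seed + prior_seed_offset(priors[[i]])) %%
                             .Machine$integer.max)
    fit <- tryCatch(
      zip_icar(window, prior = priors[[i]], control = ctl,
               adjacency = adjacency),
      error = function(e)
        stop("fit failed under prior [", labels[i], "]: ",
             conditionMessage(e), call. = FALSE))
    runs[[i]] <- summarize_run(fit, label = labels[i])
  }
  structure(list(kind = "prior", runs = runs, labels = labels,
                 pairwise = pairwise_ep_concordance(runs, labels)),
            class = "sensitivity_report")
}

summarize_run <- function(fit, label) {
  s <- fit$samples$sigma
  rhat <- if (fit$control$n_chains >= 2) {
    pars <- monitored_parameters(ncol(fit$samples$S))
    vapply(pars, function(p) gelman_rubin(fit, p)$rhat, 0)
  } else NULL
  cl <- detect_clusters(exceedance(fit))
  list(label = label,
       sigma = c(median = median(s), `2.5%` = unname(quantile(s, 0.025)),
                 `97.5%` = unname(quantile(s, 0.975))),
       rhat = rhat,
       ep = exceedance(fit),
       clusters = site_proximity(cl, fit$window),
       seed = fit$control$seed)
}

pairwise_ep_concordance <- function(runs, labels, threshold = 0.99) {
  if (length(runs) < 2) return(NULL)
  pairs <- utils::combn(length(runs), 2)
  out <- data.frame(a = labels[pairs[1, ]], b = labels[pairs[2, ]],
                    max_abs_ep_diff = NA_real_, status_agreement = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    e1 <- runs[[pairs[1, k]]]$ep$ep
    e2 <- runs[[pairs[2, k]]]$ep$ep
    out$max_abs_ep_diff[k] <- max(abs(e1 - e2))
    out$status_agreement[k] <- mean((e1 > threshold) == (e2 > threshold))
  }
  out
}

#' Outcome sensitivity analysis
#'
#' Runs the full pipeline (overall rate, binning, window extraction,
#' expected counts, model fit, EP surface, cluster screen) once per outcome
#' on the same point records, and summarises pairwise cluster-location
#' concordance as the distance between the largest clusters' centroids.
#'
#' @param points point records (planar km) with one 0/1 column per outcome.
#' @param outcomes character vector of outcome column names to analyse.
#' @param site site as for [extract_window()].
#' @param width,height window dimensions in pixels.
#' @param resolution pixel size (km).
#' @param prior a `zip_icar_prior`.
#' @param control an [mcmc_control()].
#' @return a `sensitivity_report` (kind `"outcome"`) whose `pairwise` table
#'   reports, per pair of outcomes, the distance in km between the top
#'   clusters' centroids (`NA` when either outcome yields no cluster).
#' @export
run_outcome_sensitivity <- function(points, outcomes, site,
                                    width = 20, height = 20, resolution = 1,
                                    prior = prior_uniform_sd(0, 100),
                                    control = mcmc_control()) {
  stopifnot(length(outcomes) >= 1)
  missing <- setdiff(outcomes, names(points))
  if (length(missing))
    stop("outcome column(s) not found: ", paste(missing, collapse = ", "))
  binned <- bin_to_pixels(points, resolution = resolution)
  runs <- vector("list", length(outcomes))
  for (i in seq_along(outcomes)) {
    o <- outcomes[i]
    rate <- overall_rate(points, o)
    if (rate == 0)
      stop("outcome '", o, "' has zero cases; cannot form expected counts")
    win <- extract_window(binned, site, width = width, height = height,
                          outcome = o)
    win <- compute_expected(win, rate)
    ctl <- control
    ctl$seed <- as.integer((control$seed +
                              sum(utf8ToInt(o))) %% .Machine$integer.max)
    fit <- zip_icar(win, prior = prior, control = ctl)
    runs[[i]] <- summarize_run(fit, label = o)
    runs[[i]]$rate <- rate
  }
  pairwise <- NULL
  if (length(runs) >= 2) {
    pairs <- utils::combn(length(runs), 2)
    pairwise <- data.frame(a = outcomes[pairs[1, ]], b = outcomes[pairs[2, ]],
                           centroid_distance_km = NA_real_)
    for (k in seq_len(ncol(pairs))) {
      c1 <- runs[[pairs[1, k]]]$clusters$clusters
      c2 <- runs[[pairs[2, k]]]$clusters$clusters
      if (nrow(c1) && nrow(c2))
        pairwise$centroid_distance_km[k] <-
          sqrt((c1$centroid_x[1] - c2$centroid_x[1])^2 +
                 (c1$centroid_y[1] - c2$centroid_y[1])^2)
    }
  }
  structure(list(kind = "outcome", runs = runs, labels = outcomes,
                 pairwise = pairwise),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report (", x$kind, "), ", length(x$runs), " runs\n",
      sep = "")
  for (r in x$runs) {
    cat("  [", r$label, "] sigma median ", format(r$sigma["median"], digits = 4),
        " (95% CI ", format(r$sigma["2.5%"], digits = 4), " - ",
        format(r$sigma["97.5%"], digits = 4), "); clusters: ",
        nrow(r$clusters$clusters), sep = "")
    if (!is.null(r$rhat))
      cat("; max R-hat ", format(max(r$rhat), digits = 4), sep = "")
    cat("\n")
  }
  if (!is.null(x$pairwise)) {
    cat("pairwise concordance:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
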