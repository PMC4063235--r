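# S3 methods for fitted zip_icar models.

#' @export
print.zip_icar <- function(x, ...) {
  ctl <- x$control
  cat("Zero-inflated Poisson ICAR model fit\n")
  cat("  window:", x$window$width, "x", x$window$height, "pixels;",
      sum(x$window$occupied), "occupied;",
      sum(x$window$cases), "cases /",
      format(sum(x$window$expected), digits = 5), "expected\n")
  cat("  prior: ", format(x$prior), "\n", sep = "")
  cat("  chains:", ctl$n_chains, "x", length(x$samples$alpha) / ctl$n_chains,
      "retained draws (burn-in", ctl$burn_in, ", thin", ctl$thin, ")\n")
  cat("  posterior mean alpha:", format(mean(x$samples$alpha), digits = 4),
      " sigma:", format(mean(x$samples$sigma), digits = 4), "\n")
  invisible(x)
}

#' Posterior summary of a zip_icar fit
#'
#' Posterior means, SDs and central 95% intervals for the intercept and the
#' neighbourhood SD, the range of posterior-median pixel relative risks, and
#' (with two or more chains) potential-scale-reduction diagnostics.
#'
#' @param object a `zip_icar` fit.
#' @param ... unused.
#' @export
summary.zip_icar <- function(object, ...) {
  qs <- function(v) c(mean = mean(v), sd = sd(v),
                      `2.5%` = unname(quantile(v, 0.025)),
                      median = median(v),
                      `97.5%` = unname(quantile(v, 0.975)))
  par <- rbind(alpha = qs(object$samples$alpha),
               sigma = qs(object$samples$sigma))
  rhat <- if (object$control$n_chains >= 2)
    c(alpha = gelman_rubin(object, "alpha")$rhat,
      sigma = gelman_rubin(object, "sigma")$rhat)
  else NULL
  ep <- exceedance(object)
  structure(list(parameters = par, rhat = rhat,
                 rr_median_range = range(ep$rr_median),
                 n_high_ep = sum(ep$ep > 0.99),
                 n_draws = length(object$samples$alpha),
                 prior = object$prior, control = object$control),
            class = "summary.zip_icar")
}

#' @export
print.summary.zip_icar <- function(x, ...) {
  cat("Posterior summary (", x$n_draws, " draws, prior: ",
      format(x$prior), ")\n", sep = "")
  print(round(x$parameters, 4))
  if (!is.null(x$rhat))
    cat("R-hat: alpha", format(x$rhat["alpha"], digits = 5),
        " sigma", format(x$rhat["sigma"], digits = 5), "\n")
  cat("posterior-median RR range: [",
      format(x$rr_median_range[1], digits = 4), ", ",
      format(x$rr_median_range[2], digits = 4), "]; pixels with EP > 0.99: ",
      x$n_high_ep, "\n", sep = "")
  invisible(x)
}

#' @export
coef.zip_icar <- function(object, spatial = FALSE, ...) {
  out <- c(alpha = mean(object$samples$alpha),
           sigma = mean(object$samples$sigma))
  if (spatial) {
    S <- colMeans(object$samples$S)
    names(S) <- paste0("S[", seq_along(S), "]")
    out <- c(out, S)
  }
  out
}

#' @export
fitted.zip_icar <- function(object, ...) {
  # posterior mean of mu_i = group_i * E_i exp(alpha + S_i), window-shaped
  w <- object$window
  # samples$S is draws x pixels; adding the draw-length alpha vector recycles
  # it down each column, giving per-draw per-pixel log relative risks
  rr_mean <- colMeans(exp(object$samples$S + object$samples$alpha))
  mu <- rr_mean * as.vector(w$expected) * as.vector(w$occupied)
  matrix(mu, w$height, w$width)
}

#' @export
residuals.zip_icar <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  w <- object$window
  mu <- fitted(object)
  r <- w$cases - mu
  if (type == "pearson") r <- r / sqrt(pmax(mu, .Machine$double.eps))
  r[w$occupied == 0] <- NA_real_
  r
}

#' Posterior-predictive case counts
#'
#' Draws replicate per-pixel case counts: for each replicate a retained
#' posterior draw is selected at random and counts are drawn
#' `Poisson(E_i exp(alpha + S_i))` at occupied pixels (structural zeros stay
#' zero).
#'
#' @param object a `zip_icar` fit.
#' @param nsim number of replicate windows.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `[height x width]` integer matrices.
#' @export
simulate.zip_icar <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  w <- object$window
  occ <- as.vector(w$occupied) == 1L
  E <- as.vector(w$expected)
  nd <- length(object$samples$alpha)
  lapply(seq_len(nsim), function(r) {
    k <- sample.int(nd, 1)
    mu <- E * exp(object$samples$alpha[k] + object$samples$S[k, ])
    y <- integer(length(E))
    y[occ] <- rpois(sum(occ), mu[occ])
    matrix(y, w$height, w$width)
  })
}

#' Map a fitted surface
#'
#' Images the exceedance-probability surface (default) or the
#' posterior-median relative risk over the study window, marking the site.
#'
#' @param x a `zip_icar` fit.
#' @param layer `"ep"` or `"rr_median"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.zip_icar <- function(x, layer = c("ep", "rr_median"), ...) {
  layer <- match.arg(layer)
  plot(exceedance(x), layer = layer, ...)
  invisible(x)
}
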