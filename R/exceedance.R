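# Exceedance-probability surfaces from posterior draws.

#' Exceedance-probability and relative-risk surface
#'
#' Converts the retained posterior draws of a fitted model into per-pixel
#' summaries: the exceedance probability `EP_i` — the fraction of draws in
#' which the pixel's relative risk is strictly greater than one — and the
#' posterior median relative risk.  By default the relative risk is
#' `RR_i = exp(alpha + S_i)`, the ratio of the pixel's Poisson mean to its
#' expected count; `include_intercept = FALSE` gives the spatial-only reading
#' `exp(S_i)`.
#'
#' @param fit a `zip_icar` fit with at least one retained draw.
#' @param include_intercept include `alpha` in the relative risk (default).
#' @return an `ep_surface` object: `[height x width]` matrices `ep` and
#'   `rr_median` plus the window geometry (`origin`, `resolution`, `site`).
#' @seealso [exceedance_from_draws()] for raw draw vectors,
#'   [detect_clusters()] for screening.
#' @export
exceedance <- function(fit, include_intercept = TRUE) {
  stopifnot(inherits(fit, "zip_icar"))
  nd <- length(fit$samples$alpha)
  if (nd == 0L) stop("no posterior draws")
  w <- fit$window
  es <- exceedance_from_draws(fit$samples$alpha, fit$samples$S,
                              include_intercept = include_intercept)
  structure(list(ep = matrix(es$ep, w$height, w$width),
                 rr_median = matrix(es$rr_median, w$height, w$width),
                 origin = w$origin, resolution = w$resolution,
                 width = w$width, height = w$height, site = w$site,
                 include_intercept = include_intercept, n_draws = nd),
            class = "ep_surface")
}

#' Exceedance summaries from raw draws
#'
#' @param alpha vector of intercept draws.
#' @param S draws-by-pixels matrix of spatial-field draws.
#' @param include_intercept include `alpha` in the relative risk.
#' @return list with per-pixel vectors `ep` and `rr_median`.
#' @rdname exceedance
#' @export
exceedance_from_draws <- function(alpha, S, include_intercept = TRUE) {
  S <- as.matrix(S)
  if (length(alpha) != nrow(S))
    stop("alpha draws and S draws differ in length")
  if (length(alpha) == 0L) stop("no posterior draws")
  eta <- if (include_intercept) S + alpha else S  # column-major recycling
  list(ep = colMeans(eta > 0),                    # strict: RR > 1
       rr_median = exp(apply(eta, 2, median)))
}

#' @export
print.ep_surface <- function(x, ...) {
  cat("Exceedance-probability surface:", x$width, "x", x$height,
      "pixels (", x$n_draws, "draws )\n")
  cat("  EP range [", format(min(x$ep), digits = 4), ", ",
      format(max(x$ep), digits = 4), "]; pixels with EP > 0.99: ",
      sum(x$ep > 0.99), "\n", sep = "")
  cat("  RR median range [", format(min(x$rr_median), digits = 4), ", ",
      format(max(x$rr_median), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.ep_surface <- function(x, layer = c("ep", "rr_median"), ...) {
  layer <- match.arg(layer)
  z <- x[[layer]]
  xs <- (x$origin[1] + seq_len(x$width) - 1) * x$resolution
  ys <- (x$origin[2] + seq_len(x$height) - 1) * x$resolution
  graphics::image(xs, ys, t(z), xlab = "x (km)", ylab = "y (km)",
                  main = if (layer == "ep") "Exceedance probability"
                         else "Posterior median relative risk",
                  useRaster = TRUE, ...)
  graphics::points(x$site$x, x$site$y, pch = 4, cex = 1.5, lwd = 2)
  invisible(x)
}

#' Most elevated pixel of an EP surface
#'
#' The pixel with the highest exceedance probability; because EP saturates at
#' exactly 1 once every retained draw exceeds one, ties are broken by the
#' posterior median relative risk (the most elevated of the tied pixels).
#'
#' @param x an `ep_surface`.
#' @return list with `ix`, `iy` (integer pixel indices), `x`, `y` (km pixel
#'   centre), `ep` and `rr_median`.
#' @export
peak_pixel <- function(x) {
  stopifnot(inherits(x, "ep_surface"))
  k <- which(x$ep == max(x$ep))
  if (length(k) > 1) k <- k[which.max(x$rr_median[k])]
  iy <- (k - 1L) %% x$height + 1L
  ix <- (k - 1L) %/% x$height + 1L
  list(ix = x$origin[1] + ix - 1L, iy = x$origin[2] + iy - 1L,
       x = (x$origin[1] + ix - 1L) * x$resolution,
       y = (x$origin[2] + iy - 1L) * x$resolution,
       ep = x$ep[k], rr_median = x$rr_median[k])
}

#' Long-format export of an EP surface
#'
#' @param x an `ep_surface`.
#' @param ... unused.
#' @return data frame with one row per pixel: integer pixel indices `ix`,
#'   `iy`, `ep` and `rr_median`.
#' @export
as.data.frame.ep_surface <- function(x, ...) {
  g <- window_grid(list(origin = x$origin, width = x$width, height = x$height))
  data.frame(ix = g$ix, iy = g$iy, ep = as.vector(x$ep),
             rr_median = as.vector(x$rr_median))
}
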