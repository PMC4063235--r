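# Planar projection, kilometre binning and study-window extraction.
#
# Internal conventions:
#   * point records are data frames with columns `x`, `y` plus one 0/1 column
#     per outcome; after projection x/y are planar kilometres.
#   * pixel (ix, iy) has its centre at (ix * res, iy * res) km; the pixel is
#     the half-open square around the centre after round-half-to-even tie
#     resolution (base R `round()`).
#   * window matrices are [height x width]; row 1 is the southernmost row,
#     column 1 the westernmost column.  The linear pixel index is the usual
#     column-major index `(ix - 1) * height + iy`, i.e. `as.vector(mat)`.

# mean Earth radius (km) -> km per degree of latitude; the same constant
# scaled by cos(latitude) gives km per degree of longitude.
KM_PER_DEG <- 2 * pi * 6371.0088 / 360

# GRS80 ellipsoid, as used by UTM NAD83.
.GRS80_A <- 6378137.0
.GRS80_F <- 1 / 298.257222101

#' Project point records to planar kilometre coordinates
#'
#' Converts geocoded records to a planar kilometre system suitable for
#' square-kilometre binning.  Three modes are supported: `"utm"` projects
#' longitude/latitude degrees with a Transverse Mercator projection on the
#' GRS80 ellipsoid (UTM NAD83, default zone 14); `"equirect"` is the simple
#' equirectangular approximation in which a degree of latitude measures a
#' constant ~111 km and a degree of longitude is shrunk by the cosine of a
#' reference latitude (about 97 km per degree at Houston); `"none"` accepts
#' coordinates already projected to planar metres and only rescales them to
#' kilometres.
#'
#' @param points data frame with numeric columns `x` and `y` (longitude and
#'   latitude degrees for `"utm"`/`"equirect"`, planar metres for `"none"`);
#'   any other columns (outcome flags) are carried through unchanged.
#' @param mode projection mode, see Details.
#' @param zone UTM zone (default 14, central meridian 99 degrees W).
#' @param ref_lat reference latitude in degrees for `"equirect"`; defaults to
#'   the mean latitude of the input.
#' @return `points` with `x` and `y` replaced by planar kilometre coordinates.
#' @examples
#' pts <- data.frame(x = c(-95.4, -95.36), y = c(29.76, 29.8))
#' project_coordinates(pts, "utm")
#' @seealso [utm_forward()], [utm_inverse()], [bin_to_pixels()]
#' @export
project_coordinates <- function(points, mode = c("none", "utm", "equirect"),
                                zone = 14, ref_lat = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x)
  y <- as.numeric(points$y)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  if (mode %in% c("utm", "equirect")) {
    if (any(x < -180 | x > 180))
      stop("longitude outside [-180, 180]")
    if (any(y < -90 | y > 90))
      stop("latitude outside [-90, 90]")
  }
  km <- switch(mode,
    none = list(x = x / 1000, y = y / 1000),
    equirect = {
      if (is.null(ref_lat)) ref_lat <- mean(y)
      list(x = x * KM_PER_DEG * cos(ref_lat * pi / 180),
           y = y * KM_PER_DEG)
    },
    utm = {
      m <- utm_forward(x, y, zone = zone)
      list(x = m$x / 1000, y = m$y / 1000)
    })
  points$x <- km$x
  points$y <- km$y
  points
}

#' Forward and inverse UTM (Transverse Mercator, GRS80) projection
#'
#' Standard Transverse Mercator series (Snyder) on the GRS80 ellipsoid with
#' scale factor 0.9996 and 500 km false easting — the UTM NAD83 convention.
#' `utm_forward` maps degrees to metres, `utm_inverse` maps metres back to
#' degrees; the pair round-trips to well under a metre.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param x,y easting/northing in metres.
#' @param zone UTM zone number (1-60).
#' @return a list with components `x`/`y` (metres) or `lon`/`lat` (degrees).
#' @export
utm_forward <- function(lon, lat, zone = 14) {
  stopifnot(zone >= 1, zone <= 60)
  a <- .GRS80_A
  f <- .GRS80_F
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lon0 <- (-183 + 6 * zone) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180

  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lon0) * cos(phi)

  M <- .merid_arc(phi, a, e2)

  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                   (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 5e5
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
               (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
               (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  list(x = x, y = y)
}

#' @rdname utm_forward
#' @export
utm_inverse <- function(x, y, zone = 14) {
  a <- .GRS80_A
  f <- .GRS80_F
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lon0 <- (-183 + 6 * zone) * pi / 180
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))

  M <- y / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu +
    (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)

  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  D <- (x - 5e5) / (N1 * k0)

  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) *
         D^6 / 720)
  lam <- lon0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
                   (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
                     D^5 / 120) / cos(phi1)
  list(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# meridian arc length from the equator (Snyder 3-21)
.merid_arc <- function(phi, a, e2) {
  a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
         (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
         (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
         (35 * e2^3 / 3072) * sin(6 * phi))
}

#' Read point records or site locations from delimited text
#'
#' `read_points` reads a header CSV with columns `x`, `y` and one 0/1 column
#' per outcome; `read_sites` reads a site table with columns `name`, `x`, `y`.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_points <- function(path) {
  d <- read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    stop("point file must have columns 'x' and 'y'")
  validate_points(d)
  d
}

#' @rdname read_points
#' @export
read_sites <- function(path) {
  d <- read.csv(path)
  if (!all(c("name", "x", "y") %in% names(d)))
    stop("site file must have columns 'name', 'x' and 'y'")
  if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
    stop("site coordinates must be finite")
  d
}

validate_points <- function(points) {
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("coordinates must be finite")
  for (o in outcome_names(points)) {
    v <- points[[o]]
    if (!all(v %in% c(0, 1)))
      stop("outcome '", o, "' must be coded 0/1")
  }
  invisible(points)
}

outcome_names <- function(points) setdiff(names(points), c("x", "y"))

#' Overall (study-wide) outcome rate
#'
#' The proportion of records flagged for an outcome over the whole study
#' region — the internal standard used to form expected counts.
#'
#' @param points point-record data frame.
#' @param outcome outcome column name; defaults to the first outcome column.
#' @return a proportion in `[0, 1]`.
#' @export
overall_rate <- function(points, outcome = NULL) {
  if (!is.data.frame(points) || nrow(points) == 0L)
    stop("at least one record is required")
  if (is.null(outcome)) outcome <- outcome_names(points)[1]
  if (is.na(outcome) || !outcome %in% names(points))
    stop("outcome column not found")
  validate_points(points[outcome])
  mean(points[[outcome]])
}

#' Bin point records into square pixels
#'
#' Assigns every record to the pixel whose centre (an integer multiple of
#' `resolution` km in each coordinate) is nearest; half-way ties are resolved
#' by round-half-to-even.  Counts are conserved: the per-pixel birth counts
#' sum to the number of records and each outcome's case counts sum to its
#' number of cases.
#'
#' @param points point records in planar kilometre coordinates.
#' @param resolution pixel edge length in km (default 1).
#' @return a `pixel_counts` data frame with columns `ix`, `iy` (integer pixel
#'   indices; the pixel centre is at `(ix, iy) * resolution` km), `n` (birth
#'   count) and one case-count column per outcome.
#' @export
bin_to_pixels <- function(points, resolution = 1) {
  stopifnot(is.data.frame(points), resolution > 0)
  validate_points(points)
  outs <- outcome_names(points)
  if (nrow(points) == 0L) {
    out <- data.frame(ix = integer(), iy = integer(), n = integer())
    for (o in outs) out[[o]] <- integer()
    return(structure(out, resolution = resolution, class = c("pixel_counts", "data.frame")))
  }
  ix <- as.integer(round(points$x / resolution))
  iy <- as.integer(round(points$y / resolution))
  key <- paste(ix, iy)
  mat <- cbind(n = rep(1L, nrow(points)))
  if (length(outs))
    mat <- cbind(mat, as.matrix(points[, outs, drop = FALSE]))
  agg <- rowsum(mat, key)
  kk <- strsplit(rownames(agg), " ", fixed = TRUE)
  out <- data.frame(ix = as.integer(vapply(kk, `[`, "", 1L)),
                    iy = as.integer(vapply(kk, `[`, "", 2L)))
  out$n <- as.integer(agg[, "n"])
  for (o in outs) out[[o]] <- as.integer(agg[, o])
  out <- out[order(out$ix, out$iy), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, resolution = resolution, class = c("pixel_counts", "data.frame"))
}

as_site <- function(site) {
  if (is.data.frame(site)) site <- as.list(site[1, , drop = FALSE])
  if (is.null(site$name)) site$name <- "site"
  stopifnot(is.finite(site$x), is.finite(site$y))
  site[c("name", "x", "y")]
}

#' Extract a study window around a site
#'
#' Cuts a `width` x `height` pixel window out of binned counts, centred on the
#' pixel containing the site (for even dimensions the site pixel sits at
#' 0-based index `width %/% 2`, i.e. just east/north of centre).  Pixels with
#' no records get zero births and cases and are marked unoccupied — the
#' "structural zeros" of the zero-inflated model.
#'
#' @param binned a `pixel_counts` data frame from [bin_to_pixels()].
#' @param site a site as `list(name=, x=, y=)` or one-row data frame, planar
#'   km coordinates.
#' @param width,height window dimensions in pixels (default 20 x 20).
#' @param outcome which outcome's case counts to carry as `cases`; defaults
#'   to the first outcome column.
#' @return a `study_window` object: a list with the site, `origin` (integer
#'   pixel index of the south-west pixel centre), `width`, `height`,
#'   `resolution`, and `[height x width]` matrices `births`, `cases`,
#'   `occupied` (1 iff any birth) and `expected` (`NULL` until
#'   [compute_expected()] is called).
#' @export
extract_window <- function(binned, site, width = 20, height = 20,
                           outcome = NULL) {
  stopifnot(inherits(binned, "pixel_counts") || is.data.frame(binned),
            width >= 1, height >= 1)
  resolution <- attr(binned, "resolution")
  if (is.null(resolution)) resolution <- 1
  site <- as_site(site)
  outs <- setdiff(names(binned), c("ix", "iy", "n"))
  if (is.null(outcome)) outcome <- if (length(outs)) outs[1] else NULL
  sx <- as.integer(round(site$x / resolution))
  sy <- as.integer(round(site$y / resolution))
  origin <- c(sx - width %/% 2, sy - height %/% 2)

  births <- matrix(0L, height, width)
  cases <- matrix(0L, height, width)
  col <- binned$ix - origin[1] + 1L   # 1-based window column
  row <- binned$iy - origin[2] + 1L   # 1-based window row
  keep <- col >= 1L & col <= width & row >= 1L & row <= height
  if (any(keep)) {
    idx <- cbind(row[keep], col[keep])
    births[idx] <- binned$n[keep]
    if (!is.null(outcome)) {
      if (!outcome %in% names(binned)) stop("outcome column not found")
      cases[idx] <- binned[[outcome]][keep]
    }
  }
  w <- structure(list(
    site = site, origin = origin, width = as.integer(width),
    height = as.integer(height), resolution = resolution,
    outcome = outcome, births = births, cases = cases,
    occupied = matrix(as.integer(births >= 1L), height, width),
    expected = NULL), class = "study_window")
  validate_window(w)
  w
}

#' Build a study window directly from count matrices
#'
#' Convenience constructor used for small hand-built examples and simulated
#' windows: takes `[height x width]` birth and case matrices and returns the
#' same `study_window` structure as [extract_window()].
#'
#' @param births,cases integer matrices of identical dimension.
#' @param origin integer pixel index of the south-west pixel centre.
#' @param resolution pixel edge length (km).
#' @param site optional site list; defaults to the centre pixel.
#' @param expected optional matrix of expected counts.
#' @export
study_window <- function(births, cases = 0 * births, origin = c(0L, 0L),
                         resolution = 1, site = NULL, expected = NULL) {
  births <- as.matrix(births)
  cases <- as.matrix(cases)
  height <- nrow(births)
  width <- ncol(births)
  if (is.null(site))
    site <- list(name = "site",
                 x = (origin[1] + width %/% 2) * resolution,
                 y = (origin[2] + height %/% 2) * resolution)
  w <- structure(list(
    site = as_site(site), origin = as.integer(origin),
    width = as.integer(width), height = as.integer(height),
    resolution = resolution, outcome = "outcome",
    births = births, cases = cases,
    occupied = matrix(as.integer(births >= 1), height, width),
    expected = expected), class = "study_window")
  validate_window(w)
  w
}

validate_window <- function(w) {
  stopifnot(inherits(w, "study_window"))
  if (any(w$births < 0) || any(w$cases < 0))
    stop("negative counts in window")
  if (any(w$cases > w$births))
    stop("cases exceed births in some pixel (cases at unoccupied pixels are impossible)")
  if (!identical(dim(w$births), dim(w$cases)))
    stop("births/cases dimension mismatch")
  if (any((w$occupied == 1) != (w$births >= 1)))
    stop("occupied indicator inconsistent with birth counts")
  if (!is.null(w$expected)) {
    if (any(w$expected < 0)) stop("negative expected counts")
    if (any(w$expected[w$births == 0] != 0))
      stop("expected count must be 0 at structural-zero pixels")
    if (any(w$occupied == 1 & w$expected == 0))
      stop("occupied pixel with zero expected count")
  }
  invisible(w)
}

#' Attach expected counts to a study window
#'
#' Internal standardisation: the expected case count of a pixel is its birth
#' count times the overall (study-wide) outcome rate, so pixels with zero
#' births get an expected count of exactly zero (a structural zero).
#'
#' @param window a `study_window`.
#' @param rate overall outcome rate, strictly between 0 and 1 (see
#'   [overall_rate()]).
#' @return the window with its `expected` matrix filled in.
#' @export
compute_expected <- function(window, rate) {
  stopifnot(inherits(window, "study_window"))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate >= 1)
    stop("rate must be a single number strictly between 0 and 1")
  window$expected <- window$births * rate
  validate_window(window)
  window
}

#' @export
print.study_window <- function(x, ...) {
  cat("Study window:", x$width, "x", x$height, "pixels of",
      x$resolution, "km around site '", x$site$name, "'\n", sep = " ")
  cat("  origin (SW pixel centre): (", x$origin[1], ", ", x$origin[2],
      ") km; outcome: ", x$outcome %||% "<none>", "\n", sep = "")
  cat("  births:", sum(x$births), "in", sum(x$occupied), "occupied pixels;",
      "cases:", sum(x$cases), "\n")
  if (!is.null(x$expected))
    cat("  expected cases:", format(sum(x$expected), digits = 5), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write window counts as CSV
#'
#' One row per pixel with integer pixel indices, counts, expected counts and
#' the occupancy flag.
#'
#' @param window a `study_window` with expected counts.
#' @param path output file.
#' @export
write_window_csv <- function(window, path) {
  g <- window_grid(window)
  d <- data.frame(ix = g$ix, iy = g$iy,
                  n = as.vector(window$births),
                  Y = as.vector(window$cases),
                  E = if (is.null(window$expected)) NA_real_ else as.vector(window$expected),
                  occupied = as.vector(window$occupied))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# integer pixel indices (ix, iy) for each linear (column-major) pixel of a window
window_grid <- function(window) {
  ix <- rep(window$origin[1] + seq_len(window$width) - 1L, each = window$height)
  iy <- rep(window$origin[2] + seq_len(window$height) - 1L, times = window$width)
  list(ix = ix, iy = iy)
}
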