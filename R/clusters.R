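# Cluster screening: connected components of high-exceedance pixels.

#' Detect disease clusters on an exceedance surface
#'
#' Screens a study window for clusters, defined as connected components of
#' pixels whose exceedance probability is strictly greater than a threshold
#' (default 99%).  Components smaller than `min_size` (default 2 — a cluster
#' is "multiple adjacent pixels") are discarded.  Connectivity uses the
#' queen (8-neighbour) rule by default, matching the model's nine-pixel
#' neighbourhoods; the rook (4-neighbour) rule is available for sensitivity.
#'
#' @param surface an `ep_surface` from [exceedance()], or a bare EP matrix
#'   (row 1 = south) for hand-built examples.
#' @param threshold exceedance threshold, strictly between 0 and 1.
#' @param min_size smallest component size kept.
#' @param adjacency `"queen"` or `"rook"`.
#' @return a `cluster_set` object: data frame `clusters` (one row per
#'   cluster: `id`, `size`, `max_ep`, centroid km coordinates) plus the
#'   member pixel indices, threshold and rule used.  Empty result allowed.
#' @export
detect_clusters <- function(surface, threshold = 0.99, min_size = 2,
                            adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly between 0 and 1")
  if (inherits(surface, "ep_surface")) {
    ep <- surface$ep
    origin <- surface$origin
    resolution <- surface$resolution
    site <- surface$site
  } else {
    ep <- as.matrix(surface)
    origin <- attr(surface, "origin") %||% c(0L, 0L)
    resolution <- attr(surface, "resolution") %||% 1
    site <- NULL
  }
  h <- nrow(ep)
  w <- ncol(ep)
  mask <- ep > threshold  # strict inequality
  comp <- flood_fill_components(mask, adjacency)
  ids <- setdiff(unique(as.vector(comp)), 0L)
  members <- lapply(ids, function(id) which(comp == id))
  keep <- lengths(members) >= min_size
  members <- members[keep]
  # deterministic order: largest first, ties by smallest member index
  if (length(members)) {
    ord <- order(-lengths(members),
                 vapply(members, min, 0L))
    members <- members[ord]
  }
  rows <- lapply(seq_along(members), function(i) {
    k <- members[[i]]
    iy <- (k - 1L) %% h + 1L
    ix <- (k - 1L) %/% h + 1L
    cx <- mean(origin[1] + ix - 1) * resolution
    cy <- mean(origin[2] + iy - 1) * resolution
    data.frame(id = i, size = length(k), max_ep = max(ep[k]),
               centroid_x = cx, centroid_y = cy)
  })
  clusters <- if (length(rows)) do.call(rbind, rows)
    else data.frame(id = integer(), size = integer(), max_ep = numeric(),
                    centroid_x = numeric(), centroid_y = numeric())
  structure(list(clusters = clusters, members = members,
                 threshold = threshold, min_size = min_size,
                 adjacency = adjacency, origin = origin,
                 resolution = resolution, site = site,
                 dim = c(h, w)),
            class = "cluster_set")
}

# label connected components of a logical matrix; 0 = background
flood_fill_components <- function(mask, rule = "queen") {
  h <- nrow(mask)
  w <- ncol(mask)
  comp <- matrix(0L, h, w)
  offs <- if (rule == "queen")
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nextid <- 0L
  for (start in which(mask & comp == 0L)) {
    if (comp[start] != 0L) next
    nextid <- nextid + 1L
    stack <- start
    comp[start] <- nextid
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      vy <- (v - 1L) %% h + 1L
      vx <- (v - 1L) %/% h + 1L
      ny <- vy + offs[, 1]
      nx <- vx + offs[, 2]
      ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= w
      for (u in (nx[ok] - 1L) * h + ny[ok]) {
        if (mask[u] && comp[u] == 0L) {
          comp[u] <- nextid
          stack <- c(stack, u)
        }
      }
    }
  }
  comp
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster screen: EP >", x$threshold, "(", x$adjacency,
      "adjacency, min size", x$min_size, ")\n")
  if (nrow(x$clusters) == 0L) {
    cat("  no clusters detected\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' Annotate clusters with distance and bearing to the site
#'
#' Adds, per cluster, the Euclidean distance (km) from its centroid to the
#' centre of the site's pixel and the 8-point compass bearing from the site
#' towards the centroid (`NA` for a centroid on the site pixel itself).
#'
#' @param clusters a `cluster_set`.
#' @param window the `study_window` the surface was fitted on (supplies the
#'   site-pixel geometry).
#' @return the `cluster_set` with `distance_km` and `bearing` columns added.
#' @export
site_proximity <- function(clusters, window) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(window, "study_window"))
  res <- window$resolution
  sx <- round(window$site$x / res) * res  # site pixel centre, km
  sy <- round(window$site$y / res) * res
  cl <- clusters$clusters
  if (nrow(cl)) {
    dx <- cl$centroid_x - sx
    dy <- cl$centroid_y - sy
    cl$distance_km <- sqrt(dx^2 + dy^2)
    cl$bearing <- compass_bearing(dx, dy)
  } else {
    cl$distance_km <- numeric()
    cl$bearing <- character()
  }
  clusters$clusters <- cl
  clusters$site <- window$site
  clusters
}

# 8-point compass sector of the direction (dx east, dy north)
compass_bearing <- function(dx, dy) {
  ang <- atan2(dx, dy) * 180 / pi       # 0 = N, 90 = E
  ang <- (ang + 360) %% 360
  sect <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  out <- sect[(floor((ang + 22.5) / 45) %% 8) + 1]
  out[dx == 0 & dy == 0] <- NA_character_
  out
}

#' Human-readable cluster report
#'
#' @param clusters an annotated `cluster_set` (see [site_proximity()]).
#' @param path optional file to write the report to.
#' @return the report lines, invisibly when written to file.
#' @export
cluster_report <- function(clusters, path = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  cl <- clusters$clusters
  site <- clusters$site$name %||% "site"
  lines <- c(sprintf("Cluster screen for '%s': EP > %g, %s adjacency, min size %d",
                     site, clusters$threshold, clusters$adjacency,
                     clusters$min_size))
  if (nrow(cl) == 0L) {
    lines <- c(lines, "  no clusters detected")
  } else {
    for (i in seq_len(nrow(cl))) {
      r <- cl[i, ]
      loc <- if (!is.null(r$distance_km)) {
        if (is.na(r$bearing)) "at the site pixel"
        else sprintf("%.1f km %s of the site", r$distance_km, r$bearing)
      } else sprintf("centroid (%.1f, %.1f) km", r$centroid_x, r$centroid_y)
      lines <- c(lines, sprintf("  cluster %d: %d pixels, max EP %.3f, %s",
                                r$id, r$size, r$max_ep, loc))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
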