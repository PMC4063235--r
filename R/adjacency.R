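# Grid neighbourhood structure for the ICAR prior and cluster screening.

#' Grid adjacency (pixel neighbourhoods)
#'
#' Builds the neighbourhood structure of a `width` x `height` pixel grid.
#' The default `"queen"` rule gives every interior pixel its 8 surrounding
#' pixels, so interior neighbourhoods contain nine pixels (centre + 8);
#' boundary pixels have fewer neighbours.  Pixels are indexed column-major:
#' pixel `k` corresponds to `(iy, ix)` with `k = (ix - 1) * height + iy`,
#' matching `as.vector()` on the window matrices.
#'
#' @param width,height grid dimensions in pixels; both must be at least 2.
#' @param type `"queen"` (8 neighbours, the default) or `"rook"` (4).
#' @return a `grid_adjacency` object: list with `neighbors` (list of integer
#'   vectors, one per pixel), `width`, `height`, `type` and `n_pairs` (number
#'   of unordered neighbour pairs).  All weights are binary.
#' @examples
#' a <- build_adjacency(3, 3)
#' lengths(a$neighbors)  # corner 3, edge 5, centre 8
#' @export
build_adjacency <- function(width, height, type = c("queen", "rook")) {
  type <- match.arg(type)
  if (width < 2 || height < 2)
    stop("grid must be at least 2 x 2")
  .grid_adjacency(width, height, type)
}

# internal constructor without the >= 2 restriction (a 1 x 1 window has an
# empty neighbourhood and degenerates to a Poisson model with offset)
.grid_adjacency <- function(width, height, type = "queen") {
  offs <- if (type == "queen")
    cbind(dx = c(-1, -1, -1, 0, 0, 1, 1, 1), dy = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else
    cbind(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))
  n <- width * height
  nbr <- vector("list", n)
  for (ix in seq_len(width)) {
    for (iy in seq_len(height)) {
      k <- (ix - 1L) * height + iy
      nx <- ix + offs[, "dx"]
      ny <- iy + offs[, "dy"]
      ok <- nx >= 1 & nx <= width & ny >= 1 & ny <= height
      nbr[[k]] <- sort(as.integer((nx[ok] - 1L) * height + ny[ok]))
    }
  }
  structure(list(neighbors = nbr, width = as.integer(width),
                 height = as.integer(height), type = type,
                 n_pairs = sum(lengths(nbr)) / 2L),
            class = "grid_adjacency")
}

#' @export
print.grid_adjacency <- function(x, ...) {
  cat("Grid adjacency:", x$width, "x", x$height, "pixels,", x$type,
      "rule;", x$n_pairs, "neighbour pairs\n")
  invisible(x)
}

# number of connected components of the adjacency graph (1 on any grid, but
# the ICAR normalising rank (n - c) is computed, not assumed)
n_components <- function(adjacency) {
  n <- length(adjacency$neighbors)
  if (n == 0L) return(0L)
  comp <- integer(n)
  c_id <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    c_id <- c_id + 1L
    queue <- s
    comp[s] <- c_id
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (u in adjacency$neighbors[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- c_id
          queue <- c(queue, u)
        }
      }
    }
  }
  c_id
}

# flatten the neighbour list to 0-based CSR arrays for the C++ sampler
flatten_adjacency <- function(adjacency) {
  nbr <- adjacency$neighbors
  idx <- as.integer(unlist(nbr, use.names = FALSE)) - 1L
  ptr <- c(0L, cumsum(lengths(nbr)))
  list(idx = idx, ptr = as.integer(ptr))
}
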