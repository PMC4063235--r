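# ESRI ASCII grid export/import for EP and relative-risk layers.

#' Write a surface layer as an ESRI ASCII grid
#'
#' Writes one layer of an [exceedance()] surface (or any window-shaped
#' matrix) in the plain-text ESRI ASCII raster format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value -9999`) followed by rows of values written from the
#' northernmost row down.  Cell size and corner coordinates are written in
#' metres (internal maths is in km); values are written with six decimals and
#' round-trip bit-identically at that precision through
#' [read_esri_ascii()].  `NA` values are written as the NODATA code.
#'
#' @param x an `ep_surface`, or a `[height x width]` matrix (row 1 = south).
#' @param path output file path.
#' @param layer which layer of an `ep_surface` to write.
#' @param origin,resolution geometry (km) when `x` is a bare matrix.
#' @param nodata NODATA code (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(x, path, layer = c("ep", "rr_median"),
                             origin = c(0L, 0L), resolution = 1,
                             nodata = -9999) {
  if (inherits(x, "ep_surface")) {
    layer <- match.arg(layer)
    m <- x[[layer]]
    origin <- x$origin
    resolution <- x$resolution
  } else {
    m <- as.matrix(x)
  }
  nr <- nrow(m)
  nc <- ncol(m)
  cell_m <- resolution * 1000
  hdr <- c(paste("ncols", nc),
           paste("nrows", nr),
           paste("xllcorner", format((origin[1] - 0.5) * resolution * 1000,
                                     scientific = FALSE)),
           paste("yllcorner", format((origin[2] - 0.5) * resolution * 1000,
                                     scientific = FALSE)),
           paste("cellsize", format(cell_m, scientific = FALSE)),
           paste("NODATA_value", nodata))
  body <- apply(m[rev(seq_len(nr)), , drop = FALSE], 1, function(row) {
    row <- ifelse(is.na(row), nodata, row)
    paste(formatC(row, format = "f", digits = 6), collapse = " ")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Counterpart of [write_esri_ascii()].  NODATA cells become `NA`.
#'
#' @param path file path.
#' @return a `[height x width]` matrix (row 1 = southernmost row) with
#'   attributes `origin` (integer pixel index of the south-west pixel centre,
#'   km units) and `resolution` (km).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != nc * nr) stop("malformed ESRI ASCII grid")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to south-up
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  res_km <- hdr$cellsize / 1000
  structure(m,
            origin = c(round(hdr$xllcorner / 1000 / res_km + 0.5),
                       round(hdr$yllcorner / 1000 / res_km + 0.5)),
            resolution = res_km)
}
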