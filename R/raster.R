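# Lightweight gridded covariate surfaces (patch quality, landcover,
# distance maps).  One convention, used everywhere:
#   - origin = (x, y) of the LOWER-LEFT corner of cell [1, 1];
#   - values[r, c] covers the half-open square
#       x in [origin_x + (c-1)*cell, origin_x + c*cell)
#       y in [origin_y + (r-1)*cell, origin_y + r*cell)
#     i.e. rows index y (south to north), columns index x (west to east);
#   - lookup is nearest-cell (the cell containing the point), never
#     interpolated.

#' Create a raster grid
#'
#' @param values numeric matrix; rows index y (south to north), columns x.
#' @param origin length-2 numeric, (x, y) of the lower-left corner in km.
#' @param cell_size cell edge length in km (> 0).
#' @param name covariate name.
#' @return an object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell_size = 1,
                        name = "layer") {
  stopifnot(is.matrix(values), cell_size > 0, length(origin) == 2)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = cell_size, name = name),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid '%s': %d x %d cells, cell %.4g km, origin (%.4g, %.4g)\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

raster_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + ncol(grid$values) * grid$cell_size,
    ymin = grid$origin[2],
    ymax = grid$origin[2] + nrow(grid$values) * grid$cell_size)
}

#' Extract raster values at points
#'
#' Value of the cell containing each point (nearest-cell, no
#' interpolation).  Points outside the grid extent raise an error unless
#' \code{outside = "na"}, in which case NA is returned for them so the
#' caller can decide to drop or clamp.
#'
#' @param grid a \code{raster_grid}.
#' @param x,y point coordinates in km (vectors of equal length).
#' @param outside "error" (default) or "na".
#' @return numeric vector of cell values.
#' @export
extract_raster <- function(grid, x, y, outside = c("error", "na")) {
  outside <- match.arg(outside)
  stopifnot(length(x) == length(y))
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1
  bad <- col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values) |
    !is.finite(x) | !is.finite(y)
  if (any(bad) && outside == "error")
    stop("extract_raster: ", sum(bad), " point(s) outside the grid extent")
  out <- rep(NA_real_, length(x))
  ok <- !bad
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values from the
#' NORTH down, which are flipped into this package's south-to-north row
#' order.
#'
#' @param path file path.
#' @param name covariate name for the returned grid.
#' @return a \code{raster_grid}.
#' @export
read_ascii_grid <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # north-down file -> south-up
  raster_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              cell_size = hdr$cellsize, name = name)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a \code{raster_grid}.
#' @param path output file path.
#' @param nodata value used for NA cells.
#' @return invisibly, the path.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  m <- grid$values
  m[is.na(m)] <- nodata
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
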