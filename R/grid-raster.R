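#' Georeferenced grid raster
#'
#' A minimal single-band raster: a numeric matrix with a lower-left origin
#' and a square cell size, in projected metric coordinates. Row 1 is the
#' northernmost row (the ESRI ASCII grid convention), `NA` marks nodata.
#'
#' @param values Numeric matrix of cell values; row 1 is the top (north) row.
#' @param xll,yll Coordinates (m) of the lower-left corner of the grid.
#' @param cellsize Cell edge length in metres; must be positive.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 30) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values), cellsize > 0)
  storage.mode(values) <- "double"
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid_raster> %d x %d cells, %.6g m cells, origin (%.6g, %.6g)\n",
    nrow(v), ncol(v), x$cellsize, x$xll, x$yll
  ))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values: [%.6g, %.6g], %d nodata\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Coordinates of every cell center
#'
#' @param r A `grid_raster`.
#' @return A list with matrices `x` and `y` of cell-center coordinates,
#'   same shape as the value matrix.
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  cx <- r$xll + (seq_len(nc) - 0.5) * r$cellsize
  cy <- r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(
    x = matrix(cx, nr, nc, byrow = TRUE),
    y = matrix(cy, nr, nc)
  )
}

#' Extent of a raster
#'
#' @param r A `grid_raster`.
#' @return Numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  c(
    xmin = r$xll, xmax = r$xll + nc * r$cellsize,
    ymin = r$yll, ymax = r$yll + nr * r$cellsize
  )
}

# Row/col of the cell containing each point, half-open cell convention
# [x0, x0 + w) x [y0, y0 + w): a point on a shared edge belongs to the
# cell to its east/north.
point_cell <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cellsize) + 1L
  row <- nr - floor((y - r$yll) / r$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "point (%.6g, %.6g) lies outside the raster extent", x[i], y[i]
    ), call. = FALSE)
  }
  list(row = row, col = col)
}

#' Extract raster values at point coordinates
#'
#' Returns the value of the cell containing each point. Cells are half-open
#' (`[x0, x0 + w)` in both axes), so a point on a shared cell edge is
#' assigned to the cell to its east/north.
#'
#' @param r A `grid_raster`.
#' @param x,y Point coordinates (m); recycled to common length.
#' @return Numeric vector of cell values (NA where the cell is nodata).
#' @export
extract_at_points <- function(r, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  rc <- point_cell(r, x, y)
  r$values[cbind(rc$row, rc$col)]
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return A `grid_raster`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  vv <- scan(path, skip = 6, quiet = TRUE)
  stopifnot(length(vv) == nr * nc)
  m <- matrix(vv, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_raster(m,
    xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
    cellsize = vals[["cellsize"]]
  )
}

#' Write an ESRI ASCII grid
#'
#' @param r A `grid_raster`.
#' @param path Output path.
#' @param digits Significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 10) {
  v <- r$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    "NODATA_value -9999"
  )
  vv <- v
  vv[is.na(vv)] <- -9999
  body <- apply(vv, 1, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
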