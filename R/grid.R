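#' Define a regular planar analysis grid
#'
#' All rasters in the package live on a regular kilometre grid. Layers are
#' stored as `ny x nx` matrices whose rows run north to south, so `layer[1, 1]`
#' is the north-west corner cell. Coordinates refer to cell centres: column
#' `j` has `x = x0 + (j - 0.5) * cell_size_km`, row `i` has
#' `y = y0 + (ny - i + 0.5) * cell_size_km`. The x axis points offshore
#' (east), the y axis alongshore (north).
#'
#' @param nx,ny Number of columns (across-shore) and rows (alongshore).
#' @param cell_size_km Cell edge length in km (default 1, i.e. 1 km^2 cells).
#' @param x0,y0 Coordinates of the grid's south-west corner, in km.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, cell_size_km = 1, x0 = 0, y0 = 0) {
  stopifnot(nx >= 1, ny >= 1, cell_size_km > 0)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         cell_size_km = cell_size_km, x0 = x0, y0 = y0),
    class = "grid_spec"
  )
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with `x` (length `nx`) and `y` (length `ny`, ordered to
#'   match matrix rows, i.e. north first).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cs <- grid$cell_size_km
  list(
    x = grid$x0 + (seq_len(grid$nx) - 0.5) * cs,
    y = grid$y0 + (grid$ny - seq_len(grid$ny) + 0.5) * cs
  )
}

#' Coordinates of every cell centre as a two-column matrix
#'
#' Rows are in matrix element order (column-major over the `ny x nx` layer).
#' @param grid A [grid_spec()].
#' @return A numeric matrix with columns `x`, `y` and `nx * ny` rows.
#' @export
cell_xy <- function(grid) {
  cc <- cell_centers(grid)
  cbind(x = rep(cc$x, each = grid$ny), y = rep(cc$y, times = grid$nx))
}

#' Map point coordinates to matrix indices
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates in km.
#' @return Integer matrix with columns `row`, `col`; points outside the grid
#'   get `NA`.
#' @export
xy_to_rowcol <- function(grid, x, y) {
  cs <- grid$cell_size_km
  col <- floor((x - grid$x0) / cs) + 1
  row <- grid$ny - floor((y - grid$y0) / cs)
  bad <- col < 1 | col > grid$nx | row < 1 | row > grid$ny
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster with the usual 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`). `NA` cells are
#' written as the nodata value. Data rows run north to south, matching the
#' matrix layout.
#'
#' @param layer `ny x nx` numeric matrix.
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @param nodata Value used for `NA` cells (default -9999).
#' @export
write_ascii_grid <- function(layer, grid, path, nodata = -9999) {
  stopifnot(is.matrix(layer), nrow(layer) == grid$ny, ncol(layer) == grid$nx)
  hdr <- c(
    sprintf("ncols %d", grid$nx),
    sprintf("nrows %d", grid$ny),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", grid$y0),
    sprintf("cellsize %.10g", grid$cell_size_km),
    sprintf("NODATA_value %.10g", nodata)
  )
  m <- layer
  m[is.na(m)] <- nodata
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ASCII-grid file).
#' @return A list with `layer` (matrix, nodata mapped to `NA`) and `grid`
#'   (a [grid_spec()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nx <- as.integer(vals[["ncols"]])
  ny <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  stopifnot(nrow(m) == ny, ncol(m) == nx)
  m[m == nodata] <- NA_real_
  list(
    layer = m,
    grid = grid_spec(nx, ny, cell_size_km = vals[["cellsize"]],
                     x0 = vals[["xllcorner"]], y0 = vals[["yllcorner"]])
  )
}
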