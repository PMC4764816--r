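#' Define a regular raster grid
#'
#' A grid definition anchors all raster layers in the package: a regular grid
#' of square cells whose origin is the *outer north-west corner*. Row 1 is the
#' northernmost row and cell values refer to cell centers, so the center of
#' cell (row, col) lies at
#' `x = x_origin + (col - 0.5) * cell_size` and
#' `y = y_origin - (row - 0.5) * cell_size`.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_origin,y_origin Map coordinates of the north-west corner, in the
#'   units of `crs` (typically meters for a projected grid).
#' @param cell_size Cell edge length in map units (> 0); 90 m grids are the
#'   working resolution for regional SOC mapping.
#' @param crs Free-form identifier of the coordinate reference system.
#' @return An object of class `soc_grid`.
#' @examples
#' g <- grid_def(100, 120, 0, 9000, cell_size = 90)
#' g
#' @export
grid_def <- function(n_rows, n_cols, x_origin = 0, y_origin = n_rows * cell_size,
                     cell_size = 90, crs = "local") {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  if (n_rows < 1 || n_cols < 1) stop("grid must have at least one row and column", call. = FALSE)
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
      cell_size = as.numeric(cell_size), crs = as.character(crs)
    ),
    class = "soc_grid"
  )
}

#' @export
print.soc_grid <- function(x, ...) {
  cat(sprintf(
    "<soc_grid> %d x %d cells of %g map units (NW corner %g, %g; crs '%s')\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin, x$crs
  ))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "x_origin", "y_origin", "cell_size")],
                   unclass(b)[c("n_rows", "n_cols", "x_origin", "y_origin", "cell_size")]))
}

#' Convert between map coordinates and cell indices
#'
#' `cell_from_xy()` returns the (row, col) of the cell containing each point;
#' `xy_from_cell()` returns cell-center coordinates. Points on a cell edge
#' belong to the cell to the south/east (half-open cells), except on the outer
#' south/east boundary which is included so the grid extent is closed.
#'
#' @param grid A [grid_def()].
#' @param x,y Numeric vectors of map coordinates.
#' @param row,col Integer vectors of cell indices (1-based).
#' @return A tibble with columns `row`, `col` (NA outside the grid), or with
#'   columns `x`, `y`.
#' @export
cell_from_xy <- function(grid, x, y) {
  stopifnot(inherits(grid, "soc_grid"), length(x) == length(y))
  col <- floor((x - grid$x_origin) / grid$cell_size) + 1
  row <- floor((grid$y_origin - y) / grid$cell_size) + 1
  # close the outer boundary
  col[x == grid$x_origin + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$y_origin - grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' @rdname cell_from_xy
#' @export
xy_from_cell <- function(grid, row, col) {
  stopifnot(inherits(grid, "soc_grid"), length(row) == length(col))
  if (any(row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols, na.rm = TRUE)) {
    stop("cell index outside grid", call. = FALSE)
  }
  tibble::tibble(
    x = grid$x_origin + (col - 0.5) * grid$cell_size,
    y = grid$y_origin - (row - 0.5) * grid$cell_size
  )
}

#' Build per-pixel coordinate layers
#'
#' Produces the two spatial-position predictor layers (`Lat`, `Lon`) holding
#' the cell-center y and x coordinate of every pixel. Position layers let a
#' scorpan-style model absorb broad geographic trends that the other
#' covariates miss.
#'
#' @param grid A [grid_def()].
#' @return Named list of two matrices `Lat` and `Lon` with `dim = c(n_rows,
#'   n_cols)`.
#' @export
make_coordinate_layers <- function(grid) {
  stopifnot(inherits(grid, "soc_grid"))
  ys <- grid$y_origin - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  xs <- grid$x_origin + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  list(
    Lat = matrix(ys, nrow = grid$n_rows, ncol = grid$n_cols),
    Lon = matrix(xs, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  )
}

#' Resample a raster layer onto another grid
#'
#' Nearest-neighbour (for categorical layers) or bilinear (for continuous
#' layers) resampling of a single layer between two grid definitions, e.g.
#' bringing 1-km climate surfaces onto a common 90-m grid. Bilinear
#' interpolation operates on the source cell-center lattice with edge
#' clamping; any NA among the contributing source cells propagates to NA.
#'
#' @param layer Matrix conforming to `src_grid`.
#' @param src_grid,dst_grid [grid_def()] objects; their extents must overlap.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Matrix conforming to `dst_grid`.
#' @export
resample_to_grid <- function(layer, src_grid, dst_grid, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(layer), nrow(layer) == src_grid$n_rows, ncol(layer) == src_grid$n_cols)
  ctr <- make_coordinate_layers(dst_grid)
  x <- as.vector(ctr$Lon)
  y <- as.vector(ctr$Lat)

  src_xmax <- src_grid$x_origin + src_grid$n_cols * src_grid$cell_size
  src_ymin <- src_grid$y_origin - src_grid$n_rows * src_grid$cell_size
  inside <- x >= src_grid$x_origin & x <= src_xmax & y >= src_ymin & y <= src_grid$y_origin
  if (!any(inside)) stop("destination grid does not overlap the source extent", call. = FALSE)

  out <- rep(NA_real_, length(x))
  if (method == "nearest") {
    idx <- cell_from_xy(src_grid, x, y)
    ok <- !is.na(idx$row)
    out[ok] <- layer[cbind(idx$row[ok], idx$col[ok])]
  } else {
    # fractional position on the source cell-center lattice
    fc <- (x - src_grid$x_origin) / src_grid$cell_size + 0.5
    fr <- (src_grid$y_origin - y) / src_grid$cell_size + 0.5
    c0 <- pmin(pmax(floor(fc), 1), src_grid$n_cols - 1L)
    r0 <- pmin(pmax(floor(fr), 1), src_grid$n_rows - 1L)
    if (src_grid$n_cols == 1) c0 <- rep(1L, length(fc))
    if (src_grid$n_rows == 1) r0 <- rep(1L, length(fr))
    c1 <- pmin(c0 + 1, src_grid$n_cols)
    r1 <- pmin(r0 + 1, src_grid$n_rows)
    wc <- pmin(pmax(fc - c0, 0), 1)
    wr <- pmin(pmax(fr - r0, 0), 1)
    v00 <- layer[cbind(r0, c0)]; v01 <- layer[cbind(r0, c1)]
    v10 <- layer[cbind(r1, c0)]; v11 <- layer[cbind(r1, c1)]
    out <- (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
    out[!inside] <- NA_real_
  }
  matrix(out, nrow = dst_grid$n_rows, ncol = dst_grid$n_cols)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text single-layer raster I/O in the ESRI ASCII grid (`.asc`) dialect:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from north to south. The llcorner
#' convention of the format is translated to this package's NW-corner origin.
#'
#' @param path File path.
#' @param crs Coordinate-system tag to attach on read (the format itself
#'   carries none).
#' @param layer Matrix to write.
#' @param grid The layer's [grid_def()].
#' @param nodata Value used to encode NA on disk.
#' @return `read_ascii_grid()` returns `list(grid, layer)`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, crs = "local") {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, what = numeric(), skip = 6, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(body) != nr * nc) {
    stop(sprintf("expected %d values in %s, found %d", nr * nc, path, length(body)), call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  g <- grid_def(nr, nc,
    x_origin = vals[["xllcorner"]],
    y_origin = vals[["yllcorner"]] + nr * vals[["cellsize"]],
    cell_size = vals[["cellsize"]], crs = crs
  )
  list(grid = g, layer = m)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(layer, grid, path, nodata = -9999) {
  stopifnot(is.matrix(layer), nrow(layer) == grid$n_rows, ncol(layer) == grid$n_cols)
  m <- layer
  m[is.na(m)] <- nodata
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$x_origin),
    sprintf("yllcorner %.10g", grid$y_origin - grid$n_rows * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  rows <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}
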