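#' Georeferenced raster grid geometry
#'
#' A `grid_spec` describes a regular raster on a projected, metric coordinate
#' reference system: the west edge (`x_min`), the north edge (`y_max`), the
#' square cell size in metres, and the number of rows and columns. Row 1 is
#' the northernmost row, column 1 the westernmost column.
#'
#' The CRS is carried as an opaque label (default the Dutch national grid,
#' `"EPSG:28992"`) and is only checked for plausibility as a projected,
#' metre-unit system; no reprojection is performed anywhere in the package.
#'
#' @param x_min West edge of the grid (m).
#' @param y_max North edge of the grid (m).
#' @param cell_size Cell edge length (m); must be > 0.
#' @param n_rows,n_cols Grid dimensions; must be >= 1.
#' @param crs CRS label, e.g. an EPSG code string. Geographic (degree) CRS
#'   labels such as `"EPSG:4326"` are rejected.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(0, 50, 5, 10, 10)
#' @export
grid_spec <- function(x_min, y_max, cell_size, n_rows, n_cols,
                      crs = "EPSG:28992") {
  stopifnot(is.numeric(x_min), is.numeric(y_max), is.numeric(cell_size))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number (metres)")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("`n_rows` and `n_cols` must be >= 1")
  if (!is.character(crs) || length(crs) != 1L)
    stop("`crs` must be a single character label")
  # degree-based systems have no metric cell size; refuse the common ones
  if (grepl("4326|4258|CRS84|longlat", crs, ignore.case = TRUE))
    stop("CRS '", crs, "' is geographic; a projected metric CRS is required")
  structure(
    list(x_min = as.numeric(x_min), y_max = as.numeric(y_max),
         cell_size = as.numeric(cell_size),
         n_rows = n_rows, n_cols = n_cols, crs = crs),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols @ %g m, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_max, x$crs))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm(%g,%g)", x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_max)
}

grid_extent <- function(spec) {
  c(x_min = spec$x_min, x_max = spec$x_min + spec$n_cols * spec$cell_size,
    y_min = spec$y_max - spec$n_rows * spec$cell_size, y_max = spec$y_max)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(a$x_min, b$x_min)) && isTRUE(all.equal(a$y_max, b$y_max)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Coordinates of a cell centre
#'
#' @param spec A [grid_spec()].
#' @param row,col 1-based cell indices (row 1 = northernmost row).
#' @return Numeric vector `c(x, y)` of the cell centre in map units (m).
#' @examples
#' cell_center(grid_spec(0, 50, 5, 10, 10), 1, 1)  # c(2.5, 47.5)
#' @export
cell_center <- function(spec, row, col) {
  stopifnot(inherits(spec, "grid_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (any(is.na(row)) || any(row < 1L) || any(row > spec$n_rows))
    stop("row index out of range [1, ", spec$n_rows, "]")
  if (any(is.na(col)) || any(col < 1L) || any(col > spec$n_cols))
    stop("col index out of range [1, ", spec$n_cols, "]")
  cbind(x = spec$x_min + (col - 0.5) * spec$cell_size,
        y = spec$y_max - (row - 0.5) * spec$cell_size)[, , drop = TRUE]
}

#' Cell containing a point
#'
#' Cells are half-open towards the east and the south: a point on a cell's
#' west or north edge belongs to that cell, a point on its east or south
#' edge to the neighbouring one. The grid's own west/north boundary is
#' included in the extent, the east/south boundary is not.
#'
#' @inheritParams cell_center
#' @param x,y Point coordinates (m), vectorised.
#' @return Integer matrix with columns `row`, `col` (a named vector for a
#'   single point).
#' @export
point_to_cell <- function(spec, x, y) {
  stopifnot(inherits(spec, "grid_spec"))
  ext <- grid_extent(spec)
  bad <- x < ext["x_min"] | x >= ext["x_max"] | y <= ext["y_min"] | y > ext["y_max"]
  if (any(bad))
    stop("point(s) outside grid extent: ",
         paste(sprintf("(%g, %g)", x[bad], y[bad]), collapse = ", "))
  col <- as.integer(floor((x - spec$x_min) / spec$cell_size)) + 1L
  row <- as.integer(floor((spec$y_max - y) / spec$cell_size)) + 1L
  # guard against floating slop exactly on the included boundary
  col <- pmin.int(pmax.int(col, 1L), spec$n_cols)
  row <- pmin.int(pmax.int(row, 1L), spec$n_rows)
  cbind(row = row, col = col)[, , drop = TRUE]
}

#' Raster: a grid_spec plus cell values
#'
#' Cell values are held as a numeric matrix in the grid's row/col layout
#' (row 1 = north). Missing cells are represented as `NA` internally; the
#' `nodata` sentinel is only used when reading and writing files. `NA`
#' propagates through arithmetic and is excluded from all aggregations.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows` x `n_cols`, or a single
#'   number recycled over the grid.
#' @param nodata Sentinel written for `NA` cells in file output.
#' @return An object of class `lur_raster`.
#' @export
new_raster <- function(spec, values = 0, nodata = -9999) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop(sprintf("values are %dx%d but the grid is %dx%d",
                 nrow(values), ncol(values), spec$n_rows, spec$n_cols))
  structure(list(spec = spec, values = values, nodata = as.numeric(nodata)),
            class = "lur_raster")
}

#' @export
print.lur_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<lur_raster> %s | %d NA cells | range [%s, %s]\n",
              format(x$spec), sum(is.na(x$values)),
              if (length(v)) format(min(v)) else "-",
              if (length(v)) format(max(v)) else "-"))
  invisible(x)
}

raster_check_pair <- function(a, b, what = "rasters") {
  if (!same_spec(a$spec, b$spec))
    stop(what, " are on different grids (", format(a$spec), " vs ",
         format(b$spec), ")")
  invisible(TRUE)
}

#' Crop a raster to a rectangular window of cells
#'
#' Georeferencing of the retained cells is preserved: the new origin is the
#' corner of the retained window.
#'
#' @param raster A [new_raster()] object.
#' @param rows,cols Integer ranges (length-2, inclusive) of retained rows and
#'   columns.
#' @return The cropped `lur_raster`.
#' @export
crop_raster <- function(raster, rows, cols) {
  stopifnot(inherits(raster, "lur_raster"))
  sp <- raster$spec
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L) stop("rows/cols must be length-2 ranges")
  if (rows[1] < 1L || rows[2] > sp$n_rows || rows[1] > rows[2] ||
      cols[1] < 1L || cols[2] > sp$n_cols || cols[1] > cols[2])
    stop("crop window outside the grid extent")
  nsp <- grid_spec(sp$x_min + (cols[1] - 1L) * sp$cell_size,
                   sp$y_max - (rows[1] - 1L) * sp$cell_size,
                   sp$cell_size, rows[2] - rows[1] + 1L, cols[2] - cols[1] + 1L,
                   sp$crs)
  new_raster(nsp, raster$values[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
             raster$nodata)
}

#' Aggregate a raster to a coarser resolution by integer blocks
#'
#' Each `factor` x `factor` block of input cells becomes one output cell.
#' Use `mode = "sum"` for additive quantities (lengths, loads, counts, areas)
#' so total mass is conserved, and `mode = "mean"` for intensive quantities
#' such as concentrations. `NA` cells are ignored within a block; an all-`NA`
#' block yields `NA`.
#'
#' @param raster A `lur_raster` whose dimensions are divisible by `factor`.
#' @param factor Positive integer aggregation factor.
#' @param mode `"sum"` or `"mean"`.
#' @return The aggregated `lur_raster` with cell size `factor * cell_size`.
#' @export
resample_raster <- function(raster, factor, mode = c("mean", "sum")) {
  stopifnot(inherits(raster, "lur_raster"))
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  sp <- raster$spec
  if (sp$n_rows %% factor != 0L || sp$n_cols %% factor != 0L)
    stop("grid dimensions must be divisible by `factor`")
  nr <- sp$n_rows %/% factor; nc <- sp$n_cols %/% factor
  v <- raster$values
  ri <- rep(seq_len(nr), each = factor)
  ci <- rep(seq_len(nc), each = factor)
  grp <- ri[row(v)] + nr * (ci[col(v)] - 1L)
  s <- vapply(split(as.vector(v), grp), function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_real_)
    if (mode == "sum") sum(z) else mean(z)
  }, numeric(1))
  out <- matrix(s[as.character(seq_len(nr * nc))], nr, nc)
  nsp <- grid_spec(sp$x_min, sp$y_max, sp$cell_size * factor, nr, nc, sp$crs)
  new_raster(nsp, out, raster$nodata)
}
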