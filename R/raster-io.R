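#' Read and write rasters as ESRI ASCII grids
#'
#' The on-disk raster format of this package is the plain-text ESRI ASCII
#' grid (`.asc`), readable by GDAL and every common GIS. Values are written
#' with 17 significant digits (`%.17g`), which round-trips IEEE doubles
#' exactly, so `read_raster(write_raster(x))` reproduces every cell value
#' bit for bit. `NA` cells are written as the raster's `nodata` sentinel
#' (default `-9999`).
#'
#' The format has no CRS slot; the CRS label is written to a sidecar
#' `<path>.crs` text file and read back when present (defaulting to
#' `"EPSG:28992"` otherwise).
#'
#' @param raster A [new_raster()] object.
#' @param path File path (conventionally ending in `.asc`).
#' @param digits Significant digits used when writing; the default 17
#'   preserves doubles exactly.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `lur_raster`.
#' @export
write_raster <- function(raster, path, digits = 17L) {
  stopifnot(inherits(raster, "lur_raster"))
  sp <- raster$spec
  y_min <- sp$y_max - sp$n_rows * sp$cell_size
  fmt <- paste0("%.", as.integer(digits), "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", sp$n_cols),
    sprintf("nrows %d", sp$n_rows),
    sprintf("xllcorner %s", sprintf(fmt, sp$x_min)),
    sprintf("yllcorner %s", sprintf(fmt, y_min)),
    sprintf("cellsize %s", sprintf(fmt, sp$cell_size)),
    sprintf("NODATA_value %s", sprintf(fmt, raster$nodata))), con)
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  txt <- matrix(sprintf(fmt, v), nrow(v), ncol(v))
  writeLines(apply(txt, 1L, paste, collapse = " "), con)
  crs_path <- paste0(path, ".crs")
  writeLines(sp$crs, crs_path)
  invisible(path)
}

#' @rdname write_raster
#' @param crs CRS label to assume when no `<path>.crs` sidecar exists.
#' @export
read_raster <- function(path, crs = "EPSG:28992") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("malformed ASCII grid (truncated header): ", path)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, " (missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), ")")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("malformed ASCII grid %s: header declares %d x %d = %d cells but file holds %d values",
                 path, nr, nc, nr * nc, length(vals)))
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == nodata] <- NA_real_
  crs_path <- paste0(path, ".crs")
  if (file.exists(crs_path)) crs <- readLines(crs_path, warn = FALSE)[1]
  spec <- grid_spec(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                    hdr$cellsize, nr, nc, crs)
  new_raster(spec, v, nodata)
}
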