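#' Predictor identifiers and their units
#'
#' Per-cell base predictors: road length `RL`/`MRL` (m), traffic load
#' `TL`/`TML`/`HTL` (vehicles day^-1 m), land-use class areas
#' `IND`/`HAR`/`RES` (m^2), population `POP` (inhabitants per cell).
#' Unbuffered predictors: inverse distance to all/major roads `IDC`/`IDM`
#' (m^-1) and the regional background estimates `BEO`/`BEX`/`BEP` (ug m^-3)
#' and `BEA` (1e-5 m^-1).
#'
#' @format Named character vector mapping predictor id to unit string.
#' @export
predictor_units <- c(
  RL = "m", MRL = "m",
  TL = "vehicles day-1 m", TML = "vehicles day-1 m", HTL = "vehicles day-1 m",
  IND = "m2", HAR = "m2", RES = "m2",
  POP = "inhabitants",
  IDC = "m-1", IDM = "m-1",
  BEO = "ug m-3", BEX = "ug m-3", BEP = "ug m-3", BEA = "1e-5 m-1")

set_predictor_meta <- function(raster, predictor_id) {
  attr(raster, "predictor_id") <- predictor_id
  attr(raster, "units") <- unname(predictor_units[predictor_id])
  raster
}

# Clip one segment to the grid extent and return the parameter interval
# [t0, t1] in which it lies inside (Liang-Barsky), or NULL if fully outside.
clip_segment_t <- function(x1, y1, dx, dy, ext) {
  t0 <- 0; t1 <- 1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - ext["x_min"], ext["x_max"] - x1, y1 - ext["y_min"], ext["y_max"] - y1)
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(NULL)
    } else {
      r <- q[k] / p[k]
      if (p[k] < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
      else          { if (r < t0) return(NULL); if (r < t1) t1 <- r }
    }
  }
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

ints_between <- function(a, b) {
  lo <- ceiling(a); hi <- floor(b)
  if (lo > hi) integer() else seq.int(lo, hi)
}

# Split a polyline into per-cell pieces; returns data.frame(row, col, length)
# of clipped lengths inside the grid extent. Exact rectangle intersection:
# the segment parameter is cut at every grid line crossing and each piece is
# assigned to the cell containing its midpoint.
segment_cell_lengths <- function(coords, spec) {
  ext <- grid_extent(spec)
  cs <- spec$cell_size
  out_r <- integer(); out_c <- integer(); out_l <- numeric()
  for (s in seq_len(nrow(coords) - 1L)) {
    x1 <- coords[s, 1]; y1 <- coords[s, 2]
    dx <- coords[s + 1L, 1] - x1; dy <- coords[s + 1L, 2] - y1
    L <- sqrt(dx^2 + dy^2)
    if (L == 0) next
    tt <- clip_segment_t(x1, y1, dx, dy, ext)
    if (is.null(tt)) next
    ts <- tt
    if (dx != 0) {
      jr <- range((c(x1 + tt[1] * dx, x1 + tt[2] * dx) - ext["x_min"]) / cs)
      j <- ints_between(jr[1], jr[2])
      j <- j[j >= 1 & j <= spec$n_cols - 1L]
      ts <- c(ts, (ext["x_min"] + j * cs - x1) / dx)
    }
    if (dy != 0) {
      ir <- range((ext["y_max"] - c(y1 + tt[1] * dy, y1 + tt[2] * dy)) / cs)
      i <- ints_between(ir[1], ir[2])
      i <- i[i >= 1 & i <= spec$n_rows - 1L]
      ts <- c(ts, (ext["y_max"] - i * cs - y1) / dy)
    }
    ts <- sort(unique(pmin(pmax(ts, tt[1]), tt[2])))
    if (length(ts) < 2L) next
    ta <- ts[-length(ts)]; tb <- ts[-1L]
    keep <- tb > ta
    ta <- ta[keep]; tb <- tb[keep]
    tm <- (ta + tb) / 2
    col <- as.integer(floor((x1 + tm * dx - ext["x_min"]) / cs)) + 1L
    row <- as.integer(floor((ext["y_max"] - (y1 + tm * dy)) / cs)) + 1L
    ok <- row >= 1L & row <= spec$n_rows & col >= 1L & col <= spec$n_cols
    out_r <- c(out_r, row[ok]); out_c <- c(out_c, col[ok])
    out_l <- c(out_l, (tb - ta)[ok] * L)
  }
  data.frame(row = out_r, col = out_c, length = out_l)
}

accumulate_cells <- function(spec, row, col, value) {
  m <- matrix(0, spec$n_rows, spec$n_cols)
  if (length(row)) {
    idx <- row + (col - 1L) * spec$n_rows
    agg <- rowsum(value, idx)
    m[as.integer(rownames(agg))] <- agg[, 1]
  }
  m
}

#' Rasterize road length per cell
#'
#' Each cell receives the total length (m) of the filtered road segments
#' clipped to the cell rectangle, by exact segment-rectangle intersection.
#' The sum over all cells equals the total network length inside the grid
#' extent. Cells without roads hold 0.
#'
#' @param roads A `road_network` from [read_roads()].
#' @param spec A [grid_spec()].
#' @param class_filter `"all"` (predictor `RL`) or `"major"` (`MRL`).
#' @return A `lur_raster` with predictor metadata attached.
#' @export
rasterize_line_length <- function(roads, spec, class_filter = c("all", "major")) {
  class_filter <- match.arg(class_filter)
  sel <- filter_roads(roads, class_filter)
  m <- matrix(0, spec$n_rows, spec$n_cols)
  for (g in sel$geometry) {
    pieces <- segment_cell_lengths(g, spec)
    m <- m + accumulate_cells(spec, pieces$row, pieces$col, pieces$length)
  }
  set_predictor_meta(new_raster(spec, m),
                     if (class_filter == "all") "RL" else "MRL")
}

#' Rasterize traffic load per cell
#'
#' Per cell, the sum over clipped segments of clipped length times the
#' segment's daily traffic intensity (vehicles day^-1 m). `TL` uses all
#' roads with total intensity, `TML` major roads with total intensity, and
#' `HTL` all roads with heavy-duty intensity. A filtered segment without the
#' required intensity attribute is an error (missing is not zero).
#'
#' @inheritParams rasterize_line_length
#' @param load `"TL"`, `"TML"` or `"HTL"`.
#' @return A `lur_raster` with predictor metadata attached.
#' @export
rasterize_traffic_load <- function(roads, spec, load = c("TL", "TML", "HTL")) {
  load <- match.arg(load)
  class_filter <- if (load == "TML") "major" else "all"
  field <- if (load == "HTL") "heavy_traffic_intensity" else "traffic_intensity"
  sel <- filter_roads(roads, class_filter)
  miss <- is.na(sel[[field]])
  if (any(miss))
    stop("segment(s) without '", field, "' needed for ", load, ": feature id(s) ",
         paste(unique(sel$feature_id[miss]), collapse = ", "))
  m <- matrix(0, spec$n_rows, spec$n_cols)
  for (k in seq_len(nrow(sel))) {
    pieces <- segment_cell_lengths(sel$geometry[[k]], spec)
    m <- m + accumulate_cells(spec, pieces$row, pieces$col,
                              pieces$length * sel[[field]][k])
  }
  set_predictor_meta(new_raster(spec, m), load)
}

# Logical matrix of cells whose centre lies inside the polygon (outer ring
# minus holes, even-odd rule; ring-boundary centres count as inside).
cells_in_rings <- function(rings, spec) {
  ext <- grid_extent(spec)
  cs <- spec$cell_size
  bb <- apply(do.call(rbind, rings), 2, range)
  c0 <- max(1L, as.integer(floor((bb[1, 1] - ext["x_min"]) / cs)) + 1L)
  c1 <- min(spec$n_cols, as.integer(floor((bb[2, 1] - ext["x_min"]) / cs)) + 1L)
  r0 <- max(1L, as.integer(floor((ext["y_max"] - bb[2, 2]) / cs)) + 1L)
  r1 <- min(spec$n_rows, as.integer(floor((ext["y_max"] - bb[1, 2]) / cs)) + 1L)
  if (c0 > c1 || r0 > r1)
    return(list(rows = integer(), cols = integer()))
  rows <- r0:r1; cols <- c0:c1
  px <- ext["x_min"] + (rep(cols, each = length(rows)) - 0.5) * cs
  py <- ext["y_max"] - (rep(rows, times = length(cols)) - 0.5) * cs
  parity <- integer(length(px))
  for (ring in rings) {
    inside <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0
    parity <- parity + as.integer(inside)
  }
  keep <- parity %% 2L == 1L
  list(rows = rep(rows, times = length(cols))[keep],
       cols = rep(cols, each = length(rows))[keep])
}

#' Rasterize land-use class area per cell
#'
#' A cell holds the full cell area (`cell_size^2`, i.e. 25 m^2 at 5 m cells)
#' when its centre falls inside any polygon of the target class, else 0 --
#' cell-centre membership, not fractional coverage.
#'
#' @param landuse A `landuse_layer` from [read_landuse()] (already
#'   reclassified).
#' @param spec A [grid_spec()].
#' @param target_class `"IND"`, `"HAR"` or `"RES"`.
#' @return A `lur_raster` with predictor metadata attached.
#' @export
rasterize_class_area <- function(landuse, spec,
                                 target_class = c("IND", "HAR", "RES")) {
  target_class <- match.arg(target_class)
  m <- matrix(0, spec$n_rows, spec$n_cols)
  sel <- landuse[landuse$class == target_class, ]
  for (rings in sel$rings) {
    cc <- cells_in_rings(rings, spec)
    m[cbind(cc$rows, cc$cols)] <- spec$cell_size^2
  }
  set_predictor_meta(new_raster(spec, m), target_class)
}

#' Rasterize population counts per cell
#'
#' Each polygon's inhabitant count is spread uniformly over the cells whose
#' centre it covers; the cell value is the number of inhabitants in that
#' cell, so the raster total conserves the layer total (up to polygons that
#' cover no cell centre, which are reported in a warning).
#'
#' @param pop A `population_layer` from [read_population()].
#' @param spec A [grid_spec()].
#' @return A `lur_raster` with predictor metadata attached.
#' @export
rasterize_population <- function(pop, spec) {
  m <- matrix(0, spec$n_rows, spec$n_cols)
  lost <- 0
  for (k in seq_len(nrow(pop))) {
    cc <- cells_in_rings(pop$rings[[k]], spec)
    n <- length(cc$rows)
    if (n == 0L) { lost <- lost + pop$count[k]; next }
    idx <- cbind(cc$rows, cc$cols)
    m[idx] <- m[idx] + pop$count[k] / n
  }
  if (lost > 0)
    warning(lost, " inhabitants in polygon(s) covering no cell centre were dropped")
  set_predictor_meta(new_raster(spec, m), "POP")
}
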