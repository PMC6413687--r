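#' Distance from every cell centre to the nearest road
#'
#' Exact Euclidean point-to-polyline distance from the cell centre
#' coordinate to the closest segment of the (filtered) network -- measured
#' against the vector geometry, not against rasterized roads.
#'
#' @param roads A `road_network`.
#' @param spec A [grid_spec()].
#' @param class_filter `"all"` or `"major"`.
#' @return A `lur_raster` of distances (m).
#' @export
distance_to_network <- function(roads, spec, class_filter = c("all", "major")) {
  class_filter <- match.arg(class_filter)
  sel <- filter_roads(roads, class_filter)
  if (nrow(sel) == 0L)
    stop("no '", class_filter, "' road segments to measure distances to")
  segs <- do.call(rbind, lapply(sel$geometry, function(g) {
    n <- nrow(g)
    cbind(g[-n, 1], g[-n, 2], g[-1, 1], g[-1, 2])
  }))
  cs <- spec$cell_size
  px <- rep(spec$x_min + (seq_len(spec$n_cols) - 0.5) * cs, each = spec$n_rows)
  py <- rep(spec$y_max - (seq_len(spec$n_rows) - 0.5) * cs, times = spec$n_cols)
  d <- min_dist_point_segments_cpp(px, py, segs[, 1], segs[, 2],
                                   segs[, 3], segs[, 4])
  out <- new_raster(spec, matrix(d, spec$n_rows, spec$n_cols))
  attr(out, "network_filter") <- class_filter
  out
}

#' Inverse distance to the nearest road
#'
#' `1 / max(distance, d_min)`: the clamp bounds the value for cells lying on
#' or very near a road, where the raw inverse distance would diverge. The
#' default clamp of half a cell size (2.5 m at 5 m cells) caps the predictor
#' at `1/d_min` on-road.
#'
#' @param dist A distance raster from [distance_to_network()].
#' @param d_min Clamp distance (m), > 0; default `cell_size / 2`.
#' @return A `lur_raster` of inverse distances (m^-1) with predictor id
#'   `IDC` (all roads) or `IDM` (major roads).
#' @export
inverse_distance <- function(dist, d_min = dist$spec$cell_size / 2) {
  stopifnot(inherits(dist, "lur_raster"))
  if (!is.numeric(d_min) || length(d_min) != 1L || d_min <= 0)
    stop("`d_min` must be a single positive number (metres)")
  out <- new_raster(dist$spec, 1 / pmax(dist$values, d_min), dist$nodata)
  filt <- attr(dist, "network_filter")
  if (!is.null(filt))
    out <- set_predictor_meta(out, if (filt == "major") "IDM" else "IDC")
  out
}
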