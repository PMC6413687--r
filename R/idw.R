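#' Inverse-distance-weighted regional background surface
#'
#' Interpolates station measurements onto the grid with weights
#' `d^(-power)` over the stations within `radius` of each cell centre
#' (default search radius 100 km, exponent 2). A cell whose centre
#' coincides with a station location (closer than `cell_size / 100`) takes
#' that station's value exactly; cells with no station within the search
#' radius are `NA`. The result is convex: every defined cell lies within
#' the range of the contributing station values.
#'
#' These surfaces serve as the regional background predictors `BEO` (NO2),
#' `BEX` (NOx), `BEP` (PM2.5) and `BEA` (PM2.5 absorbance). The PM10 model
#' has no background term.
#'
#' @param stations A `station_set` (at least one station).
#' @param spec A [grid_spec()].
#' @param radius Search radius (m), default 100 000.
#' @param power IDW exponent, default 2.
#' @param predictor_id Optional background id (`"BEO"`, `"BEX"`, `"BEP"`,
#'   `"BEA"`) attached as predictor metadata.
#' @return A `lur_raster`.
#' @export
idw_interpolate <- function(stations, spec, radius = 100000, power = 2,
                            predictor_id = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.data.frame(stations) || nrow(stations) == 0L)
    stop("`stations` must hold at least one station")
  if (radius <= 0) stop("`radius` must be > 0")
  if (power <= 0) stop("`power` must be > 0")
  if (!is.null(predictor_id) &&
      !predictor_id %in% c("BEO", "BEX", "BEP", "BEA"))
    stop("unknown background predictor '", predictor_id,
         "' (PM10 has no regional background term)")
  v <- idw_grid_cpp(spec$n_rows, spec$n_cols, spec$x_min, spec$y_max,
                    spec$cell_size, stations$x, stations$y, stations$value,
                    radius, power, spec$cell_size / 100)
  out <- new_raster(spec, v)
  if (!is.null(predictor_id)) out <- set_predictor_meta(out, predictor_id)
  out
}
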