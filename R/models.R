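unbuffered_predictors <- c("BEO", "BEX", "BEP", "BEA", "IDC", "IDM")
buffered_predictors <- c("RL", "MRL", "TL", "TML", "HTL", "IND", "HAR",
                         "RES", "POP")

#' A single LUR model term
#'
#' A term is `coefficient * predictor`, where the predictor is either an
#' unbuffered surface (`IDC`, `IDM` or a regional background `BEO`/`BEX`/
#' `BEP`/`BEA`), a circular-buffer sum (`buffer = radius` in metres), or an
#' annulus sum (`buffer = c(r_inner, r_outer)`).
#'
#' @param predictor Predictor id (see [predictor_units]).
#' @param coefficient Finite numeric weight, in output units per predictor
#'   unit.
#' @param buffer `NULL` for unbuffered predictors, a single radius (m), or
#'   a length-2 annulus `c(r_inner, r_outer)`.
#' @return A `lur_term`.
#' @export
lur_term <- function(predictor, coefficient, buffer = NULL) {
  if (!predictor %in% names(predictor_units))
    stop("unknown predictor '", predictor, "'")
  if (!is.finite(coefficient)) stop("coefficient must be finite")
  if (is.null(buffer)) {
    if (!predictor %in% unbuffered_predictors)
      stop("predictor '", predictor, "' requires a buffer radius")
  } else {
    if (!predictor %in% buffered_predictors)
      stop("predictor '", predictor, "' takes no buffer")
    buffer <- as.numeric(buffer)
    if (!length(buffer) %in% 1:2 || any(buffer < 0))
      stop("buffer must be one radius or c(r_inner, r_outer), in metres")
    if (length(buffer) == 2L && buffer[1] >= buffer[2])
      stop("annulus needs r_inner < r_outer")
  }
  structure(list(predictor = predictor, coefficient = as.numeric(coefficient),
                 buffer = buffer), class = "lur_term")
}

term_key <- function(term) {
  if (is.null(term$buffer)) term$predictor
  else paste0(term$predictor, "_", paste(format(term$buffer, scientific = FALSE,
                                                trim = TRUE), collapse = "-"))
}

term_type <- function(term) {
  if (is.null(term$buffer)) "none"
  else if (length(term$buffer) == 1L) "buffer" else "annulus"
}

#' A land use regression model
#'
#' A linear model `intercept + sum(coefficient_j * predictor_j)` evaluated
#' per raster cell. Output units are fixed by the pollutant: `10^-5 m^-1`
#' for PM2.5 absorbance, `ug m^-3` for all others.
#'
#' @param pollutant One of `"NO2"`, `"NO2background"`, `"NOx"`, `"PM25"`,
#'   `"PM25absorbance"`, `"PM10"`, or a custom label.
#' @param intercept Model intercept, in output units.
#' @param terms List of [lur_term()] objects.
#' @param output_units Output unit string; defaults from the pollutant.
#' @return A `lur_model`.
#' @export
lur_model <- function(pollutant, intercept, terms,
                      output_units = if (identical(pollutant, "PM25absorbance"))
                        "1e-5 m-1" else "ug m-3") {
  if (!is.finite(intercept)) stop("intercept must be finite")
  if (!length(terms) || !all(vapply(terms, inherits, logical(1), "lur_term")))
    stop("`terms` must be a non-empty list of lur_term objects")
  structure(list(pollutant = pollutant, intercept = as.numeric(intercept),
                 terms = terms, output_units = output_units),
            class = "lur_model")
}

#' @export
print.lur_model <- function(x, ...) {
  rhs <- vapply(x$terms, function(t)
    sprintf("%g*%s", t$coefficient, term_key(t)), character(1))
  cat(sprintf("<lur_model> %s [%s] = %g + %s\n", x$pollutant, x$output_units,
              x$intercept, paste(rhs, collapse = " + ")))
  invisible(x)
}

model_terms_table <- function(model) {
  data.frame(
    predictor = vapply(model$terms, `[[`, character(1), "predictor"),
    type = vapply(model$terms, term_type, character(1)),
    r1 = vapply(model$terms, function(t)
      if (length(t$buffer) == 2L) t$buffer[1] else NA_real_, numeric(1)),
    r2 = vapply(model$terms, function(t)
      if (is.null(t$buffer)) NA_real_ else t$buffer[length(t$buffer)], numeric(1)),
    key = vapply(model$terms, term_key, character(1)),
    stringsAsFactors = FALSE)
}

#' The six built-in Dutch ESCAPE LUR models
#'
#' The registry of annual-average (2009) concentration models for the
#' Netherlands: NO2, NO2 background, NOx, PM2.5, PM2.5 absorbance and PM10,
#' with regional background estimates, traffic, road-length, land-use and
#' population predictors in circular buffers from 25 m to 5000 m. PM2.5
#' absorbance is in 10^-5 m^-1, all other pollutants in ug m^-3; the PM10
#' model carries no regional background term.
#'
#' @return Named list of six [lur_model()] objects.
#' @examples
#' names(builtin_models())
#' @export
builtin_models <- function() {
  list(
    NO2 = lur_model("NO2", -7.8, list(
      lur_term("BEO", 1.18),
      lur_term("POP", 2.3e-05, 5000),
      lur_term("TL", 2.47e-06, 50),
      lur_term("RL", 1.06e-4, 1000),
      lur_term("HTL", 9.84e-05, 25),
      lur_term("IDC", 12.19),
      lur_term("HTL", 4.47e-07, c(25, 500)))),
    NO2background = lur_model("NO2background", 3.21, list(
      lur_term("BEO", 0.74),
      lur_term("POP", 2.29e-05, 5000),
      lur_term("IND", 6.4e-07, 5000),
      lur_term("HAR", 4.72e-07, 5000))),
    NOx = lur_model("NOx", 3.25, list(
      lur_term("BEX", 0.74),
      lur_term("TL", 4.22e-06, 50),
      lur_term("POP", 6.36e-04, 1000),
      lur_term("HTL", 2.39e-06, 500),
      lur_term("IDM", 71.65),
      lur_term("MRL", 0.21, 25))),
    PM25 = lur_model("PM25", 9.46, list(
      lur_term("BEP", 0.42),
      lur_term("MRL", 0.014, 50),
      lur_term("TML", 2.28e-09, 1000))),
    PM25absorbance = lur_model("PM25absorbance", 0.07, list(
      lur_term("TL", 2.95e-09, 500),
      lur_term("MRL", 0.0029, 50),
      lur_term("BEA", 0.85),
      lur_term("RES", 7.90e-09, 5000),
      lur_term("HTL", 1.72e-06, 50))),
    PM10 = lur_model("PM10", 23.71, list(
      lur_term("TML", 2.16e-08, 500),
      lur_term("POP", 6.68e-06, 5000),
      lur_term("MRL", 0.015, 50))))
}

#' Serialize LUR models to and from JSON
#'
#' Models are data, not code: the JSON form
#' `{"pollutant": ..., "output_units": ..., "intercept": ...,`
#' `"terms": [{"predictor": ..., "buffer": radius | [r_in, r_out] | null,`
#' `"coefficient": ...}]}` round-trips exactly and lets users supply their
#' own models with the same term vocabulary.
#'
#' @param model A [lur_model()].
#' @param path JSON file path.
#' @return `read_model` returns a `lur_model`; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lur_model"))
  obj <- list(pollutant = model$pollutant, output_units = model$output_units,
              intercept = model$intercept,
              terms = lapply(model$terms, function(t)
                list(predictor = t$predictor, buffer = t$buffer,
                     coefficient = t$coefficient)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- lapply(obj$terms, function(t)
    lur_term(t$predictor, as.numeric(t$coefficient),
             if (is.null(t$buffer)) NULL else as.numeric(unlist(t$buffer))))
  lur_model(obj$pollutant, as.numeric(obj$intercept), terms,
            output_units = obj$output_units)
}

#' Evaluate a LUR model over a predictor stack
#'
#' Per-cell map algebra: `intercept + sum(coefficient * predictor)`. Every
#' term's raster must be present in the stack under its term key (e.g.
#' `"POP_5000"`, `"HTL_25-500"`, `"IDC"`) and share the model grid. A cell
#' that is `NA` in any term is `NA` in the output. Negative predicted
#' concentrations are not clipped by default (the count is available via
#' [summary()]); pass `clip_zero = TRUE` to truncate at 0.
#'
#' @param model A [lur_model()].
#' @param stack Named list of rasters, e.g. from
#'   [compute_predictor_stack()].
#' @param clip_zero Truncate negative predictions to 0? Default `FALSE`.
#' @return A `lur_raster` of concentrations in the model's output units.
#' @export
evaluate_model <- function(model, stack, clip_zero = FALSE) {
  stopifnot(inherits(model, "lur_model"))
  spec <- NULL
  acc <- NULL
  for (t in model$terms) {
    key <- term_key(t)
    r <- stack[[key]]
    if (is.null(r))
      stop("predictor stack is missing term '", key, "' for the ",
           model$pollutant, " model")
    if (is.null(spec)) {
      spec <- r$spec
      acc <- matrix(model$intercept, spec$n_rows, spec$n_cols)
    } else if (!same_spec(spec, r$spec)) {
      stop("term '", key, "' is on a different grid than the other terms")
    }
    u <- attr(r, "units")
    if (!is.null(u) && !identical(u, unname(predictor_units[t$predictor])))
      stop("term '", key, "' has units '", u, "' but predictor ",
           t$predictor, " requires '", predictor_units[t$predictor], "'")
    acc <- acc + t$coefficient * r$values
  }
  if (clip_zero) acc <- pmax(acc, 0)
  out <- new_raster(spec, acc)
  attr(out, "pollutant") <- model$pollutant
  attr(out, "units") <- model$output_units
  out
}

#' Summary of a raster's values
#'
#' Reports cell counts (including `NA` and negative cells -- negative
#' predicted concentrations are never clipped silently) and the value range.
#' @param object A `lur_raster`.
#' @param ... Unused.
#' @method summary lur_raster
#' @export
summary.lur_raster <- function(object, ...) {
  v <- object$values
  ok <- !is.na(v)
  res <- list(n_cells = length(v), n_na = sum(!ok),
              n_negative = sum(v[ok] < 0),
              min = if (any(ok)) min(v[ok]) else NA_real_,
              mean = if (any(ok)) mean(v[ok]) else NA_real_,
              max = if (any(ok)) max(v[ok]) else NA_real_)
  class(res) <- "summary.lur_raster"
  res
}

#' @export
print.summary.lur_raster <- function(x, ...) {
  cat(sprintf("cells: %d (NA: %d, negative: %d)  min/mean/max: %g / %g / %g\n",
              x$n_cells, x$n_na, x$n_negative, x$min, x$mean, x$max))
  invisible(x)
}

#' Extract concentration values at point locations
#'
#' Returns the value of the raster cell containing each point (the surface
#' is cell-constant; no sub-cell interpolation). Points outside the grid
#' extent are flagged with `inside = FALSE` and an `NA` value rather than
#' dropped.
#'
#' @param raster A concentration (or any) `lur_raster`.
#' @param x,y Point coordinates (m).
#' @return A tibble with columns `x`, `y`, `inside`, `value`.
#' @export
extract_at_points <- function(raster, x, y) {
  stopifnot(inherits(raster, "lur_raster"))
  ext <- grid_extent(raster$spec)
  inside <- x >= ext["x_min"] & x < ext["x_max"] &
            y > ext["y_min"] & y <= ext["y_max"]
  val <- rep(NA_real_, length(x))
  if (any(inside)) {
    rc <- point_to_cell(raster$spec, x[inside], y[inside])
    rc <- matrix(rc, ncol = 2)
    val[inside] <- raster$values[rc]
  }
  tibble(x = x, y = y, inside = inside, value = val)
}

#' Evaluate a model and read it off at points
#'
#' Convenience wrapper: [evaluate_model()] then [extract_at_points()].
#' @inheritParams evaluate_model
#' @param x,y Point coordinates (m).
#' @export
evaluate_at_points <- function(model, stack, x, y, clip_zero = FALSE) {
  extract_at_points(evaluate_model(model, stack, clip_zero = clip_zero), x, y)
}

#' Coarse particulate matter as PM10 minus PM2.5
#'
#' Cellwise difference of the PM10 and PM2.5 surfaces. Values may be
#' negative where the two models disagree; they are reported as-is (check
#' `summary()$n_negative`). `NA` in either input propagates.
#'
#' @param pm10,pm25 `lur_raster` objects on the same grid.
#' @return A `lur_raster` of PMcoarse concentrations (ug m^-3).
#' @export
derive_pm_coarse <- function(pm10, pm25) {
  raster_check_pair(pm10, pm25, "PM10 and PM2.5 rasters")
  out <- new_raster(pm10$spec, pm10$values - pm25$values, pm10$nodata)
  attr(out, "pollutant") <- "PMcoarse"
  attr(out, "units") <- "ug m-3"
  out
}
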