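#' @importFrom tibble tibble as_tibble
NULL

# ---- GeoJSON helpers (coordinates are taken as-is: already projected, metres)

gj_read <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop(path, " is not a GeoJSON FeatureCollection")
  gj
}

gj_coords_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  colnames(m) <- c("x", "y")
  m
}

gj_prop <- function(feat, name) {
  p <- feat$properties[[name]]
  if (is.null(p)) NA else p
}

#' Read a road network from GeoJSON
#'
#' Features must carry `LineString` (or `MultiLineString`) geometries. Each
#' feature is one road polyline; `MultiLineString` parts become separate
#' polylines sharing the feature's attributes. The class attribute must take
#' values `"major"` or `"minor"`; traffic intensity attributes, when present,
#' are average daily counts (vehicles day^-1). A missing intensity is kept as
#' `NA`, never silently treated as zero: traffic-load predictors require it
#' and fail loudly when absent.
#'
#' @param path GeoJSON file with line features.
#' @param class_field Property name holding the road class
#'   (default `"road_class"`).
#' @param intensity_field,heavy_intensity_field Property names for total and
#'   heavy-duty daily traffic intensity.
#' @return A `road_network`: a tibble with columns `feature_id`, `road_class`,
#'   `traffic_intensity`, `heavy_traffic_intensity` and a list-column
#'   `geometry` of two-column coordinate matrices.
#' @export
read_roads <- function(path, class_field = "road_class",
                       intensity_field = "traffic_intensity",
                       heavy_intensity_field = "heavy_traffic_intensity") {
  gj <- gj_read(path)
  rows <- list()
  bad_geom <- character(); bad_class <- character(); bad_int <- character()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- f$id %||% gj_prop(f, "id")
    id <- if (is.null(id) || is.na(id)) as.character(k) else as.character(id)
    gtype <- f$geometry$type
    parts <- if (identical(gtype, "LineString")) list(f$geometry$coordinates)
             else if (identical(gtype, "MultiLineString")) f$geometry$coordinates
             else { bad_geom <- c(bad_geom, id); next }
    cls <- gj_prop(f, class_field)
    if (is.na(cls) || !cls %in% c("major", "minor")) {
      bad_class <- c(bad_class, id); next
    }
    ti <- suppressWarnings(as.numeric(gj_prop(f, intensity_field)))
    hi <- suppressWarnings(as.numeric(gj_prop(f, heavy_intensity_field)))
    if ((!is.na(ti) && ti < 0) || (!is.na(hi) && hi < 0)) {
      bad_int <- c(bad_int, id); next
    }
    for (p in parts) {
      m <- gj_coords_matrix(p)
      if (nrow(m) < 2L) { bad_geom <- c(bad_geom, id); next }
      rows[[length(rows) + 1L]] <- list(feature_id = id, road_class = cls,
                                        traffic_intensity = ti,
                                        heavy_traffic_intensity = hi,
                                        geometry = m)
    }
  }
  if (length(bad_geom))
    stop("non-line or degenerate geometry for feature id(s): ",
         paste(unique(bad_geom), collapse = ", "))
  if (length(bad_class))
    stop("unknown or missing road class (expected 'major'/'minor') for feature id(s): ",
         paste(unique(bad_class), collapse = ", "))
  if (length(bad_int))
    stop("negative traffic intensity for feature id(s): ",
         paste(unique(bad_int), collapse = ", "))
  net <- tibble(
    feature_id = vapply(rows, `[[`, character(1), "feature_id"),
    road_class = vapply(rows, `[[`, character(1), "road_class"),
    traffic_intensity = vapply(rows, `[[`, numeric(1), "traffic_intensity"),
    heavy_traffic_intensity = vapply(rows, `[[`, numeric(1), "heavy_traffic_intensity"),
    geometry = lapply(rows, `[[`, "geometry"))
  class(net) <- c("road_network", class(net))
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter a road network by class
#'
#' `"all"` keeps every segment; `"major"` keeps the major-road subset.
#' @param roads A `road_network`.
#' @param class_filter `"all"` or `"major"`.
#' @export
filter_roads <- function(roads, class_filter = c("all", "major")) {
  class_filter <- match.arg(class_filter)
  if (class_filter == "all") roads else roads[roads$road_class == "major", ]
}

read_polygon_features <- function(path, prop_fields) {
  gj <- gj_read(path)
  rows <- list()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    gtype <- f$geometry$type
    polys <- if (identical(gtype, "Polygon")) list(f$geometry$coordinates)
             else if (identical(gtype, "MultiPolygon")) f$geometry$coordinates
             else stop("feature ", k, " in ", path, " is not a polygon (", gtype, ")")
    props <- lapply(prop_fields, function(p) gj_prop(f, p))
    names(props) <- prop_fields
    for (poly in polys) {
      rings <- lapply(poly, gj_coords_matrix)
      rows[[length(rows) + 1L]] <- c(props, list(rings = rings))
    }
  }
  rows
}

#' Read a reclassification table
#'
#' Two-column CSV `source_class,target_class` mapping source land-use codes
#' onto the predictor classes `IND`, `HAR`, `RES` or `other`.
#' @param path CSV path.
#' @return Named character vector: `reclass[source] -> target`.
#' @export
read_reclass <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("source_class", "target_class") %in% names(tab)))
    stop("reclass table needs columns source_class, target_class")
  if (anyDuplicated(tab$source_class))
    stop("reclass table maps source class(es) more than once: ",
         paste(unique(tab$source_class[duplicated(tab$source_class)]), collapse = ", "))
  bad <- setdiff(unique(tab$target_class), c("IND", "HAR", "RES", "other"))
  if (length(bad))
    stop("unknown target class(es): ", paste(bad, collapse = ", "))
  stats::setNames(tab$target_class, tab$source_class)
}

#' Read a land-use polygon layer from GeoJSON
#'
#' Each feature carries a source class code in `class_field`; the reclass
#' table maps codes to the predictor classes `IND`/`HAR`/`RES`/`other`.
#' Codes absent from the table are an error (silent gaps would bias the
#' class-area predictors).
#'
#' @param path GeoJSON file with polygon features.
#' @param reclass Named vector from [read_reclass()], or `NULL` to use the
#'   codes as-is (they must then already be `IND`/`HAR`/`RES`/`other`).
#' @param class_field Property holding the source class code.
#' @return A `landuse_layer` tibble with columns `class_src`, `class` and
#'   list-column `rings` (outer ring first, holes after).
#' @export
read_landuse <- function(path, reclass = NULL, class_field = "landuse") {
  feats <- read_polygon_features(path, class_field)
  src <- vapply(feats, function(f) as.character(f[[class_field]]), character(1))
  if (is.null(reclass)) {
    tgt <- src
    bad <- setdiff(unique(src), c("IND", "HAR", "RES", "other"))
    if (length(bad))
      stop("no reclass table given and source class(es) not already ",
           "IND/HAR/RES/other: ", paste(bad, collapse = ", "))
  } else {
    bad <- setdiff(unique(src), names(reclass))
    if (length(bad))
      stop("source class(es) missing from the reclass table: ",
           paste(bad, collapse = ", "))
    tgt <- unname(reclass[src])
  }
  lu <- tibble(class_src = src, class = tgt,
               rings = lapply(feats, `[[`, "rings"))
  class(lu) <- c("landuse_layer", class(lu))
  lu
}

#' Read a population layer from GeoJSON
#'
#' Polygon features with a non-negative inhabitant count property.
#' @param path GeoJSON file.
#' @param count_field Property holding the inhabitant count.
#' @return A `population_layer` tibble with columns `count` and `rings`.
#' @export
read_population <- function(path, count_field = "population") {
  feats <- read_polygon_features(path, count_field)
  cnt <- vapply(feats, function(f) as.numeric(f[[count_field]]), numeric(1))
  if (anyNA(cnt)) stop("population feature(s) without a '", count_field, "' count")
  if (any(cnt < 0)) stop("negative population count(s)")
  pop <- tibble(count = cnt, rings = lapply(feats, `[[`, "rings"))
  class(pop) <- c("population_layer", class(pop))
  pop
}

#' Read monitoring stations from CSV
#'
#' Expects header columns `id`, `x`, `y` and one or more value columns.
#' Rows whose selected value is missing are dropped with a message reporting
#' the count; duplicate station ids are an error.
#'
#' @param path CSV path.
#' @param value_col Name of the value column to use (default `"value"`).
#' @return A `station_set` tibble with columns `id`, `x`, `y`, `value` and,
#'   when present in the file, `site_type`.
#' @export
read_stations <- function(path, value_col = "value") {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", value_col)
  if (!all(need %in% names(tab)))
    stop("station CSV needs columns ", paste(need, collapse = ", "))
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop("duplicate station id(s): ", paste(dup, collapse = ", "))
  miss <- is.na(tab[[value_col]])
  if (any(miss))
    message(sum(miss), " station row(s) dropped for missing '", value_col, "'")
  tab <- tab[!miss, , drop = FALSE]
  st <- tibble(id = as.character(tab$id), x = as.numeric(tab$x),
               y = as.numeric(tab$y), value = as.numeric(tab[[value_col]]))
  if ("site_type" %in% names(tab)) st$site_type <- tab$site_type
  class(st) <- c("station_set", class(st))
  st
}

#' Construct a station set in code
#'
#' @param id,x,y,value Equal-length vectors of station id, coordinates (m)
#'   and measured value.
#' @param site_type Optional site classification.
#' @export
station_set <- function(id, x, y, value, site_type = NULL) {
  if (anyDuplicated(id)) stop("duplicate station id(s)")
  st <- tibble(id = as.character(id), x = as.numeric(x), y = as.numeric(y),
               value = as.numeric(value))
  if (!is.null(site_type)) st$site_type <- site_type
  class(st) <- c("station_set", class(st))
  st
}
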