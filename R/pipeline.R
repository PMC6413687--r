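background_pollutants <- c(BEO = "BEO", BEX = "BEX", BEP = "BEP", BEA = "BEA")

#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration driving
#' [run_pipeline()]. All method constants are inspectable defaults: IDW
#' search radius 100 km with exponent 2, inverse-distance clamp of half a
#' cell (2.5 m at 5 m cells), 5 m cells.
#'
#' @param grid Named list or `grid_spec` with `x_min`, `y_max`, `cell_size`,
#'   `n_rows`, `n_cols` and optional `crs`.
#' @param roads,landuse,population,stations,reclass Input file paths
#'   (GeoJSON / CSV); any not needed by the requested models may be `NULL`.
#' @param models Character vector of built-in model names (see
#'   [builtin_models()]) and/or paths to model JSON files.
#' @param out_dir Output directory for all rasters and the manifest.
#' @param idw_radius,idw_power IDW background parameters (m; exponent).
#' @param dist_clamp Inverse-distance clamp `d_min` (m); default half the
#'   cell size.
#' @param tile_size Optional focal tile edge (cells); tiled output is
#'   bit-identical to untiled.
#' @param clip_zero Truncate negative predicted concentrations to 0?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid, roads = NULL, landuse = NULL,
                            population = NULL, stations = NULL,
                            reclass = NULL, models = names(builtin_models()),
                            out_dir = "lurmap_out",
                            idw_radius = 100000, idw_power = 2,
                            dist_clamp = NULL, tile_size = NULL,
                            clip_zero = FALSE) {
  spec <- if (inherits(grid, "grid_spec")) grid
          else grid_spec(grid$x_min, grid$y_max, grid$cell_size,
                         grid$n_rows, grid$n_cols,
                         grid$crs %||% "EPSG:28992")
  structure(list(spec = spec,
                 inputs = list(roads = roads, landuse = landuse,
                               population = population, stations = stations,
                               reclass = reclass),
                 models = models, out_dir = out_dir,
                 idw_radius = idw_radius, idw_power = idw_power,
                 dist_clamp = dist_clamp %||% (spec$cell_size / 2),
                 tile_size = tile_size, clip_zero = clip_zero),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same fields (`grid:` as a mapping,
#'   `inputs:` as a mapping of paths, remaining keys at top level).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(grid = y$grid,
                  roads = y$inputs$roads, landuse = y$inputs$landuse,
                  population = y$inputs$population,
                  stations = y$inputs$stations, reclass = y$inputs$reclass,
                  models = unlist(y$models) %||% names(builtin_models()),
                  out_dir = y$out_dir %||% "lurmap_out",
                  idw_radius = y$idw_radius %||% 100000,
                  idw_power = y$idw_power %||% 2,
                  dist_clamp = y$dist_clamp,
                  tile_size = y$tile_size,
                  clip_zero = isTRUE(y$clip_zero))
}

resolve_models <- function(names_or_paths) {
  reg <- builtin_models()
  models <- list()
  for (m in names_or_paths) {
    if (m %in% names(reg)) models[[m]] <- reg[[m]]
    else if (file.exists(m)) {
      mod <- read_model(m)
      models[[mod$pollutant]] <- mod
    } else stop("model '", m, "' is neither a built-in name (",
                paste(names(reg), collapse = ", "), ") nor a file")
  }
  models
}

#' Run the full mapping pipeline
#'
#' Orchestrates rasterize -> circular buffers -> road distances -> IDW
#' backgrounds -> model evaluation for the requested models, computing only
#' the base rasters and buffered predictors those models need (each distinct
#' predictor once). Every produced raster is written to `out_dir` as an
#' ASCII grid, and `manifest.csv` records each file with its stage and
#' parameters. Re-running with identical inputs reproduces identical files;
#' `tile_size` changes memory use, never values.
#'
#' @param config A [pipeline_config()] (or a path to a YAML config).
#' @param scene Optionally, an in-memory scene from [generate_scene()] used
#'   in place of the configured input files.
#' @return Invisibly, a list with `manifest` (tibble), `stack` (the named
#'   predictor-raster list) and `concentrations` (named list of
#'   `lur_raster`s per pollutant).
#' @export
run_pipeline <- function(config, scene = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- resolve_models(config$models)
  terms <- unique(do.call(rbind, lapply(models, model_terms_table)))
  manifest <- list()
  note <- function(file, stage, params = "") {
    manifest[[length(manifest) + 1L]] <<-
      tibble(file = file, stage = stage, params = params)
  }
  emit <- function(raster, name, stage, params = "") {
    file <- paste0(name, ".asc")
    write_raster(raster, file.path(config$out_dir, file))
    # the manifest records paths relative to out_dir so that identical runs
    # in different directories produce byte-identical manifests
    note(file, stage, params)
    raster
  }
  stage_input <- function(what) {
    p <- config$inputs[[what]]
    if (is.null(p))
      stop("stage 'inputs': the requested models need a '", what,
           "' input but none is configured")
    if (!file.exists(p))
      stop("stage 'inputs': ", what, " file not found: ", p)
    p
  }

  base_needed <- unique(terms$predictor[terms$type != "none"])
  flat <- terms$predictor[terms$type == "none"]
  need_roads <- length(intersect(c("RL", "MRL", "TL", "TML", "HTL"),
                                 base_needed)) > 0 ||
                length(intersect(c("IDC", "IDM"), flat)) > 0

  roads <- if (!is.null(scene)) scene$roads
           else if (need_roads) read_roads(stage_input("roads")) else NULL
  landuse <- if (!is.null(scene)) scene$landuse
             else if (length(intersect(c("IND", "HAR", "RES"), base_needed)))
               read_landuse(stage_input("landuse"),
                            read_reclass(stage_input("reclass")))
             else NULL
  population <- if (!is.null(scene)) scene$population
                else if ("POP" %in% base_needed)
                  read_population(stage_input("population"))
                else NULL

  base <- list()
  for (pid in base_needed) {
    base[[pid]] <- switch(pid,
      RL = rasterize_line_length(roads, spec, "all"),
      MRL = rasterize_line_length(roads, spec, "major"),
      TL = rasterize_traffic_load(roads, spec, "TL"),
      TML = rasterize_traffic_load(roads, spec, "TML"),
      HTL = rasterize_traffic_load(roads, spec, "HTL"),
      IND = rasterize_class_area(landuse, spec, "IND"),
      HAR = rasterize_class_area(landuse, spec, "HAR"),
      RES = rasterize_class_area(landuse, spec, "RES"),
      POP = rasterize_population(population, spec),
      stop("stage 'rasterize': no rule for base predictor '", pid, "'"))
    emit(base[[pid]], pid, "rasterize")
  }

  for (filt in c("all", "major")) {
    id <- if (filt == "all") "IDC" else "IDM"
    if (!id %in% flat) next
    d <- distance_to_network(roads, spec, filt)
    emit(d, paste0("dist_", filt), "distance")
    base[[id]] <- inverse_distance(d, config$dist_clamp)
    emit(base[[id]], id, "distance",
         sprintf("d_min=%g", config$dist_clamp))
  }

  bg_needed <- intersect(names(background_pollutants), flat)
  if (length(bg_needed)) {
    spath <- if (is.null(scene)) stage_input("stations") else NULL
    for (bg in bg_needed) {
      st <- if (!is.null(scene)) {
        if (!bg %in% names(scene$stations))
          stop("stage 'background': scene stations lack a '", bg, "' column")
        station_set(scene$stations$id, scene$stations$x, scene$stations$y,
                    scene$stations[[bg]])
      } else read_stations(spath, value_col = bg)
      base[[bg]] <- idw_interpolate(st, spec, radius = config$idw_radius,
                                    power = config$idw_power,
                                    predictor_id = bg)
      emit(base[[bg]], bg, "background",
           sprintf("radius=%g power=%g n_stations=%d",
                   config$idw_radius, config$idw_power, nrow(st)))
    }
  }

  stack <- compute_predictor_stack(base, models, tile_size = config$tile_size)
  for (key in setdiff(names(stack), names(base)))
    emit(stack[[key]], key, "buffers",
         if (is.null(config$tile_size)) "" else
           sprintf("tile_size=%d", config$tile_size))

  concentrations <- list()
  for (nm in names(models)) {
    concentrations[[nm]] <- evaluate_model(models[[nm]], stack,
                                           clip_zero = config$clip_zero)
    emit(concentrations[[nm]], nm, "map",
         sprintf("clip_zero=%s", config$clip_zero))
  }
  if (all(c("PM10", "PM25") %in% names(concentrations)))
    emit(derive_pm_coarse(concentrations$PM10, concentrations$PM25),
         "PMcoarse", "map", "PM10 - PM25")

  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(list(manifest = manifest, stack = stack,
                 concentrations = concentrations, models = models))
}

#' Extract pipeline concentrations at points
#'
#' Reads a pollutant raster produced by [run_pipeline()] from its output
#' directory and returns the cell values containing each point.
#'
#' @param out_dir Pipeline output directory.
#' @param pollutant Model/pollutant name (file `<pollutant>.asc`).
#' @param points Data frame with columns `x`, `y` (optional `id`).
#' @return Tibble of `id` (if given), `x`, `y`, `inside`, `value`.
#' @export
extract_points <- function(out_dir, pollutant, points) {
  path <- file.path(out_dir, paste0(pollutant, ".asc"))
  if (!file.exists(path))
    stop("no '", pollutant, "' map in ", out_dir,
         "; run the 'map' stage first")
  res <- extract_at_points(read_raster(path), points$x, points$y)
  if (!is.null(points$id)) res <- cbind(tibble(id = points$id), res)
  as_tibble(res)
}

#' Validate a concentration surface against station measurements
#'
#' Pairs each station's observed value with the modelled value of the cell
#' containing it and computes the validation statistics (r^2, RMSE, bias,
#' t-test on bias). Stations outside the grid are dropped with a message.
#'
#' @param raster A concentration `lur_raster` (or a pipeline `out_dir` plus
#'   `pollutant`).
#' @param stations A `station_set`.
#' @param dataset Label for the report row.
#' @return One-row validation report tibble (see [validation_report()]).
#' @export
validate_against_stations <- function(raster, stations, dataset = "stations") {
  ex <- extract_at_points(raster, stations$x, stations$y)
  if (any(!ex$inside))
    message(sum(!ex$inside), " station(s) outside the grid were dropped")
  s <- paired_sample(stations$value[ex$inside], ex$value[ex$inside],
                     labels = stations$id[ex$inside])
  validation_report(s, dataset = dataset,
                    pollutant = attr(raster, "pollutant") %||% NA_character_)
}
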