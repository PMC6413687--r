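#' Configuration of the synthetic test scene
#'
#' A deterministic, seeded toy study area used to exercise every pipeline
#' stage without external data: a 2 km x 2 km town at 5 m cells with a
#' major ring road plus crossing arterials, a minor street grid carrying
#' lower traffic intensities, axis-aligned land-use blocks (industry,
#' harbour, residential), population spread over the residential blocks,
#' regional background stations on a jittered lattice, and random
#' validation sites. Axis-aligned geometry keeps analytic lengths and
#' areas available as test oracles.
#'
#' @param seed Integer seed; fully determines the scene.
#' @param extent Side length of the square domain (m).
#' @param cell_size Cell size (m).
#' @param n_major_roads Number of straight arterials (the ring road is
#'   always present); alternating vertical/horizontal.
#' @param n_minor_roads Number of minor streets, alternating orientation.
#' @param major_intensity,minor_intensity Length-2 ranges of daily traffic
#'   intensity (vehicles day^-1) drawn per segment class.
#' @param heavy_fraction Heavy-duty share of each segment's intensity.
#' @param n_ind,n_har,n_res Numbers of industry/harbour/residential blocks.
#' @param total_population Inhabitants spread over residential blocks.
#' @param n_background_stations Regional background stations for the IDW
#'   surfaces.
#' @param n_validation_sites Random sites used for forward observations.
#' @param noise_sd Gaussian noise s.d. added to forward observations
#'   (pollutant units).
#' @return A `scene_config` list.
#' @export
scene_config <- function(seed = 1L, extent = 2000, cell_size = 5,
                         n_major_roads = 4L, n_minor_roads = 20L,
                         major_intensity = c(10000, 40000),
                         minor_intensity = c(500, 5000),
                         heavy_fraction = 0.1,
                         n_ind = 2L, n_har = 1L, n_res = 4L,
                         total_population = 20000,
                         n_background_stations = 20L,
                         n_validation_sites = 200L,
                         noise_sd = 1.0) {
  if (extent <= 0 || cell_size <= 0 || extent < 2 * cell_size)
    stop("degenerate extent")
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("n_major_roads", "n_minor_roads", "n_ind", "n_har",
                       "n_res", "n_background_stations",
                       "n_validation_sites")]) < 0))
    stop("counts must be >= 0")
  if (any(c(major_intensity, minor_intensity) < 0) || heavy_fraction < 0)
    stop("intensities must be >= 0")
  structure(cfg, class = "scene_config")
}

#' @rdname scene_config
#' @param config A `scene_config`.
#' @export
scene_grid <- function(config) {
  n <- as.integer(round(config$extent / config$cell_size))
  grid_spec(0, config$extent, config$cell_size, n, n)
}

scene_line <- function(coords, id, class, intensity, heavy) {
  tibble(feature_id = id, road_class = class, traffic_intensity = intensity,
         heavy_traffic_intensity = heavy, geometry = list(coords))
}

rect_ring <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

#' Generate the synthetic scene
#'
#' @param config A [scene_config()].
#' @return List with elements `roads` (a `road_network`), `landuse`,
#'   `population`, `stations` (tibble with one value column per background
#'   predictor `BEO`/`BEX`/`BEP`/`BEA`), `sites` (validation site
#'   coordinates), `spec` and `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  E <- config$extent
  draw <- function(rng) runif(1, rng[1], rng[2])

  roads <- list()
  inset <- 0.1 * E
  roads[[1]] <- scene_line(rect_ring(inset, inset, E - inset, E - inset),
                           "ring", "major", NA, NA)
  k_major <- config$n_major_roads
  if (k_major > 0) {
    pos <- E * seq_len(k_major) / (k_major + 1)
    for (k in seq_len(k_major)) {
      g <- if (k %% 2L == 1L) cbind(x = c(pos[k], pos[k]), y = c(0, E))
           else cbind(x = c(0, E), y = c(pos[k], pos[k]))
      roads[[length(roads) + 1L]] <-
        scene_line(g, paste0("arterial", k), "major", NA, NA)
    }
  }
  if (config$n_minor_roads > 0) {
    for (k in seq_len(config$n_minor_roads)) {
      p <- runif(1, 0.05 * E, 0.95 * E)
      g <- if (k %% 2L == 1L) cbind(x = c(p, p), y = c(0, E))
           else cbind(x = c(0, E), y = c(p, p))
      roads[[length(roads) + 1L]] <-
        scene_line(g, paste0("street", k), "minor", NA, NA)
    }
  }
  roads <- do.call(rbind, roads)
  rng <- function(cls) if (cls == "major") config$major_intensity else config$minor_intensity
  roads$traffic_intensity <-
    vapply(roads$road_class, function(cl) draw(rng(cl)), numeric(1))
  roads$heavy_traffic_intensity <- config$heavy_fraction * roads$traffic_intensity
  class(roads) <- c("road_network", class(roads))

  rand_block <- function(size_rng) {
    w <- runif(1, size_rng[1], size_rng[2])
    h <- runif(1, size_rng[1], size_rng[2])
    x0 <- runif(1, 0, E - w); y0 <- runif(1, 0, E - h)
    rect_ring(x0, y0, x0 + w, y0 + h)
  }
  blocks <- list(); cls <- character()
  for (i in seq_len(config$n_ind)) { blocks <- c(blocks, list(rand_block(c(0.1, 0.3) * E))); cls <- c(cls, "IND") }
  for (i in seq_len(config$n_har)) { blocks <- c(blocks, list(rand_block(c(0.1, 0.25) * E))); cls <- c(cls, "HAR") }
  for (i in seq_len(config$n_res)) { blocks <- c(blocks, list(rand_block(c(0.15, 0.35) * E))); cls <- c(cls, "RES") }
  landuse <- tibble(class_src = cls, class = cls,
                    rings = lapply(blocks, list))
  class(landuse) <- c("landuse_layer", class(landuse))

  res <- landuse[landuse$class == "RES", ]
  if (nrow(res) > 0 && config$total_population > 0) {
    area <- vapply(res$rings, function(r) {
      ring <- r[[1]]
      abs(diff(range(ring[, 1])) * diff(range(ring[, 2])))
    }, numeric(1))
    counts <- floor(config$total_population * area / sum(area))
    counts[1] <- counts[1] + config$total_population - sum(counts)
    population <- tibble(count = counts, rings = res$rings)
  } else {
    population <- tibble(count = numeric(), rings = list())
  }
  class(population) <- c("population_layer", class(population))

  ns <- config$n_background_stations
  stations <- NULL
  if (ns > 0) {
    side <- ceiling(sqrt(ns))
    gx <- E * (rep(seq_len(side), times = side) - 0.5) / side
    gy <- E * (rep(seq_len(side), each = side) - 0.5) / side
    gx <- (gx + runif(side^2, -0.05 * E, 0.05 * E))[seq_len(ns)]
    gy <- (gy + runif(side^2, -0.05 * E, 0.05 * E))[seq_len(ns)]
    gx <- pmin(pmax(gx, 1), E - 1); gy <- pmin(pmax(gy, 1), E - 1)
    # regional backgrounds: smooth large-scale gradient plus small site noise,
    # base levels typical of Dutch annual averages (BEA in 1e-5 m^-1)
    bases <- c(BEO = 18, BEX = 28, BEP = 14, BEA = 1.2)
    stations <- tibble(id = sprintf("bg%02d", seq_len(ns)), x = gx, y = gy,
                       site_type = "regional")
    for (bg in names(bases)) {
      b <- bases[[bg]]
      stations[[bg]] <- b * (1 + 0.15 * (gx / E - 0.5) + 0.10 * (gy / E - 0.5)) +
        rnorm(ns, 0, 0.02 * b)
    }
  } else {
    stations <- tibble(id = character(), x = numeric(), y = numeric(),
                       site_type = character())
  }

  nv <- config$n_validation_sites
  sites <- tibble(id = sprintf("site%03d", seq_len(nv)),
                  x = runif(nv, config$cell_size, E - config$cell_size),
                  y = runif(nv, config$cell_size, E - config$cell_size))

  list(roads = roads, landuse = landuse, population = population,
       stations = stations, sites = sites, spec = scene_grid(config),
       config = config)
}

gj_feature_line <- function(coords, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = "LineString",
                       coordinates = lapply(seq_len(nrow(coords)),
                                            function(i) as.numeric(coords[i, ]))))
}

gj_feature_polygon <- function(rings, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon",
                       coordinates = lapply(rings, function(ring)
                         lapply(seq_len(nrow(ring)),
                                function(i) as.numeric(ring[i, ])))))
}

gj_write <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a scene to GeoJSON/CSV fixture files
#'
#' Materializes the exact file dialects the readers consume:
#' `roads.geojson`, `landuse.geojson`, `population.geojson`,
#' `stations.csv` (columns `id`, `x`, `y`, `site_type`, and one value
#' column per background predictor), `sites.csv` and `reclass.csv`
#' (identity mapping for the scene's class codes). Output is byte-identical
#' for identical scenes.
#'
#' @param scene A scene from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feats <- lapply(seq_len(nrow(scene$roads)), function(k) {
    r <- scene$roads[k, ]
    gj_feature_line(r$geometry[[1]], list(
      id = r$feature_id, road_class = r$road_class,
      traffic_intensity = r$traffic_intensity,
      heavy_traffic_intensity = r$heavy_traffic_intensity))
  })
  gj_write(feats, file.path(dir, "roads.geojson"))

  feats <- lapply(seq_len(nrow(scene$landuse)), function(k)
    gj_feature_polygon(scene$landuse$rings[[k]],
                       list(landuse = scene$landuse$class_src[k])))
  gj_write(feats, file.path(dir, "landuse.geojson"))

  feats <- lapply(seq_len(nrow(scene$population)), function(k)
    gj_feature_polygon(scene$population$rings[[k]],
                       list(population = scene$population$count[k])))
  gj_write(feats, file.path(dir, "population.geojson"))

  write.csv(scene$stations, file.path(dir, "stations.csv"), row.names = FALSE)
  write.csv(scene$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(data.frame(source_class = c("IND", "HAR", "RES"),
                       target_class = c("IND", "HAR", "RES")),
            file.path(dir, "reclass.csv"), row.names = FALSE)
  invisible(dir)
}

#' Synthetic observations from a model surface
#'
#' Samples the model's own concentration surface at the given sites and adds
#' seeded Gaussian noise -- the ground-truth generator for parameter-free
#' end-to-end validation: with `noise_sd = 0`, validating the model against
#' these observations must give r^2 = 1, RMSE = 0, bias = 0.
#'
#' @param model A [lur_model()].
#' @param stack Predictor stack for [evaluate_model()].
#' @param sites Data frame with columns `id`, `x`, `y`.
#' @param noise_sd Gaussian noise standard deviation (pollutant units).
#' @param seed Integer seed.
#' @return A `station_set` of observed values at the sites.
#' @export
forward_observations <- function(model, stack, sites, noise_sd = 0, seed = 1L) {
  vals <- evaluate_at_points(model, stack, sites$x, sites$y)
  if (any(!vals$inside)) stop("site(s) outside the model grid")
  set.seed(seed)
  obs <- vals$value + rnorm(nrow(sites), 0, noise_sd)
  station_set(sites$id, sites$x, sites$y, obs)
}
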