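write_test_roads <- function(features) {
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

line_feature <- function(id, class, coords, ti = NULL, hti = NULL) {
  props <- list(id = id, road_class = class)
  if (!is.null(ti)) props$traffic_intensity <- ti
  if (!is.null(hti)) props$heavy_traffic_intensity <- hti
  list(type = "Feature", properties = props,
       geometry = list(type = "LineString", coordinates = coords))
}

test_that("road reading keeps classes, intensities and the major subset", {
  path <- write_test_roads(list(
    line_feature("a", "major", list(c(0, 0), c(100, 0)), ti = 20000, hti = 2000),
    line_feature("b", "minor", list(c(0, 50), c(100, 50)))))
  net <- read_roads(path)
  expect_s3_class(net, "road_network")
  expect_equal(nrow(net), 2)
  expect_equal(nrow(filter_roads(net, "major")), 1)
  expect_equal(net$traffic_intensity, c(20000, NA))
  # missing intensity stays NA, it is not zero
  expect_true(is.na(net$heavy_traffic_intensity[2]))
})

test_that("invalid road features are rejected naming the offender", {
  path <- write_test_roads(list(
    line_feature("ok", "major", list(c(0, 0), c(1, 1))),
    line_feature("bad", "major", list(c(0, 0), c(1, 1)), ti = -5)))
  expect_error(read_roads(path), "bad")
  path <- write_test_roads(list(
    line_feature("x", "highway", list(c(0, 0), c(1, 1)))))
  expect_error(read_roads(path), "unknown or missing road class.*x")
})

test_that("scene writer and readers round-trip geometry and attributes", {
  sc <- generate_scene(scene_config(seed = 3, n_minor_roads = 5L,
                                    n_background_stations = 6L))
  dir <- tempfile()
  write_scene(sc, dir)
  net <- read_roads(file.path(dir, "roads.geojson"))
  expect_equal(nrow(net), nrow(sc$roads))
  expect_equal(net$road_class, sc$roads$road_class)
  for (k in seq_len(nrow(net)))
    expect_equal(unname(net$geometry[[k]]), unname(sc$roads$geometry[[k]]))
  lu <- read_landuse(file.path(dir, "landuse.geojson"),
                     read_reclass(file.path(dir, "reclass.csv")))
  expect_equal(lu$class, sc$landuse$class)
  pop <- read_population(file.path(dir, "population.geojson"))
  expect_equal(pop$count, sc$population$count)
  st <- read_stations(file.path(dir, "stations.csv"), value_col = "BEO")
  expect_equal(nrow(st), 6)
  expect_equal(st$value, sc$stations$BEO)
})

test_that("station CSV validation: duplicates error, missing values dropped", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("s1", "s2", "s3"), x = 1:3, y = 1:3,
                       value = c(5, NA, 7)), path, row.names = FALSE)
  expect_message(st <- read_stations(path), "1 station row")
  expect_equal(nrow(st), 2)
  write.csv(data.frame(id = c("s1", "s1"), x = 1:2, y = 1:2, value = c(1, 2)),
            path, row.names = FALSE)
  expect_error(read_stations(path), "duplicate station id.*s1")
})

test_that("reclass tables are validated", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(source_class = c("121", "123"),
                       target_class = c("IND", "HAR")), path, row.names = FALSE)
  rc <- read_reclass(path)
  expect_equal(unname(rc["121"]), "IND")
  write.csv(data.frame(source_class = c("121", "121"),
                       target_class = c("IND", "HAR")), path, row.names = FALSE)
  expect_error(read_reclass(path), "more than once")
  write.csv(data.frame(source_class = "121", target_class = "FARM"),
            path, row.names = FALSE)
  expect_error(read_reclass(path), "unknown target")
})
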