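spec10 <- grid_spec(0, 50, 5, 10, 10)

one_segment <- function(coords, class = "minor", ti = NA, hti = NA) {
  net <- tibble::tibble(feature_id = "s1", road_class = class,
                        traffic_intensity = ti, heavy_traffic_intensity = hti,
                        geometry = list(coords))
  class(net) <- c("road_network", class(net))
  net
}

test_that("line-length rasterization handles simple exact geometries", {
  # a horizontal segment spanning exactly one 5 m cell
  r <- rasterize_line_length(one_segment(cbind(c(0, 5), c(47.5, 47.5))), spec10)
  expect_equal(r$values[1, 1], 5)
  expect_equal(sum(r$values), 5)
  # a segment along a cell diagonal
  r <- rasterize_line_length(one_segment(cbind(c(0, 5), c(50, 45))), spec10)
  expect_equal(r$values[1, 1], 5 * sqrt(2), tolerance = 1e-12)
})

test_that("per-cell lengths conserve total clipped length and match dense sampling", {
  for (seed in 1:3) {
    net <- random_network(4, extent = 50, seed = seed)
    r <- rasterize_line_length(net, spec10, "all")
    expect_equal(sum(r$values), total_network_length(net), tolerance = 1e-9)
    oracle <- oracle_line_length(net, spec10, step = 0.001)
    expect_equal(r$values, oracle, tolerance = 1e-3)
  }
})

test_that("traffic load is clipped length times intensity, by class and field", {
  seg <- one_segment(cbind(c(0, 5), c(47.5, 47.5)), class = "major",
                     ti = 1000, hti = 100)
  expect_equal(rasterize_traffic_load(seg, spec10, "TL")$values[1, 1], 5000)
  expect_equal(rasterize_traffic_load(seg, spec10, "TML")$values[1, 1], 5000)
  expect_equal(rasterize_traffic_load(seg, spec10, "HTL")$values[1, 1], 500)
  # zero intensity gives a zero raster
  z <- one_segment(cbind(c(0, 50), c(25, 25)), ti = 0)
  expect_true(all(rasterize_traffic_load(z, spec10, "TL")$values == 0))
  # missing intensity fails naming the segment
  expect_error(rasterize_traffic_load(one_segment(cbind(c(0, 5), c(1, 1))),
                                      spec10, "TL"), "s1")
})

test_that("traffic load decomposes as intensity-weighted line length", {
  net <- random_network(6, extent = 50, seed = 9)
  tl <- rasterize_traffic_load(net, spec10, "TL")$values
  ref <- matrix(0, 10, 10)
  for (k in seq_len(nrow(net)))
    ref <- ref + net$traffic_intensity[k] *
      rasterize_line_length(net[k, ], spec10, "all")$values
  expect_equal(tl, ref, tolerance = 1e-12)
  # doubling every intensity doubles every cell exactly
  net2 <- net
  net2$traffic_intensity <- 2 * net$traffic_intensity
  expect_identical(rasterize_traffic_load(net2, spec10, "TL")$values, 2 * tl)
})

make_landuse <- function(rects, classes) {
  lu <- tibble::tibble(class_src = classes, class = classes,
                       rings = lapply(rects, function(r)
                         list(cbind(x = c(r[1], r[2], r[2], r[1], r[1]),
                                    y = c(r[3], r[3], r[4], r[4], r[3])))))
  class(lu) <- c("landuse_layer", class(lu))
  lu
}

test_that("class-area rasterization is all-or-nothing by cell centre", {
  # polygon covering the whole extent: every cell holds the full 25 m^2
  lu <- make_landuse(list(c(-1, 51, -1, 51)), "IND")
  r <- rasterize_class_area(lu, spec10, "IND")
  expect_true(all(r$values == 25))
  # absent class gives a zero raster
  expect_true(all(rasterize_class_area(lu, spec10, "HAR")$values == 0))
  expect_true(all(r$values %in% c(0, 25)))
})

test_that("class areas match analytic rectangle areas within a perimeter band", {
  set.seed(21)
  for (rep in 1:5) {
    x0 <- runif(1, 0, 30); y0 <- runif(1, 0, 30)
    w <- runif(1, 8, 20); h <- runif(1, 8, 20)
    lu <- make_landuse(list(c(x0, x0 + w, y0, y0 + h)), "RES")
    r <- rasterize_class_area(lu, spec10, "RES")
    true_area <- w * h
    band <- 2 * (w + h) * 5  # one cell-width band around the perimeter
    expect_lt(abs(sum(r$values) - true_area), band)
  }
})

test_that("population spreads uniformly per polygon and conserves totals", {
  pop <- tibble::tibble(count = c(1000, 60),
                        rings = list(
                          list(cbind(x = c(0, 50, 50, 0, 0), y = c(0, 0, 50, 50, 0))),
                          list(cbind(x = c(0, 15, 15, 0, 0), y = c(35, 35, 50, 50, 35)))))
  class(pop) <- c("population_layer", class(pop))
  r <- rasterize_population(pop, spec10)
  expect_equal(sum(r$values), 1060)
  # the big polygon covers all 100 cells: 10 per cell, plus 60/9 in the corner
  expect_equal(r$values[10, 10], 10)
  expect_equal(r$values[1, 1], 10 + 60 / 9)
})
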