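test_that("kernel membership follows cell-centre distance with closed ties", {
  expect_equal(nrow(make_kernel(2.4, 5)$offsets), 1)   # only the focal cell
  expect_equal(nrow(make_kernel(5, 5)$offsets), 5)     # centre + 4-neighbours
  expect_equal(nrow(make_kernel(25, 5)$offsets), 81)   # classic discrete disk
  # independent count: integer pairs with i^2 + j^2 <= 25
  cnt <- sum(outer((-5:5)^2, (-5:5)^2, "+") <= 25)
  expect_equal(cnt, 81)
  expect_error(make_kernel(-1, 5), ">= 0")
})

test_that("focal sums reproduce kernel counts on constant rasters", {
  sp <- grid_spec(0, 250, 5, 50, 50)
  r <- new_raster(sp, 3)
  f <- focal_sum(r, 25)
  expect_equal(f$values[25, 25], 81 * 3)
  # radius 0 is the identity
  expect_identical(focal_sum(r, 0)$values, r$values)
  # border cells see fewer cells than interior ones (zero padding)
  expect_lt(f$values[1, 1], f$values[25, 25])
})

test_that("focal and annulus sums equal the brute-force per-cell oracle", {
  set.seed(33)
  sp <- grid_spec(0, 150, 5, 30, 30)
  for (rep in 1:3) {
    v <- matrix(rnorm(900), 30, 30)
    r <- new_raster(sp, v)
    for (rad in c(10, 25, 60)) {
      expect_equal(focal_sum(r, rad)$values, oracle_focal(v, rad, 5),
                   tolerance = 1e-12)
    }
    expect_equal(annulus_sum(r, 25, 60)$values, oracle_focal(v, 60, 5, 25),
                 tolerance = 1e-12)
  }
})

test_that("annulus equals kernel-count arithmetic on constants and rejects bad radii", {
  sp <- grid_spec(0, 500, 5, 100, 100)
  r <- new_raster(sp, 2)
  n60 <- nrow(make_kernel(60, 5)$offsets)
  n25 <- nrow(make_kernel(25, 5)$offsets)
  a <- annulus_sum(r, 25, 60)
  # cell (50,50) is > 12 cells from every edge, so the ring fits entirely
  expect_equal(a$values[50, 50], (n60 - n25) * 2)
  expect_error(annulus_sum(r, 60, 60), "r_inner < r_outer")
  expect_error(annulus_sum(r, -1, 60), "r_inner")
})

test_that("an annulus lying entirely off-grid sums to 0, not NA", {
  # on a 4x4 grid the 25-500 m ring (5 m cells) has no in-grid member for
  # any cell: zero padding makes every sum 0
  sp <- grid_spec(0, 20, 5, 4, 4)
  r <- new_raster(sp, 7)
  a <- annulus_sum(r, 25, 500)
  expect_identical(a$values, matrix(0, 4, 4))
  expect_identical(a$values, oracle_focal(r$values, 500, 5, 25))
})

test_that("focal sums are monotone in radius and linear in the input", {
  set.seed(4)
  sp <- grid_spec(0, 100, 5, 20, 20)
  x <- new_raster(sp, matrix(runif(400), 20, 20))
  y <- new_raster(sp, matrix(runif(400), 20, 20))
  f10 <- focal_sum(x, 10)$values
  f25 <- focal_sum(x, 25)$values
  f60 <- focal_sum(x, 60)$values
  expect_true(all(f25 >= f10) && all(f60 >= f25))
  lhs <- focal_sum(new_raster(sp, 2 * x$values + 3 * y$values), 25)$values
  rhs <- 2 * f25 + 3 * focal_sum(y, 25)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("NA cells contribute nothing but all-NA neighbourhoods stay NA", {
  sp <- grid_spec(0, 50, 5, 10, 10)
  v <- matrix(1, 10, 10)
  v[1:3, 1:3] <- NA
  f <- focal_sum(new_raster(sp, v), 5)
  expect_true(is.na(f$values[1, 1]))     # kernel entirely NA
  expect_equal(f$values[1, 4], 3)        # NA neighbour contributes 0
  expect_equal(f$values[10, 10], 3)
  all_na <- new_raster(sp, matrix(NA_real_, 10, 10))
  expect_true(all(is.na(focal_sum(all_na, 25)$values)))
})

test_that("tiled focal sums are bit-identical to untiled ones", {
  set.seed(8)
  sp <- grid_spec(0, 300, 5, 60, 60)
  r <- new_raster(sp, matrix(rnorm(3600), 60, 60))
  for (rad in c(25, 125)) {
    ref <- focal_sum(r, rad)$values
    for (ts in c(17, 30, 64))
      expect_identical(focal_sum(r, rad, tile_size = ts)$values, ref)
  }
  expect_identical(annulus_sum(r, 25, 125, tile_size = 23)$values,
                   annulus_sum(r, 25, 125)$values)
})

test_that("a radius covering the whole grid yields the grand total everywhere", {
  set.seed(5)
  sp <- grid_spec(0, 100, 5, 20, 20)
  v <- matrix(rpois(400, 10), 20, 20)
  f <- focal_sum(new_raster(sp, v), 5000)
  expect_true(all(f$values == sum(v)))
})

test_that("the predictor stack holds exactly the deduplicated buffered terms", {
  sp <- grid_spec(0, 50, 5, 10, 10)
  base <- list()
  for (pid in c("RL", "MRL", "TL", "TML", "HTL", "IND", "HAR", "RES", "POP",
                "IDC", "IDM", "BEO", "BEX", "BEP", "BEA"))
    base[[pid]] <- new_raster(sp, 0)
  models <- builtin_models()
  stack <- compute_predictor_stack(base, models)
  buffered <- grep("_", names(stack), value = TRUE)
  expect_length(buffered, 16)
  expect_setequal(buffered, c(
    "POP_5000", "TL_50", "RL_1000", "HTL_25", "HTL_25-500", "IND_5000",
    "HAR_5000", "POP_1000", "HTL_500", "MRL_25", "MRL_50", "TML_1000",
    "TL_500", "RES_5000", "HTL_50", "TML_500"))
  pm10 <- compute_predictor_stack(base, models["PM10"])
  expect_setequal(names(pm10), c("TML_500", "POP_5000", "MRL_50"))
  expect_length(compute_predictor_stack(base, list()), 0)
  expect_error(compute_predictor_stack(base["RL"], models["PM10"]),
               "missing base raster")
})
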