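spec4 <- grid_spec(0, 20, 5, 4, 4)

test_that("the built-in registry carries the six models with fixed intercepts", {
  models <- builtin_models()
  expect_named(models, c("NO2", "NO2background", "NOx", "PM25",
                         "PM25absorbance", "PM10"))
  intercepts <- vapply(models, `[[`, numeric(1), "intercept")
  expect_identical(unname(intercepts),
                   c(-7.8, 3.21, 3.25, 9.46, 0.07, 23.71))
  expect_identical(models$PM25absorbance$output_units, "1e-5 m-1")
  expect_identical(models$NO2$output_units, "ug m-3")
  # zero predictors leave exactly the intercept everywhere
  for (m in models) {
    r <- evaluate_model(m, constant_stack(m, spec4, 0))
    expect_identical(r$values, matrix(m$intercept, 4, 4))
  }
})

test_that("evaluation matches hand arithmetic for the PM10 model", {
  m <- builtin_models()$PM10
  stack <- constant_stack(m, spec4, 0)
  stack[["TML_500"]]$values[] <- 1e8
  stack[["POP_5000"]]$values[] <- 1e5
  stack[["MRL_50"]]$values[] <- 100
  r <- evaluate_model(m, stack)
  # 23.71 + 2.16e-8*1e8 + 6.68e-6*1e5 + 0.015*100 = 23.71 + 2.16 + 0.668 + 1.5
  expect_equal(r$values[1, 1], 28.038, tolerance = 1e-12)
  expect_identical(attr(r, "pollutant"), "PM10")
  expect_identical(attr(r, "units"), "ug m-3")
})

test_that("evaluation is linear in predictors and clip_zero truncates", {
  m <- builtin_models()$PM25
  s1 <- constant_stack(m, spec4, 1)
  s2 <- constant_stack(m, spec4, 2)
  v0 <- evaluate_model(m, constant_stack(m, spec4, 0))$values[1, 1]
  v1 <- evaluate_model(m, s1)$values[1, 1]
  v2 <- evaluate_model(m, s2)$values[1, 1]
  expect_equal(v2 - v1, v1 - v0, tolerance = 1e-12)
  neg <- lur_model("custom", -5, list(lur_term("IDC", 1)))
  stack <- list(IDC = new_raster(spec4, 0.1))
  expect_equal(evaluate_model(neg, stack)$values[1, 1], -4.9)
  expect_equal(evaluate_model(neg, stack, clip_zero = TRUE)$values[1, 1], 0)
  expect_equal(summary(evaluate_model(neg, stack))$n_negative, 16)
})

test_that("NA predictors propagate to NA concentrations", {
  m <- builtin_models()$PM10
  stack <- constant_stack(m, spec4, 1)
  stack[["MRL_50"]]$values[2, 3] <- NA
  r <- evaluate_model(m, stack)
  expect_true(is.na(r$values[2, 3]))
  expect_equal(sum(is.na(r$values)), 1)
})

test_that("missing terms, grid mismatches and unit mismatches are errors", {
  m <- builtin_models()$PM10
  stack <- constant_stack(m, spec4, 0)
  expect_error(evaluate_model(m, stack[-1]), "missing term 'TML_500'")
  bad <- stack
  bad[["MRL_50"]] <- new_raster(grid_spec(0, 20, 5, 4, 5), 0)
  expect_error(evaluate_model(m, bad), "different grid")
  bad2 <- stack
  attr(bad2[["POP_5000"]], "units") <- "m"
  expect_error(evaluate_model(m, bad2), "units")
})

test_that("lur_term validates the predictor/buffer vocabulary", {
  expect_error(lur_term("XYZ", 1, 100), "unknown predictor")
  expect_error(lur_term("POP", 1), "requires a buffer")
  expect_error(lur_term("IDC", 1, 100), "takes no buffer")
  expect_error(lur_term("HTL", 1, c(500, 25)), "r_inner < r_outer")
  expect_error(lur_term("RL", Inf, 100), "finite")
  expect_identical(lurmap:::term_key(lur_term("HTL", 1, c(25, 500))),
                   "HTL_25-500")
  expect_identical(lurmap:::term_key(lur_term("POP", 1, 5000)), "POP_5000")
  expect_identical(lurmap:::term_key(lur_term("BEO", 1)), "BEO")
})

test_that("models round-trip exactly through JSON", {
  for (m in builtin_models()) {
    path <- tempfile(fileext = ".json")
    write_model(m, path)
    back <- read_model(path)
    expect_identical(back$pollutant, m$pollutant)
    expect_identical(back$intercept, m$intercept)
    expect_identical(back$output_units, m$output_units)
    expect_equal(back$terms, m$terms)
  }
})

test_that("extract_at_points flags outside points instead of dropping them", {
  r <- new_raster(spec4, matrix(1:16, 4, 4))
  got <- extract_at_points(r, c(2.5, 17.5, 25, -1), c(17.5, 2.5, 10, 10))
  expect_equal(got$inside, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(got$value, c(r$values[1, 1], r$values[4, 4], NA, NA))
  expect_equal(nrow(got), 4)
})

test_that("PMcoarse is the cellwise PM10 - PM2.5 difference", {
  pm10 <- new_raster(spec4, 24)
  pm25 <- new_raster(spec4, matrix(c(10, rep(9, 15)), 4, 4))
  pc <- derive_pm_coarse(pm10, pm25)
  expect_equal(pc$values[1, 1], 14)
  expect_equal(pc$values[2, 2], 15)
  expect_identical(attr(pc, "pollutant"), "PMcoarse")
  pm25$values[3, 3] <- NA
  expect_true(is.na(derive_pm_coarse(pm10, pm25)$values[3, 3]))
  other <- new_raster(grid_spec(0, 20, 5, 4, 5), 1)
  expect_error(derive_pm_coarse(pm10, other), "grid")
})
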