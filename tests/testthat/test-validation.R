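test_that("rmse, bias and r-squared match hand-computed values", {
  ps <- paired_sample(c(1, 2, 3), c(2, 2, 2))
  # differences -1, 0, 1: rmse = sqrt(2/3), bias = 0
  expect_equal(rmse(ps), sqrt(2 / 3))
  expect_equal(bias(ps), 0)
  ps2 <- paired_sample(c(10, 12), c(9, 10))
  expect_equal(r_squared(ps2), 1)  # perfectly correlated pair
  expect_equal(bias(ps2), 1.5)  # observed minus modelled
  expect_equal(rmse(ps2), sqrt((1 + 4) / 2))
})

test_that("paired_sample drops NA pairs and validates lengths", {
  ps <- paired_sample(c(1, NA, 3, 4), c(1, 2, NA, 5), labels = letters[1:4])
  expect_equal(ps$n, 2)
  expect_equal(ps$observed, c(1, 4))
  expect_equal(ps$labels, c("a", "d"))
  expect_error(paired_sample(1:3, 1:2), "equal length")
  expect_error(rmse(paired_sample(NA_real_, 1)), "empty")
})

test_that("r-squared is scale- and shift-invariant but errors on zero variance", {
  set.seed(2)
  o <- rnorm(30); m <- 0.7 * o + rnorm(30, sd = 0.3)
  base <- r_squared(paired_sample(o, m))
  expect_equal(r_squared(paired_sample(o, 5 + 3 * m)), base)
  expect_equal(r_squared(paired_sample(2 * o - 1, m)), base)
  expect_error(r_squared(paired_sample(o, rep(1, 30))), "zero variance")
  expect_error(r_squared(paired_sample(1, 1)), "at least 2")
})

test_that("the bias t-test follows the degenerate-case conventions", {
  exact <- bias_t_test(paired_sample(c(1, 2, 3), c(1, 2, 3)))
  expect_identical(exact$t, 0)
  expect_identical(exact$p, 1)
  expect_true(exact$degenerate)
  const <- bias_t_test(paired_sample(c(2, 3, 4), c(1, 2, 3)))
  expect_identical(const$t, Inf)
  expect_identical(const$p, 0)
  down <- bias_t_test(paired_sample(c(1, 2), c(2, 3)))
  expect_identical(down$t, -Inf)
  # a regular case agrees with stats::t.test on the differences
  set.seed(3)
  o <- rnorm(20, 10); m <- rnorm(20, 10)
  got <- bias_t_test(paired_sample(o, m))
  ref <- t.test(o - m)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$df, 19)
  expect_false(got$degenerate)
})

test_that("under the null the t-test p-values are uniform", {
  set.seed(99)
  p <- replicate(400, {
    d <- rnorm(15)
    bias_t_test(paired_sample(d, rep(0, 15)))$p
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("validation_report assembles one labelled row of all statistics", {
  set.seed(4)
  o <- rnorm(25, 20, 4); m <- o + rnorm(25)
  ps <- paired_sample(o, m)
  rep <- validation_report(ps, dataset = "routine", pollutant = "NO2")
  expect_equal(nrow(rep), 1)
  expect_identical(rep$dataset, "routine")
  expect_identical(rep$pollutant, "NO2")
  expect_equal(rep$n, 25)
  expect_equal(rep$rmse, rmse(ps))
  expect_equal(rep$bias, bias(ps))
  expect_equal(rep$r2, r_squared(ps))
})

test_that("station screening excludes strictly above the missing threshold", {
  rec <- data.frame(
    id = rep(c("a", "b", "c"), each = 10),
    x = rep(1:3, each = 10), y = rep(1:3, each = 10),
    value = c(c(rep(10, 8), NA, NA),      # a: 20% missing -> retained
              c(rep(20, 7), NA, NA, NA),  # b: 30% missing -> excluded
              rep(30, 10)))               # c: complete
  st <- screen_stations(rec)
  expect_setequal(st$id, c("a", "c"))
  expect_equal(st$value[st$id == "a"], 10)  # mean of non-missing records
  expect_equal(st$value[st$id == "c"], 30)
  expect_warning(out <- screen_stations(rec[rec$id != "c", ],
                                        max_missing_fraction = 0),
                 "no station passed")
  expect_equal(nrow(out), 0)
  expect_error(screen_stations(data.frame(id = 1)), "columns")
})
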