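m_default <- variogram_model("spherical", 0.15, 0.10, 27)

test_that("a single sample forces weight 1 and its own value", {
  d <- point_dataset(data.frame(x = 5, y = 5, z = 3.2))
  kr <- krige(d, "z", m_default, data.frame(x = c(0, 50), y = c(0, 80)),
              keep_weights = TRUE)
  expect_equal(kr$pred, c(3.2, 3.2))
  expect_equal(as.vector(kr$weights), c(1, 1))
})

test_that("two equidistant samples share the weight equally", {
  d <- point_dataset(data.frame(x = c(0, 20), y = c(0, 0), z = c(1, 5)))
  for (kind in c("spherical", "exponential", "gaussian")) {
    m <- variogram_model(kind, 0.2, 1, 15)
    kr <- krige(d, "z", m, data.frame(x = 10, y = 7), keep_weights = TRUE)
    expect_equal(as.vector(kr$weights), c(0.5, 0.5), tolerance = 1e-9)
    expect_equal(kr$pred, 3)
  }
})

test_that("kriging honors the data exactly with zero variance", {
  d <- random_dataset(15, seed = 3)
  kr <- krige(d, "z", m_default, d[3:5, c("x", "y")])
  expect_equal(kr$pred, d$z[3:5], tolerance = 1e-8)
  expect_equal(kr$var, rep(0, 3), tolerance = 1e-8)
  # and away from the data the variance is positive for C1 > 0
  off <- krige(d, "z", m_default, data.frame(x = 1.23, y = 4.56))
  expect_gt(off$var, 0)
})

test_that("pure-nugget kriging returns the arithmetic mean with equal weights", {
  d <- random_dataset(12, seed = 4)
  m <- variogram_model("spherical", 1.7, 0, 10)
  kr <- krige(d, "z", m, data.frame(x = 200, y = 200), keep_weights = TRUE)
  expect_equal(as.vector(kr$weights), rep(1 / 12, 12), tolerance = 1e-9)
  expect_equal(kr$pred, mean(d$z), tolerance = 1e-10)
})

test_that("weights agree with an independently coded dense solve", {
  for (seed in 1:5) {
    d <- random_dataset(10, seed = 100 + seed)
    kr <- krige(d, "z", m_default, data.frame(x = 33, y = 41),
                keep_weights = TRUE)
    oracle <- brute_ok(d, "z", m_default, 33, 41)
    expect_equal(as.vector(kr$weights), oracle$weights, tolerance = 1e-8)
    expect_equal(kr$pred, oracle$pred, tolerance = 1e-8)
    expect_equal(kr$lagrange, oracle$mu, tolerance = 1e-8)
    expect_equal(sum(kr$weights), 1, tolerance = 1e-9)
  }
})

test_that("predictions are translation invariant", {
  d <- random_dataset(20, seed = 9)
  kr1 <- krige(d, "z", m_default, data.frame(x = 10, y = 20))
  d2 <- d; d2$x <- d2$x + 1000; d2$y <- d2$y - 500
  kr2 <- krige(point_dataset(as.data.frame(d2)), "z", m_default,
               data.frame(x = 1010, y = -480))
  expect_equal(kr1$pred, kr2$pred, tolerance = 1e-8)
  expect_equal(kr1$var, kr2$var, tolerance = 1e-8)
})

test_that("duplicate sample coordinates are named in the error", {
  d <- data.frame(x = c(0, 10, 10), y = c(0, 5, 5), z = 1:3)
  expect_error(point_dataset(d), "row\\(s\\): 3")
  dd <- structure(d, class = c("point_dataset", "data.frame"))
  expect_error(krige(dd, "z", m_default, data.frame(x = 1, y = 1)),
               "duplicate")
})

test_that("constant data krige to a constant map honoring samples", {
  g <- paper_grid()
  d <- point_dataset(cbind(g, z = 4.2), spacing = 10)
  km <- krige_map(d, "z", m_default, cell_size = 10)
  expect_true(all(abs(km$prediction$values - 4.2) < 1e-8))
  # sample locations sit on cell centers and are honored exactly
  centers <- raster_cell_centers(km$prediction)
  idx <- match(paste(g$x, g$y), paste(centers$x, centers$y))
  expect_true(all(!is.na(idx)))
  vals <- as.vector(t(km$prediction$values))
  expect_equal(vals[idx], rep(4.2, 100), tolerance = 1e-8)
})

test_that("map exactness holds for a simulated survey", {
  g <- paper_grid()
  z <- simulate_grf(g, m_default, mean = 2.9, seed = 77)
  d <- point_dataset(cbind(g, z = z), spacing = 10)
  km <- krige_map(d, "z", m_default, cell_size = 10)
  centers <- raster_cell_centers(km$prediction)
  idx <- match(paste(g$x, g$y), paste(centers$x, centers$y))
  vals <- as.vector(t(km$prediction$values))
  expect_equal(vals[idx], z, tolerance = 1e-6)
})

test_that("map mean is an unbiased summary of stationary fields", {
  g <- expand.grid(x = seq(0, 40, 10), y = seq(0, 40, 10))
  m <- variogram_model("spherical", 0.05, 0.2, 20)
  diffs <- vapply(1:50, function(i) {
    z <- simulate_grf(g, m, mean = 10, seed = 800 + i)
    d <- point_dataset(cbind(g, z = z), spacing = 10)
    km <- krige_map(d, "z", m, cell_size = 5)
    mean(km$prediction$values) - mean(z)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-9)
})

test_that("leave-one-out RMSE matches hand arithmetic in closed-form cases", {
  d <- point_dataset(data.frame(x = c(0, 10, 20), y = 0, z = c(1, 2, 6)))
  m <- variogram_model("spherical", 1, 0, 5)  # pure nugget -> mean of others
  # errors: 1 - 4, 2 - 3.5, 6 - 1.5
  expect_equal(loo_rmse(d, "z", m), sqrt(mean(c(3, 1.5, 4.5)^2)))
  dc <- point_dataset(data.frame(x = c(0, 10, 20, 30), y = 0, z = 2))
  expect_equal(loo_rmse(dc, "z", m_default), 0, tolerance = 1e-9)
  expect_error(loo_rmse(d[1:2, ], "z", m_default), "at least 3")
})

test_that("cross-validation error grows with added noise", {
  g <- expand.grid(x = seq(0, 50, 10), y = seq(0, 50, 10))
  base <- simulate_grf(g, variogram_model("spherical", 0.01, 0.2, 25),
                       mean = 0, seed = 12)
  m <- variogram_model("spherical", 0.05, 0.2, 25)
  med_rmse <- vapply(c(0, 0.5, 1.5), function(sig) {
    median(vapply(1:20, function(i) {
      set.seed(900 + i)
      d <- point_dataset(cbind(g, z = base + rnorm(length(base), 0, sig)))
      loo_rmse(d, "z", m)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_rmse) > 0))
})

test_that("raster containers and cell centers are coherent", {
  r <- raster_grid(c(0, 0), 2, matrix(1:6, nrow = 2, byrow = TRUE))
  expect_equal(r$n_rows, 2); expect_equal(r$n_cols, 3)
  cc <- raster_cell_centers(r)
  expect_equal(nrow(cc), 6)
  expect_equal(cc$y[1], 3)  # first row is the northernmost
  expect_error(raster_grid(c(0, 0), 0, matrix(1)), "cell_size")
})
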