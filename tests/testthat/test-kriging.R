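gauss_model <- function(nugget = 0, psill = 0.5, range_param = 1500) {
  variogram_model("gaussian", nugget, psill, range_param)
}

test_that("kriging with zero nugget honours the data exactly", {
  ds <- make_dataset(8, seed = 2)
  mod <- gauss_model()
  for (i in seq_len(8)) {
    k <- simple_kriging(c(ds$points$x[i], ds$points$y[i]), ds, mod)
    expect_equal(k$estimate, unname(ds$values[i]), tolerance = 1e-9)
    expect_lt(k$variance, 1e-9)
  }
})

test_that("a pure-nugget model predicts the mean with variance C0", {
  ds <- make_dataset(6, seed = 3)
  mod <- variogram_model("gaussian", nugget = 0.3, psill = 0,
                         range_param = NA)
  k <- simple_kriging(c(4000, 4000), ds, mod)
  expect_equal(k$weights, setNames(rep(0, 6), ds$points$id),
               tolerance = 1e-12)
  expect_equal(k$estimate, mean(ds$values), tolerance = 1e-12)
  expect_equal(k$variance, 0.3, tolerance = 1e-12)
})

test_that("the 3-point system matches an independent dense solve", {
  pts <- as_sampling_points(data.frame(
    id = c("a", "b", "c"), x = c(0, 1000, 0), y = c(0, 0, 1000),
    altitude = 100, zone = "termomediterranean"))
  z <- c(1.2, 2.4, 3.1)
  ds <- pheno_dataset(pts, z, "2004-04-23")
  mod <- gauss_model(nugget = 0.05, psill = 0.4, range_param = 800)
  tgt <- c(300, 400)
  k <- simple_kriging(tgt, ds, mod, mean = 2.0)
  # oracle: explicit covariance algebra
  sill <- 0.45
  cov_fn <- function(h) ifelse(h == 0, sill, 0.4 * exp(-(h / 800)^2))
  D <- as.matrix(dist(cbind(pts$x, pts$y)))
  Cm <- matrix(cov_fn(D), 3, 3)
  cv <- cov_fn(sqrt((pts$x - tgt[1])^2 + (pts$y - tgt[2])^2))
  lam <- solve(Cm) %*% cv
  expect_equal(unname(k$weights), drop(lam), tolerance = 1e-10)
  expect_equal(k$estimate, sum(lam * z) + 2.0 * (1 - sum(lam)),
               tolerance = 1e-10)
  expect_equal(k$variance, sill - sum(lam * cv), tolerance = 1e-10)
})

test_that("kriging is linear in the data and its variance ignores them", {
  ds <- make_dataset(9, seed = 6, values = runif(9, 0.5, 3.5))
  mod <- gauss_model(nugget = 0.02, psill = 0.3, range_param = 2000)
  tgt <- c(5200, 4800)
  k1 <- simple_kriging(tgt, ds, mod, mean = 2)
  a <- 0.4; b <- 0.8
  ds2 <- pheno_dataset(ds$points, a * ds$values + b, ds$date)
  k2 <- simple_kriging(tgt, ds2, mod, mean = a * 2 + b)
  expect_equal(k2$estimate, a * k1$estimate + b, tolerance = 1e-10)
  expect_equal(k2$variance, k1$variance, tolerance = 1e-12)
  expect_equal(k2$weights, k1$weights, tolerance = 1e-12)
})

test_that("far from all data the prediction reverts to the mean", {
  ds <- make_dataset(5, seed = 8)
  mod <- gauss_model(nugget = 0.1, psill = 0.5, range_param = 1000)
  k <- simple_kriging(c(1e7, 1e7), ds, mod, mean = 1.7)
  expect_equal(k$estimate, 1.7, tolerance = 1e-9)
  expect_equal(k$variance, 0.6, tolerance = 1e-9)
})

test_that("coincident points with zero nugget raise a named error", {
  pts <- as_sampling_points(data.frame(
    id = c("a", "b", "c", "d"), x = c(0, 0, 1000, 2000),
    y = c(0, 0, 0, 1000), altitude = 100,
    zone = "termomediterranean"))
  ds <- pheno_dataset(pts, c(1, 1.5, 2, 3), "2004-04-23")
  expect_error(simple_kriging(c(500, 500), ds, gauss_model()),
               "a / b")
})

test_that("grid kriging matches per-cell point kriging", {
  ds <- make_dataset(7, seed = 12, bbox = c(0, 0, 6000, 6000))
  mod <- gauss_model(nugget = 0.03, psill = 0.4, range_param = 1800)
  g <- krige_grid(ds, mod, cellsize = 500, clamp = FALSE)
  xc <- g$xll + (seq_len(ncol(g$values)) - 0.5) * g$cellsize
  yc_north_first <- rev(g$yll + (seq_len(nrow(g$values)) - 0.5) *
                          g$cellsize)
  for (i in seq(1, nrow(g$values), by = 3)) {
    for (j in seq(1, ncol(g$values), by = 4)) {
      k <- simple_kriging(c(xc[j], yc_north_first[i]), ds, mod)
      expect_equal(g$values[i, j], k$estimate, tolerance = 1e-12)
      expect_equal(attr(g, "variance")[i, j], k$variance,
                   tolerance = 1e-12)
    }
  }
})

test_that("grid kriging reproduces constants and clamps with flags", {
  ds <- make_dataset(5, seed = 4, values = rep(2.2, 5))
  mod <- gauss_model(nugget = 0, psill = 0.3, range_param = 1500)
  g <- krige_grid(ds, mod, cellsize = 2000)
  expect_true(all(abs(g$values - 2.2) < 1e-9))
  expect_false(any(g$clamp_flags))

  # a datum-coincident cell centre with zero nugget honours the datum
  pts <- as_sampling_points(data.frame(
    id = c("a", "b", "c"), x = c(500, 1500, 2500), y = c(500, 500, 1500),
    altitude = 100, zone = "termomediterranean"))
  dsx <- pheno_dataset(pts, c(1, 2, 3), "2004-04-23")
  gx <- krige_grid(dsx, mod, bbox = c(0, 0, 3000, 2000),
                   cellsize = 1000)
  expect_equal(grid_extract(gx, pts$x, pts$y), c(1, 2, 3),
               tolerance = 1e-9)

  # bbox away from the data warns and extrapolates toward the mean
  expect_warning(
    gfar <- krige_grid(dsx, mod, bbox = c(50000, 50000, 52000, 52000),
                       cellsize = 1000),
    "excludes all data")
  expect_true(all(abs(gfar$values - 2) < 1e-6))
})
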