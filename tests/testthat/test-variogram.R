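test_that("empirical semivariogram handles elementary cases", {
  pts <- as_sampling_points(data.frame(
    id = c("a", "b", "c"), x = c(0, 1000, 5000), y = 0,
    altitude = 100, zone = "termomediterranean"))
  ds <- pheno_dataset(pts, c(0, 2, 2), "2004-04-23")
  # pair a-b alone in the first bin: (0-2)^2 / 2 = 2
  emp <- empirical_semivariogram(ds, n_lags = 5, max_lag = 5000)
  expect_equal(emp$gamma[1], 2)
  expect_equal(emp$np[1], 1L)
  # constant field -> all bins zero
  ds0 <- pheno_dataset(pts, c(1, 1, 1), "2004-04-23")
  expect_true(all(empirical_semivariogram(ds0)$gamma == 0))
  expect_error(empirical_semivariogram(
    pheno_dataset(pts[1:2, ], c(0, 1), "2004-04-23")), "at least 3")
})

test_that("binned semivariogram equals exhaustive pair enumeration", {
  for (seed in 1:25) {
    n <- sample(4:12, 1)
    ds <- make_dataset(n, seed = seed)
    n_lags <- sample(3:8, 1)
    emp <- empirical_semivariogram(ds, n_lags = n_lags)
    D <- as.matrix(dist(cbind(ds$points$x, ds$points$y)))
    oracle <- oracle_semivariogram(ds$points, unname(ds$values),
                                   n_lags, max(D))
    expect_equal(emp$lag, oracle$lag)
    expect_equal(emp$gamma, oracle$gamma)
    expect_equal(emp$np, oracle$np)
  }
})

test_that("semivariogram is shift-invariant and scales quadratically", {
  ds <- make_dataset(10, seed = 5, values = runif(10, 1, 3))
  emp <- empirical_semivariogram(ds, n_lags = 6)
  shifted <- pheno_dataset(ds$points, ds$values + 0.7, ds$date)
  scaled <- pheno_dataset(ds$points, 0.5 * ds$values, ds$date)
  expect_equal(empirical_semivariogram(shifted, n_lags = 6)$gamma,
               emp$gamma, tolerance = 1e-12)
  expect_equal(empirical_semivariogram(scaled, n_lags = 6)$gamma,
               0.25 * emp$gamma, tolerance = 1e-12)
})

test_that("the Gaussian model has its closed-form values and shape", {
  C0 <- 0.05; C <- 0.3; A0 <- 2000
  expect_equal(gaussian_model_value(0, C0, C, A0), 0)
  expect_equal(gaussian_model_value(A0, C0, C, A0),
               C0 + C * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(gaussian_model_value(10 * A0, C0, C, A0), C0 + C,
               tolerance = 1e-9)
  expect_error(gaussian_model_value(-1, C0, C, A0), "non-negative")
  h <- seq(0, 10000, by = 50)
  g <- gaussian_model_value(h, C0, C, A0)
  expect_true(all(diff(g[-1]) >= 0))          # non-decreasing beyond 0
  expect_true(all(g <= C0 + C + 1e-12))
  m <- variogram_model("gaussian", C0, C, A0)
  expect_equal(effective_range(m), sqrt(3) * A0)
  expect_equal(model_sill(m), C0 + C)
  expect_equal(variogram_model_value(h, m), g)
})

test_that("noiseless bins recover the generating parameters", {
  truth <- c(0.05, 0.30, 2000)
  fit <- fit_variogram(noiseless_bins(truth[1], truth[2], truth[3]))
  expect_equal(c(fit$nugget, fit$psill, fit$range_param), truth,
               tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-12)
})

test_that("flat bins collapse to a flagged pure-nugget model", {
  bins <- noiseless_bins(0.2, 0, 1000)   # gamma = 0.2 everywhere
  fit <- fit_variogram(bins)
  expect_true("pure_nugget" %in% fit$flags)
  expect_equal(fit$nugget, 0.2, tolerance = 1e-12)
  expect_equal(fit$psill, 0)
  expect_error(fit_variogram(bins[1:2, ]), "at least 3")
})

test_that("fitted RSS never exceeds the pure-nugget RSS and r2 is sane", {
  for (seed in 1:10) {
    set.seed(seed)
    lags <- seq(400, 9000, length.out = 7)
    true_m <- variogram_model("gaussian", 0.05, 0.4, 2500)
    gam <- pmax(0, variogram_model_value(lags, true_m) +
                  rnorm(7, 0, 0.05))
    bins <- structure(
      data.frame(lag = lags, gamma = gam, np = sample(3:12, 7, TRUE)),
      class = c("empirical_variogram", "data.frame"),
      max_lag = max(lags), n_lags = 7, z_var = 0.45)
    for (wt in c("none", "pairs")) {
      fit <- fit_variogram(bins, weighting = wt)
      w <- if (wt == "pairs") bins$np else rep(1, 7)
      gbar <- sum(w * gam) / sum(w)
      nug_rss <- sum(w * (gam - gbar)^2)
      expect_lte(fit$rss, nug_rss + 1e-12)
      expect_true(fit$r2 >= 0 && fit$r2 <= 1)
      expect_true(is.finite(fit$rss))
    }
  }
})

test_that("least-squares fit agrees with a grid-search oracle on noisy bins", {
  set.seed(77)
  lags <- seq(400, 9000, length.out = 8)
  true_m <- variogram_model("gaussian", 0.05, 0.4, 2500)
  gam <- pmax(0, variogram_model_value(lags, true_m) + rnorm(8, 0, 0.03))
  bins <- structure(
    data.frame(lag = lags, gamma = gam, np = 10L),
    class = c("empirical_variogram", "data.frame"),
    max_lag = max(lags), n_lags = 8, z_var = 0.45)
  fit <- fit_variogram(bins)
  # dense grid search over (C0, C, A0)
  grid <- expand.grid(C0 = seq(0, 0.15, length.out = 31),
                      C = seq(0.1, 0.8, length.out = 71),
                      A0 = seq(200, 9000, length.out = 89))
  rss <- mapply(function(C0, C, A0) {
    sum((gam - (C0 + C * (1 - exp(-(lags / A0)^2))))^2)
  }, grid$C0, grid$C, grid$A0)
  expect_lte(fit$rss, min(rss) * 1.05)
  expect_lt(fit$rss, sum((gam - mean(gam))^2))
  expect_true(fit$r2 < 1 && fit$rss > 0)
})
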