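test_that("network generation is reproducible and respects its bounds", {
  cfg <- simulation_config(seed = 42)
  p1 <- generate_network(cfg)
  p2 <- generate_network(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10)
  b <- cfg$bbox
  expect_true(all(p1$x >= b[1] & p1$x <= b[3]))
  expect_true(all(p1$y >= b[2] & p1$y <= b[4]))
  expect_true(all(p1$altitude >= 92 & p1$altitude <= 585))
  expect_setequal(unique(p1$zone),
                  c("termomediterranean", "mesomediterranean"))
  p3 <- generate_network(simulation_config(n_points = 3, seed = 1))
  expect_equal(nrow(p3), 3)
  expect_error(simulation_config(n_points = 2), "at least 3")
  expect_error(simulation_config(bbox = c(0, 0, 0, 10)), "degenerate")
})

test_that("the noise-free limit reproduces the deterministic trend", {
  cfg <- simulation_config(seed = 7, grf_nugget = 0, grf_psill = 0,
                           quadrat_sd = 0)
  pts <- generate_network(cfg)
  dss <- simulate_phenology(pts, cfg)
  for (k in seq_along(dss)) {
    trend <- cfg$phase_at_origin + cfg$weekly_advance * (k - 1) +
      cfg$altitude_delay * pts$altitude
    expect_equal(unname(dss[[k]]$values), pmin(pmax(trend, 0), 4),
                 tolerance = 1e-12)
    expect_identical(attr(dss[[k]], "clamped"),
                     trend < 0 | trend > 4)
  }
})

test_that("simulated observations satisfy the data-model invariants", {
  cfg <- simulation_config(seed = 11)
  pts <- generate_network(cfg)
  dss <- simulate_phenology(pts, cfg)
  expect_length(dss, length(cfg$dates))
  for (ds in dss) {
    expect_s3_class(ds, "pheno_dataset")
    expect_true(all(ds$values >= 0 & ds$values <= 4))
    expect_false(anyNA(ds$values))
    # clamp flags fire only where the value was pushed to a bound
    inside <- ds$values > 0 & ds$values < 4
    expect_false(any(attr(ds, "clamped")[inside]))
    expect_true(all(ds$values[attr(ds, "clamped")] %in% c(0, 4)))
  }
  # same seed, same draw
  expect_identical(simulate_phenology(pts, cfg)[[2]]$values,
                   dss[[2]]$values)
})

test_that("a negative altitude effect shows up as a negative rank correlation", {
  meds <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_points = 15, seed = s,
                             altitude_delay = -0.003,
                             dates = as.Date("2004-05-07"))
    pts <- generate_network(cfg)
    ds <- simulate_phenology(pts, cfg)[[1]]
    cor(pts$altitude, unname(ds$values), method = "spearman")
  })
  expect_lt(median(meds), 0)
})

test_that("the realised field matches the configured semivariance at range", {
  # mean empirical semivariance at the effective range, over 50 seeds
  nugget <- 0.02; psill <- 0.15; range <- 2000
  er <- sqrt(3) * range
  model <- variogram_model("gaussian", nugget, psill, range)
  target <- variogram_model_value(er, model)
  at_er <- sapply(1:50, function(s) {
    cfg <- flat_field_config(250, seed = s, nugget = nugget,
                             psill = psill, range = range)
    pts <- generate_network(cfg)
    ds <- simulate_phenology(pts, cfg)[[1]]
    emp <- empirical_semivariogram(ds, n_lags = 10, max_lag = 2 * er)
    # bin whose mean lag is nearest the effective range
    emp$gamma[which.min(abs(emp$lag - er))]
  })
  expect_lt(abs(mean(at_er) - target) / target, 0.15)
})

test_that("simulated pollen tracks the full-flowering fraction", {
  cfg <- simulation_config(seed = 3, pollen_noise_sd = 0)
  pts <- generate_network(cfg)
  dss <- simulate_phenology(pts, cfg)
  pol <- simulate_pollen(dss, cfg)
  expect_s3_class(pol, "pollen_series")
  expect_true(all(pol$count >= 0))
  # identical seeds -> identical series
  expect_identical(simulate_pollen(dss, cfg)$count, pol$count)
  # noise-free: the peak day lies on the date of maximum latent
  # full-flowering fraction
  frac <- sapply(dss, function(ds) {
    z <- attr(ds, "latent"); mean(z >= 1.5 & z <= 2.5)
  })
  best_date <- as.Date(names(dss))[which.max(frac)]
  expect_equal(pol$date[which.max(pol$count)], best_date)

  # a field entirely past flowering emits no pollen
  cfg2 <- simulation_config(seed = 3, phase_at_origin = 8,
                            altitude_delay = 0, grf_psill = 0,
                            grf_nugget = 0, quadrat_sd = 0,
                            pollen_noise_sd = 0)
  dss2 <- simulate_phenology(pts, cfg2)
  pol2 <- simulate_pollen(dss2, cfg2)
  expect_true(all(pol2$count == 0))
})
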