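# Shared fixtures: small random networks and independent brute-force
# oracles used across the suite.

make_points <- function(n, seed = 1, bbox = c(0, 0, 10000, 10000),
                        altitude = NULL) {
  set.seed(seed)
  if (is.null(altitude)) altitude <- runif(n, 50, 600)
  as_sampling_points(data.frame(
    id = sprintf("p%02d", seq_len(n)),
    x = runif(n, bbox[1], bbox[3]),
    y = runif(n, bbox[2], bbox[4]),
    altitude = altitude,
    zone = "termomediterranean"))
}

make_dataset <- function(n, seed = 1, values = NULL, ...) {
  pts <- make_points(n, seed, ...)
  if (is.null(values)) {
    set.seed(seed + 1000)
    values <- runif(n, 0, 4)
  }
  pheno_dataset(pts, values, "2004-04-23")
}

# Brute-force method-of-moments semivariogram: explicit double loop,
# no shared code with the implementation.
oracle_semivariogram <- function(points, values, n_lags, max_lag) {
  n <- length(values)
  d <- c(); g <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sqrt((points$x[i] - points$x[j])^2 +
                 (points$y[i] - points$y[j])^2)
      if (dd > 0 && dd <= max_lag) {
        d <- c(d, dd)
        g <- c(g, (values[i] - values[j])^2)
      }
    }
  }
  breaks <- (0:n_lags) * (max_lag / n_lags)
  breaks[n_lags + 1] <- max_lag
  out <- NULL
  for (k in seq_len(n_lags)) {
    lo <- breaks[k]; hi <- breaks[k + 1]
    in_bin <- d > lo & d <= hi
    if (k == 1) in_bin <- d > 0 & d <= hi
    if (any(in_bin)) {
      out <- rbind(out, data.frame(
        lag = mean(d[in_bin]),
        gamma = sum(g[in_bin]) / (2 * sum(in_bin)),
        np = sum(in_bin)))
    }
  }
  out[order(out$lag), , drop = FALSE]
}

# Closed-form OLS of y on x.
oracle_ols <- function(y, x) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Noise-free empirical bins generated from a known Gaussian model.
noiseless_bins <- function(nugget, psill, range_param,
                           lags = seq(500, 8000, length.out = 8)) {
  m <- variogram_model("gaussian", nugget, psill, range_param)
  structure(
    data.frame(lag = lags, gamma = variogram_model_value(lags, m),
               np = 10L),
    class = c("empirical_variogram", "data.frame"),
    max_lag = max(lags), n_lags = length(lags),
    z_var = nugget + psill)
}

# Zero-trend stationary simulation at the configured GRF.
flat_field_config <- function(n, seed, nugget = 0.02, psill = 0.15,
                              range = 2000, quadrat_sd = 0) {
  simulation_config(
    n_points = n, phase_at_origin = 2, weekly_advance = 0,
    altitude_delay = 0, grf_nugget = nugget, grf_psill = psill,
    grf_range = range, quadrat_sd = quadrat_sd,
    dates = as.Date("2004-04-23"), seed = seed)
}
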