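#' Configuration for the synthetic phenology generator
#'
#' Collects every knob of the synthetic study: the sampling network,
#' the deterministic flowering trend (start phase, weekly advance,
#' altitude delay), the Gaussian random field giving spatial
#' autocorrelation, the quadrat observation noise and the pollen-curve
#' emulation.  Defaults reproduce the study conditions: a ten-point
#' network over a ~17 x 10 km extent with altitudes 92-585 m, weekly
#' visits through the spring flowering season, a phase advance of about
#' half a phase per week, and per-date spatial variance of the order
#' seen in the screening tables (0.15-0.4 phase squared, most of it
#' altitude-driven).
#'
#' @param n_points Number of sampling points (>= 3; default 10).
#' @param bbox `c(xmin, ymin, xmax, ymax)` in metres; default the study
#'   network extent.
#' @param altitude_range `c(min, max)` altitude in metres
#'   (default 92-585).
#' @param dates Observation dates; default six weekly visits starting
#'   2004-04-23.
#' @param phase_at_origin Deterministic phase at the first date at
#'   altitude 0 (default 1.8).
#' @param weekly_advance Phase advance per week (default 0.5).
#' @param altitude_delay Phase change per metre of altitude (default
#'   -0.003: higher sites flower later).
#' @param grf_nugget,grf_psill,grf_range Gaussian-covariance parameters
#'   of the latent spatial field (defaults 0.02, 0.15 phase squared and
#'   2000 m).
#' @param quadrat_sd Standard deviation of a single quadrat score about
#'   the latent phase (default 0.5; the recorded value is the mean of
#'   `n_quadrats` scores).
#' @param n_quadrats Quadrat throws per point per visit (default 5).
#' @param pollen_scale Peak daily pollen level (grains/m3) when the
#'   whole latent field is at full flowering (default 120).
#' @param pollen_noise_sd Standard deviation of the multiplicative
#'   lognormal noise on daily pollen counts (default 0.3; 0 =
#'   noise-free).
#' @param seed Integer seed; the whole simulation is deterministic
#'   given it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_points = 10,
                              bbox = c(340584, 4193395, 357483, 4203129),
                              altitude_range = c(92, 585),
                              dates = seq(as.Date("2004-04-23"),
                                          by = 7, length.out = 6),
                              phase_at_origin = 1.8,
                              weekly_advance = 0.5,
                              altitude_delay = -0.003,
                              grf_nugget = 0.02,
                              grf_psill = 0.15,
                              grf_range = 2000,
                              quadrat_sd = 0.5,
                              n_quadrats = 5,
                              pollen_scale = 120,
                              pollen_noise_sd = 0.3,
                              seed = 1) {
  if (n_points < 3) stop("`n_points` must be at least 3", call. = FALSE)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("degenerate bounding box", call. = FALSE)
  }
  if (quadrat_sd < 0 || grf_nugget < 0 || grf_psill < 0 ||
      pollen_noise_sd < 0) {
    stop("variance parameters must be non-negative", call. = FALSE)
  }
  if (grf_psill > 0 && grf_range <= 0) {
    stop("`grf_range` must be positive", call. = FALSE)
  }
  if (n_quadrats < 1) stop("`n_quadrats` must be at least 1", call. = FALSE)
  structure(list(n_points = as.integer(n_points), bbox = bbox,
                 altitude_range = as.numeric(altitude_range),
                 dates = as.Date(dates),
                 phase_at_origin = phase_at_origin,
                 weekly_advance = weekly_advance,
                 altitude_delay = altitude_delay,
                 grf_nugget = grf_nugget, grf_psill = grf_psill,
                 grf_range = grf_range, quadrat_sd = quadrat_sd,
                 n_quadrats = as.integer(n_quadrats),
                 pollen_scale = pollen_scale,
                 pollen_noise_sd = pollen_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic per-date sub-seed below 2^31.
.date_seed <- function(seed, k) {
  ((as.integer(seed) %% 46337L) * 46337L + 7919L * as.integer(k)) %%
    2147483647L
}

#' Generate a synthetic sampling network
#'
#' Points are uniform over the bounding box; altitude increases with
#' northing (the Sierra gradient north of the city) plus jitter, then
#' is clamped to the configured range.  Sites below the altitude
#' midpoint are labelled termomediterranean, the rest
#' mesomediterranean.  Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return A `sampling_points` table with `n_points` rows.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.date_seed(config$seed, 0L))
  n <- config$n_points
  b <- config$bbox
  x <- stats::runif(n, b[1], b[3])
  y <- stats::runif(n, b[2], b[4])
  ar <- config$altitude_range
  base_alt <- ar[1] + (y - b[2]) / (b[4] - b[2]) * (ar[2] - ar[1])
  alt <- base_alt + stats::rnorm(n, 0, 0.1 * (ar[2] - ar[1]))
  alt <- pmin(pmax(alt, ar[1]), ar[2])
  zone <- ifelse(alt < base::mean(ar), "termomediterranean",
                 "mesomediterranean")
  as_sampling_points(data.frame(
    id = sprintf("P%02d", seq_len(n)), x = x, y = y,
    altitude = alt, zone = zone))
}

# Lower-triangular factor of the latent-field covariance over a point
# set: psill * exp(-(d/range)^2) + nugget on the diagonal, with a tiny
# jitter for numerical positive-definiteness.
.grf_factor <- function(points, nugget, psill, range) {
  n <- nrow(points)
  if (psill == 0 && nugget == 0) return(matrix(0, n, n))
  D <- point_distances(points)
  S <- if (psill > 0) psill * exp(-(D / range)^2) else matrix(0, n, n)
  diag(S) <- psill + nugget
  R <- tryCatch(chol(S + diag(1e-10, n)), error = function(e) e)
  if (inherits(R, "error")) {
    stop("latent covariance is not positive definite: ",
         conditionMessage(R), call. = FALSE)
  }
  t(R)
}

#' Simulate per-date phenology observations
#'
#' The latent phase at point x on visit t (weeks since the first date)
#' is `z_t(x) = beta0 + r t + beta_alt alt(x) + G(x)` where G is a
#' zero-mean Gaussian random field with Gaussian covariance
#' (`grf_psill`, `grf_range`) plus an independent nugget, realised
#' exactly through the Cholesky factor of its covariance over the point
#' set.  The recorded observation is the mean of `n_quadrats`
#' independent draws from `N(z, quadrat_sd^2)`, clamped to the phase
#' scale \[0, 4\].  Dates are simulated conditionally independent given
#' the trend, each from a deterministic sub-seed of the config seed.
#'
#' @param points A `sampling_points` table.
#' @param config A [simulation_config()].
#' @return A named list of [pheno_dataset()] objects (one per date).
#'   Each carries attributes `"latent"` (pre-noise field) and
#'   `"clamped"` (logical, where the quadrat mean left \[0, 4\]).
#' @export
simulate_phenology <- function(points, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!inherits(points, "sampling_points")) points <- as_sampling_points(points)
  n <- nrow(points)
  Lf <- .grf_factor(points, config$grf_nugget, config$grf_psill,
                    config$grf_range)
  t_weeks <- as.numeric(config$dates - config$dates[1]) / 7
  out <- vector("list", length(config$dates))
  for (k in seq_along(config$dates)) {
    set.seed(.date_seed(config$seed, k))
    trend <- config$phase_at_origin +
      config$weekly_advance * t_weeks[k] +
      config$altitude_delay * points$altitude
    G <- drop(Lf %*% stats::rnorm(n))
    latent <- trend + G
    if (config$quadrat_sd > 0) {
      q <- matrix(stats::rnorm(n * config$n_quadrats, mean = latent,
                               sd = config$quadrat_sd),
                  nrow = n)
      obs <- rowMeans(q)
    } else {
      obs <- latent
    }
    clamped <- obs < 0 | obs > 4
    obs <- pmin(pmax(obs, 0), 4)
    ds <- pheno_dataset(points, obs, config$dates[k])
    attr(ds, "latent") <- latent
    attr(ds, "clamped") <- clamped
    out[[k]] <- ds
  }
  stats::setNames(out, format(config$dates))
}

#' Simulate a daily airborne pollen series
#'
#' Daily counts are proportional to the fraction of the latent
#' phenology field inside the full-flowering band \[1.5, 2.5\],
#' linearly interpolated between observation dates, times multiplicative
#' lognormal noise (median-preserving).  Deterministic under the config
#' seed.
#'
#' @param datasets Output of [simulate_phenology()] (the latent fields
#'   attached as attributes are used).
#' @param config A [simulation_config()].
#' @return A `pollen_series` spanning the observation dates.
#' @export
simulate_pollen <- function(datasets, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(datasets) < 1) stop("need at least one date", call. = FALSE)
  dates <- as.Date(names(datasets))
  frac <- vapply(datasets, function(ds) {
    z <- attr(ds, "latent")
    if (is.null(z)) z <- ds$values
    base::mean(z >= 1.5 & z <= 2.5)
  }, numeric(1))
  days <- seq(min(dates), max(dates), by = 1)
  daily_frac <- if (length(dates) == 1) {
    rep(frac, length(days))
  } else {
    stats::approx(as.numeric(dates), frac, xout = as.numeric(days))$y
  }
  set.seed(.date_seed(config$seed, length(datasets) + 1L))
  noise <- if (config$pollen_noise_sd > 0) {
    exp(stats::rnorm(length(days), 0, config$pollen_noise_sd))
  } else {
    rep(1, length(days))
  }
  as_pollen_series(data.frame(
    date = days, count = config$pollen_scale * daily_frac * noise))
}
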