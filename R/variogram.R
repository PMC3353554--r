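#' Empirical semivariogram by the method of moments
#'
#' Bins all point pairs by Euclidean separation into `n_lags` uniform
#' distance classes on `(0, max_lag]` and computes, per class,
#' `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` over the pairs falling in
#' the class.  The reported lag of a class is the mean pair distance
#' within it; empty classes are dropped.
#'
#' @param dataset A [pheno_dataset()] (or a list with `points` and
#'   `values`).
#' @param n_lags Number of uniform distance classes (default 6 — with a
#'   ten-point network there are at most 45 pairs to spread).
#' @param max_lag Upper cut-off distance in metres; defaults to the
#'   maximum pairwise distance.
#' @return An object of class `"empirical_variogram"`: a data.frame with
#'   columns `lag` (metres), `gamma` (phase squared) and `np`
#'   (pair count), plus attributes `max_lag`, `n_lags`, `n_points`,
#'   `z_var`.
#' @export
empirical_semivariogram <- function(dataset, n_lags = 6, max_lag = NULL) {
  pts <- dataset$points
  z <- as.numeric(dataset$values)
  n <- length(z)
  if (n < 3) stop("need at least 3 points for a semivariogram", call. = FALSE)
  D <- point_distances(pts)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  dz2 <- (z[iu[, 1]] - z[iu[, 2]])^2
  zero <- d == 0
  if (any(zero)) {
    warning(sum(zero), " coincident point pair(s) dropped from the ",
            "semivariogram (zero separation)")
    d <- d[!zero]; dz2 <- dz2[!zero]
  }
  if (!length(d)) stop("no pairs with positive separation", call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(d)
  if (max_lag <= 0) stop("`max_lag` must be positive", call. = FALSE)
  if (n_lags < 1) stop("`n_lags` must be at least 1", call. = FALSE)

  keep <- d <= max_lag
  d <- d[keep]; dz2 <- dz2[keep]
  if (!length(d)) stop("no pairs within `max_lag`", call. = FALSE)
  breaks <- (0:n_lags) * (max_lag / n_lags)
  breaks[n_lags + 1] <- max_lag          # exact upper edge
  bin <- findInterval(d, breaks, left.open = TRUE)  # (breaks[k], breaks[k+1]]
  bin <- pmin(pmax(bin, 1L), n_lags)
  lag <- tapply(d, bin, mean)
  gamma <- tapply(dz2, bin, function(v) sum(v) / (2 * length(v)))
  np <- tapply(dz2, bin, length)
  out <- data.frame(lag = as.numeric(lag), gamma = as.numeric(gamma),
                    np = as.integer(np))
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 1 && n_lags > 1) {
    warning("all pairs fall in a single distance class")
  }
  structure(out,
            class = c("empirical_variogram", "data.frame"),
            max_lag = max_lag, n_lags = n_lags, n_points = n,
            z_var = if (n > 1) stats::var(z) else 0)
}

#' Gaussian semivariogram model value
#'
#' `gamma(h) = C0 + C (1 - exp(-(h / A0)^2))` for `h > 0`, and 0 at
#' `h = 0` (the semivariogram is 0 at zero lag by definition; the nugget
#' `C0` is the limit from above).  Effective range is `sqrt(3) A0`.
#'
#' @param h Lag distance(s) in metres, non-negative.
#' @param nugget Nugget variance C0 (phase squared).
#' @param psill Structural (partial) sill C (phase squared).
#' @param range_param Range parameter A0 in metres.
#' @return Semivariance value(s), phase squared.
#' @export
#' @examples
#' gaussian_model_value(2000, nugget = 0.05, psill = 0.3, range_param = 2000)
gaussian_model_value <- function(h, nugget, psill, range_param) {
  if (any(h < 0)) stop("lag distances must be non-negative", call. = FALSE)
  ifelse(h == 0, 0, nugget + psill * (1 - exp(-(h / range_param)^2)))
}

#' Construct a fitted (or hand-specified) variogram model
#'
#' @param kind One of `"gaussian"`, `"spherical"`, `"exponential"`.
#' @param nugget Nugget C0 >= 0 (phase squared).
#' @param psill Structural sill C >= 0 (phase squared).
#' @param range_param Range parameter A0 > 0, metres (may be `NA` for a
#'   pure-nugget model).
#' @param r2,rss Fit statistics (optional).
#' @param flags Character vector of fit flags.
#' @return An object of class `"variogram_model"`.
#' @export
variogram_model <- function(kind = c("gaussian", "spherical", "exponential"),
                            nugget, psill, range_param,
                            r2 = NA_real_, rss = NA_real_,
                            flags = character(0)) {
  kind <- match.arg(kind)
  if (nugget < 0 || psill < 0) {
    stop("nugget and partial sill must be non-negative", call. = FALSE)
  }
  if (psill > 0 && (!is.finite(range_param) || range_param <= 0)) {
    stop("range parameter must be positive when the structural sill is ",
         "positive", call. = FALSE)
  }
  structure(list(kind = kind, nugget = nugget, psill = psill,
                 range_param = range_param, r2 = r2, rss = rss,
                 flags = flags),
            class = "variogram_model")
}

#' Total sill (C0 + C) of a variogram model
#' @param model A `variogram_model`.
#' @return The sill in phase squared.
#' @export
model_sill <- function(model) model$nugget + model$psill

#' Effective range of a variogram model
#'
#' The lag at which the model reaches ~95% of its sill: `sqrt(3) A0`
#' for the Gaussian model, `A0` for the spherical, `3 A0` for the
#' exponential.
#' @param model A `variogram_model`.
#' @return Metres (`NA` for a pure-nugget model).
#' @export
effective_range <- function(model) {
  if (model$psill == 0 || !is.finite(model$range_param)) return(NA_real_)
  switch(model$kind,
         gaussian = sqrt(3) * model$range_param,
         spherical = model$range_param,
         exponential = 3 * model$range_param)
}

#' Evaluate a variogram model at lag distances
#'
#' @param h Non-negative lag distance(s), metres.
#' @param model A `variogram_model`.
#' @return Semivariance value(s); 0 at `h = 0`.
#' @export
variogram_model_value <- function(h, model) {
  if (any(h < 0)) stop("lag distances must be non-negative", call. = FALSE)
  C0 <- model$nugget; C <- model$psill; a <- model$range_param
  if (C == 0) return(ifelse(h == 0, 0, C0))
  g <- switch(model$kind,
    gaussian = C0 + C * (1 - exp(-(h / a)^2)),
    exponential = C0 + C * (1 - exp(-h / a)),
    spherical = ifelse(h >= a, C0 + C,
                       C0 + C * (1.5 * h / a - 0.5 * (h / a)^3)))
  ifelse(h == 0, 0, g)
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(paste0("<variogram_model> %s: nugget C0 = %.4g, ",
                     "partial sill C = %.4g, range A0 = %.4g m\n"),
              x$kind, x$nugget, x$psill, x$range_param))
  cat(sprintf("  sill = %.4g, effective range = %.4g m\n",
              model_sill(x), effective_range(x)))
  if (is.finite(x$r2) || is.finite(x$rss)) {
    cat(sprintf("  fit: r2 = %.4f, RSS = %.4g\n", x$r2, x$rss))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Weighted RSS of a model against empirical bins (gamma evaluated at
# the bins' positive lags).
.variogram_rss <- function(emp, model, w) {
  sum(w * (emp$gamma - variogram_model_value(emp$lag, model))^2)
}

#' Fit an isotropic variogram model by least squares
#'
#' Fits the three parameters (nugget C0, structural sill C, range A0) of
#' an isotropic model to empirical semivariogram bins by bounded
#' Levenberg-Marquardt least squares, minimising
#' `RSS = sum w_k (gamma_hat_k - gamma(h_k))^2` with `w = 1`
#' (`weighting = "none"`, the default) or `w = N(h_k)`
#' (`weighting = "pairs"`).  Initialisation is a deterministic
#' multi-start (C0 = 0, C = the data variance, A0 at 1/4, 1/2 and 1
#' times the maximum lag); a pure-nugget candidate (C = 0, C0 = the
#' weighted mean semivariance) is always evaluated as well and wins when
#' it has the lowest RSS, so the fitted RSS never exceeds the
#' pure-nugget RSS.  `r2 = 1 - RSS / TSS` with TSS about the weighted
#' mean of the empirical semivariances.
#'
#' @param emp An [empirical_semivariogram()] result with at least 3
#'   non-empty bins.
#' @param kind Model family; the default `"gaussian"` suits very
#'   continuous fields such as phenology.
#' @param weighting `"none"` or `"pairs"`.
#' @return A [variogram_model()] with `r2`, `rss` and any flags
#'   (`"pure_nugget"`, `"degenerate_flat"`).
#' @export
fit_variogram <- function(emp,
                          kind = c("gaussian", "spherical", "exponential"),
                          weighting = c("none", "pairs")) {
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  stopifnot(inherits(emp, "empirical_variogram") || is.data.frame(emp))
  if (nrow(emp) < 3) {
    stop("need at least 3 non-empty bins to fit 3 parameters", call. = FALSE)
  }
  w <- if (weighting == "pairs") as.numeric(emp$np) else rep(1, nrow(emp))
  gbar <- sum(w * emp$gamma) / sum(w)
  tss <- sum(w * (emp$gamma - gbar)^2)

  # pure-nugget candidate: flat model at the weighted mean semivariance
  nug_model <- variogram_model(kind, nugget = gbar, psill = 0,
                               range_param = NA_real_,
                               flags = "pure_nugget")
  nug_rss <- .variogram_rss(emp, nug_model, w)

  if (tss <= max(1e-24, 1e-12 * gbar^2)) {
    nug_model$rss <- nug_rss
    nug_model$r2 <- NA_real_
    nug_model$flags <- c("pure_nugget", "degenerate_flat")
    return(nug_model)
  }

  max_lag <- attr(emp, "max_lag")
  if (is.null(max_lag)) max_lag <- max(emp$lag)
  c_start <- attr(emp, "z_var")
  if (is.null(c_start) || !is.finite(c_start) || c_start <= 0) {
    c_start <- max(emp$gamma)
  }
  model_fun <- function(par, h) {
    variogram_model_value(h, list(kind = kind, nugget = par[1],
                                  psill = par[2], range_param = par[3]))
  }
  sw <- sqrt(w)
  best <- NULL
  best_rss <- Inf
  for (a0 in c(0.25, 0.5, 1) * max_lag) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(0, c_start, a0),
        lower = c(0, 0, 1e-9 * max_lag),
        upper = c(Inf, Inf, 10 * max_lag),
        fn = function(par) sw * (emp$gamma - model_fun(par, emp$lag)),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best_rss) {
      best <- unname(fit$par)
      best_rss <- rss
    }
  }
  if (is.null(best)) {
    stop("variogram fit failed to converge from every start", call. = FALSE)
  }
  # A Gaussian with A0 far below the smallest lag is indistinguishable
  # from a flat model on the bins; prefer the explicit pure-nugget
  # solution unless the structured fit is genuinely better.
  if (best_rss < nug_rss - 1e-9 * max(nug_rss, 1e-12) && best[2] > 0) {
    model <- variogram_model(kind, nugget = best[1], psill = best[2],
                             range_param = best[3])
    model$rss <- best_rss
  } else {
    model <- nug_model
    model$rss <- nug_rss
  }
  model$r2 <- max(0, min(1, 1 - model$rss / tss))
  model
}

#' Plot an empirical semivariogram with an optional fitted model
#'
#' @param x An `empirical_variogram`.
#' @param model Optional `variogram_model` to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  graphics::plot(x$lag, x$gamma, pch = 16,
                 xlab = "lag h (m)",
                 ylab = expression(hat(gamma)(h) ~ "(phase"^2 * ")"),
                 ylim = c(0, max(x$gamma) * 1.1), ...)
  if (!is.null(model)) {
    hh <- seq(1e-6, max(x$lag), length.out = 200)
    graphics::lines(hh, variogram_model_value(hh, model), col = "steelblue")
  }
  invisible(x)
}
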