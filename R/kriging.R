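# Covariance function implied by a variogram model:
# Cov(h) = (C0 + C) - gamma(h), so Cov(0) = C0 + C and, for the
# Gaussian model, Cov(h > 0) = C exp(-(h/A0)^2).
model_covariance <- function(h, model) {
  model_sill(model) - variogram_model_value(h, model)
}

# Covariance matrix of the data locations, and a singularity check
# that names colliding points.
.kriging_matrix <- function(points, model) {
  D <- point_distances(points)
  C <- model_covariance(D, model)
  dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  list(C = C, dup = dup, D = D)
}

.solve_kriging <- function(Cmat, rhs, points, model) {
  out <- tryCatch(solve(Cmat, rhs), error = function(e) e)
  if (inherits(out, "error")) {
    D <- point_distances(points)
    dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
    if (nrow(dup) && model$nugget == 0) {
      pairs <- apply(dup, 1, function(ij) {
        paste0(points$id[ij[1]], " / ", points$id[ij[2]])
      })
      stop("singular kriging system: coincident points with zero nugget (",
           paste(pairs, collapse = "; "), ")", call. = FALSE)
    }
    stop("singular kriging system: ", conditionMessage(out), call. = FALSE)
  }
  out
}

#' Simple kriging prediction at a target location
#'
#' Solves the simple-kriging system `C lambda = c` for the weights,
#' where `C_ij` is the model covariance between data locations and
#' `c_i` the covariance between datum i and the target
#' (`Cov(h) = sill - gamma(h)`, so `Cov(0)` includes the nugget).  The
#' estimate is `Z* = sum lambda_i Z(x_i) + m (1 - sum lambda_i)` with
#' `m` the known stationary mean, and the kriging variance is
#' `sill - lambda' c` (clipped at 0 within a 1e-10 tolerance).
#'
#' @param target Numeric `c(x, y)` location in metres.
#' @param dataset A [pheno_dataset()].
#' @param model A fitted [variogram_model()].
#' @param mean The stationary mean m.  Defaults to the arithmetic mean
#'   of the dataset values; `"median"` uses their median instead.
#' @param nugget_as_error Treat the nugget as measurement error
#'   (filtered kriging): the target-to-datum covariance at zero
#'   distance then excludes the nugget, so predictions smooth rather
#'   than honour the data.  Default `FALSE`.
#' @return An object of class `"kriging_estimate"`: list with
#'   `location`, `estimate`, `variance`, `weights` (named by point id)
#'   and `weight_sum`.
#' @export
#' @examples
#' pts <- as_sampling_points(data.frame(
#'   id = c("a", "b", "c"), x = c(0, 1000, 0), y = c(0, 0, 1000),
#'   altitude = 100, zone = "termomediterranean"))
#' ds <- pheno_dataset(pts, c(1, 2, 3), "2004-04-23")
#' mod <- variogram_model("gaussian", nugget = 0, psill = 0.5,
#'                        range_param = 800)
#' simple_kriging(c(500, 500), ds, mod)
simple_kriging <- function(target, dataset, model, mean = NULL,
                           nugget_as_error = FALSE) {
  stopifnot(inherits(model, "variogram_model"))
  pts <- dataset$points
  z <- as.numeric(dataset$values)
  n <- length(z)
  if (n < 1) stop("need at least one datum", call. = FALSE)
  target <- as.numeric(target)
  if (length(target) != 2 || anyNA(target)) {
    stop("`target` must be a finite (x, y) pair", call. = FALSE)
  }
  m <- .stationary_mean(mean, z)

  km <- .kriging_matrix(pts, model)
  h0 <- sqrt((pts$x - target[1])^2 + (pts$y - target[2])^2)
  cvec <- model_covariance(h0, model)
  if (nugget_as_error && any(h0 == 0)) {
    cvec[h0 == 0] <- model$psill
  }
  lambda <- drop(.solve_kriging(km$C, cvec, pts, model))
  est <- sum(lambda * z) + m * (1 - sum(lambda))
  v <- model_sill(model) - sum(lambda * cvec)
  if (v < 0) {
    if (v < -1e-10) {
      warning(sprintf("negative kriging variance %.3g clipped to 0", v))
    }
    v <- 0
  }
  structure(list(location = c(x = target[1], y = target[2]),
                 estimate = est, variance = v,
                 weights = stats::setNames(lambda, pts$id),
                 weight_sum = sum(lambda), mean = m),
            class = "kriging_estimate")
}

.stationary_mean <- function(mean, z) {
  if (is.null(mean)) return(base::mean(z))
  if (identical(mean, "median")) return(stats::median(z))
  if (identical(mean, "mean")) return(base::mean(z))
  if (is.numeric(mean) && length(mean) == 1 && is.finite(mean)) return(mean)
  stop("`mean` must be NULL, a number, \"mean\" or \"median\"",
       call. = FALSE)
}

#' @export
print.kriging_estimate <- function(x, ...) {
  cat(sprintf(paste0("<kriging_estimate> at (%.1f, %.1f): Z* = %.4f, ",
                     "variance = %.4g, sum(lambda) = %.4f\n"),
              x$location[1], x$location[2], x$estimate, x$variance,
              x$weight_sum))
  invisible(x)
}

#' Simple kriging onto a regular grid
#'
#' Predicts at every cell centre of a regular raster over `bbox` and
#' returns a [pheno_grid()].  Estimates are clamped to the phase scale
#' \[0, 4\] after estimation; cells where clamping fired are flagged in
#' the grid's `clamp_flags`.
#'
#' @inheritParams simple_kriging
#' @param bbox `c(xmin, ymin, xmax, ymax)` in metres; defaults to the
#'   data bounding box padded by 5% on each side.
#' @param cellsize Cell size in metres (default 100).
#' @param clamp Clamp estimates to \[0, 4\] (default `TRUE`).
#' @return A [pheno_grid()] whose attribute `"variance"` holds the
#'   kriging variance matrix.
#' @export
krige_grid <- function(dataset, model, mean = NULL, bbox = NULL,
                       cellsize = 100, nugget_as_error = FALSE,
                       clamp = TRUE) {
  stopifnot(inherits(model, "variogram_model"))
  pts <- dataset$points
  z <- as.numeric(dataset$values)
  if (is.null(bbox)) bbox <- default_bbox(pts)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("`bbox` must be c(xmin, ymin, xmax, ymax) with positive extent",
         call. = FALSE)
  }
  if (cellsize <= 0) stop("`cellsize` must be positive", call. = FALSE)
  inside <- pts$x >= bbox[1] & pts$x <= bbox[3] &
    pts$y >= bbox[2] & pts$y <= bbox[4]
  if (!any(inside)) {
    warning("bounding box excludes all data; extrapolating")
  }
  m <- .stationary_mean(mean, z)

  ncols <- max(1L, ceiling((bbox[3] - bbox[1]) / cellsize))
  nrows <- max(1L, ceiling((bbox[4] - bbox[2]) / cellsize))
  xc <- bbox[1] + (seq_len(ncols) - 0.5) * cellsize
  yc <- bbox[2] + (seq_len(nrows) - 0.5) * cellsize  # south to north

  km <- .kriging_matrix(pts, model)
  # covariance of each datum with each cell centre (n x ncell), cells
  # in column-major order over (row of matrix = north first)
  gx <- rep(xc, times = nrows)
  gy <- rep(rev(yc), each = ncols)          # north row first, row-major
  H <- sqrt(outer(pts$x, gx, "-")^2 + outer(pts$y, gy, "-")^2)
  Cc <- model_covariance(H, model)
  if (nugget_as_error && any(H == 0)) {
    Cc[H == 0] <- model$psill
  }
  L <- .solve_kriging(km$C, Cc, pts, model)
  est <- drop(crossprod(L, z)) + m * (1 - colSums(L))
  v <- model_sill(model) - colSums(L * Cc)
  if (any(v < -1e-10)) {
    warning(sprintf("negative kriging variance %.3g clipped to 0", min(v)))
  }
  v[v < 0] <- 0

  vals <- matrix(est, nrow = nrows, ncol = ncols, byrow = TRUE)
  vmat <- matrix(v, nrow = nrows, ncol = ncols, byrow = TRUE)
  clamp_flags <- matrix(FALSE, nrow = nrows, ncol = ncols)
  if (clamp) {
    clamp_flags <- vals < 0 | vals > 4
    vals[vals < 0] <- 0
    vals[vals > 4] <- 4
  }
  g <- pheno_grid(vals, xll = bbox[1], yll = bbox[2], cellsize = cellsize,
                  clamp_flags = clamp_flags, validate = clamp)
  attr(g, "variance") <- vmat
  g
}

#' Default analysis bounding box for a point set
#'
#' The data bounding box padded by 5% of each span on every side — the
#' default map extent.
#' @param points A `sampling_points` table.
#' @return `c(xmin, ymin, xmax, ymax)`.
#' @export
default_bbox <- function(points) {
  rx <- range(points$x); ry <- range(points$y)
  px <- 0.05 * max(diff(rx), 1)
  py <- 0.05 * max(diff(ry), 1)
  c(rx[1] - px, ry[1] - py, rx[2] + px, ry[2] + py)
}
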