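#' Leave-one-out cross-validation of a kriging model
#'
#' Each observation is removed in turn and predicted by simple kriging
#' from the remaining n - 1 points, using the variogram model fitted on
#' the full dataset (the model is not refitted per fold by default —
#' refitting is unstable at the study's n of about 7 — but
#' `refit_per_fold = TRUE` is available).  The stationary mean is
#' recomputed from the retained values in every fold.  The actual
#' values are then regressed on the estimated values by ordinary least
#' squares; the slope is the "regression coefficient" used to score the
#' interpolation (closer to 1 is better).
#'
#' @param dataset A [pheno_dataset()] with at least 4 points.
#' @param model A fitted [variogram_model()].
#' @param mean Mean policy per fold: `NULL`/`"mean"` (arithmetic mean of
#'   retained values) or `"median"`.
#' @param refit_per_fold Refit the variogram on each fold's n - 1
#'   points (default `FALSE`).
#' @param nugget_as_error Passed to [simple_kriging()].
#' @param ... When `refit_per_fold = TRUE`, arguments passed to
#'   [empirical_semivariogram()] (e.g. `n_lags`).
#' @return An object of class `"cv_result"`: list with `pairs`
#'   (data.frame `point_id`, `actual`, `estimated`), `slope`,
#'   `intercept`, `r2`, `rmse`, `bias` (mean of actual - estimated) and
#'   `flags` (`"degenerate"` when the estimates have zero variance and
#'   the regression is undefined).
#' @export
loo_cross_validation <- function(dataset, model, mean = NULL,
                                 refit_per_fold = FALSE,
                                 nugget_as_error = FALSE, ...) {
  stopifnot(inherits(model, "variogram_model"))
  z <- as.numeric(dataset$values)
  pts <- dataset$points
  n <- length(z)
  if (n < 4) {
    stop("leave-one-out cross-validation needs at least 4 points",
         call. = FALSE)
  }
  est <- numeric(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    sub_pts <- pts[keep, , drop = FALSE]
    rownames(sub_pts) <- NULL
    class(sub_pts) <- c("sampling_points", "data.frame")
    sub <- pheno_dataset(sub_pts, z[keep], dataset$date)
    fold_model <- model
    if (refit_per_fold) {
      emp <- empirical_semivariogram(sub, ...)
      fold_model <- fit_variogram(emp, kind = model$kind)
    }
    est[i] <- simple_kriging(c(pts$x[i], pts$y[i]), sub, fold_model,
                             mean = mean,
                             nugget_as_error = nugget_as_error)$estimate
  }
  pairs <- data.frame(point_id = pts$id, actual = z, estimated = est)
  flags <- character(0)
  if (stats::var(est) < 1e-15) {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
    flags <- "degenerate"
  } else {
    fit <- stats::lm(actual ~ estimated, data = pairs)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  }
  structure(list(pairs = pairs, slope = slope, intercept = intercept,
                 r2 = r2, rmse = sqrt(base::mean((z - est)^2)),
                 bias = base::mean(z - est), flags = flags),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> n = %d folds\n", nrow(x$pairs)))
  if (length(x$flags)) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  } else {
    cat(sprintf("  actual ~ estimated: slope %.3f, intercept %.3f, r2 %.3f\n",
                x$slope, x$intercept, x$r2))
  }
  cat(sprintf("  rmse %.4f, bias %.4f (phase units)\n", x$rmse, x$bias))
  invisible(x)
}

#' Cross-validation summary table for several dates
#'
#' Runs [empirical_semivariogram()], [fit_variogram()] and
#' [loo_cross_validation()] for each dataset and returns one row per
#' date with the fitted model parameters and regression scores — the
#' layout of a cross-validation summary table.
#'
#' @param datasets Named list of [pheno_dataset()] objects.
#' @param n_lags,max_lag Passed to [empirical_semivariogram()].
#' @param kind,weighting Passed to [fit_variogram()].
#' @param ... Passed to [loo_cross_validation()].
#' @return A data.frame with one row per date.
#' @export
cross_validate_dates <- function(datasets, n_lags = 6, max_lag = NULL,
                                 kind = "gaussian", weighting = "none",
                                 ...) {
  rows <- lapply(datasets, function(ds) {
    emp <- empirical_semivariogram(ds, n_lags = n_lags, max_lag = max_lag)
    model <- fit_variogram(emp, kind = kind, weighting = weighting)
    cv <- loo_cross_validation(ds, model, ...)
    data.frame(date = format(ds$date), n = length(ds$values),
               nugget = model$nugget, psill = model$psill,
               range_param = model$range_param,
               model_r2 = model$r2, model_rss = model$rss,
               slope = cv$slope, intercept = cv$intercept,
               cv_r2 = cv$r2, rmse = cv$rmse, bias = cv$bias,
               flags = paste(c(model$flags, cv$flags), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
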